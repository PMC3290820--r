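test_that("an exactly representable outcome is captured by its term", {
  set.seed(1)
  n <- 12
  y <- rep_len(c(1, -1), n)              # zero-mean +/-1 target
  X <- cbind(n1 = rnorm(n), hit = y, n2 = rnorm(n))
  m <- fos_select(X, y, fos_config(max_terms = 3))
  expect_identical(m$terms[1], "hit")
  expect_equal(m$residual_mse, 0, tolerance = 1e-12)
  # scores reproduce y exactly
  co <- X[, m$term_idx, drop = FALSE]; colnames(co) <- m$terms
  expect_equal(predict_linear(m, co), y, tolerance = 1e-10)
})

test_that("FOS prefix residuals match the least-squares oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(6:12, 1); J <- sample(3:10, 1)
    X <- matrix(rnorm(n * J), n, J, dimnames = list(NULL, paste0("c", 1:J)))
    y <- sample(c(-1, 1), n, replace = TRUE)
    m <- fos_select(X, y, fos_config(max_terms = 5, min_Q_fraction = 1e-12))
    tr <- mse_trace(m)
    off <- if (m$include_constant) 1 else 0
    for (k in seq_along(m$term_idx)) {
      expect_lt(abs(tr$cumulative_mse[k + off] -
                      ols_resid_mse(X[, m$term_idx[1:k], drop = FALSE], y)),
                1e-10 * m$msq_y)
    }
    # energy conservation <y^2> = sum Q + residual
    expect_equal(m$msq_y, sum(m$Q) + m$residual_mse, tolerance = 1e-9)
  }
})

test_that("each greedy commit is single-step optimal (exhaustive oracle)", {
  for (seed in 1:15) {
    set.seed(100 + seed)
    n <- 10; J <- 8
    X <- matrix(rnorm(n * J), n, J, dimnames = list(NULL, paste0("c", 1:J)))
    y <- sample(c(-1, 1), n, replace = TRUE)
    m <- fos_select(X, y, fos_config(max_terms = 4, min_Q_fraction = 1e-12))
    for (k in seq_along(m$term_idx)) {
      prev <- m$term_idx[seq_len(k - 1)]
      best <- min(vapply(setdiff(seq_len(J), prev), function(j) {
        ols_resid_mse(X[, c(prev, j), drop = FALSE], y)
      }, 0))
      expect_lt(abs(ols_resid_mse(X[, m$term_idx[1:k], drop = FALSE], y) - best),
                1e-9 * m$msq_y)
    }
  }
})

test_that("row permutation leaves the fitted model unchanged", {
  set.seed(42)
  X <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, paste0("c", 1:6)))
  y <- sample(c(-1, 1), 10, replace = TRUE)
  m1 <- fos_select(X, y, fos_config(max_terms = 4))
  perm <- sample(10)
  m2 <- fos_select(X[perm, ], y[perm], fos_config(max_terms = 4))
  expect_identical(m1$terms, m2$terms)
  expect_equal(m1$a, m2$a, tolerance = 1e-10)
  expect_equal(m1$Q, m2$Q, tolerance = 1e-10)
})

test_that("duplicate and dependent candidates are excluded, never re-committed", {
  set.seed(8)
  n <- 10
  base <- rnorm(n)
  X <- cbind(a = base, b = base, c = 2 * base, d = rnorm(n))
  y <- sample(c(-1, 1), n, replace = TRUE)
  m <- fos_select(X, y, fos_config(max_terms = 4, min_Q_fraction = 1e-12))
  expect_equal(anyDuplicated(m$terms), 0)
  # b and c are linear in a (after a is committed they carry no energy)
  expect_false(all(c("a", "b") %in% m$terms) || all(c("a", "c") %in% m$terms))
  # a wins any a/b/c tie by lowest index
  expect_false("b" %in% m$terms[1])

  # all-dependent candidate set -> constant-only model with warning
  Xdep <- cbind(u = rep(1, n), v = rep(2, n))
  expect_warning(mdep <- fos_select(Xdep, y, fos_config(max_terms = 2)),
                 "dependent")
  expect_length(mdep$terms, 0)
  expect_true(mdep$include_constant)
})

test_that("stopping rules: cap, floor, significance gate", {
  set.seed(9)
  n <- 40; J <- 8
  X <- matrix(rnorm(n * J), n, J, dimnames = list(NULL, paste0("c", 1:J)))
  y <- sample(c(-1, 1), n, replace = TRUE)
  expect_lte(length(fos_select(X, y, fos_config(max_terms = 2))$terms), 2)
  mfloor <- fos_select(X, y, fos_config(max_terms = 8, min_Q_fraction = 0.9))
  expect_equal(mfloor$stop_reason, "Q_floor")
  mgate <- fos_select(X, y, fos_config(max_terms = 8, significance_alpha = 1e-6))
  expect_equal(mgate$stop_reason, "not_significant")
  expect_lte(length(mgate$terms), length(fos_select(X, y, fos_config(max_terms = 8))$terms))
})

test_that("the significance gate rejects pure-noise candidate sets", {
  zero <- vapply(1:25, function(s) {
    set.seed(500 + s)
    X <- matrix(rlnorm(200 * 12), 200, 12,
                dimnames = list(NULL, paste0("m", 1:12)))
    cand <- build_candidate_set(apply_normalization(fit_normalization(X), X))
    y <- sample(c(-1, 1), 200, replace = TRUE)
    length(fos_select(cand, y, fos_config(significance_alpha = 0.05))$terms) == 0
  }, TRUE)
  expect_gte(mean(zero), 0.9)
})

test_that("mse_trace is non-increasing with non-negative Q", {
  set.seed(10)
  X <- matrix(rnorm(14 * 10), 14, 10, dimnames = list(NULL, paste0("c", 1:10)))
  y <- sample(c(-1, 1), 14, replace = TRUE)
  m <- fos_select(X, y, fos_config(max_terms = 6))
  tr <- mse_trace(m)
  expect_true(all(m$Q >= 0))
  expect_true(all(diff(tr$cumulative_mse) <= 1e-12))
  expect_equal(tr$cumulative_mse[nrow(tr)], m$residual_mse, tolerance = 1e-12)
})

test_that("predict_linear validates coordinates and handles edge cases", {
  set.seed(2)
  X <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("c", 1:4)))
  y <- sample(c(-1, 1), 10, replace = TRUE)
  m <- fos_select(X, y, fos_config(max_terms = 2))
  k <- length(m$terms)
  expect_error(predict_linear(m, X), "do not match")
  zero <- matrix(0, 3, k, dimnames = list(NULL, m$terms))
  expect_equal(predict_linear(m, zero), rep(m$a[1], 3))
  # residual of training scores equals the model residual MSE
  co <- X[, m$term_idx, drop = FALSE]; colnames(co) <- m$terms
  expect_equal(mean((y - predict_linear(m, co))^2), m$residual_mse,
               tolerance = 1e-10)
})

test_that("input validation", {
  X <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fos_select(X, c(1, -1)), "match")
  expect_error(fos_select(X, c(1, -1, 0, 1)), "-1/\\+1")
  expect_error(fos_select(X[0, , drop = FALSE], numeric(0)), "no patients")
})
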