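test_that("range normalization maps training extremes to the bounds", {
  m <- matrix(c(2, 4, 6), ncol = 1, dimnames = list(NULL, "x"))
  nz <- fit_normalization(m)
  out <- apply_normalization(nz, m)
  expect_equal(as.vector(out), c(0.02, 6.76, 13.5))

  # fitted map extrapolates without clipping: 0.02 + 13.48 * (3 - 1)/(2 - 1)
  m2 <- matrix(c(1, 2), ncol = 1, dimnames = list(NULL, "x"))
  nz2 <- fit_normalization(m2)
  expect_equal(as.vector(apply_normalization(nz2, matrix(3, 1, 1,
    dimnames = list(NULL, "x")))), 26.98)

  # constant marker: midpoint with degenerate flag and warning
  mc <- matrix(c(5, 5, 1, 2), ncol = 2, dimnames = list(NULL, c("c", "v")))
  expect_warning(nzc <- fit_normalization(mc), "constant")
  expect_true(nzc$degenerate[["c"]])
  expect_false(nzc$degenerate[["v"]])
  expect_equal(as.vector(apply_normalization(nzc, mc)[, "c"]), c(6.76, 6.76))
})

test_that("fit -> apply spans [0.02, 13.5] per column on training data", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rlnorm(12 * 8, sdlog = 1), 8, 12,
                dimnames = list(NULL, cbc_marker_names()))
    out <- apply_normalization(fit_normalization(m), m)
    expect_equal(unname(apply(out, 2, min)), rep(0.02, 12))
    expect_equal(unname(apply(out, 2, max)), rep(13.5, 12))
  }
})

test_that("normalization validates input", {
  m <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_normalization(m[1, , drop = FALSE]), "at least 2")
  m[1, 1] <- NA
  expect_error(fit_normalization(m), "non-finite.*a")
  nz <- fit_normalization(matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "b"))))
  expect_error(apply_normalization(nz, matrix(1, 1, 1, dimnames = list(NULL, "a"))),
               "missing marker")
})

test_that("candidate set counts p + p(p+1)/2 terms for p in 1..16", {
  set.seed(7)
  for (p in 1:16) {
    x <- matrix(runif(6 * p), 6, p, dimnames = list(NULL, paste0("m", p, "_", 1:p)))
    cs <- build_candidate_set(x)
    expect_equal(nrow(cs$terms), p + p * (p + 1) / 2)
    expect_equal(sum(cs$terms$kind == "first_order"), p)
    expect_equal(ncol(cs$values), nrow(cs$terms))
  }
})

test_that("the 12-marker algebra has 90 terms named by the A*B convention", {
  set.seed(1)
  x <- matrix(rlnorm(5 * 12), 5, 12, dimnames = list(NULL, cbc_marker_names()))
  cs <- build_candidate_set(x)
  expect_equal(nrow(cs$terms), 90)
  expect_equal(sum(cs$terms$kind == "cross_product"), 78)
  expect_equal(sum(cs$terms$i == cs$terms$j & cs$terms$kind == "cross_product"), 12)
  expect_true("PLT28*ANC28" %in% cs$terms$name)
  expect_identical(cs$terms$name[1:12], cbc_marker_names())
})

test_that("cross-product columns equal elementwise products (oracle)", {
  set.seed(3)
  x <- matrix(rlnorm(9 * 5), 9, 5, dimnames = list(NULL, letters[1:5]))
  cs <- build_candidate_set(x)
  for (k in which(cs$terms$kind == "cross_product")) {
    expect_equal(cs$values[, k], x[, cs$terms$i[k]] * x[, cs$terms$j[k]],
                 ignore_attr = TRUE)
  }
  # squares: normalized value 3 -> 9
  x2 <- matrix(c(3, 1), 2, 1, dimnames = list(NULL, "ANC0"))
  expect_equal(build_candidate_set(x2)$values[1, "ANC0*ANC0"], 9,
               ignore_attr = TRUE)
})

test_that("two markers expand to the five expected terms", {
  x <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "b")))
  cs <- build_candidate_set(x)
  expect_identical(cs$terms$name, c("a", "b", "a*a", "a*b", "b*b"))
})

test_that("candidate ordering is deterministic", {
  set.seed(11)
  x <- matrix(rlnorm(8 * 12), 8, 12, dimnames = list(NULL, cbc_marker_names()))
  expect_identical(build_candidate_set(x), build_candidate_set(x))
  expect_error(build_candidate_set(cbind(x, x[, 1, drop = FALSE])), "duplicate")
})

test_that("projection onto selected terms", {
  set.seed(5)
  x <- matrix(rlnorm(7 * 12), 7, 12, dimnames = list(NULL, cbc_marker_names()))
  co <- project_selected(published_terms(), x)
  expect_equal(dim(co), c(7, 11))
  expect_equal(colnames(co), published_terms())
  expect_equal(co[, "PLT28*ANC28"], x[, "PLT28"] * x[, "ANC28"],
               ignore_attr = TRUE)
  # single first-order term is the marker column itself
  expect_equal(project_selected("ANC0", x)[, 1], x[, "ANC0"], ignore_attr = TRUE)
  # empty list -> zero-column matrix
  expect_equal(dim(project_selected(character(0), x)), c(7, 0))
  expect_error(project_selected("NOPE", x), "unknown term")
  # unordered pair labels are canonicalized
  expect_equal(parse_terms("ANC28*PLT28")$name, "PLT28*ANC28")
})

test_that("patient CSV round trip and rejection of incomplete records", {
  p <- make_patients(6, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_patients(p, f)
  p2 <- read_patients(f)
  expect_equal(as.data.frame(p2), as.data.frame(p), tolerance = 1e-12)

  raw <- as.data.frame(p)
  raw$anc_d7[2] <- NA
  raw$wbc_d28[4] <- -1
  expect_warning(expect_warning(kept <- as_patients(raw), "anc_d7"), "wbc_d28")
  expect_equal(nrow(kept), 4)
  expect_false(any(c("T02", "T04") %in% kept$patient_id))

  # labels parse from words and signs
  raw2 <- as.data.frame(make_patients(2, labelled = FALSE))
  raw2$risk_label <- c("high", "low")
  expect_equal(as_patients(raw2)$risk_label, c(1, -1))
  raw2$risk_label <- c("+1", "maybe")
  expect_error(as_patients(raw2), "risk_label")
})
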