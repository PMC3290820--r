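#' FOS configuration
#'
#' Controls the greedy search. Selection stops at the first of:
#' \itemize{
#'   \item `max_terms` non-constant terms committed (default 11, the
#'     dimensionality of the published classifier space);
#'   \item best remaining MSE reduction `Q` below
#'     `min_Q_fraction * <y^2>` (absolute floor, default `1e-4`);
#'   \item when `significance_alpha` is finite (opt-in, default off): best
#'     `Q` fails a Bonferroni-corrected chi-square test against the
#'     hypothesis that the candidate is pure noise, i.e.
#'     `Q <= resid_MSE * qchisq(1 - alpha/J, 1) / n` with `J` the
#'     surviving candidate count.
#' }
#' The default dual rule (cap + floor) reproduces the historical
#' behaviour of selecting up to 11 terms from a 14-patient cohort; note
#' that a small absolute floor cannot reject noise terms (a random
#' candidate reduces MSE by about `resid_MSE/n` in expectation, and the
#' best of `J` candidates by more), so on large noisy candidate sets the
#' significance gate is recommended: with it, pure-noise outcomes select
#' zero non-constant terms with probability about `1 - alpha` regardless
#' of candidate count. The gate is deliberately not the default because at
#' very small `n` (e.g. the 14-patient protocol) no term can pass a
#' Bonferroni chi-square test over 90 candidates, and the package could
#' then never reproduce the 11-term protocol.
#' Candidates whose orthogonalized energy `D(m,m)` falls below
#' `epsilon * <p_m^2>` are permanently excluded as linearly dependent on
#' the committed terms.
#'
#' @param max_terms maximum number of non-constant terms (>= 1).
#' @param min_Q_fraction relative MSE-reduction floor (> 0).
#' @param epsilon relative linear-dependence guard (> 0).
#' @param include_constant include the constant term `p_0 = 1` (default
#'   TRUE). The constant is fitted but never counted against `max_terms`
#'   and never used as a classifier coordinate.
#' @param significance_alpha Bonferroni family level for the noise gate in
#'   (0, 1), or NA to disable.
#' @return list of class `fos3nn_config`.
#' @export
fos_config <- function(max_terms = 11, min_Q_fraction = 1e-4, epsilon = 1e-8,
                       include_constant = TRUE, significance_alpha = NA) {
  stopifnot(max_terms >= 1, min_Q_fraction > 0, epsilon > 0,
            is.na(significance_alpha) ||
              (significance_alpha > 0 && significance_alpha < 1))
  structure(list(max_terms = as.integer(max_terms),
                 min_Q_fraction = min_Q_fraction, epsilon = epsilon,
                 include_constant = isTRUE(include_constant),
                 significance_alpha = significance_alpha),
            class = "fos3nn_config")
}

#' Fast Orthogonal Search term selection
#'
#' Greedy forward selection of model terms for
#' `y(n) = sum_m a_m p_m(n) + e(n)`, `y in {-1, +1}`. At each step every
#' surviving candidate is scored by the reduction in mean-squared error,
#' `Q_m = g_m^2 D(m,m)`, it would achieve if orthogonalized against the
#' committed terms; the maximal-Q candidate is committed (ties broken
#' toward the lowest candidate index). Orthogonalization is implicit via
#' the Cholesky-like recursions on averages over patients `<.>`:
#' \deqn{D(m,r) = <p_m p_r> - \sum_{i<r} \alpha(r,i) D(m,i), \quad
#'       \alpha(m,r) = D(m,r)/D(r,r),}
#' \deqn{C(m) = <y p_m> - \sum_{r<m} \alpha(m,r) C(r), \quad
#'       g_m = C(m)/D(m,m), \quad Q_m = g_m^2 D(m,m),}
#' with `p_0(n) = 1` when the constant is included (so `D(m,0) = <p_m>`,
#' `C(0) = <y>`). No orthogonal basis function is ever materialized: each
#' candidate carries only its cached `D` row against the committed terms,
#' extended by one entry per commit. Final coefficients are recovered by
#' back-substitution `a_m = sum_{i>=m} g_i v_i` with `v_m = 1`,
#' `v_i = -sum_{r=m}^{i-1} alpha(i,r) v_r`.
#'
#' @param candidates a `fos3nn_candidates` object, or a plain numeric
#'   matrix (columns = candidate terms, named).
#' @param y outcome vector in `{-1, +1}`, length = rows of the matrix.
#' @param config a [fos_config()].
#' @return object of class `fos3nn_fos_model`: list with `terms` (selected
#'   non-constant term names in commit order), `term_idx` (their candidate
#'   indices), `a` (coefficients; first entry is the constant's when
#'   included), `g`, `Q`, `D` (diagonal), `alpha` (list of rows),
#'   `residual_mse`, `msq_y`, `include_constant`, `n`, `excluded`
#'   (indices dropped as linearly dependent), `stop_reason`.
#' @export
fos_select <- function(candidates, y, config = fos_config()) {
  X <- if (inherits(candidates, "fos3nn_candidates")) candidates$values else candidates
  stopifnot(is.matrix(X), is.numeric(X))
  n <- nrow(X)
  if (n == 0) stop("no patients")
  if (length(y) != n) stop("length of y must match candidate matrix rows")
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1/+1")
  if (n < 2) stop("need at least 2 patients")
  J <- ncol(X)
  cand_names <- colnames(X) %||% paste0("c", seq_len(J))

  msq_y <- mean(y^2)                      # 1 for +/-1 coding, kept general
  meansq <- colMeans(X^2)
  mean_yp <- as.vector(crossprod(X, y)) / n

  # committed-term bookkeeping; entry 1 may be the constant p0 = 1
  Ddiag <- numeric(0); Cvec <- numeric(0); gvec <- numeric(0); Qvec <- numeric(0)
  alpha <- list(); committed_idx <- integer(0)  # 0 = constant
  DR <- matrix(numeric(0), nrow = J, ncol = 0)  # candidate D rows vs committed
  active <- rep(TRUE, J)
  excluded <- logical(J)

  commit <- function(d, cval, idx) {
    m <- length(Ddiag)
    alpha[[m + 1]] <<- if (m == 0) numeric(0) else DR_committed_row
    Ddiag <<- c(Ddiag, d); Cvec <<- c(Cvec, cval)
    g <- cval / d
    gvec <<- c(gvec, g); Qvec <<- c(Qvec, g^2 * d)
    committed_idx <<- c(committed_idx, idx)
  }
  DR_committed_row <- numeric(0)

  extend_DR <- function(p_new) {
    # D(m, r_new) = <p_m p_new> - sum_{i<r_new} alpha(r_new, i) D(m, i)
    cross <- as.vector(crossprod(X, p_new)) / n
    a_new <- alpha[[length(alpha)]]
    newcol <- if (length(a_new)) cross - as.vector(DR %*% a_new) else cross
    DR <<- cbind(DR, newcol)
  }

  if (config$include_constant) {
    DR_committed_row <- numeric(0)
    commit(1, mean(y), 0L)                # D(0,0) = <1> = 1
    extend_DR(rep(1, n))
  }

  stop_reason <- "max_terms"
  n_terms <- 0L
  while (n_terms < config$max_terms) {
    if (!any(active)) { stop_reason <- "no_candidates"; break }
    idx <- which(active)
    DRa <- DR[idx, , drop = FALSE]
    A <- if (ncol(DRa)) sweep(DRa, 2, Ddiag, "/") else DRa   # alpha(m, r)
    Dmm <- meansq[idx] - if (ncol(DRa)) rowSums(A * DRa) else 0
    dep <- meansq[idx] == 0 | Dmm < config$epsilon * meansq[idx]
    if (any(dep)) {
      active[idx[dep]] <- FALSE
      excluded[idx[dep]] <- TRUE
      idx <- idx[!dep]; A <- A[!dep, , drop = FALSE]; Dmm <- Dmm[!dep]
      if (!length(idx)) next
    }
    Cm <- mean_yp[idx] - if (ncol(A)) as.vector(A %*% Cvec) else 0
    Q <- Cm^2 / Dmm
    best <- which.max(Q)                  # ties: first = lowest index
    resid <- max(msq_y - sum(Qvec), 0)
    if (Q[best] < config$min_Q_fraction * msq_y) { stop_reason <- "Q_floor"; break }
    if (!is.na(config$significance_alpha)) {
      gate <- resid * stats::qchisq(1 - config$significance_alpha / length(idx), 1) / n
      if (Q[best] <= gate) { stop_reason <- "not_significant"; break }
    }
    j <- idx[best]
    DR_committed_row <- DR[j, ] / Ddiag
    commit(Dmm[best], Cm[best], j)
    active[j] <- FALSE
    extend_DR(X[, j])
    n_terms <- n_terms + 1L
  }

  if (n_terms == 0L && config$include_constant && stop_reason == "no_candidates") {
    warning("all candidates linearly dependent; constant-only model", call. = FALSE)
  }

  # back-substitution for the a_m of the final model
  M <- length(Ddiag)
  a <- numeric(M)
  if (M) {
    for (m in seq_len(M)) {
      v <- numeric(M); v[m] <- 1
      if (m < M) for (i in (m + 1):M) {
        v[i] <- -sum(vapply((m):(i - 1), function(r) alpha[[i]][r] * v[r], 0))
      }
      a[m] <- sum(gvec[m:M] * v[m:M])
    }
  }

  sel <- committed_idx != 0L
  structure(list(
    terms = cand_names[committed_idx[sel]],
    term_idx = committed_idx[sel],
    include_constant = config$include_constant,
    a = a, g = gvec, Q = Qvec, D = Ddiag, alpha = alpha,
    C = Cvec,
    residual_mse = max(msq_y - sum(Qvec), 0),
    msq_y = msq_y, n = n,
    excluded = which(excluded),
    stop_reason = stop_reason,
    config = config), class = "fos3nn_fos_model")
}

#' Linear model scores from a fitted FOS model
#'
#' Diagnostic real-valued scores `a_0 + sum_m a_m p_m(n)`; classification
#' itself is done by the nearest-neighbour stage, not by thresholding
#' these.
#'
#' @param model a `fos3nn_fos_model`.
#' @param coordinates matrix whose columns are the model's selected terms,
#'   in model order (see [project_selected()]).
#' @return numeric score vector.
#' @export
predict_linear <- function(model, coordinates) {
  stopifnot(inherits(model, "fos3nn_fos_model"), is.matrix(coordinates))
  k <- length(model$terms)
  if (ncol(coordinates) != k) stop("coordinate columns do not match model terms")
  if (!is.null(colnames(coordinates)) && k > 0 &&
      !identical(colnames(coordinates), model$terms)) {
    stop("coordinate column names do not match model terms")
  }
  a <- model$a
  a0 <- if (model$include_constant) a[1] else 0
  at <- if (model$include_constant) a[-1] else a
  as.vector(a0 + if (k) coordinates %*% at else 0)
}

#' Per-term MSE reduction trace
#'
#' @param model a `fos3nn_fos_model`.
#' @return data.frame with one row per committed term (the constant listed
#'   as `"(const)"`): `term`, `Q` (MSE reduction) and `cumulative_mse`
#'   (`<y^2> - sum of Q so far`), non-increasing down the rows.
#' @export
mse_trace <- function(model) {
  stopifnot(inherits(model, "fos3nn_fos_model"))
  labels <- if (model$include_constant) c("(const)", model$terms) else model$terms
  data.frame(term = labels, Q = model$Q,
             cumulative_mse = model$msq_y - cumsum(model$Q),
             stringsAsFactors = FALSE)
}

#' @export
print.fos3nn_fos_model <- function(x, ...) {
  cat(sprintf("FOS model: %d term(s)%s, residual MSE %.4g (of <y^2> = %.4g), stop: %s\n",
              length(x$terms),
              if (x$include_constant) " + constant" else "",
              x$residual_mse, x$msq_y, x$stop_reason))
  if (length(x$terms)) {
    tr <- mse_trace(x)
    print(utils::head(tr, 15), row.names = FALSE)
  }
  invisible(x)
}
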