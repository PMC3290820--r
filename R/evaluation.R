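#' 2x2 confusion matrix for +/-1 risk labels
#'
#' Convention: "positive" is the high-risk class (+1). `tp` counts
#' actual-high predicted-high, `fn` actual-high predicted-low, `fp`
#' actual-low predicted-high, `tn` actual-low predicted-low.
#'
#' @param actual,predicted vectors in `{-1, +1}` of equal length, or (for
#'   `confusion_2x2`) the four counts directly.
#' @return object of class `fos3nn_confusion` (list `tp`, `fn`, `fp`,
#'   `tn`).
#' @export
confusion <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (!all(c(actual, predicted) %in% c(-1, 1))) stop("labels must be -1/+1")
  confusion_2x2(sum(actual == 1 & predicted == 1),
                sum(actual == 1 & predicted == -1),
                sum(actual == -1 & predicted == 1),
                sum(actual == -1 & predicted == -1))
}

#' @rdname confusion
#' @param tp,fn,fp,tn non-negative integer cell counts.
#' @export
confusion_2x2 <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  structure(as.list(cells), class = "fos3nn_confusion")
}

# hypergeometric pmf over the feasible range of the tp cell, margins fixed
# (row1 = tp+fn, row2 = fp+tn, col1 = tp+fp). Exact via log-binomials.
hypergeom_pmf <- function(r1, r2, c1) {
  n <- r1 + r2
  a <- max(0, c1 - r2):min(r1, c1)
  p <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  list(a = a, p = p)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric computation with fixed margins. The one-tailed
#' probability sums the tail in the direction of the observed association
#' (tables at least as extreme as observed, toward larger `tp` when the
#' observed association is positive, toward smaller when negative). The
#' two-tailed probability follows the sum-of-small-probabilities rule: all
#' tables whose point probability does not exceed the observed one's
#' (within relative tolerance 1e-9 for floating-point ties).
#'
#' @param m a `fos3nn_confusion`.
#' @return list with `one_tailed`, `two_tailed` probabilities in (0, 1].
#' @export
fisher_exact <- function(m) {
  stopifnot(inherits(m, "fos3nn_confusion"))
  r1 <- m$tp + m$fn; r2 <- m$fp + m$tn; c1 <- m$tp + m$fp
  n <- r1 + r2
  if (n < 1) stop("empty table")
  h <- hypergeom_pmf(r1, r2, c1)
  p_obs <- h$p[match(m$tp, h$a)]
  positive <- m$tp * n >= r1 * c1        # tp >= its expectation under H0
  one <- if (positive) sum(h$p[h$a >= m$tp]) else sum(h$p[h$a <= m$tp])
  two <- sum(h$p[h$p <= p_obs * (1 + 1e-9)])
  list(one_tailed = min(one, 1), two_tailed = min(two, 1))
}

#' Matthews' correlation coefficient (phi)
#'
#' `phi = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, in
#' `[-1, +1]`: +1 for perfect prediction, 0 for chance, -1 for total
#' disagreement. When any margin is zero the coefficient is undefined; 0
#' is returned with attribute `degenerate = TRUE`.
#'
#' @param m a `fos3nn_confusion`.
#' @return numeric scalar in `[-1, 1]`.
#' @export
mcc <- function(m) {
  stopifnot(inherits(m, "fos3nn_confusion"))
  margins <- c(m$tp + m$fp, m$tp + m$fn, m$tn + m$fp, m$tn + m$fn)
  if (any(margins == 0)) return(structure(0, degenerate = TRUE))
  # products of counts can overflow integer range; compute in double
  num <- as.numeric(m$tp) * m$tn - as.numeric(m$fp) * m$fn
  num / exp(sum(log(margins)) / 2)
}

#' Pooled / Welch two-sample t-test
#'
#' Student's pooled-variance t by default (used for marker-wise high- vs
#' low-risk group comparison); Welch's unpooled variant by flag. Two-sided
#' p from the t distribution.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 finite values.
#' @param pooled use the pooled-variance Student statistic (default TRUE);
#'   FALSE gives Welch with Satterthwaite degrees of freedom.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(group_a, group_b, pooled = TRUE) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 finite values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (pooled) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    t <- 0
  } else {
    t <- (mean(a) - mean(b)) / se
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Full evaluation report for a prediction set
#'
#' @param actual,predicted label vectors in `{-1, +1}`.
#' @return object of class `fos3nn_eval`: confusion matrix, Fisher one-
#'   and two-tailed probabilities, Matthews coefficient, `n_correct`,
#'   `n_total`.
#' @export
eval_report <- function(actual, predicted) {
  m <- confusion(actual, predicted)
  f <- fisher_exact(m)
  structure(list(confusion = m,
                 fisher_one_tailed = f$one_tailed,
                 fisher_two_tailed = f$two_tailed,
                 mcc = as.numeric(mcc(m)),
                 n_correct = m$tp + m$tn,
                 n_total = m$tp + m$fn + m$fp + m$tn),
            class = "fos3nn_eval")
}

#' @export
print.fos3nn_confusion <- function(x, ...) {
  cat("          predicted high  predicted low\n")
  cat(sprintf("act high  %14d %14d\n", x$tp, x$fn))
  cat(sprintf("act low   %14d %14d\n", x$fp, x$tn))
  invisible(x)
}

#' @export
print.fos3nn_eval <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("correct: %d / %d (%.1f%%)\n", x$n_correct, x$n_total,
              100 * x$n_correct / x$n_total))
  cat(sprintf("Fisher exact: one-tailed %.3g, two-tailed %.3g\n",
              x$fisher_one_tailed, x$fisher_two_tailed))
  cat(sprintf("Matthews phi: %+.2f\n", x$mcc))
  invisible(x)
}
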