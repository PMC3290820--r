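# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# minimal labelled patient frame with arbitrary but valid CBC values
make_patients <- function(n, seed = 1, labelled = TRUE) {
  set.seed(seed)
  df <- data.frame(patient_id = sprintf("T%02d", seq_len(n)))
  for (col in fos3nn::cbc_marker_columns()) {
    base <- switch(substr(col, 1, 3), wbc = 6, hgb = 130, plt = 250, anc = 4)
    df[[col]] <- round(base * exp(rnorm(n, 0, 0.3)), 2)
  }
  if (labelled) df$risk_label <- rep_len(c(1, -1), n)
  fos3nn::as_patients(df)
}

# an uneventful 6-cycle course, optionally perturbed
make_course <- function(delay_days = rep(0, 6), hospitalization = rep(FALSE, 6),
                        dose_reduction = rep(FALSE, 6),
                        day7_treatment_given = rep(TRUE, 6)) {
  data.frame(cycle = 1:6, delay_days = delay_days,
             hospitalization = hospitalization, dose_reduction = dose_reduction,
             day7_treatment_given = day7_treatment_given)
}

# independent least-squares residual MSE of y on (1, columns of Z)
ols_resid_mse <- function(Z, y) {
  fit <- lm.fit(cbind(1, Z), y)
  mean(fit$residuals^2)
}

# independent Fisher oracle built on stats::dhyper and explicit tail logic
fisher_oracle <- function(tp, fn, fp, tn) {
  r1 <- tp + fn; r2 <- fp + tn; c1 <- tp + fp; n <- r1 + r2
  a <- max(0, c1 - r2):min(r1, c1)
  p <- dhyper(a, r1, r2, c1)
  p_obs <- dhyper(tp, r1, r2, c1)
  positive <- tp * n >= r1 * c1
  one <- if (positive) sum(p[a >= tp]) else sum(p[a <= tp])
  two <- sum(p[p <= p_obs * (1 + 1e-9)])
  list(one = min(one, 1), two = min(two, 1))
}

# phi as the Pearson correlation of the expanded +/-1 label vectors
mcc_oracle <- function(tp, fn, fp, tn) {
  actual <- rep(c(1, 1, -1, -1), c(tp, fn, fp, tn))
  predicted <- rep(c(1, -1, 1, -1), c(tp, fn, fp, tn))
  if (length(unique(actual)) < 2 || length(unique(predicted)) < 2) return(NA_real_)
  suppressWarnings(cor(actual, predicted))
}
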