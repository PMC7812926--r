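REGRESSORS <- c("abp", "lf_hf", "rmssd", "gender")

# design matrix of the four regressors, with validity checks
design_matrix <- function(table, regressors = REGRESSORS) {
  if ("valid" %in% names(table) && any(!table$valid)) {
    stop("cohort contains invalid rows: ",
         paste(table$subject_id[!table$valid], collapse = ", "))
  }
  x <- as.matrix(table[, regressors, drop = FALSE])
  if (any(!is.finite(x)) || any(!is.finite(table$sa))) stop("missing regressors")
  x
}

# sample-sd z-scoring for cohort variables; returns scaler for reuse on test data
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv == 0)) stop("zero variance")
  list(mean = mu, sd = sdv)
}
apply_scaler <- function(x, sc) sweep(sweep(x, 2, sc$mean), 2, sc$sd, "/")

#' Fit the standardized general linear model
#'
#' z-scores the outcome and every regressor column (gender included, coded
#' 1/2) with the sample-sd convention, then fits `Y = X beta + eps` by
#' ordinary least squares without intercept. On standardized variables the
#' coefficients are comparable measures of association strength, and the
#' model R^2 equals the squared in-sample Pearson correlation between fitted
#' and observed Y.
#'
#' @param table a `cohort_table` (or data.frame) with columns `abp`, `lf_hf`,
#'   `rmssd`, `gender`, `sa`, all rows valid.
#' @param regressors regressor column names (default the standard four).
#' @return object of class `glm_fit`: `beta`, `t_stats`, `p_values`, `r2`,
#'   `residuals`, `fitted`, `df`, `scaler_x`, `scaler_y`.
#' @export
fit_glm <- function(table, regressors = REGRESSORS) {
  x <- design_matrix(table, regressors)
  n <- nrow(x); p <- ncol(x)
  if (n < p + 2) stop("underdetermined cohort")
  scx <- fit_scaler(x); scy <- fit_scaler(matrix(table$sa, ncol = 1))
  xz <- apply_scaler(x, scx)
  yz <- (table$sa - scy$mean) / scy$sd
  qr_x <- qr(xz)
  if (qr_x$rank < p) stop("collinear regressors")
  xtx_inv <- chol2inv(qr.R(qr_x))
  beta <- drop(xtx_inv %*% crossprod(xz, yz))
  fitted <- drop(xz %*% beta)
  res <- yz - fitted
  df <- n - p
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- beta / se
  r2 <- 1 - sum(res^2) / sum(yz^2)
  structure(
    list(beta = stats::setNames(beta, regressors),
         t_stats = stats::setNames(tval, regressors),
         p_values = stats::setNames(2 * stats::pt(-abs(tval), df), regressors),
         r2 = r2, residuals = res, fitted = fitted, df = df,
         scaler_x = scx, scaler_y = scy, regressors = regressors),
    class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> standardized OLS, R^2 =", round(x$r2, 4), "\n")
  print(data.frame(beta = round(x$beta, 4), t = round(x$t_stats, 3),
                   p = signif(x$p_values, 3)))
  invisible(x)
}

#' Repeated random-split cross-validation of the anxiety model
#'
#' Draws `n_splits` random train/test partitions (train size `n_train`, test =
#' complement). Each split fits the standardized GLM on the training rows
#' only — the feature and outcome scalers are fit on the training split and
#' applied to the test split, so no information leaks — and predicts the test
#' outcomes back on the raw anxiety-score scale. The predicted score `sap` for
#' a subject is the mean prediction over the splits in which that subject fell
#' in the test set; `r_splits` collects the per-split Pearson correlations
#' between predicted and observed test outcomes.
#'
#' @param table cohort table with valid rows.
#' @param n_splits number of random splits.
#' @param n_train training-set size (test size is `nrow(table) - n_train`).
#' @param seed RNG seed governing all splits.
#' @param regressors regressor columns.
#' @return object of class `cv_result`: `sap` (per-subject mean prediction),
#'   `r_splits`, `r_mean`, `r_sd`, `mean_beta`, `n_splits`, `n_train`, `seed`,
#'   plus `r_pooled` (correlation of pooled sap vs observed).
#' @export
cross_validate <- function(table, n_splits = 1000L, n_train = 75L, seed = 1L,
                           regressors = REGRESSORS) {
  x <- design_matrix(table, regressors)
  y <- table$sa
  n <- nrow(x); p <- ncol(x)
  if (n <= n_train) stop("cohort not larger than the training set")
  if (n_train < p + 2) stop("underdetermined cohort")
  set.seed(as.integer(seed))
  pred_sum <- numeric(n); pred_cnt <- integer(n)
  r_splits <- numeric(n_splits)
  beta_sum <- numeric(p)
  one_split <- function() {
    tr <- sample.int(n, n_train)
    te <- setdiff(seq_len(n), tr)
    scx <- fit_scaler(x[tr, , drop = FALSE])
    scy <- fit_scaler(matrix(y[tr], ncol = 1))
    xz <- apply_scaler(x[tr, , drop = FALSE], scx)
    yz <- (y[tr] - scy$mean) / scy$sd
    beta <- qr.coef(qr(xz), yz)
    pz <- apply_scaler(x[te, , drop = FALSE], scx) %*% beta
    list(te = te, pred = drop(pz) * scy$sd + scy$mean, beta = beta)
  }
  for (s in seq_len(n_splits)) {
    sp <- one_split()
    pred_sum[sp$te] <- pred_sum[sp$te] + sp$pred
    pred_cnt[sp$te] <- pred_cnt[sp$te] + 1L
    beta_sum <- beta_sum + sp$beta
    r_splits[s] <- stats::cor(sp$pred, y[sp$te])
  }
  # every subject must be covered by at least one test set; with 1000 splits
  # of 27/102 a miss has probability ~ (75/102)^1000, but draw extra splits
  # deterministically if it ever happens
  while (any(pred_cnt == 0L)) {
    sp <- one_split()
    pred_sum[sp$te] <- pred_sum[sp$te] + sp$pred
    pred_cnt[sp$te] <- pred_cnt[sp$te] + 1L
  }
  sap <- pred_sum / pred_cnt
  structure(
    list(sap = sap, r_splits = r_splits,
         r_mean = mean(r_splits), r_sd = stats::sd(r_splits),
         r_pooled = stats::cor(sap, y),
         mean_beta = stats::setNames(beta_sum / n_splits, regressors),
         n_splits = n_splits, n_train = n_train, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d splits (train %d): r_mean = %.3f (sd %.3f), r_pooled = %.3f\n",
              x$n_splits, x$n_train, x$r_mean, x$r_sd, x$r_pooled))
  invisible(x)
}

#' Agreement statistics between observed and predicted scores
#'
#' Pearson correlation with two-sided p, paired t-test (on `sap - sa`), and
#' Bland-Altman bias with 1.96-sd limits of agreement.
#'
#' @param sa,sap numeric vectors of equal length (>= 3).
#' @return object of class `agreement_stats`.
#' @export
agreement <- function(sa, sap) {
  sa <- as.numeric(sa); sap <- as.numeric(sap)
  if (length(sa) != length(sap) || length(sa) < 3) stop("need >= 3 pairs")
  if (stats::sd(sa) == 0 || stats::sd(sap) == 0) stop("degenerate agreement")
  ct <- stats::cor.test(sa, sap)
  d <- sap - sa
  if (stats::sd(d) == 0) {
    # constant differences: the paired t is 0/0 (no shift) or infinite
    tt <- list(statistic = c(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf),
               parameter = c(df = length(d) - 1),
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(sap, sa, paired = TRUE)
  }
  bias <- mean(d); s <- stats::sd(d)
  structure(
    list(pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
         t = unname(tt$statistic), df = unname(tt$parameter), t_p = tt$p.value,
         bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s),
    class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement> r = %.3f (p = %.3g); paired t = %.3f (df %d, p = %.3g); bias %.3f [%.3f, %.3f]\n",
              x$pearson_r, x$pearson_p, x$t, x$df, x$t_p,
              x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

# rank-tolerant R^2 via QR projection (defined even for collinear designs)
r2_projection <- function(xz, yz) {
  fitted <- qr.fitted(qr(xz), yz)
  1 - sum((yz - fitted)^2) / sum(yz^2)
}

#' Incremental R-squared of each regressor
#'
#' For each regressor k, `delta_R2[k] = R2(model without k) - R2(full model)`,
#' a non-positive quantity (up to numerical noise) measuring how much
#' explained variance is lost when the regressor is removed. Computed by QR
#' projection so an exactly duplicated regressor yields 0 rather than an
#' error.
#'
#' @param table cohort table with valid rows.
#' @param regressors regressor columns.
#' @return named list: `full_r2` and `delta_r2` (named vector, <= 0 up to noise).
#' @export
incremental_r2 <- function(table, regressors = REGRESSORS) {
  x <- design_matrix(table, regressors)
  xz <- apply_scaler(x, fit_scaler(x))
  yz <- drop(scale(table$sa))
  full <- r2_projection(xz, yz)
  delta <- vapply(seq_along(regressors), function(k) {
    r2_projection(xz[, -k, drop = FALSE], yz) - full
  }, numeric(1))
  list(full_r2 = full,
       delta_r2 = stats::setNames(delta, regressors))
}

#' Steiger's z-test for two dependent correlations sharing one variable
#'
#' Compares `cor(X, A)` and `cor(X, B)` measured on the same n subjects, where
#' `r_ab = cor(A, B)` captures the dependence. Uses Fisher-z transformed
#' correlations with Steiger's (1980) modification of the Dunn-Clark statistic
#' (average squared correlation plugged into the covariance term).
#'
#' @param r_a,r_b the two correlations with the shared variable.
#' @param r_ab correlation between the two predictors.
#' @param n sample size (> 3).
#' @return list with `z` and two-sided `p`.
#' @export
compare_dependent_correlations <- function(r_a, r_b, r_ab, n) {
  if (any(abs(c(r_a, r_b, r_ab)) >= 1)) stop("degenerate correlation")
  if (n <= 3) stop("need n > 3")
  za <- atanh(r_a); zb <- atanh(r_b)
  rm2 <- (r_a^2 + r_b^2) / 2
  f <- min((1 - r_ab) / (2 * (1 - rm2)), 1)
  h <- (1 - f * rm2) / (1 - rm2)
  z <- (za - zb) * sqrt((n - 3) / (2 * (1 - r_ab) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
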