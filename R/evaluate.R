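#' Binarize anxiety scores into high/low labels
#'
#' High contingent state anxiety is a score strictly above the threshold
#' (default 40): `sa = 40 -> 0`, `sa = 41 -> 1`.
#'
#' @param sa numeric anxiety scores.
#' @param threshold cut point; strictly-greater scores are labeled 1.
#' @return integer vector of 0/1 labels.
#' @export
binarize_sa <- function(sa, threshold = 40) {
  if (any(!is.finite(sa))) stop("non-finite scores")
  as.integer(sa > threshold)
}

# trapezoidal/Mann-Whitney AUC: probability a positive outranks a negative,
# ties counting one half (midrank formulation)
auc_mw <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and area
#'
#' Thresholds are placed at the unique score values (plus sentinels); the AUC
#' is the trapezoidal area, identical to the normalized Mann-Whitney U with
#' ties contributing half weight.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return object of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("undefined ROC")
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, numeric(1))
  structure(
    list(thresholds = thr, tpr = tpr, fpr = fpr,
         auc = auc_mw(scores, labels)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)", x$auc, length(x$thresholds)))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("; balanced bootstrap mean %.4f [%.4f, %.4f] (%d iter)",
                x$bootstrap$mean_auc, x$bootstrap$ci[1], x$bootstrap$ci[2],
                x$bootstrap$n_iter))
  }
  cat("\n")
  invisible(x)
}

#' Class-balanced bootstrap of the ROC AUC
#'
#' When the two classes are unbalanced, each bootstrap iteration resamples,
#' with replacement, `m` subjects from each class where `m` is the smaller
#' class size — the minimal intervention that balances the classes — and
#' recomputes the AUC. Reports the bootstrap mean and percentile 95% CI
#' alongside the plug-in (full-sample) AUC.
#'
#' @param scores,labels as in [roc_curve()]; each class needs >= 2 members.
#' @param n_iter bootstrap iterations.
#' @param seed RNG seed.
#' @return `roc_result` with a `bootstrap` element: `n_iter`, `seed`,
#'   `auc_samples`, `mean_auc`, `ci`.
#' @export
balanced_bootstrap_auc <- function(scores, labels, n_iter = 10000L, seed = 1L) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (length(pos) < 2 || length(neg) < 2) stop("each class needs >= 2 members")
  m <- min(length(pos), length(neg))
  set.seed(as.integer(seed))
  bal_labels <- rep(c(1L, 0L), each = m)
  aucs <- vapply(seq_len(n_iter), function(i) {
    s <- c(scores[sample(pos, m, replace = TRUE)],
           scores[sample(neg, m, replace = TRUE)])
    auc_mw(s, bal_labels)
  }, numeric(1))
  out <- roc_curve(scores, labels)
  out$bootstrap <- list(n_iter = n_iter, seed = seed, auc_samples = aucs,
                        mean_auc = mean(aucs),
                        ci = unname(stats::quantile(aucs, c(0.025, 0.975))))
  out
}

# Hanley-McNeil standard error of an AUC
hm_se <- function(a, n1, n0) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) / (n1 * n0))
}

#' Compare two correlated AUCs measured on the same subjects
#'
#' Default is the Hanley-McNeil (1983) paired z-test:
#' `z = (A1 - A2) / sqrt(SE1^2 + SE2^2 - 2 r SE1 SE2)` with the
#' Hanley-McNeil SE formula and `r` taken as the average of the Pearson
#' correlations between the two score sets within the positive and within the
#' negative class (used directly in place of the original printed lookup
#' table). `method = "delong"` uses the DeLong placement-value covariance
#' instead.
#'
#' @param scores_a,scores_b two score vectors for the same subjects.
#' @param labels 0/1 labels.
#' @param method `"hanley-mcneil"` (default) or `"delong"`.
#' @return list with `auc_a`, `auc_b`, `z`, two-sided `p`.
#' @export
compare_correlated_aucs <- function(scores_a, scores_b, labels,
                                    method = c("hanley-mcneil", "delong")) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("undefined ROC")
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop("length mismatch")
  }
  pos <- labels == 1L; neg <- labels == 0L
  a1 <- auc_mw(scores_a, labels); a2 <- auc_mw(scores_b, labels)
  if (method == "hanley-mcneil") {
    n1 <- sum(pos); n0 <- sum(neg)
    r <- (stats::cor(scores_a[pos], scores_b[pos]) +
          stats::cor(scores_a[neg], scores_b[neg])) / 2
    se1 <- hm_se(a1, n1, n0); se2 <- hm_se(a2, n1, n0)
    denom <- sqrt(se1^2 + se2^2 - 2 * r * se1 * se2)
  } else {
    # DeLong: variance of A1 - A2 from per-subject placement values
    v <- function(s) {
      x <- s[pos]; y <- s[neg]
      v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
      v01 <- vapply(y, function(yi) mean((x > yi) + 0.5 * (x == yi)), numeric(1))
      list(v10 = v10, v01 = v01)
    }
    pa <- v(scores_a); pb <- v(scores_b)
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    svar <- s10 / sum(pos) + s01 / sum(neg)
    denom <- sqrt(svar[1, 1] + svar[2, 2] - 2 * svar[1, 2])
  }
  z <- if (denom == 0) 0 else (a1 - a2) / denom
  list(auc_a = a1, auc_b = a2, z = z, p = 2 * stats::pnorm(-abs(z)))
}
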