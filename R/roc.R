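#' ROC area under the curve with DeLong confidence interval
#'
#' AUC is the Mann-Whitney concordance probability: the fraction of
#' (positive, negative) score pairs where the positive scores higher, with
#' ties credited 0.5.  The 95% CI uses the DeLong variance estimator on the
#' per-observation placement values, clipped to [0, 1].
#'
#' @param scores numeric score vector (higher = more positive).
#' @param labels binary 0/1 (or logical) class labels; both classes must be
#'   present.
#' @return Object of class `roc_result`: `auc`, `ci_95` (length 2), `se`,
#'   `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  if (m == 0L || n == 0L) stop("both classes must be present")
  r <- rank(scores)                       # midranks handle ties
  auc <- (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
  # DeLong placements: V10_i = P(neg < pos_i) + 0.5 P(neg == pos_i)
  rp <- rank(scores[labels == 1L])
  rn <- rank(scores[labels == 0L])
  v10 <- (r[labels == 1L] - rp) / n
  v01 <- 1 - (r[labels == 0L] - rn) / m
  s10 <- if (m > 1L) stats::var(v10) else 0
  s01 <- if (n > 1L) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  ci <- pmin(pmax(auc + c(-1.96, 1.96) * se, 0), 1)
  structure(list(auc = auc, ci_95 = ci, se = se, n_pos = m, n_neg = n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci_95[1], x$ci_95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Bootstrap-by-cluster AUC confidence interval
#'
#' Percentile bootstrap resampling whole clusters (patients), for settings
#' where lesion scores within a patient are correlated and the DeLong CI
#' (which assumes independence) may be too narrow.
#'
#' @inheritParams roc_auc
#' @param cluster cluster id per observation.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return `roc_result` with `ci_95` replaced by the bootstrap interval.
#' @export
roc_auc_cluster_boot <- function(scores, labels, cluster, n_boot = 500,
                                 seed = 1) {
  base <- roc_auc(scores, labels)
  ids <- unique(cluster)
  reps <- with_preserved_seed(seed, vapply(seq_len(n_boot), function(i) {
    take <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(lapply(take, function(id) which(cluster == id)),
                  use.names = FALSE)
    if (length(unique(labels[idx])) < 2L) return(NA_real_)
    roc_auc(scores[idx], labels[idx])$auc
  }, numeric(1)))
  base$ci_95 <- unname(stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  base
}
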