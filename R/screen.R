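#' Univariate GEE screen of candidate features
#'
#' Fits one single-feature logistic GEE per candidate column and keeps the
#' features whose Wald p-value is strictly below `alpha` (default 0.1).
#' All-missing or constant features are skipped with a warning.
#'
#' @param features data frame of numeric candidate columns (e.g. the
#'   [transform_pool()] output), rows aligned with `y`.
#' @param y binary HPDv outcome per lesion.
#' @param cluster patient id per lesion.
#' @param alpha selection threshold on the Wald p-value (strict `<`).
#' @return Data frame with one row per screened feature: `feature`,
#'   `estimate`, `or`, `p_value`, `selected`; attribute `selected` holds the
#'   selected feature names.
#' @export
univariate_screen <- function(features, y, cluster, alpha = 0.1) {
  stopifnot(nrow(features) == length(y), length(cluster) == length(y))
  rows <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    if (all(is.na(x))) {
      warning("feature ", nm, " is all-missing; skipped")
      return(NULL)
    }
    ok <- is.finite(x) & !is.na(y)
    if (length(unique(x[ok])) < 2L) {
      warning("feature ", nm, " is constant; skipped")
      return(NULL)
    }
    fit <- gee_logistic(y[ok], cbind(1, x[ok]), cluster[ok])
    p <- unname(fit$p_value[2])
    data.frame(feature = nm, estimate = unname(fit$coefficients[2]),
               or = unname(fit$or[2]), p_value = p,
               selected = is.finite(p) && p < alpha,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "selected") <- out$feature[out$selected]
  out
}

#' Per-stratum multivariable GEE model with backward elimination and AUC
#'
#' Fits all selected features jointly in a logistic GEE, then removes the
#' term with the largest Wald p-value while any non-intercept p-value is
#' at or above `elim_alpha` (default 0.05), refitting after each removal.
#' The final model's linear predictor is scored against the outcome for the
#' in-sample ROC AUC.  If every term is eliminated, an intercept-only model
#' is reported with AUC 0.5.
#'
#' @param features data frame holding at least the `selected` columns.
#' @param selected character vector of feature names to start from.
#' @param y binary outcome; `cluster` patient ids.
#' @param elim_alpha backward-elimination threshold.
#' @param cluster cluster id per row.
#' @return List of class `stratum_model`: `fit` (a `gee_fit` or `NULL`),
#'   `terms`, `roc` (a `roc_result`, or `NULL` when a class is absent),
#'   `table` (report rows: variable, p, OR, CI), `dropped`.
#' @export
multivariable_model <- function(features, selected, y, cluster,
                                elim_alpha = 0.05) {
  stopifnot(length(selected) >= 1L)
  terms <- selected
  dropped <- character(0)
  fit <- NULL
  while (length(terms) > 0L) {
    X <- cbind(1, as.matrix(features[, terms, drop = FALSE]))
    colnames(X) <- c("(Intercept)", terms)
    fit <- gee_logistic(y, X, cluster)
    pv <- fit$p_value[-1]
    if (all(is.finite(pv)) && max(pv) < elim_alpha) break
    worst <- names(pv)[which.max(ifelse(is.finite(pv), pv, Inf))]
    dropped <- c(dropped, worst)
    terms <- setdiff(terms, worst)
    fit <- NULL
  }
  if (length(terms) == 0L) {
    roc <- NULL
    auc_row <- data.frame(variable = "(intercept only)", p_value = NA_real_,
                          or = NA_real_, or_lower = NA_real_,
                          or_upper = NA_real_, auc = 0.5,
                          auc_lower = NA_real_, auc_upper = NA_real_)
    return(structure(list(fit = NULL, terms = character(0), roc = NULL,
                          table = auc_row, dropped = dropped, auc = 0.5),
                     class = "stratum_model"))
  }
  roc <- if (length(unique(y)) == 2L) roc_auc(fit$linear_predictor, y)
         else NULL
  tab <- data.frame(
    variable = terms,
    p_value = unname(fit$p_value[terms]),
    or = unname(fit$or[terms]),
    or_lower = unname(fit$or_lower[terms]),
    or_upper = unname(fit$or_upper[terms]),
    auc = if (is.null(roc)) NA_real_ else roc$auc,
    auc_lower = if (is.null(roc)) NA_real_ else roc$ci_95[1],
    auc_upper = if (is.null(roc)) NA_real_ else roc$ci_95[2],
    stringsAsFactors = FALSE)
  structure(list(fit = fit, terms = terms, roc = roc, table = tab,
                 dropped = dropped,
                 auc = if (is.null(roc)) NA_real_ else roc$auc),
            class = "stratum_model")
}

#' @export
print.stratum_model <- function(x, ...) {
  if (length(x$terms) == 0L) cat("Intercept-only model (AUC 0.5)\n")
  else {
    cat("Final terms:", paste(x$terms, collapse = ", "), "\n")
    print(x$table, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Screen and model HPDv discrimination per organ stratum
#'
#' Runs the univariate GEE screen and the multivariable backward-eliminated
#' GEE + AUC, for the all-lesion stratum and each organ separately, mirroring
#' the per-organ subgroup analysis layout (strata are fit independently).
#'
#' @param features data frame of candidate features (post [transform_pool()]).
#' @param y binary HPDv outcome; `cluster` patient ids; `organ` organ labels.
#' @param organ character vector of organ labels per lesion.
#' @param screen_alpha,elim_alpha thresholds for the two stages.
#' @param min_n smallest stratum size worth fitting (default 10).
#' @return Named list (`all` plus one entry per organ present) of lists with
#'   `screen`, `model` (or `NULL` with `reason` when skipped).
#' @export
fit_organ_models <- function(features, y, cluster, organ, screen_alpha = 0.1,
                             elim_alpha = 0.05, min_n = 10) {
  strata <- c(list(all = rep(TRUE, length(y))),
              stats::setNames(lapply(.lk_organs, function(o) organ == o),
                              .lk_organs))
  lapply(strata, function(keep) {
    idx <- which(keep & !is.na(y))
    if (length(idx) < min_n || length(unique(y[idx])) < 2L)
      return(list(screen = NULL, model = NULL,
                  reason = "stratum too small or single-class"))
    scr <- suppressWarnings(
      univariate_screen(features[idx, , drop = FALSE], y[idx], cluster[idx],
                        alpha = screen_alpha))
    sel <- attr(scr, "selected")
    if (length(sel) == 0L)
      return(list(screen = scr, model = NULL,
                  reason = "no feature passed the univariate screen"))
    mod <- multivariable_model(features[idx, , drop = FALSE], sel, y[idx],
                               cluster[idx], elim_alpha = elim_alpha)
    list(screen = scr, model = mod, reason = NULL)
  })
}
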