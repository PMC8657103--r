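#' Kaplan-Meier curves and log-rank test for DR vs non-DR survival
#'
#' Product-limit overall-survival estimate per group and the unstratified
#' two-group log-rank chi-square (1 df).  Estimation is delegated to the
#' `survival` package (survfit / survdiff); curves are returned as explicit
#' step functions with numbers at risk so they can be written as CSV.
#'
#' @param os_days follow-up time in days (> 0).
#' @param os_event event indicator: 1 = death, 0 = censored.
#' @param group group label per patient (e.g. `"DR"` / `"NON_DR"`); exactly
#'   two levels, each non-empty.
#' @return Object of class `km_logrank`: `curves` (named list of data frames
#'   `time`, `n_risk`, `n_event`, `survival`), `chi_square`, `p_value`,
#'   `n_events`.
#' @export
km_logrank <- function(os_days, os_event, group) {
  if (any(os_days <= 0, na.rm = TRUE)) stop("os_days must be > 0")
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2L)
    stop("exactly two non-empty groups are required (got ",
         length(lev), ")")
  if (sum(os_event, na.rm = TRUE) < 1L) stop("need at least one event")
  gf <- factor(group, levels = sort(lev))
  fit <- survival::survfit(survival::Surv(os_days, os_event) ~ gf)
  strata_id <- rep(names(fit$strata), fit$strata)
  curves <- lapply(paste0("gf=", sort(lev)), function(s) {
    k <- strata_id == s
    data.frame(time = fit$time[k], n_risk = fit$n.risk[k],
               n_event = fit$n.event[k], survival = fit$surv[k])
  })
  names(curves) <- sort(lev)
  sd <- survival::survdiff(survival::Surv(os_days, os_event) ~ gf)
  chi <- unname(sd$chisq)
  structure(list(curves = curves, chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 n_events = sum(os_event)), class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("Log-rank chi-square %.3f (1 df), p = %.4g; %d events\n",
              x$chi_square, x$p_value, x$n_events))
  for (nm in names(x$curves)) {
    cu <- x$curves[[nm]]
    cat(sprintf("  %s: %d timepoints, final S(t) = %.3f\n",
                nm, nrow(cu), if (nrow(cu)) cu$survival[nrow(cu)] else 1))
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step-function evaluation with S(0) = 1.
#'
#' @param curve one element of `km_logrank()$curves`.
#' @param times numeric times.
#' @return Survival probabilities at `times`.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    k <- curve$time <= t
    if (!any(k)) 1 else curve$survival[max(which(k))]
  }, numeric(1))
}
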