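#' Default HPDv criteria
#'
#' The three-clause volumetric hyperprogression rule: time to treatment
#' failure below `ttf_max_months` months (1 month = 30.44 days, strict `<`),
#' TGK ratio of at least `ratio_min`, and a volume increase at first
#' follow-up of at least `increase_min_pct` percent over baseline (both
#' inclusive).
#'
#' @param ttf_max_months TTF ceiling in months (default 2).
#' @param ratio_min minimum TGK ratio (default 2).
#' @param increase_min_pct minimum percent volume increase vs baseline
#'   (default 50).
#' @param days_per_month days per month used for the TTF conversion
#'   (default 30.44).
#' @return A named list of thresholds.
#' @export
hpdv_criteria <- function(ttf_max_months = 2, ratio_min = 2,
                          increase_min_pct = 50, days_per_month = 30.44) {
  list(ttf_max_months = ttf_max_months, ratio_min = ratio_min,
       increase_min_pct = increase_min_pct, days_per_month = days_per_month)
}

.lk_organs <- c("lung", "bone", "lymph_node", "liver", "other")
.lk_timepoints <- c("pre_baseline", "baseline", "follow_up")

#' Organs recognized by the lesion classifier
#' @return Character vector: lung, bone, lymph_node, liver, other.
#' @export
organ_levels <- function() .lk_organs

#' Single-lesion record
#'
#' One lesion's identity and its volume/date series over the three required
#' timepoints (pre-baseline, baseline, first follow-up).  An absent volume
#' (`NA`) marks a timepoint where the lesion was not measurable.
#'
#' @param lesion_id,patient_id identifiers.
#' @param organ one of [organ_levels()].
#' @param dates named numeric day-integers for `pre_baseline`, `baseline`,
#'   `follow_up` (strictly increasing).
#' @param volumes named numeric volumes in mm^3 (>= 0 or `NA` = absent), same
#'   names as `dates`.
#' @return Object of class `lesion_record`.
#' @export
lesion_record <- function(lesion_id, patient_id, organ, dates, volumes) {
  organ <- match.arg(organ, .lk_organs)
  dates <- dates[.lk_timepoints]
  volumes <- as.numeric(volumes[.lk_timepoints])
  names(volumes) <- .lk_timepoints
  pres <- !is.na(dates)
  if (any(diff(dates[pres]) <= 0))
    stop("scan dates must be strictly increasing")
  if (any(volumes < 0, na.rm = TRUE)) stop("volumes must be >= 0")
  structure(list(lesion_id = lesion_id, patient_id = patient_id,
                 organ = organ, dates = dates, volumes = volumes),
            class = "lesion_record")
}

#' HPDv eligibility of a lesion
#'
#' A lesion can be assessed for hyperprogression only if it is present (has
#' a measured volume) on all three scans: pre-baseline, baseline and first
#' follow-up.  Ineligible lesions are classified `NOT_EVALUABLE` and counted
#' as excluded.
#'
#' @param lesion a [lesion_record()].
#' @return `TRUE`/`FALSE`.
#' @export
eligible_for_hpdv <- function(lesion) {
  all(!is.na(lesion$volumes[.lk_timepoints]))
}

#' Tumor growth kinetics of a lesion
#'
#' Pre-treatment rate `(V_baseline - V_pre) / (t_baseline - t_pre)` and
#' post-treatment rate `(V_fu - V_baseline) / (t_fu - t_baseline)`, both in
#' mm^3/day, and their ratio `post / pre`.  The ratio is defined only when
#' the pre-treatment rate is strictly positive: a lesion that was stable or
#' shrinking before treatment has no meaningful growth acceleration ratio
#' and cannot be called hyperprogressive through it.
#'
#' @param lesion an HPDv-eligible [lesion_record()].
#' @return List of class `tgk_result`: `tgk_pre`, `tgk_post`, `ratio`
#'   (`NA` when undefined), `ratio_defined`.
#' @export
compute_tgk <- function(lesion) {
  if (!eligible_for_hpdv(lesion))
    stop("TGK requires volumes at all three timepoints")
  d <- lesion$dates; v <- lesion$volumes
  dt1 <- d["baseline"] - d["pre_baseline"]
  dt2 <- d["follow_up"] - d["baseline"]
  if (dt1 <= 0 || dt2 <= 0) stop("zero or negative day gap between scans")
  pre <- unname((v["baseline"] - v["pre_baseline"]) / dt1)
  post <- unname((v["follow_up"] - v["baseline"]) / dt2)
  def <- pre > 0
  structure(list(tgk_pre = pre, tgk_post = post,
                 ratio = if (def) post / pre else NA_real_,
                 ratio_defined = def),
            class = "tgk_result")
}

#' Classify a lesion as HPDv / non-HPDv / not evaluable
#'
#' Applies the three-clause rule of [hpdv_criteria()] to an eligible lesion:
#' `HPDV` iff TTF < 2 months and TGK ratio >= 2 and volume increase vs
#' baseline >= 50% (thresholds configurable).  Eligible lesions failing any
#' clause — including those with an undefined ratio — are `NON_HPDV`;
#' `NOT_EVALUABLE` arises only from eligibility.
#'
#' @param lesion a [lesion_record()].
#' @param ttf_days the patient's time to treatment failure, days.
#' @param criteria thresholds from [hpdv_criteria()].
#' @return `"HPDV"`, `"NON_HPDV"` or `"NOT_EVALUABLE"`.
#' @export
classify_hpdv <- function(lesion, ttf_days, criteria = hpdv_criteria()) {
  if (!eligible_for_hpdv(lesion)) return("NOT_EVALUABLE")
  v <- lesion$volumes
  if (v["baseline"] <= 0)
    stop("baseline volume must be > 0: percent change undefined")
  tgk <- compute_tgk(lesion)
  incr <- unname((v["follow_up"] - v["baseline"]) / v["baseline"])
  ok <- ttf_days < criteria$ttf_max_months * criteria$days_per_month &&
    tgk$ratio_defined && tgk$ratio >= criteria$ratio_min &&
    incr >= criteria$increase_min_pct / 100
  if (ok) "HPDV" else "NON_HPDV"
}

#' Nelson volumetric response category
#'
#' Volumetric single-lesion response between baseline and first follow-up:
#' `PROGRESSION` when the volume increased by `threshold_pct` percent or
#' more, `PARTIAL_RESPONSE` when it shrank by at least `threshold_pct`
#' percent, `STABLE` otherwise.  Both boundaries are inclusive.
#'
#' @param v_baseline,v_follow_up volumes in mm^3; baseline must be > 0.
#' @param threshold_pct percent threshold (default 25).
#' @return `"PROGRESSION"`, `"PARTIAL_RESPONSE"` or `"STABLE"`.
#' @export
classify_nelson <- function(v_baseline, v_follow_up, threshold_pct = 25) {
  if (is.na(v_baseline) || v_baseline <= 0)
    stop("baseline volume must be > 0 for the Nelson category")
  change <- (v_follow_up - v_baseline) / v_baseline * 100
  if (change >= threshold_pct) "PROGRESSION"
  else if (change <= -threshold_pct) "PARTIAL_RESPONSE"
  else "STABLE"
}

#' Patient-level dissociated response
#'
#' A patient shows a dissociated response (DR) when lesions in *different*
#' organs disagree between progression and partial response: there is a
#' `PROGRESSION` lesion in one organ and a `PARTIAL_RESPONSE` lesion in
#' another.  Patients with exactly one lesion are non-DR by definition.  A
#' same-organ-discordance mode (progression and partial response within one
#' organ also count) is available but off by default.
#'
#' @param organs character vector, one organ per lesion.
#' @param responses character vector of Nelson categories, same length
#'   (lesions without a computable category may be `NA`).
#' @param same_organ_counts if `TRUE`, discordance within a single organ
#'   also qualifies as DR.
#' @return `"DR"` or `"NON_DR"`.
#' @export
classify_dissociated <- function(organs, responses, same_organ_counts = FALSE) {
  if (length(organs) == 0L) stop("patient must have at least one lesion")
  if (length(organs) != length(responses))
    stop("`organs` and `responses` must be the same length")
  if (length(organs) == 1L) return("NON_DR")
  prog <- organs[!is.na(responses) & responses == "PROGRESSION"]
  pr <- organs[!is.na(responses) & responses == "PARTIAL_RESPONSE"]
  if (length(prog) == 0L || length(pr) == 0L) return("NON_DR")
  if (same_organ_counts) return("DR")
  if (any(outer(prog, pr, "!="))) "DR" else "NON_DR"
}
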