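#' Classify every lesion of a cohort table
#'
#' Runs the deterministic rule engine over a long lesion table (one row per
#' lesion per timepoint, the `lesions.csv` contract) joined with the patient
#' table: eligibility, TGK rates and ratio, the HPDv call, and the Nelson
#' category at first follow-up.  The Nelson category is computed for every
#' lesion with volumes at baseline and follow-up, including lesions that are
#' HPDv-ineligible because the pre-baseline scan is missing.
#'
#' @param lesions data frame with columns `patient_id`, `lesion_id`, `organ`,
#'   `timepoint` (`pre_baseline`/`baseline`/`follow_up`), `scan_date` (day
#'   integer), `volume_mm3` (`NA` = absent).
#' @param patients data frame with columns `patient_id`, `ttf_days`,
#'   `os_days`, `os_event`.
#' @param criteria HPDv thresholds, see [hpdv_criteria()].
#' @param nelson_threshold_pct Nelson percent threshold (default 25).
#' @return Data frame, one row per lesion: identifiers, organ, `eligible`,
#'   `tgk_pre`, `tgk_post`, `tgk_ratio`, `hpdv_status`, `nelson_response`.
#' @export
classify_lesions <- function(lesions, patients, criteria = hpdv_criteria(),
                             nelson_threshold_pct = 25) {
  .check_lesion_columns(lesions)
  if (!all(c("patient_id", "ttf_days") %in% names(patients)))
    stop("`patients` must contain patient_id and ttf_days")
  ids <- unique(lesions$lesion_id)
  first <- match(ids, lesions$lesion_id)
  pid <- lesions$patient_id[first]
  organ <- lesions$organ[first]
  ttf <- patients$ttf_days[match(pid, patients$patient_id)]
  if (anyNA(ttf))
    stop("lesion ", ids[which(is.na(ttf))[1]],
         " references an unknown patient")
  # wide volume/date matrices (NA where the timepoint row is absent)
  key <- paste(lesions$lesion_id, lesions$timepoint)
  vol <- date <- matrix(NA_real_, length(ids), 3L,
                        dimnames = list(NULL, .lk_timepoints))
  for (tp in .lk_timepoints) {
    m <- match(paste(ids, tp), key)
    vol[, tp] <- lesions$volume_mm3[m]
    date[, tp] <- lesions$scan_date[m]
  }
  date[is.na(vol)] <- NA_real_        # absent volume = lesion not present
  if (any(vol < 0, na.rm = TRUE)) stop("volumes must be >= 0")
  dd <- cbind(date[, 2] - date[, 1], date[, 3] - date[, 2],
              date[, 3] - date[, 1])
  if (any(dd <= 0, na.rm = TRUE))
    stop("scan dates must be strictly increasing for lesion ",
         ids[which(apply(dd <= 0, 1, any, na.rm = TRUE))[1]])

  eligible <- !is.na(vol[, 1]) & !is.na(vol[, 2]) & !is.na(vol[, 3])
  if (any(eligible & vol[, "baseline"] <= 0))
    stop("baseline volume must be > 0: percent change undefined")
  tgk_pre <- tgk_post <- tgk_ratio <- rep(NA_real_, length(ids))
  e <- eligible
  tgk_pre[e] <- (vol[e, 2] - vol[e, 1]) / (date[e, 2] - date[e, 1])
  tgk_post[e] <- (vol[e, 3] - vol[e, 2]) / (date[e, 3] - date[e, 2])
  rd <- e & tgk_pre > 0
  tgk_ratio[rd] <- tgk_post[rd] / tgk_pre[rd]
  incr <- (vol[, 3] - vol[, 2]) / vol[, 2]
  hpdv <- ifelse(!eligible, "NOT_EVALUABLE",
    ifelse(ttf < criteria$ttf_max_months * criteria$days_per_month &
             !is.na(tgk_ratio) & tgk_ratio >= criteria$ratio_min &
             incr >= criteria$increase_min_pct / 100,
           "HPDV", "NON_HPDV"))
  has_bf <- !is.na(vol[, 2]) & !is.na(vol[, 3])
  if (any(has_bf & vol[, 2] <= 0))
    stop("baseline volume must be > 0 for the Nelson category")
  chg <- incr * 100
  thr <- nelson_threshold_pct
  nelson <- ifelse(!has_bf, NA_character_,
                   ifelse(chg >= thr, "PROGRESSION",
                          ifelse(chg <= -thr, "PARTIAL_RESPONSE", "STABLE")))
  data.frame(lesion_id = ids, patient_id = pid, organ = organ,
             eligible = eligible, tgk_pre = tgk_pre, tgk_post = tgk_post,
             tgk_ratio = tgk_ratio, hpdv_status = hpdv,
             nelson_response = nelson, stringsAsFactors = FALSE)
}

#' Classify every patient's dissociated-response status
#'
#' @param classified output of [classify_lesions()].
#' @param same_organ_counts see [classify_dissociated()].
#' @return Data frame with `patient_id`, `n_lesions`, `dr_status`.
#' @export
classify_patients_dr <- function(classified, same_organ_counts = FALSE) {
  sp <- split(classified, classified$patient_id)
  out <- lapply(sp, function(d)
    data.frame(patient_id = d$patient_id[1], n_lesions = nrow(d),
               dr_status = classify_dissociated(d$organ, d$nelson_response,
                                                same_organ_counts),
               stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.pct1 <- function(num, den) round(num / den * 100, 1)

#' Cohort-level lesion and patient accounting
#'
#' Counts and percentages of HPDv / non-HPDv / excluded lesions (all-lesion
#' denominator), the per-organ composition of the HPDv and non-HPDv groups
#' (category total as denominator), and the patient-level DR / non-DR split.
#' Percentages are rounded to one decimal.
#'
#' @param classified output of [classify_lesions()].
#' @param dr output of [classify_patients_dr()].
#' @return List of class `cohort_summary` with components `lesions` (counts
#'   and percentages), `by_organ` (organ x status count table plus organ
#'   shares), and `patients` (DR split).
#' @export
summarize_cohort <- function(classified, dr) {
  n <- nrow(classified)
  st <- classified$hpdv_status
  n_hpdv <- sum(st == "HPDV")
  n_non <- sum(st == "NON_HPDV")
  n_excl <- sum(st == "NOT_EVALUABLE")
  organ <- factor(classified$organ, levels = .lk_organs)
  tab <- table(organ, factor(st, levels = c("HPDV", "NON_HPDV",
                                            "NOT_EVALUABLE")))
  organ_share <- function(col) {
    tot <- sum(tab[, col])
    if (tot == 0) rep(NA_real_, nrow(tab)) else .pct1(tab[, col], tot)
  }
  n_pat <- nrow(dr)
  n_dr <- sum(dr$dr_status == "DR")
  structure(list(
    lesions = list(
      n_total = n, n_hpdv = n_hpdv, n_non_hpdv = n_non, n_excluded = n_excl,
      pct_hpdv = .pct1(n_hpdv, n), pct_non_hpdv = .pct1(n_non, n),
      pct_excluded = .pct1(n_excl, n)),
    by_organ = list(
      counts = tab,
      hpdv_share_pct = organ_share("HPDV"),
      non_hpdv_share_pct = organ_share("NON_HPDV")),
    patients = list(
      n_patients = n_pat, n_dr = n_dr, n_non_dr = n_pat - n_dr,
      pct_dr = .pct1(n_dr, n_pat), pct_non_dr = .pct1(n_pat - n_dr, n_pat))),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  l <- x$lesions; p <- x$patients
  cat(sprintf("Lesions: %d total | HPDv %d (%.1f%%) | non-HPDv %d (%.1f%%) | excluded %d (%.1f%%)\n",
              l$n_total, l$n_hpdv, l$pct_hpdv, l$n_non_hpdv, l$pct_non_hpdv,
              l$n_excluded, l$pct_excluded))
  cat("Organ composition (% of category):\n")
  sh <- rbind(HPDv = x$by_organ$hpdv_share_pct,
              `non-HPDv` = x$by_organ$non_hpdv_share_pct)
  colnames(sh) <- rownames(x$by_organ$counts)
  print(sh)
  cat(sprintf("Patients: %d | DR %d (%.1f%%) | non-DR %d (%.1f%%)\n",
              p$n_patients, p$n_dr, p$pct_dr, p$n_non_dr, p$pct_non_dr))
  invisible(x)
}

.check_lesion_columns <- function(lesions) {
  need <- c("patient_id", "lesion_id", "organ", "timepoint", "scan_date",
            "volume_mm3")
  miss <- setdiff(need, names(lesions))
  if (length(miss))
    stop("lesion table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(lesions$timepoint), .lk_timepoints)
  if (length(bad))
    stop("unknown timepoint value(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
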