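# interleave categories proportionally: for category j with count c_j the
# items sit at fractional positions (i - 0.5)/c_j, then all are merge-sorted
.interleave <- function(counts) {
  pos <- unlist(lapply(seq_along(counts), function(j)
    if (counts[j] > 0) (seq_len(counts[j]) - 0.5) / counts[j] else numeric(0)))
  lab <- rep(names(counts), counts)
  lab[order(pos, lab)]
}

#' Deterministic reference cohort with fixed published marginals
#'
#' Builds, by construction rather than random search, a cohort of 196
#' patients and 621 lesions whose volume/date series and TTF values make the
#' deterministic rule engine reproduce the reference lesion accounting of
#' the motivating advanced-NSCLC ICI cohort exactly:
#' 147 HPDv lesions (23.7%), 349 non-HPDv (56.2%), 125 excluded by the
#' three-timepoint eligibility filter; HPDv organ split lung/bone/lymph
#' node/liver/other = 80/15/24/21/7 and non-HPDv split 154/50/90/26/29;
#' and at patient level 54 DR (27.6%) vs 142 non-DR (72.4%).
#'
#' The organ split of the 125 excluded lesions is not published; this
#' fixture uses 50/18/25/14/18.  Lesion volume templates (growth
#' quadrupling for HPDv lesions, -40% shrinkage for the partial responses
#' that drive DR, +30% for non-HPDv progressions, +5% for stable lesions)
#' are scaled per lesion by a seeded lognormal factor and scan dates are
#' jittered by up to 10 days — both perturbations preserve every rule
#' decision, so the marginals are invariant.  The internal seed is fixed:
#' every call returns the same cohort.
#'
#' @return A `synthetic_cohort` (see [generate_cohort()]) with elements
#'   `lesions`, `patients`, `truth`.
#' @export
fixture_cohort <- function() {
  with_preserved_seed(20211201L, .fixture_impl())
}

.fixture_impl <- function() {
  hpdv_n <- c(lung = 80, bone = 15, lymph_node = 24, liver = 21, other = 7)
  non_n <- c(lung = 154, bone = 50, lymph_node = 90, liver = 26, other = 29)
  excl_n <- c(lung = 50, bone = 18, lymph_node = 25, liver = 14, other = 18)
  hpdv_org <- .interleave(hpdv_n)      # 147
  non_org <- .interleave(non_n)        # 349
  excl_org <- .interleave(excl_n)      # 125
  n_dr <- 54; n_pat <- 196
  pid <- sprintf("P%04d", seq_len(n_pat))

  # lesion roster: class, organ, patient
  roster <- list()
  add <- function(cls, organ, patient)
    roster[[length(roster) + 1L]] <<- list(cls = cls, organ = organ,
                                           patient = patient)

  # DR patients: one HPDv (progressing) lesion + one partial-response
  # lesion in a different organ
  non_used <- rep(FALSE, length(non_org))
  for (i in seq_len(n_dr)) {
    o_h <- hpdv_org[i]
    j <- which(!non_used & non_org != o_h)[1]
    non_used[j] <- TRUE
    add("hpdv", o_h, pid[i])
    add("pr", non_org[j], pid[i])
  }

  # remaining pool -> non-DR patients (3 each, first 87 get a 4th)
  pool_cls <- c(rep("hpdv", length(hpdv_org) - n_dr),
                rep("nonh", sum(!non_used)),
                rep("excl", length(excl_org)))
  pool_org <- c(hpdv_org[-seq_len(n_dr)], non_org[!non_used], excl_org)
  ord <- order(.interleave_pos(table(pool_cls)[unique(pool_cls)], pool_cls))
  pool_cls <- pool_cls[ord]; pool_org <- pool_org[ord]
  nondr <- pid[(n_dr + 1L):n_pat]
  per <- rep(3L, length(nondr))
  per[seq_len(length(pool_cls) - 3L * length(nondr))] <- 4L
  host <- rep(nondr, per)
  k_stable <- 0L
  for (k in seq_along(pool_cls)) {
    cls <- pool_cls[k]
    if (cls == "nonh") {
      k_stable <- k_stable + 1L
      cls <- if (k_stable %% 5L == 0L) "prog" else "stable"
    }
    add(cls, pool_org[k], host[k])
  }

  n <- length(roster)
  cls <- vapply(roster, `[[`, "", "cls")
  organ <- vapply(roster, `[[`, "", "organ")
  patient <- vapply(roster, `[[`, "", "patient")
  excl_kind <- integer(n)
  excl_kind[cls == "excl"] <- seq_len(sum(cls == "excl")) %% 2L  # 1=miss pre

  templates <- list(  # pre, baseline, follow-up volume ratios
    hpdv = c(0.8, 1, 1.8), pr = c(0.9, 1, 0.6), prog = c(0.95, 1, 1.3),
    stable = c(0.95, 1, 1.05), excl = c(0.95, 1, 1.05))
  scale <- stats::rlnorm(n, log(1500), 0.8)
  j1 <- sample(-10:10, n, replace = TRUE)
  j2 <- sample(-10:10, n, replace = TRUE)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- templates[[cls[i]]] * scale[i]
    if (cls[i] == "excl") {
      if (excl_kind[i] == 1L) v[1] <- NA_real_ else v[3] <- NA_real_
    }
    rows[[i]] <- data.frame(
      patient_id = patient[i], lesion_id = sprintf("L%05d", i),
      organ = organ[i], timepoint = .lk_timepoints,
      scan_date = c(-60 + j1[i], 0, 60 + j2[i]),
      volume_mm3 = v, stringsAsFactors = FALSE)
  }
  lesions <- do.call(rbind, rows)

  host_hpdv <- tapply(cls == "hpdv", patient, any)
  ttf <- ifelse(host_hpdv[pid], 45, 150)
  h <- (log(2) / 250) * ifelse(pid %in% pid[seq_len(n_dr)], 2, 1)
  t_event <- stats::rexp(n_pat, h)
  hc <- (log(2) / 250) * 0.3 / 0.7
  t_cens <- stats::rexp(n_pat, hc)
  patients <- data.frame(
    patient_id = pid, ttf_days = unname(ttf),
    os_days = pmax(pmin(t_event, t_cens), 1),
    os_event = as.integer(t_event <= t_cens),
    dr_truth = ifelse(seq_len(n_pat) <= n_dr, "DR", "NON_DR"),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    lesion_id = sprintf("L%05d", seq_len(n)),
    hpdv_truth = ifelse(cls == "hpdv", "HPDV",
                        ifelse(cls == "excl", "NOT_EVALUABLE", "NON_HPDV")),
    stringsAsFactors = FALSE)

  structure(list(lesions = lesions, patients = patients, truth = truth,
                 config = NULL, features = NULL),
            class = "synthetic_cohort")
}

# fractional interleave positions for an already-labelled vector
.interleave_pos <- function(counts, labels) {
  idx <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  tot <- as.numeric(counts[labels])
  (idx - 0.5) / tot
}
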