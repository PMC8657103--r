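#' Pipeline run configuration
#'
#' Paths and thresholds for [run_pipeline()].  Every rule threshold is
#' surfaced with its conventional default: 2-month TTF ceiling, TGK ratio
#' 2, +50% HPDv volume increase, 25% Nelson threshold, univariate screen at
#' p < 0.1, backward elimination at p >= 0.05, 25 HU bin width.
#'
#' @param lesions,patients paths to the input CSVs.
#' @param features optional path to a per-lesion feature CSV (column
#'   `lesion_id` + numeric feature columns).
#' @param patch_dir optional directory of plain-text patches named
#'   `<lesion_id>.csv` (see [write_patch()]); used when `features` is absent.
#' @param out_dir output directory.
#' @param ttf_max_months,ratio_min,increase_min_pct HPDv thresholds.
#' @param nelson_threshold_pct Nelson percent threshold.
#' @param bin_width discretization bin width (HU) for feature extraction.
#' @param screen_alpha,elim_alpha screening / elimination thresholds.
#' @param same_organ_dr see [classify_dissociated()].
#' @param seed integer seed for any stochastic step.
#' @return List of class `run_config`.
#' @export
run_config <- function(lesions, patients, features = NULL, patch_dir = NULL,
                       out_dir = "lesionkinetics_out", ttf_max_months = 2,
                       ratio_min = 2, increase_min_pct = 50,
                       nelson_threshold_pct = 25, bin_width = 25,
                       screen_alpha = 0.1, elim_alpha = 0.05,
                       same_organ_dr = FALSE, seed = 1) {
  for (a in c("screen_alpha", "elim_alpha")) {
    v <- get(a)
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("`", a, "` must be in (0, 1)")
  }
  for (p in c(lesions, patients, features, patch_dir))
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  structure(list(lesions = lesions, patients = patients,
                 features = features, patch_dir = patch_dir,
                 out_dir = out_dir, ttf_max_months = ttf_max_months,
                 ratio_min = ratio_min, increase_min_pct = increase_min_pct,
                 nelson_threshold_pct = nelson_threshold_pct,
                 bin_width = bin_width, screen_alpha = screen_alpha,
                 elim_alpha = elim_alpha, same_organ_dr = same_organ_dr,
                 seed = seed), class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# small stable polynomial hash of the configuration for output provenance
.config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]  # output location is not analytic
  s <- utf8ToInt(paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), ""), collapse = ";"))
  h <- 5381
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Validate pipeline input tables
#'
#' Per-file column, type and range checks: required columns, unknown
#' timepoints, negative volumes, non-positive TTF/OS, bad event flags,
#' duplicated (lesion, timepoint) rows, lesions referencing unknown
#' patients, and non-increasing scan dates.  Problems are reported, never
#' thrown.
#'
#' @param lesions_path,patients_path CSV paths.
#' @return Data frame with columns `file`, `issue`, `detail` (zero rows =
#'   clean).
#' @export
validate_inputs <- function(lesions_path, patients_path) {
  probs <- list()
  note <- function(file, issue, detail)
    probs[[length(probs) + 1L]] <<- data.frame(file = file, issue = issue,
                                               detail = detail)
  les <- utils::read.csv(lesions_path)
  pat <- utils::read.csv(patients_path)
  need_l <- c("patient_id", "lesion_id", "organ", "timepoint", "scan_date",
              "volume_mm3")
  for (cn in setdiff(need_l, names(les)))
    note("lesions", "missing_column", cn)
  need_p <- c("patient_id", "ttf_days", "os_days", "os_event")
  for (cn in setdiff(need_p, names(pat)))
    note("patients", "missing_column", cn)
  if (all(need_l %in% names(les))) {
    bad_tp <- setdiff(unique(les$timepoint), .lk_timepoints)
    if (length(bad_tp)) note("lesions", "unknown_timepoint",
                             paste(bad_tp, collapse = ","))
    bad_org <- setdiff(unique(les$organ), .lk_organs)
    if (length(bad_org)) note("lesions", "unknown_organ",
                              paste(bad_org, collapse = ","))
    neg <- which(!is.na(les$volume_mm3) & les$volume_mm3 < 0)
    for (i in neg) note("lesions", "negative_volume",
                        paste0(les$lesion_id[i], "@", les$timepoint[i]))
    key <- paste(les$lesion_id, les$timepoint)
    for (k in unique(key[duplicated(key)]))
      note("lesions", "duplicate_timepoint", k)
    if ("patient_id" %in% names(pat)) {
      orphan <- setdiff(unique(les$patient_id), pat$patient_id)
      for (o in orphan) note("lesions", "orphan_patient", o)
    }
    for (id in unique(les$lesion_id)) {
      d <- les[les$lesion_id == id & !is.na(les$volume_mm3), ]
      d <- d[order(match(d$timepoint, .lk_timepoints)), ]
      if (nrow(d) > 1L && any(diff(d$scan_date) <= 0))
        note("lesions", "dates_not_increasing", id)
    }
  }
  if (all(need_p %in% names(pat))) {
    for (i in which(!is.na(pat$ttf_days) & pat$ttf_days <= 0))
      note("patients", "nonpositive_ttf", pat$patient_id[i])
    for (i in which(!is.na(pat$os_days) & pat$os_days <= 0))
      note("patients", "nonpositive_os", pat$patient_id[i])
    bad_ev <- which(!pat$os_event %in% c(0, 1))
    for (i in bad_ev) note("patients", "bad_event_flag", pat$patient_id[i])
  }
  if (length(probs)) do.call(rbind, probs)
  else data.frame(file = character(0), issue = character(0),
                  detail = character(0))
}

#' Run the full lesion-level analysis pipeline
#'
#' Stages, in order: input validation -> eligibility + TGK + HPDv
#' classification -> Nelson + dissociated response -> feature loading (CSV)
#' or extraction (patches), when available -> transform pool -> per-organ
#' univariate screen + multivariable GEE + AUC -> Kaplan-Meier / log-rank of
#' DR vs non-DR -> cohort summary.  Stages whose inputs are unavailable are
#' skipped with a recorded reason.  All outputs carry the configuration
#' hash and seed; re-running on identical inputs is byte-identical.
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @return Invisibly, a list with `classified`, `dr`, `summary`, `models`,
#'   `survival`, `log`; files are written under `config$out_dir`
#'   (`classifications.csv`, `patients_out.csv`, `summary.json`,
#'   `model_report.csv`/`.json`, `km_curves.csv`, `run_log.txt`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  log_lines <- c(sprintf("lesionkinetics run config=%s seed=%d", hash,
                         config$seed))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  report <- validate_inputs(config$lesions, config$patients)
  say("validate: %d problem(s)", nrow(report))
  if (any(report$issue == "missing_column"))
    stop("schema error: missing column(s): ",
         paste(report$detail[report$issue == "missing_column"],
               collapse = ", "))
  lesions <- utils::read.csv(config$lesions)
  patients <- utils::read.csv(config$patients)
  say("inputs: %d lesion rows, %d lesions, %d patients", nrow(lesions),
      length(unique(lesions$lesion_id)), nrow(patients))

  crit <- hpdv_criteria(ttf_max_months = config$ttf_max_months,
                        ratio_min = config$ratio_min,
                        increase_min_pct = config$increase_min_pct)
  classified <- classify_lesions(lesions, patients, crit,
                                 config$nelson_threshold_pct)
  dr <- classify_patients_dr(classified, config$same_organ_dr)
  summ <- summarize_cohort(classified, dr)
  say("classify: HPDv %d | non-HPDv %d | excluded %d (total %d)",
      summ$lesions$n_hpdv, summ$lesions$n_non_hpdv, summ$lesions$n_excluded,
      summ$lesions$n_total)
  say("dissociated response: DR %d | non-DR %d", summ$patients$n_dr,
      summ$patients$n_non_dr)

  # feature stage
  feats <- NULL
  if (!is.null(config$features)) {
    feats <- utils::read.csv(config$features)
    say("features: loaded %d rows x %d columns from CSV", nrow(feats),
        ncol(feats) - 1L)
  } else if (!is.null(config$patch_dir)) {
    files <- list.files(config$patch_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    if (length(files)) {
      rows <- lapply(files, function(f) {
        fv <- extract_features(read_patch(f), bin_width = config$bin_width)
        cbind(data.frame(lesion_id = sub("\\.csv$", "", basename(f))),
              as.data.frame(as.list(fv)))
      })
      feats <- do.call(rbind, rows)
      say("features: extracted for %d patches", nrow(feats))
    }
  } else say("features: skipped (no feature table or patch directory)")

  models <- NULL
  if (!is.null(feats)) {
    idx <- match(classified$lesion_id, feats$lesion_id)
    keep <- which(!is.na(idx) & classified$hpdv_status != "NOT_EVALUABLE")
    if (length(keep) >= 10L) {
      fm <- feats[idx[keep], setdiff(names(feats), "lesion_id"),
                  drop = FALSE]
      pool <- transform_pool(fm)
      say("transforms: pool of %d candidates (%d transformed variants)",
          ncol(pool$pool), length(pool$specs))
      y <- as.integer(classified$hpdv_status[keep] == "HPDV")
      models <- fit_organ_models(pool$pool, y, classified$patient_id[keep],
                                 classified$organ[keep],
                                 config$screen_alpha, config$elim_alpha)
      for (nm in names(models))
        say("model[%s]: %s", nm,
            if (is.null(models[[nm]]$model)) models[[nm]]$reason
            else paste0(paste(models[[nm]]$model$terms, collapse = "+"),
                        " AUC=", round(models[[nm]]$model$auc, 3)))
    } else say("models: skipped (fewer than 10 feature-matched lesions)")
  } else say("models: skipped (no features)")

  surv <- NULL
  pat_dr <- merge(patients, dr, by = "patient_id")
  if (length(unique(pat_dr$dr_status)) == 2L &&
      sum(pat_dr$os_event) >= 1L) {
    surv <- km_logrank(pat_dr$os_days, pat_dr$os_event, pat_dr$dr_status)
    say("survival: log-rank chi-square %.3f, p = %.4g", surv$chi_square,
        surv$p_value)
  } else say("survival: skipped (need both DR groups and >= 1 event)")

  # outputs
  out <- function(f) file.path(config$out_dir, f)
  cls_out <- classified
  cls_out$config_hash <- hash
  utils::write.csv(cls_out, out("classifications.csv"), row.names = FALSE)
  dr_out <- dr; dr_out$config_hash <- hash
  utils::write.csv(dr_out, out("patients_out.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         lesions = summ$lesions, patients = summ$patients,
         by_organ = list(
           counts = as.data.frame.matrix(summ$by_organ$counts),
           hpdv_share_pct = as.list(summ$by_organ$hpdv_share_pct),
           non_hpdv_share_pct = as.list(summ$by_organ$non_hpdv_share_pct))),
    out("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(models)) {
    tabs <- lapply(names(models), function(nm) {
      m <- models[[nm]]$model
      if (is.null(m)) return(NULL)
      cbind(stratum = nm, m$table)
    })
    tab <- do.call(rbind, Filter(Negate(is.null), tabs))
    if (!is.null(tab)) {
      utils::write.csv(tab, out("model_report.csv"), row.names = FALSE)
      jsonlite::write_json(tab, out("model_report.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
  }
  if (!is.null(surv)) {
    cu <- do.call(rbind, lapply(names(surv$curves), function(g)
      cbind(group = g, surv$curves[[g]])))
    utils::write.csv(cu, out("km_curves.csv"), row.names = FALSE)
  }
  writeLines(log_lines, out("run_log.txt"))
  invisible(list(classified = classified, dr = dr, summary = summ,
                 models = models, survival = surv, log = log_lines,
                 config_hash = hash))
}
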