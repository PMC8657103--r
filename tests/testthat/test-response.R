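mk_lesion <- function(v, d = c(-60, 0, 60), organ = "lung",
                      id = "L1", pid = "P1") {
  lesion_record(id, pid, organ,
                dates = setNames(d, c("pre_baseline", "baseline",
                                      "follow_up")),
                volumes = setNames(v, c("pre_baseline", "baseline",
                                        "follow_up")))
}

test_that("eligibility requires all three timepoints", {
  expect_true(eligible_for_hpdv(mk_lesion(c(800, 1000, 1800))))
  expect_false(eligible_for_hpdv(mk_lesion(c(NA, 1000, 1800))))
  expect_false(eligible_for_hpdv(mk_lesion(c(800, 1000, NA))))
  expect_equal(classify_hpdv(mk_lesion(c(NA, 1000, 1800)), 30),
               "NOT_EVALUABLE")
})

test_that("TGK worked example and guards", {
  t <- compute_tgk(mk_lesion(c(800, 1000, 1800)))
  expect_equal(t$tgk_pre, 200 / 60, tolerance = 1e-12)
  expect_equal(t$tgk_post, 800 / 60, tolerance = 1e-12)
  expect_equal(t$ratio, 4)

  # flat pre-treatment: ratio undefined
  t0 <- compute_tgk(mk_lesion(c(1000, 1000, 1500)))
  expect_false(t0$ratio_defined)
  expect_true(is.na(t0$ratio))
  # shrinking pre-treatment: ratio undefined, lesion not HPDv-callable
  tn <- compute_tgk(mk_lesion(c(1000, 900, 1800)))
  expect_false(tn$ratio_defined)
  expect_equal(classify_hpdv(mk_lesion(c(1000, 900, 1800)), 30), "NON_HPDV")
  expect_error(compute_tgk(mk_lesion(c(800, 1000, 1800), d = c(0, 0, 60))),
               "increasing|day gap")
})

test_that("three-clause HPDv rule with inclusive thresholds", {
  expect_equal(classify_hpdv(mk_lesion(c(800, 1000, 1800)), 45), "HPDV")
  # all three exactly at the boundary: ratio 2, +50%, ttf 59 < 60.88
  les <- mk_lesion(c(900, 1000, 1250), d = c(-60, 0, 30))
  tg <- compute_tgk(les)
  expect_equal(tg$ratio, 5)
  boundary <- mk_lesion(c(900, 1000, 1500), d = c(-60, 0, 180))
  expect_equal(compute_tgk(boundary)$ratio, 500 / 180 / (100 / 60))
  exact <- mk_lesion(c(940, 1000, 1500), d = c(-60, 0, 250))
  expect_equal(compute_tgk(exact)$ratio, 2, tolerance = 1e-12)
  expect_equal(classify_hpdv(exact, 59), "HPDV")
  # criterion (a) fails at long TTF
  expect_equal(classify_hpdv(mk_lesion(c(800, 1000, 1800)), 90), "NON_HPDV")
  expect_equal(classify_hpdv(mk_lesion(c(800, 1000, 1800)), 60.88),
               "NON_HPDV")  # strict <
  expect_error(classify_hpdv(mk_lesion(c(800, 0, 1800)), 30), "baseline")
})

test_that("HPDv and Nelson agree with clause re-evaluation on a dense grid", {
  grid <- expand.grid(
    v1 = c(600, 900, 1000, 1100, NA),
    v2 = c(800, 1000),
    v3 = c(500, 750, 1000, 1250, 1499, 1500, 1501, 2000, NA),
    ttf = c(30, 59, 60.87, 60.88, 61, 120),
    sched = 1:2)
  dates <- list(c(-60, 0, 60), c(-90, 0, 45))
  mismatch <- 0L
  for (i in seq_len(nrow(grid))) {
    v <- c(grid$v1[i], grid$v2[i], grid$v3[i])
    d <- dates[[grid$sched[i]]]
    got <- classify_hpdv(mk_lesion(v, d), grid$ttf[i])
    want <- oracle_hpdv(v, d, grid$ttf[i])
    if (!identical(got, want)) mismatch <- mismatch + 1L
    if (!is.na(v[2]) && !is.na(v[3])) {
      gn <- classify_nelson(v[2], v[3])
      if (!identical(gn, oracle_nelson(v[2], v[3]))) mismatch <- mismatch + 1L
    }
  }
  expect_identical(mismatch, 0L)
})

test_that("Nelson boundaries are inclusive on both sides", {
  expect_equal(classify_nelson(1000, 1250), "PROGRESSION")     # +25.0%
  expect_equal(classify_nelson(1000, 750), "PARTIAL_RESPONSE") # -25.0%
  expect_equal(classify_nelson(1000, 1100), "STABLE")
  expect_equal(classify_nelson(1000, 1249.99), "STABLE")
  expect_error(classify_nelson(0, 100), "baseline")
})

test_that("dissociated response requires cross-organ discordance", {
  expect_equal(classify_dissociated(c("lung", "liver"),
                                    c("PROGRESSION", "PARTIAL_RESPONSE")),
               "DR")
  expect_equal(classify_dissociated("lung", "PROGRESSION"), "NON_DR")
  expect_equal(classify_dissociated(c("lung", "lung"),
                                    c("PROGRESSION", "PARTIAL_RESPONSE")),
               "NON_DR")
  expect_equal(classify_dissociated(c("lung", "lung"),
                                    c("PROGRESSION", "PARTIAL_RESPONSE"),
                                    same_organ_counts = TRUE), "DR")
  expect_equal(classify_dissociated(c("lung", "bone", "liver"),
                                    c("STABLE", "PROGRESSION", NA)),
               "NON_DR")
  expect_error(classify_dissociated(character(0), character(0)), "at least")

  # permutation symmetry
  set.seed(1)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    org <- sample(organ_levels(), k, replace = TRUE)
    rsp <- sample(c("PROGRESSION", "PARTIAL_RESPONSE", "STABLE", NA), k,
                  replace = TRUE)
    base <- classify_dissociated(org, rsp)
    perm <- sample(k)
    expect_equal(classify_dissociated(org[perm], rsp[perm]), base)
  }
})

test_that("scale invariance and follow-up monotonicity of the rules", {
  set.seed(7)
  for (i in 1:30) {
    v <- sort(runif(3, 100, 3000))[c(2, 1, 3)]
    ttf <- runif(1, 10, 120)
    k <- runif(1, 0.1, 10)
    expect_equal(classify_hpdv(mk_lesion(v * k), ttf),
                 classify_hpdv(mk_lesion(v), ttf))
    expect_equal(compute_tgk(mk_lesion(v * k))$ratio,
                 compute_tgk(mk_lesion(v))$ratio, tolerance = 1e-9)
    expect_equal(classify_nelson(v[2] * k, v[3] * k),
                 classify_nelson(v[2], v[3]))
  }
  # increasing follow-up volume can never flip HPDV -> NON_HPDV
  for (v3 in seq(1000, 4000, by = 100)) {
    a <- classify_hpdv(mk_lesion(c(900, 1000, v3)), 45)
    b <- classify_hpdv(mk_lesion(c(900, 1000, v3 + 500)), 45)
    if (a == "HPDV") expect_equal(b, "HPDV")
  }
})

test_that("classify_lesions vectorized path agrees with per-lesion rules", {
  co <- generate_cohort(cohort_config(n_patients = 40, seed = 31))
  cls <- classify_lesions(co$lesions, co$patients)
  ttf <- setNames(co$patients$ttf_days, co$patients$patient_id)
  for (i in seq_len(nrow(cls))) {
    sub <- co$lesions[co$lesions$lesion_id == cls$lesion_id[i], ]
    v <- setNames(sub$volume_mm3, sub$timepoint)[c("pre_baseline",
                                                   "baseline", "follow_up")]
    d <- setNames(sub$scan_date, sub$timepoint)[c("pre_baseline",
                                                  "baseline", "follow_up")]
    expect_equal(cls$hpdv_status[i],
                 oracle_hpdv(unname(v), unname(d),
                             ttf[[cls$patient_id[i]]]))
  }
})

test_that("cohort summary percentages are conserved and correctly rounded", {
  fxc <- fixture_classified()
  s <- summarize_cohort(fxc$cls, fxc$dr)
  expect_equal(s$lesions$n_hpdv + s$lesions$n_non_hpdv +
                 s$lesions$n_excluded, s$lesions$n_total)
  expect_equal(s$lesions$pct_hpdv + s$lesions$pct_non_hpdv +
                 s$lesions$pct_excluded, 100, tolerance = 0.1)
  # tiny cohort: 1 of 4 lesions HPDv -> 25.0%
  les <- do.call(rbind, lapply(1:4, function(i) data.frame(
    patient_id = "P1", lesion_id = paste0("L", i), organ = "lung",
    timepoint = c("pre_baseline", "baseline", "follow_up"),
    scan_date = c(-60, 0, 60),
    volume_mm3 = if (i == 1) c(800, 1000, 1800) else c(950, 1000, 1050))))
  pat <- data.frame(patient_id = "P1", ttf_days = 45, os_days = 100,
                    os_event = 1)
  cls <- classify_lesions(les, pat)
  s2 <- summarize_cohort(cls, classify_patients_dr(cls))
  expect_equal(s2$lesions$pct_hpdv, 25.0)
})
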