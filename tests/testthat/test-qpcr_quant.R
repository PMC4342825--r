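test_that("efficiency estimation matches closed forms and recovers planted E", {
  # slope -3.3219 (10-fold per 3.3219 cycles) = 100% efficiency
  perfect <- data.frame(concentration = 10^-(0:4),
                        cq = 20 + log2(10) * (0:4))
  est <- estimate_efficiency(perfect)
  expect_equal(est$efficiency, 1.0, tolerance = 1e-9)
  expect_equal(est$r_squared, 1.0, tolerance = 1e-12)

  # slope -3.45 -> E = 10^(1/3.45) - 1
  s345 <- data.frame(concentration = 10^-(0:4), cq = 20 + 3.45 * (0:4))
  expect_equal(estimate_efficiency(s345)$efficiency, 10^(1 / 3.45) - 1,
               tolerance = 1e-9)
  expect_equal(estimate_efficiency(s345)$efficiency, 0.9492, tolerance = 1e-3)

  # round-trip on a validated assay efficiency (95.1%)
  ds <- simulate_dilution_series(0.951, n_points = 6, step = 10, noise_sd = 0)
  expect_equal(estimate_efficiency(ds)$efficiency, 0.951, tolerance = 1e-9)

  expect_error(estimate_efficiency(perfect[1:2, ]), "3 distinct dilution")
  expect_error(estimate_efficiency(
    data.frame(concentration = c(1, 0.1, 0), cq = c(20, 23, 26))), "> 0")
})

test_that("efficiency estimation is unbiased on noiseless series across E", {
  for (e in c(0.55, 0.7, 0.85, 1.0, 1.1, 1.19)) {
    ds <- simulate_dilution_series(e, n_points = 5, step = 4, noise_sd = 0)
    expect_equal(estimate_efficiency(ds)$efficiency, e, tolerance = 1e-9)
  }
})

make_cq <- function(cqs, sample = "s1", assay = "g1", run = "run01",
                    kind = "unknown") {
  data.frame(sample_id = sample, condition_id = "c1", bio_replicate = 1L,
             run_id = run, assay_id = assay, tech_rep = seq_along(cqs),
             cq = cqs, sample_kind = kind, stringsAsFactors = FALSE)
}

test_that("technical replicate aggregation uses n-1 SD and flags dispersion", {
  a <- aggregate_technical_replicates(make_cq(c(24, 24, 24)))
  expect_equal(a$cq, 24)
  expect_equal(a$cq_sd, 0)
  expect_false(a$high_sd)

  b <- aggregate_technical_replicates(make_cq(c(24, 25)))
  expect_equal(b$cq, 24.5)
  expect_equal(b$cq_sd, sqrt(0.5), tolerance = 1e-12)

  c3 <- aggregate_technical_replicates(make_cq(c(24, 26, NA)))
  expect_equal(c3$cq, 25)
  expect_equal(c3$cq_sd, sqrt(2), tolerance = 1e-12)
  expect_true(c3$high_sd)
  expect_equal(c3$n_used, 2L)

  all_na <- aggregate_technical_replicates(make_cq(c(NA, NA)))
  expect_true(is.na(all_na$cq))
  expect_equal(all_na$n_used, 0L)
})

test_that("inter-run calibration mean-centres runs and demands calibrators", {
  one_run <- make_cq(c(24, 25))
  expect_identical(interrun_calibrate(one_run), one_run)

  two_runs <- rbind(
    make_cq(25, sample = "s1", run = "run01"),
    make_cq(27, sample = "s2", run = "run02"),
    make_cq(20, sample = "IRC", run = "run01", kind = "interrun_calibrator"),
    make_cq(21, sample = "IRC", run = "run02", kind = "interrun_calibrator"))
  cal <- interrun_calibrate(two_runs)
  expect_equal(cal$cq[cal$sample_id == "s1"], 25 + 0.5)
  expect_equal(cal$cq[cal$sample_id == "s2"], 27 - 0.5)
  # calibrator records themselves become equal across runs
  expect_equal(unique(cal$cq[cal$sample_kind == "interrun_calibrator"]), 20.5)

  no_cal <- rbind(make_cq(25, run = "run01"), make_cq(27, run = "run02"),
                  make_cq(20, sample = "IRC", run = "run01",
                          kind = "interrun_calibrator"))
  expect_error(interrun_calibrate(no_cal), "run02.*g1")
})

test_that("planted run offsets are removed by calibration", {
  cfg <- sim_config(n_stable_genes = 4, n_regulated_genes = 0,
                    n_conditions = 8, stable_sd_log2 = 0, bio_sd_log2 = 0,
                    tech_sd_cycles = 0, run_shift_sd_cycles = 2,
                    n_runs = 4, gdna_fraction = 0, seed = 21)
  sim <- simulate_cq_dataset(cfg)
  cal <- interrun_calibrate(sim$cq)
  unk <- cal[cal$sample_kind == "unknown", ]
  # with no biological or technical noise, calibrated Cq is constant per gene
  spread <- tapply(unk$cq, unk$assay_id, function(x) diff(range(x)))
  expect_true(all(spread < 1e-10))
})

test_that("Cq-to-quantity transform applies efficiency correction", {
  tab <- data.frame(sample_id = c("s1", "s2"), condition_id = "c1",
                    bio_replicate = 1:2, run_id = "run01", assay_id = "g1",
                    cq = c(21, 24), cq_sd = c(0.1, 0.2), n_used = 3L,
                    sample_kind = "unknown", stringsAsFactors = FALSE)
  tab <- rbind(tab, transform(tab, assay_id = "g2", cq = c(25, 26)),
               transform(tab, assay_id = "g3", cq = c(30, 28)))
  eff <- efficiency_table(c("g1", "g2", "g3"), c(1.0, 0.951, 1.0))
  qm <- cq_to_quantity(tab, eff)
  # E = 100%, dCq = 3 -> Q = 8
  expect_equal(unname(qm$quantity["g1", "s2"]), 1 / 8)
  expect_equal(unname(qm$quantity["g1", "s1"]), 1)
  # E = 95.1%, dCq = 1 -> quantity ratio = 1.951
  expect_equal(unname(qm$quantity["g2", "s1"] / qm$quantity["g2", "s2"]),
               1.951, tolerance = 1e-12)
  # per-gene max is 1 under minimum-Cq calibration
  expect_equal(unname(apply(qm$quantity, 1, max)), c(1, 1, 1))
  # technical SD propagated to log2 scale
  expect_equal(unname(qm$log2_sd["g1", "s1"]), 0.1 * log2(2))
  expect_equal(unname(qm$log2_sd["g2", "s1"]), 0.1 * log2(1.951),
               tolerance = 1e-12)
  # Cq at the calibration point gives Q = 1 for any efficiency
  expect_equal(unname(qm$quantity["g2", "s1"]), 1)

  expect_error(cq_to_quantity(tab, efficiency_table("g1", 1.0)), "g2")
})

test_that("a supplied fixed calibration Cq is honoured", {
  tab <- make_cq(c(24, 24, 24))
  agg <- aggregate_technical_replicates(tab)
  qm <- cq_to_quantity(agg, efficiency_table("g1", 1.0),
                       calibration = c(g1 = 27))
  expect_equal(unname(qm$quantity["g1", "s1"]), 8)
})

test_that("noiseless Cq data invert exactly to the planted quantities", {
  cfg <- sim_config(n_stable_genes = 5, n_regulated_genes = 2,
                    n_conditions = 6, tech_sd_cycles = 0,
                    run_shift_sd_cycles = 0, gdna_fraction = 0, seed = 13)
  sim <- simulate_cq_dataset(cfg)
  agg <- aggregate_technical_replicates(sim$cq)
  qm <- cq_to_quantity(agg, efficiency_table(
    names(sim$truth$efficiencies), sim$truth$efficiencies))
  tl <- sim$truth$true_log2q
  for (g in rownames(qm$quantity)) {
    planted <- as.numeric(t(tl[g, , ]))  # condition-major, then replicate
    names(planted) <- sprintf("%s_b%d",
                              rep(dimnames(tl)[[2]], each = dim(tl)[3]),
                              rep(seq_len(dim(tl)[3]), times = dim(tl)[2]))
    rel_planted <- 2^(planted - max(planted))
    got <- qm$quantity[g, names(planted)]
    expect_equal(unname(got), unname(rel_planted), tolerance = 1e-9)
  }
})

test_that("gDNA contamination fractions follow the ValidPrime formula", {
  unk <- rbind(make_cq(25, sample = "s1", assay = "gA"),
               make_cq(30, sample = "s1", assay = "VPA"),
               make_cq(25, sample = "s2", assay = "gA"),
               make_cq(35, sample = "s2", assay = "VPA"),
               make_cq(25, sample = "s3", assay = "gA"),
               make_cq(NA_real_, sample = "s3", assay = "VPA"))
  ctrl <- rbind(make_cq(26, sample = "gDNA", assay = "gA", kind = "gDNA_control"),
                make_cq(26, sample = "gDNA", assay = "VPA", kind = "gDNA_control"))
  rep <- assess_gdna_contamination(rbind(unk, ctrl))
  r1 <- rep[rep$sample_id == "s1", ]
  expect_equal(r1$gdna_fraction, 2^-5)
  expect_true(r1$exceeds_threshold)
  r2 <- rep[rep$sample_id == "s2", ]
  expect_equal(r2$gdna_fraction, 2^-10, tolerance = 1e-12)
  expect_false(r2$exceeds_threshold)
  r3 <- rep[rep$sample_id == "s3", ]
  expect_equal(r3$gdna_fraction, 0)
  expect_identical(r3$status, "undetected")
  expect_false(r3$exceeds_threshold)
})

test_that("planted gDNA fraction is recovered by the screen", {
  cfg <- sim_config(n_stable_genes = 3, n_regulated_genes = 0,
                    n_conditions = 4, stable_sd_log2 = 0, bio_sd_log2 = 0,
                    tech_sd_cycles = 0, run_shift_sd_cycles = 0,
                    gdna_fraction = 0.02,
                    base_cq_range = c(25, 25), seed = 31)
  sim <- simulate_cq_dataset(cfg)
  rep <- assess_gdna_contamination(sim$cq)
  expect_equal(mean(rep$gdna_fraction), 0.02, tolerance = 1e-9)
  expect_true(all(rep$exceeds_threshold))
})

test_that("Cq box statistics follow linear-interpolation quantiles", {
  tab <- make_cq(rep(24, 6))
  s <- summarize_cq_distribution(tab)$stats
  expect_equal(s$q1, s$median)
  expect_equal(s$median, s$q3)
  expect_equal(s$mean, 24)
  expect_equal(s$n_outliers, 0L)

  tab18 <- make_cq(1:8)
  s18 <- summarize_cq_distribution(tab18)$stats
  expect_equal(s18$median, 4.5)
  expect_equal(s18$q1, 2.75)
  expect_equal(s18$q3, 6.25)

  tabo <- make_cq(c(1, 2, 3, 4, 100))
  res <- summarize_cq_distribution(tabo)
  expect_equal(res$outliers$g1, 100)
  expect_equal(res$stats$whisker_high, 4)

  few <- summarize_cq_distribution(make_cq(c(20, 21, 22)))
  expect_true(is.na(few$stats$whisker_low))
  expect_equal(few$stats$median, 21)
})

test_that("efficiency table validation warns and rejects as specified", {
  expect_warning(efficiency_table("gX", 0.5), "gX")
  expect_error(efficiency_table("gX", 2.5), "\\(0, 2\\)")
  expect_silent(efficiency_table(c("a", "b"), c(0.95, 1.05)))
})
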