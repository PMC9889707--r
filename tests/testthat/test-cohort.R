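test_that("donor generation is seeded, status-conditional and validated", {
  cfg <- generation_config()
  d1 <- generate_donor("healthy", cfg, "HD1", seed = 1)
  d2 <- generate_donor("healthy", cfg, "HD1", seed = 1)
  expect_identical(d1, d2)
  expect_error(generate_donor("sick", cfg), "unknown status")

  # zero noise collapses every latent to its status-conditional location
  cfg0 <- generation_config(noise_sd = 0)
  p0 <- generate_donor("patient", cfg0, "PT1")
  L <- cfg0$latents$patient
  expect_identical(p0$latent_cd8_bias, L$cd8_bias[[1]])
  expect_identical(p0$latent_effector_bias, L$effector_bias[[1]])
  expect_equal(p0$latent_activation_threshold, exp(L$log_threshold[[1]]))
})

test_that("patient donors are CD8- and effector-biased with lower activation
           threshold (Monte-Carlo over the latent distributions)", {
  cfg <- generation_config()
  draw <- function(status, i) {
    generate_donor(status, cfg, paste0(status, i))
  }
  n <- 1000
  hd <- lapply(seq_len(n), draw, status = "healthy")
  pt <- lapply(seq_len(n), draw, status = "patient")
  get <- function(ds, f) vapply(ds, `[[`, 0, f)
  margin <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(stats::var(a) / n + stats::var(b) / n)
  }
  expect_gt(margin(get(pt, "latent_cd8_bias"),
                   get(hd, "latent_cd8_bias")), 3)
  expect_gt(margin(get(pt, "latent_effector_bias"),
                   get(hd, "latent_effector_bias")), 3)
  expect_gt(margin(get(hd, "latent_activation_threshold"),
                   get(pt, "latent_activation_threshold")), 3)
})

test_that("blood samples recover their true fractions within binomial error
           and are seeded", {
  cfg <- generation_config(noise_sd = 0)
  d <- generate_donor("healthy", cfg, "HD1")
  n <- 20000
  bl <- generate_blood_sample(d, cfg, n_events = n, seed = 11)
  bl2 <- generate_blood_sample(d, cfg, n_events = n, seed = 11)
  expect_identical(bl$cells$intensities, bl2$cells$intensities)
  expect_error(generate_blood_sample(d, cfg, n_events = 50), ">= 100")

  fv <- apply_gating(bl$cells)
  tr <- bl$truth$fractions
  # CD3 of viable: binomial sampling error at n events, 4-sigma band
  f <- tr[["pct_CD3"]]
  expect_lt(abs(fv$pct_CD3 / 100 - f), 4 * sqrt(f * (1 - f) / n) + 1e-9)
  # truth fractions are proper fractions
  fr <- tr[setdiff(names(tr), "CD4_CD8_ratio")]
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("zero-noise events are gated exactly as their truth labels", {
  cfg <- generation_config(noise_sd = 0)
  d <- generate_donor("patient", cfg, "PT1")
  bl <- generate_blood_sample(d, cfg, n_events = 500)
  x <- bl$cells$intensities
  lab <- bl$cells$labels
  thr <- gating_strategy()$thresholds
  expect_identical(unname(x[, "Viability"] <= thr["Viability"]),
                   lab$viable)
  expect_identical(unname(x[, "CD3"] > thr["CD3"]), lab$cd3)
  cd8 <- x[, "CD8"] > thr["CD8"]
  expect_identical(unname(cd8), !is.na(lab$compartment) &
                     lab$compartment == "CD8")
})

test_that("product dose laws: healthy linear, patient accelerating past the
           activation threshold, exhaustion monotone in expectation", {
  cfg <- generation_config(noise_sd = 0)
  hd <- generate_donor("healthy", cfg, "HD1")
  doses <- c(0.05, 0.1, 0.15, 0.2)
  fh <- vapply(doses, function(m) {
    d <- stimulation_dose("APC-ms", mol_pct = m)
    generate_product(hd, d, cfg, n_events = 150)$truth$class_fractions["high"]
  }, 0)
  # equally spaced doses: second differences of a linear law vanish
  expect_lt(max(abs(diff(diff(fh)))), 1e-9)

  pt <- generate_donor("patient", cfg, "PT1")  # zero noise: threshold = 0.1
  expect_equal(pt$latent_activation_threshold, 0.1)
  f <- vapply(c(0.02, 0.1, 0.2), function(m) {
    d <- stimulation_dose("APC-ms", mol_pct = m)
    generate_product(pt, d, cfg, n_events = 150)$truth$class_fractions["high"]
  }, 0)
  expect_gt((f[2] - f[3]), (f[1] - f[2]))  # faster decline past threshold

  # class fractions are a simplex
  w <- generate_product(pt, stimulation_dose("APC-ms", mol_pct = 0.15),
                        cfg, n_events = 150)$truth$class_fractions
  expect_equal(unname(sum(w)), 1, tolerance = 1e-9)
  expect_true(all(w >= 0))

  # out-of-range dose rejected
  expect_error(generate_product(pt, stimulation_dose("APC-ms", mol_pct = 0.9),
                                cfg, n_events = 150), "outside")
})

test_that("expected PD-1+TIM-3+ fraction increases from 0.1 to 0.3 mol%
           (Monte-Carlo mean comparison)", {
  cfg <- generation_config()
  frac_at <- function(m, i) {
    d <- generate_donor("patient", cfg, paste0("PT", i))
    pr <- generate_product(d, stimulation_dose("APC-ms", mol_pct = m), cfg,
                           n_events = 150,
                           seed = substream_seed(i, "mc", m))
    pr$truth$fractions[["CD8_PD1posTIM3pos"]]
  }
  lo <- vapply(seq_len(200), frac_at, 0, m = 0.1)
  hi <- vapply(seq_len(200), frac_at, 0, m = 0.3)
  expect_gt(mean(hi), mean(lo))
  expect_gt((mean(hi) - mean(lo)) /
              sqrt(stats::var(hi) / 200 + stats::var(lo) / 200), 3)
})

test_that("cytotoxicity readings round-trip through the assay formula", {
  cfg <- generation_config(noise_sd = 0)
  truth <- list(cytotox = data.frame(et_ratio = c(0, 1.25, 5),
                                     pct_cytotoxicity = c(0, 37, 100)))
  rd <- generate_cytotox_readings(truth, "S1", cfg,
                                  et_ratios = c(0, 1.25, 5))
  pct <- percent_cytotoxicity(rd$lum_sample, rd$lum_max_lysis,
                              rd$lum_target_only)
  expect_equal(pct, c(0, 37, 100), tolerance = 1e-9)
  # control identities: 0% -> sample equals target-only; 100% -> max-lysis
  expect_equal(rd$lum_sample[1], rd$lum_target_only[1])
  expect_equal(rd$lum_sample[3], rd$lum_max_lysis[3])
  expect_error(generate_cytotox_readings(truth, "S1", cfg,
                                         et_ratios = c(1.25, 5)),
               "0:1 control")
})

test_that("cohort assembly matches the study design and handles empty or
           dropped strata", {
  co <- default_cohort()
  md <- co$metadata
  expect_identical(sum(md$stage == "product" & md$status == "patient"), 49L)
  expect_identical(sum(md$stage == "product" & md$status == "healthy"), 56L)
  expect_identical(sum(md$stage == "blood"), 16L)
  expect_true(all(md$sample_id %in% names(co$samples)))

  co_p <- generate_cohort(generation_config(n_healthy = 0, n_patient = 2,
                                            n_events_per_sample = 150))
  expect_true(all(co_p$metadata$status == "patient"))

  cfg_d <- generation_config(n_healthy = 1, n_patient = 1,
                             n_events_per_sample = 150,
                             dose_dropout = list(PT1 = c(0.05, 0.2)))
  co_d <- generate_cohort(cfg_d)
  pt_doses <- co_d$metadata$dose_mol_pct[co_d$metadata$donor_id == "PT1" &
                                           co_d$metadata$stim_type == "APC-ms"]
  expect_false(any(c(0.05, 0.2) %in% pt_doses))
})

test_that("a held-out logistic discriminator separates statuses from true
           blood fractions with accuracy above 0.9", {
  cfg <- generation_config(n_healthy = 20, n_patient = 20,
                           n_events_per_sample = 150, seed = 9)
  donors <- c(lapply(1:20, function(i) generate_donor("healthy", cfg,
                                                      paste0("HD", i))),
              lapply(1:20, function(i) generate_donor("patient", cfg,
                                                      paste0("PT", i))))
  tf <- t(vapply(donors, function(d) {
    generate_blood_sample(d, cfg, n_events = 150)$truth$fractions
  }, numeric(27)))
  y <- factor(rep(c("healthy", "patient"), each = 20))
  # leave-one-out logistic fit on the status-informative axes
  df <- data.frame(y = y, cd8 = tf[, "pct_CD8"],
                   eff = tf[, "CD8_CD45RAposCCR7neg"])
  hits <- vapply(seq_len(nrow(df)), function(i) {
    fit <- suppressWarnings(stats::glm(y ~ cd8 + eff, binomial,
                                       data = df[-i, ]))
    p <- stats::predict(fit, df[i, ], type = "response")
    (p > 0.5) == (df$y[i] == "patient")
  }, TRUE)
  expect_gt(mean(hits), 0.9)
})

test_that("identical configs give byte-identical serialized cohorts", {
  cfg <- generation_config(n_healthy = 1, n_patient = 1,
                           n_events_per_sample = 150, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1, ground_truth = TRUE)
  write_cohort(generate_cohort(cfg), d2, ground_truth = TRUE)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
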