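#' Configuration for the synthetic-cohort generator
#'
#' The generator emulates the statistical structure of a CAR-T manufacturing
#' study cohort: healthy-donor versus leukemia-patient blood phenotypes
#' (patients CD8-biased, enriched for CD45RA+CCR7- effector-like CD8 cells),
#' products manufactured across a 0.02-0.3 mol% stimulation-dose range with
#' dose-dependent exhaustion (PD-1/TIM-3), activation (CD25/CD137), memory
#' (CD45RA/CCR7) and CD4:CD8 shifts, and a highly-cytotoxic cell fraction
#' that declines linearly in dose for healthy donors but accelerates past a
#' donor-specific activation threshold for patients. Ground truth for every
#' generated quantity is recorded for testing.
#'
#' @param n_healthy,n_patient donors per stratum (default 8 + 8; with the
#'   default product design this yields 56 healthy and 49 patient products).
#' @param doses_mol_pct APC-ms doses, mol% biotin, all in (0, 1).
#' @param n_events_per_sample events per generated sample (>= 100).
#' @param noise_sd global noise scale (dimensionless, default 1). It
#'   multiplies every stochastic spread — donor-latent SDs, per-sample
#'   logit jitter, log-intensity SD and assay noise — so `noise_sd = 0`
#'   produces a fully deterministic zero-noise cohort.
#' @param seed master seed; per-sample substreams are derived from it by
#'   stable ID hashing, so the same seed gives a bit-identical cohort.
#' @param panel a [marker_panel()].
#' @param conversion a [dose_conversion_table()].
#' @param et_ratios effector:target ratios for cytotoxicity readings; must
#'   include the 0 (target-only) control.
#' @param assay_noise_pct SD of assay noise on the percent-cytotoxicity
#'   scale (scaled by `noise_sd`).
#' @param random_effect_sd SD of the per-sample logit jitter applied to
#'   subpopulation probabilities (donor random effects act through the
#'   donor latents).
#' @param dose_dropout named list: donor_id -> numeric mol% doses to skip
#'   for that donor (missing doses are absent rows, not NA rows).
#' @return Object of class `generation_config`.
#' @export
generation_config <- function(n_healthy = 8, n_patient = 8,
                              doses_mol_pct = c(0.02, 0.05, 0.1, 0.15, 0.2, 0.3),
                              n_events_per_sample = 5000,
                              noise_sd = 1, seed = 1L,
                              panel = marker_panel(),
                              conversion = dose_conversion_table(),
                              et_ratios = c(20, 10, 5, 2.5, 1.25, 0),
                              assay_noise_pct = 3,
                              random_effect_sd = 0.05,
                              dose_dropout = list()) {
  if (any(doses_mol_pct <= 0 | doses_mol_pct >= 1)) {
    stop("all doses must lie in (0, 1) mol%")
  }
  if (n_events_per_sample < 100) stop("n_events_per_sample must be >= 100")
  structure(list(
    n_healthy = n_healthy, n_patient = n_patient,
    doses_mol_pct = doses_mol_pct,
    n_events_per_sample = as.integer(n_events_per_sample),
    noise_sd = noise_sd, seed = as.integer(seed), panel = panel,
    conversion = conversion, et_ratios = et_ratios,
    assay_noise_pct = assay_noise_pct, random_effect_sd = random_effect_sd,
    dose_dropout = dose_dropout,
    # two-mode log-normal intensity model: negative/positive mode means and
    # the log-scale SD around them
    intensity = list(neg_mode = 50, pos_mode = 1000, sdlog = 0.35),
    # status-conditional donor-latent distributions (mean, sd); thresholds
    # are log-normal (log-mean, log-sd). Patients: higher CD8 and effector
    # bias, lower activation threshold.
    latents = list(
      healthy = list(cd8_bias = c(0, 0.25), effector_bias = c(0, 0.3),
                     log_threshold = c(log(0.20), 0.08),
                     cytotox_offset = c(0, 0.04)),
      patient = list(cd8_bias = c(0.9, 0.25), effector_bias = c(1.1, 0.3),
                     log_threshold = c(log(0.10), 0.08),
                     cytotox_offset = c(0, 0.04))
    )
  ), class = "generation_config")
}

clamp01 <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

# smooth hinge: ~0 below 0, ~x above; width w controls the bend
softplus <- function(x, w = 0.04) w * log1p(exp(x / w))

#' Draw a donor profile from the status-conditional latent distributions
#'
#' @param status `"healthy"` or `"patient"`.
#' @param config a [generation_config()].
#' @param donor_id donor identifier (also keys the RNG substream).
#' @param seed substream seed; derived from the master seed and donor ID by
#'   default.
#' @return Object of class `donor_profile` with latent CD8 bias and
#'   effector bias (logit offsets), activation threshold (mol% scale),
#'   cytotoxicity offset and the per-sample random-effect SD.
#' @export
generate_donor <- function(status, config = generation_config(),
                           donor_id = paste0(ifelse(status == "healthy",
                                                    "HD", "PT"), "1"),
                           seed = substream_seed(config$seed, "donor",
                                                 donor_id)) {
  if (!status %in% c("healthy", "patient")) {
    stop("unknown status '", status, "': must be 'healthy' or 'patient'")
  }
  L <- config$latents[[status]]
  ns <- config$noise_sd
  z <- with_seed(seed, stats::rnorm(4))
  eb <- L$effector_bias[1] + L$effector_bias[2] * ns * z[2]
  structure(list(
    donor_id = as.character(donor_id), status = status,
    latent_cd8_bias = L$cd8_bias[1] + L$cd8_bias[2] * ns * z[1],
    latent_effector_bias = eb,
    # more effector-differentiated donors activate (and exhaust) at lower
    # stimulation; coupling is centered so the status-conditional mean
    # threshold stays at the configured value
    latent_activation_threshold =
      exp(L$log_threshold[1] - 0.3 * (eb - L$effector_bias[1]) +
            L$log_threshold[2] * ns * z[3]),
    latent_cytotox_offset = L$cytotox_offset[1] + L$cytotox_offset[2] * ns * z[4],
    random_effect_sd = config$random_effect_sd
  ), class = "donor_profile")
}

#' @export
print.donor_profile <- function(x, ...) {
  cat("Donor ", x$donor_id, " (", x$status, "): CD8 bias ",
      signif(x$latent_cd8_bias, 3), ", effector bias ",
      signif(x$latent_effector_bias, 3), ", activation threshold ",
      signif(x$latent_activation_threshold, 3), " mol%\n", sep = "")
  invisible(x)
}

# positively-dependent 2x2 quadrant probabilities from two marginals
.quad_probs <- function(p1, p2, rho = 0.5) {
  p11 <- rho * min(p1, p2) + (1 - rho) * p1 * p2
  c(pp = p11, pn = p1 - p11, np = p2 - p11, nn = 1 - p1 - p2 + p11)
}

# per-sample jitter on the logit scale
.jit <- function(base_p, sd, n = 1) {
  clamp01(stats::plogis(stats::qlogis(clamp01(base_p)) +
                          stats::rnorm(length(base_p), 0, sd)))
}

# Subpopulation-probability model for a blood sample. All stochastic draws
# use the current RNG state (callers wrap in with_seed).
.blood_model <- function(donor, config) {
  sd <- donor$random_effect_sd * config$noise_sd
  pat <- donor$status == "patient"
  p_dead <- .jit(0.05, sd)
  p_cd3 <- .jit(0.90, sd)
  p_cd8 <- clamp01(stats::plogis(stats::qlogis(0.35) + donor$latent_cd8_bias +
                                   stats::rnorm(1, 0, sd)))
  # memory quadrants: naive RA+CCR7+, effector RA+CCR7-, cm RA-CCR7+,
  # em RA-CCR7-
  p_eff8 <- clamp01(stats::plogis(stats::qlogis(0.20) +
                                    donor$latent_effector_bias +
                                    stats::rnorm(1, 0, sd)))
  rest8 <- c(0.45, 0.20, 0.35)
  mem8 <- c(naive = (1 - p_eff8) * rest8[1], eff = p_eff8,
            cm = (1 - p_eff8) * rest8[2], em = (1 - p_eff8) * rest8[3])
  p_eff4 <- clamp01(stats::plogis(stats::qlogis(0.10) +
                                    0.5 * donor$latent_effector_bias +
                                    stats::rnorm(1, 0, sd)))
  rest4 <- c(0.55, 0.25, 0.20)
  mem4 <- c(naive = (1 - p_eff4) * rest4[1], eff = p_eff4,
            cm = (1 - p_eff4) * rest4[2], em = (1 - p_eff4) * rest4[3])
  p_pd1 <- .jit(if (pat) 0.13 else 0.10, sd)
  p_tim3 <- .jit(0.05, sd)
  exh <- .quad_probs(p_pd1, p_tim3, rho = 0.4)
  list(
    p_dead = p_dead, p_cd3 = p_cd3, p_cd8 = p_cd8, p_car = 0.01,
    CD8 = list(mem = mem8, exh = exh, p_cd25 = .jit(0.08, sd),
               p_cd137 = .jit(0.05, sd),
               p_cd95 = .jit(if (pat) 0.55 else 0.50, sd)),
    CD4 = list(mem = mem4, exh = exh, p_cd25 = .jit(0.08, sd),
               p_cd137 = .jit(0.05, sd),
               p_cd95 = .jit(if (pat) 0.55 else 0.35, sd))
  )
}

# True high/moderate/low cytotoxic-class fractions for a product.
# Healthy: exactly linear decline in dose. Patient: linear component plus a
# smooth accelerating (softplus) decline past the donor's activation
# threshold. Deterministic given (donor, dose) so the ground-truth dose laws
# are exact by construction.
.class_fractions <- function(donor, mol_equiv) {
  d <- mol_equiv
  off <- donor$latent_cytotox_offset
  if (donor$status == "healthy") {
    f_h <- 0.62 + off - 1.5 * d
  } else {
    f_h <- 0.52 + off - 0.6 * d -
      1.2 * softplus(d - donor$latent_activation_threshold)
  }
  f_h <- min(max(f_h, 0.02), 0.95)
  f_l <- min(max(0.08 + 0.9 * d, 0.01), 0.90)
  f_m <- 1 - f_h - f_l
  if (f_m < 0.01) {
    s <- (1 - 0.01) / (f_h + f_l)
    f_h <- f_h * s; f_l <- f_l * s; f_m <- 0.01
  }
  c(high = f_h, moderate = f_m, low = f_l)
}

# Class-conditional phenotype templates for product events, with direct
# dose shifts on exhaustion/activation/memory markers and (patients) a
# past-threshold loss of naive CD8 cells. Dose-effect amplitudes are set
# so that stimulation dose dominates product phenotype, as reported for
# the emulated study design.
.product_class_model <- function(donor, mol_equiv, config, sd) {
  d <- mol_equiv
  pat <- donor$status == "patient"
  dshift <- 6 * d
  thr_loss <- if (pat) 6 * softplus(d - donor$latent_activation_threshold) else 0
  shift <- function(p, s) clamp01(stats::plogis(stats::qlogis(clamp01(p)) + s))
  mk <- function(pd1, tim3, mem, cd25, cd137, cd95) {
    if (pat) tim3 <- shift(tim3, 0.4)
    p1 <- .jit(shift(pd1, dshift), sd)
    p2 <- .jit(shift(tim3, dshift), sd)
    # memory quadrant dose laws: naive cells lost past the activation
    # threshold (patients), effector-like cells lost progressively with
    # dose but carried over from the donor's blood effector bias;
    # central/effector-memory absorb the difference
    naive <- shift(mem[1], -thr_loss)
    eff <- shift(mem[2], -4 * d + 0.35 * donor$latent_effector_bias)
    rest <- mem[3:4] / sum(mem[3:4])
    mem <- c(naive, eff, (1 - naive - eff) * rest)
    names(mem) <- c("naive", "eff", "cm", "em")
    list(mem = mem, exh = .quad_probs(p1, p2, rho = 0.5),
         p_cd25 = .jit(shift(cd25, dshift), sd),
         p_cd137 = .jit(shift(cd137, dshift), sd),
         p_cd95 = .jit(cd95, sd))
  }
  list(
    high = mk(0.05, 0.04, c(0.25, 0.55, 0.08, 0.12), 0.20, 0.15, 0.60),
    moderate = mk(0.30, 0.25, c(0.30, 0.20, 0.25, 0.25), 0.45, 0.40, 0.70),
    low = mk(0.78, 0.70, c(0.08, 0.17, 0.20, 0.55), 0.82, 0.78, 0.80)
  )
}

# expected subpopulation fractions implied by a class mixture (one
# compartment)
.mix_compartment <- function(classes, w) {
  agg <- function(f) sum(vapply(seq_along(w),
                                function(i) w[i] * f(classes[[i]]), 0))
  list(
    mem = c(naive = agg(function(cl) cl$mem["naive"]),
            eff = agg(function(cl) cl$mem["eff"]),
            cm = agg(function(cl) cl$mem["cm"]),
            em = agg(function(cl) cl$mem["em"])),
    exh = c(pp = agg(function(cl) cl$exh["pp"]),
            pn = agg(function(cl) cl$exh["pn"]),
            np = agg(function(cl) cl$exh["np"]),
            nn = agg(function(cl) cl$exh["nn"])),
    p_cd25 = agg(function(cl) cl$p_cd25),
    p_cd137 = agg(function(cl) cl$p_cd137),
    p_cd95 = agg(function(cl) cl$p_cd95)
  )
}

# ground-truth feature fractions (keys match gated feature columns; values
# are fractions in [0, 1], CD4_CD8_ratio on its natural scale)
.truth_fractions <- function(p_cd3, p_cd8, p_car, comp4, comp8) {
  out <- c(pct_CD3 = p_cd3, pct_CD4 = 1 - p_cd8, pct_CD8 = p_cd8,
           pct_CAR = p_car, CD4_CD8_ratio = (1 - p_cd8) / p_cd8)
  quad <- function(prefix, comp) {
    v <- c(comp$mem["naive"], comp$mem["eff"], comp$mem["cm"], comp$mem["em"],
           comp$exh["pp"], comp$exh["pn"], comp$exh["np"], comp$exh["nn"],
           comp$p_cd25, comp$p_cd137, comp$p_cd95)
    names(v) <- paste0(prefix, "_",
                       c("CD45RAposCCR7pos", "CD45RAposCCR7neg",
                         "CD45RAnegCCR7pos", "CD45RAnegCCR7neg",
                         "PD1posTIM3pos", "PD1posTIM3neg",
                         "PD1negTIM3pos", "PD1negTIM3neg",
                         "CD25pos", "CD137pos", "CD95pos"))
    v
  }
  c(out, quad("CD4", comp4), quad("CD8", comp8))
}

# draw event marker-positivity and intensities for one sample
.draw_events <- function(n, model, classes, class_w, config, sample_id) {
  markers <- as.character(config$panel)
  ns <- config$noise_sd
  dead <- stats::runif(n) < model$p_dead
  cd3 <- !dead & stats::runif(n) < model$p_cd3
  is_cd8 <- cd3 & stats::runif(n) < model$p_cd8
  is_cd4 <- cd3 & !is_cd8
  cls <- rep(NA_character_, n)
  if (!is.null(class_w)) {
    cls[cd3] <- sample(names(class_w), sum(cd3), replace = TRUE,
                       prob = class_w)
  }
  pos <- matrix(FALSE, n, length(markers), dimnames = list(NULL, markers))
  pos[, "Viability"] <- dead
  pos[, "CD3"] <- cd3
  pos[, "CD4"] <- is_cd4
  pos[, "CD8"] <- is_cd8
  pos[cd3, "CAR"] <- stats::runif(sum(cd3)) < model$p_car
  mem_lab <- rep(NA_character_, n)
  for (comp in c("CD4", "CD8")) {
    in_comp <- if (comp == "CD8") is_cd8 else is_cd4
    idx <- which(in_comp)
    if (!length(idx)) next
    if (is.null(class_w)) {
      groups <- list(idx)
      submodels <- list(model[[comp]])
    } else {
      groups <- split(idx, cls[idx])
      submodels <- lapply(names(groups), function(cl) classes[[cl]])
    }
    for (gi in seq_along(groups)) {
      ii <- groups[[gi]]
      m <- submodels[[gi]]
      mem <- sample(c("naive", "eff", "cm", "em"), length(ii), replace = TRUE,
                    prob = m$mem)
      exh <- sample(c("pp", "pn", "np", "nn"), length(ii), replace = TRUE,
                    prob = m$exh)
      mem_lab[ii] <- mem
      pos[ii, "CD45RA"] <- mem %in% c("naive", "eff")
      pos[ii, "CCR7"] <- mem %in% c("naive", "cm")
      pos[ii, "PD1"] <- exh %in% c("pp", "pn")
      pos[ii, "TIM3"] <- exh %in% c("pp", "np")
      pos[ii, "CD25"] <- stats::runif(length(ii)) < m$p_cd25
      pos[ii, "CD137"] <- stats::runif(length(ii)) < m$p_cd137
      pos[ii, "CD95"] <- stats::runif(length(ii)) < m$p_cd95
    }
  }
  modes <- ifelse(pos, config$intensity$pos_mode, config$intensity$neg_mode)
  intens <- exp(log(modes) +
                  config$intensity$sdlog * ns *
                    stats::rnorm(length(modes)))
  dim(intens) <- dim(pos)
  colnames(intens) <- markers
  labels <- data.frame(
    viable = !dead, cd3 = cd3,
    compartment = ifelse(is_cd8, "CD8", ifelse(is_cd4, "CD4", NA)),
    memory = mem_lab, cytotox_class = cls, stringsAsFactors = FALSE)
  single_cell_matrix(intens, sample_id, labels = labels)
}

#' Generate a pre-stimulation blood sample for a donor
#'
#' Events are a mixture over T-cell subpopulations (CD4/CD8, CD45RA x CCR7
#' memory quadrants, PD-1 x TIM-3 quadrants, CD25/CD137/CD95 positivity)
#' with two-mode log-normal marker intensities; mixture weights follow the
#' donor's latent biases. The realized mixture probabilities are returned as
#' ground truth.
#'
#' @param donor a [generate_donor()] profile.
#' @param config a [generation_config()].
#' @param n_events events to draw (>= 100).
#' @param seed substream seed (defaults to a hash of the donor ID).
#' @return list with `cells` (a [single_cell_matrix()] with per-event truth
#'   labels) and `truth` (list with `fractions`, the feature-keyed true
#'   fractions in [0, 1]).
#' @export
generate_blood_sample <- function(donor, config = generation_config(),
                                  n_events = config$n_events_per_sample,
                                  seed = substream_seed(config$seed, "blood",
                                                        donor$donor_id)) {
  if (n_events < 100) stop("n_events must be >= 100")
  with_seed(seed, {
    model <- .blood_model(donor, config)
    cells <- .draw_events(n_events, model, classes = NULL, class_w = NULL,
                          config, paste0(donor$donor_id, "_blood"))
    truth <- .truth_fractions(model$p_cd3, model$p_cd8, model$p_car,
                              model$CD4, model$CD8)
    list(cells = cells, truth = list(fractions = truth))
  })
}

# true cytotoxicity (%) across E:T ratios from class fractions
.true_cytotox <- function(class_fractions, et_ratios) {
  c125 <- 100 * clamp01(0.08 + 0.80 * class_fractions["high"] +
                          0.35 * class_fractions["moderate"] +
                          0.05 * class_fractions["low"], eps = 0)
  scale <- (1 - exp(-et_ratios / 2)) / (1 - exp(-1.25 / 2))
  data.frame(et_ratio = et_ratios,
             pct_cytotoxicity = pmin(unname(c125) * scale, 98))
}

#' Generate a CAR-T product sample for a donor at a stimulation dose
#'
#' Product events are drawn from three latent cytotoxic-class archetypes
#' (high / moderate / low) whose mixing weights follow the donor- and
#' dose-specific class-fraction laws: a linear decline of the high fraction
#' with dose for healthy donors, and a decline that accelerates past the
#' donor's latent activation threshold for patients. Exhaustion
#' (PD-1/TIM-3), activation (CD25/CD137) and the CD4:CD8 ratio increase
#' with dose in expectation; patient naive (CD45RA+CCR7+) CD8 cells are lost
#' past the threshold.
#'
#' @inheritParams generate_blood_sample
#' @param dose a [stimulation_dose()] within the configured range.
#' @return list with `cells` and `truth` (`fractions`, `class_fractions`,
#'   `cytotox` data.frame of true % cytotoxicity per E:T ratio).
#' @export
generate_product <- function(donor, dose, config = generation_config(),
                             n_events = config$n_events_per_sample,
                             seed = substream_seed(config$seed, "product",
                                                   donor$donor_id,
                                                   dose$label)) {
  stopifnot(inherits(dose, "stimulation_dose"))
  rng <- range(config$doses_mol_pct)
  if (dose$mol_equiv < rng[1] - 1e-9 || dose$mol_equiv > rng[2] + 1e-9) {
    stop("dose ", dose$label, " outside configured range [",
         rng[1], ", ", rng[2], "] mol% equivalent")
  }
  with_seed(seed, {
    sd <- donor$random_effect_sd * config$noise_sd
    w <- .class_fractions(donor, dose$mol_equiv)
    classes <- .product_class_model(donor, dose$mol_equiv, config, sd)
    pat <- donor$status == "patient"
    p_cd8_blood <- clamp01(stats::plogis(stats::qlogis(0.35) +
                                           donor$latent_cd8_bias))
    p_cd8 <- clamp01(stats::plogis(stats::qlogis(p_cd8_blood) -
                                     3.0 * dose$mol_equiv +
                                     stats::rnorm(1, 0, sd)))
    model <- list(p_dead = .jit(0.08, sd), p_cd3 = .jit(0.95, sd),
                  p_cd8 = p_cd8,
                  p_car = clamp01(stats::plogis(stats::qlogis(0.6) +
                                                  (if (pat) 1.0 else 0) *
                                                    dose$mol_equiv)))
    cells <- .draw_events(n_events, model, classes = classes, class_w = w,
                          config,
                          paste0(donor$donor_id, "_", dose$label))
    comp <- .mix_compartment(classes, w)
    truth <- list(
      fractions = .truth_fractions(model$p_cd3, model$p_cd8, model$p_car,
                                   comp, comp),
      class_fractions = w,
      cytotox = .true_cytotox(w, config$et_ratios))
    list(cells = cells, truth = truth)
  })
}

#' Generate luminescence triplets consistent with a true cytotoxicity curve
#'
#' Emits (sample, max-lysis control, target-only control) luminescence
#' values per E:T ratio such that [percent_cytotoxicity()] recovers the true
#' cytotoxicity up to assay noise (exactly, at zero noise).
#'
#' @param truth a product `truth` list from [generate_product()].
#' @param sample_id sample the readings belong to.
#' @param config a [generation_config()].
#' @param et_ratios ratios to emit; must include the 0 (target-only)
#'   control and be present in the truth table.
#' @param seed substream seed.
#' @return data.frame of luminescence readings (one row per ratio).
#' @export
generate_cytotox_readings <- function(truth, sample_id,
                                      config = generation_config(),
                                      et_ratios = config$et_ratios,
                                      seed = substream_seed(config$seed,
                                                            "cytotox",
                                                            sample_id)) {
  if (!length(et_ratios)) stop("et_ratios must be non-empty")
  if (!any(et_ratios == 0)) stop("et_ratios must include the 0:1 control")
  tab <- truth$cytotox
  if (!all(et_ratios %in% tab$et_ratio)) {
    stop("requested E:T ratio(s) absent from truth table")
  }
  lum_to <- 40000; lum_max <- 2000
  with_seed(seed, {
    c_true <- tab$pct_cytotoxicity[match(et_ratios, tab$et_ratio)]
    c_noisy <- c_true + stats::rnorm(length(et_ratios), 0,
                                     config$assay_noise_pct * config$noise_sd)
    c_noisy[et_ratios == 0] <- 0  # no effectors, no killing
    data.frame(sample_id = sample_id, et_ratio = et_ratios,
               lum_sample = lum_max + (1 - c_noisy / 100) * (lum_to - lum_max),
               lum_max_lysis = lum_max, lum_target_only = lum_to)
  })
}

# default product design: every donor x every APC-ms dose (minus dropout);
# healthy donors additionally D3:1; the last patient donor additionally
# D1:1. At 8 + 8 donors and 6 doses this emits 56 healthy and 49 patient
# products.
.default_design <- function(config, donors) {
  rows <- list()
  pat_ids <- vapply(Filter(function(d) d$status == "patient", donors),
                    function(d) d$donor_id, "")
  for (d in donors) {
    doses <- setdiff(config$doses_mol_pct,
                     config$dose_dropout[[d$donor_id]] %||% numeric(0))
    for (m in doses) {
      rows[[length(rows) + 1L]] <-
        list(donor_id = d$donor_id,
             dose = stimulation_dose("APC-ms", mol_pct = m,
                                     table = config$conversion))
    }
    extra <- NULL
    if (d$status == "healthy") {
      extra <- stimulation_dose("Dynabead", bead_ratio = 3,
                                table = config$conversion)
    } else if (length(pat_ids) && d$donor_id == pat_ids[length(pat_ids)]) {
      extra <- stimulation_dose("Dynabead", bead_ratio = 1,
                                table = config$conversion)
    }
    if (!is.null(extra)) {
      rows[[length(rows) + 1L]] <- list(donor_id = d$donor_id, dose = extra)
    }
  }
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic cohort
#'
#' Draws donors, one blood sample per donor, one product per (donor, dose)
#' in the product design, and luminescence cytotoxicity readings per
#' product, all cross-referenced by IDs and carrying ground truth. The
#' whole bundle is a deterministic function of the config (substream seeds
#' are hashed from the master seed and artifact IDs).
#'
#' @param config a [generation_config()].
#' @return Object of class `cart_cohort`: list with `config`, `donors`,
#'   `samples` (named list of [single_cell_matrix()]), `metadata`
#'   (data.frame, one row per sample), `readings` (luminescence
#'   data.frame across products) and `truth` (named list per sample).
#' @export
generate_cohort <- function(config = generation_config()) {
  donors <- c(
    lapply(seq_len(config$n_healthy), function(i)
      generate_donor("healthy", config, donor_id = paste0("HD", i))),
    lapply(seq_len(config$n_patient), function(i)
      generate_donor("patient", config, donor_id = paste0("PT", i)))
  )
  names(donors) <- vapply(donors, function(d) d$donor_id, "")
  samples <- list(); truth <- list(); md <- list(); readings <- list()
  for (d in donors) {
    bl <- generate_blood_sample(d, config)
    sid <- bl$cells$sample_id
    samples[[sid]] <- bl$cells
    truth[[sid]] <- bl$truth
    md[[sid]] <- data.frame(sample_id = sid, donor_id = d$donor_id,
                            status = d$status, stage = "blood",
                            stim_type = NA_character_,
                            dose_mol_pct = NA_real_,
                            dose_pg_per_cell = NA_real_)
  }
  for (row in .default_design(config, donors)) {
    d <- donors[[row$donor_id]]
    pr <- generate_product(d, row$dose, config)
    sid <- pr$cells$sample_id
    samples[[sid]] <- pr$cells
    truth[[sid]] <- pr$truth
    md[[sid]] <- data.frame(sample_id = sid, donor_id = d$donor_id,
                            status = d$status, stage = "product",
                            stim_type = row$dose$stim_type,
                            dose_mol_pct = row$dose$mol_equiv,
                            dose_pg_per_cell = row$dose$pg_per_cell)
    readings[[sid]] <- generate_cytotox_readings(pr$truth, sid, config)
  }
  structure(list(config = config, donors = donors, samples = samples,
                 metadata = do.call(rbind, c(md, make.row.names = FALSE)),
                 readings = do.call(rbind, c(readings,
                                             make.row.names = FALSE)),
                 truth = truth),
            class = "cart_cohort")
}

#' @export
print.cart_cohort <- function(x, ...) {
  md <- x$metadata
  cat("Synthetic CAR-T cohort: ", length(x$donors), " donors (",
      sum(vapply(x$donors, function(d) d$status == "healthy", TRUE)),
      " healthy, ",
      sum(vapply(x$donors, function(d) d$status == "patient", TRUE)),
      " patient)\n", sep = "")
  for (st in c("healthy", "patient")) {
    cat("  ", st, ": ", sum(md$stage == "blood" & md$status == st),
        " blood samples, ", sum(md$stage == "product" & md$status == st),
        " products\n", sep = "")
  }
  cat("  ", x$config$n_events_per_sample, " events/sample, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}
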