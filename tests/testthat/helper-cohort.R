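# shared fixtures, built once per test run

.fixtures <- new.env()

# small cohort for structural tests (3 + 3 donors, 600 events/sample)
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- generation_config(n_healthy = 3, n_patient = 3,
                             n_events_per_sample = 600, seed = 42)
    .fixtures$small <- generate_cohort(cfg)
  }
  .fixtures$small
}

# full default cohort at seed 1 (study-scale: 56 + 49 products)
default_cohort <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- generate_cohort(generation_config(seed = 1))
  }
  .fixtures$default
}

# event matrix where every event passes (or fails) chosen gates exactly:
# markers listed in `pos` get intensity 1000, the rest 50 (viability dye 50
# = viable unless "Viability" is listed)
toy_events <- function(n, pos = character(0), sample_id = "S1") {
  markers <- as.character(marker_panel())
  x <- matrix(50, n, length(markers), dimnames = list(NULL, markers))
  x[, pos] <- 1000
  single_cell_matrix(x, sample_id)
}

# classifier design: products x (blood features + dose), labels from
# product clusters, for one stratum of a cohort
classifier_design <- function(cohort, stratum, k = 5, seed = 1) {
  ft <- cohort_features(cohort)
  pf <- ft[ft$stage == "product" & ft$status == stratum, ]
  bf <- ft[ft$stage == "blood" & ft$status == stratum, ]
  pfz <- suppressWarnings(zscore_features(pf))
  cl <- cluster_products(pfz, k = k, seed = seed)
  bfz <- suppressWarnings(zscore_features(bf))
  x <- bfz[match(pf$donor_id, bfz$donor_id), feature_columns(bfz),
           drop = FALSE]
  x$dose_pg_per_cell <- pf$dose_pg_per_cell
  rownames(x) <- NULL
  list(x = x, labels = factor(cl$labels[pf$sample_id]), cluster = cl,
       products = pf, blood = bfz)
}

# LODO design frame for the patient stratum of a cohort
patient_dose_frame <- function(cohort) {
  ft <- cohort_features(cohort)
  pf <- ft[ft$stage == "product" & ft$status == "patient" &
             ft$stim_type == "APC-ms", ]
  bf <- ft[ft$stage == "blood" & ft$status == "patient", ]
  dose_model_frame(suppressWarnings(zscore_features(bf)),
                   suppressWarnings(zscore_features(pf)))
}

# planted 3-blob event pool: 6 products, two per blob, blob-determined
# cytotoxicity {10, 50, 90}; all events pass viability/CD3/CD8 gates
planted_blob_pool <- function(n_per_product = 500, noise = 0.15,
                              seed = 5) {
  markers <- as.character(marker_panel())
  with_seed(seed, {
    centers <- matrix(stats::rnorm(3 * length(markers)), 3) * 4 + 6
    blob_of <- c(P1 = 1, P2 = 1, P3 = 2, P4 = 2, P5 = 3, P6 = 3)
    cells <- lapply(names(blob_of), function(p) {
      b <- blob_of[[p]]
      x <- exp(sweep(matrix(stats::rnorm(n_per_product * length(markers),
                                         0, noise),
                            n_per_product), 2, centers[b, ], `+`))
      colnames(x) <- markers
      x[, "Viability"] <- 50
      x[, "CD3"] <- 1000
      x[, "CD8"] <- 1000
      single_cell_matrix(x, p)
    })
    names(cells) <- names(blob_of)
    list(cells = cells,
         cytotox = c(P1 = 10, P2 = 10, P3 = 50, P4 = 50, P5 = 90, P6 = 90),
         blob = blob_of,
         blob_class = c(P1 = "low", P2 = "low", P3 = "moderate",
                        P4 = "moderate", P5 = "high", P6 = "high"))
  })
}
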