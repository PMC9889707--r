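#' Gate every sample of a cohort into a feature table
#'
#' Convenience wrapper joining [gate_features()] with the cohort's
#' metadata.
#'
#' @param cohort a [generate_cohort()] bundle.
#' @param strategy a [gating_strategy()].
#' @param stage optionally restrict to `"blood"` or `"product"` samples.
#' @return A feature table (metadata + gated frequencies).
#' @export
cohort_features <- function(cohort, strategy = gating_strategy(),
                            stage = NULL) {
  md <- cohort$metadata
  if (!is.null(stage)) md <- md[md$stage == stage, , drop = FALSE]
  gate_features(cohort$samples[md$sample_id], md, strategy)
}

#' Observed percent cytotoxicity per product at one E:T ratio
#'
#' Builds a cytotoxicity curve per product from the cohort's luminescence
#' readings and extracts the value at the requested ratio.
#'
#' @param cohort a [generate_cohort()] bundle.
#' @param et_ratio E:T ratio (default 1.25).
#' @return Named numeric vector: sample_id -> percent cytotoxicity.
#' @export
product_cytotox <- function(cohort, et_ratio = 1.25) {
  by_id <- split(cohort$readings, cohort$readings$sample_id)
  vapply(by_id, function(r) curve_at(build_curve(r), et_ratio), 0)
}

#' PCA summary of a feature table
#'
#' Principal components of the (z-scored) feature columns, for descriptive
#' reporting: per-sample scores, per-feature loadings and the variance
#' explained per component. Components follow a deterministic sign
#' convention — the largest-magnitude loading of each component is made
#' positive — so repeated runs agree.
#'
#' @param table feature table (>= 2 samples, >= 2 features; z-score first).
#' @param n_components components to keep (truncated to the matrix rank).
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components) and `var_explained` (fractions).
#' @export
pca_summary <- function(table, n_components = 2) {
  fc <- feature_columns(table)
  if (nrow(table) < 2 || length(fc) < 2) {
    stop("need >= 2 samples and >= 2 features")
  }
  x <- as.matrix(table[, fc, drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  m <- min(n_components, rank)
  load <- pc$rotation[, seq_len(m), drop = FALSE]
  scores <- pc$x[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- if (!is.null(table$sample_id)) table$sample_id
  list(scores = scores, loadings = load,
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(m)])
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Emits `events_<sample_id>.csv` (one row per event, raw linear-scale
#' intensities), `cohort_manifest.json` (donors, statuses, doses in mol%
#' and pg/cell, file paths, seed), `cytotox.csv` (luminescence readings
#' with computed percent cytotoxicity) and `ground_truth.json` (test-only;
#' withheld from analysis by default).
#'
#' @param cohort a [generate_cohort()] bundle.
#' @param dir output directory (created if needed).
#' @param ground_truth also write the ground-truth JSON.
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir, ground_truth = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in cohort$samples) {
    df <- as.data.frame(s$intensities)
    df$sample_id <- s$sample_id
    p <- file.path(dir, paste0("events_", s$sample_id, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths[s$sample_id] <- basename(p)
  }
  rd <- cohort$readings
  rd$pct_cytotoxicity <- percent_cytotoxicity(rd$lum_sample,
                                              rd$lum_max_lysis,
                                              rd$lum_target_only)
  utils::write.csv(rd, file.path(dir, "cytotox.csv"), row.names = FALSE)
  manifest <- list(
    seed = cohort$config$seed,
    n_events_per_sample = cohort$config$n_events_per_sample,
    donors = lapply(cohort$donors, function(d) {
      list(donor_id = d$donor_id, status = d$status)
    }),
    samples = lapply(seq_len(nrow(cohort$metadata)), function(i) {
      m <- cohort$metadata[i, ]
      list(sample_id = m$sample_id, donor_id = m$donor_id,
           status = m$status, stage = m$stage, stim_type = m$stim_type,
           dose_mol_pct = m$dose_mol_pct,
           dose_pg_per_cell = m$dose_pg_per_cell,
           events_file = unname(paths[m$sample_id]))
    }))
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (ground_truth) {
    jsonlite::write_json(
      lapply(cohort$truth, function(t) {
        t$fractions <- as.list(t$fractions)
        if (!is.null(t$class_fractions)) {
          t$class_fractions <- as.list(t$class_fractions)
        }
        t
      }),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(manifest)
}

#' Run the full analysis pipeline and write its artifacts
#'
#' Orchestrates simulate -> gate -> assay -> attribute -> classify ->
#' predict on a synthetic cohort, writing CSV/JSON artifacts to `out_dir`.
#' Every JSON artifact embeds the master seed so it can be re-created.
#'
#' @param out_dir output directory.
#' @param config a [generation_config()].
#' @param attribution an [attribution_config()] (its seed is overridden by
#'   the master seed).
#' @param stratum `"patient"`, `"healthy"` or `"both"` for the
#'   attribution/classification stages.
#' @param stages subset of `c("simulate", "gate", "assay", "attribute",
#'   "classify", "predict")`; earlier stages always run (they feed later
#'   ones).
#' @return Invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(out_dir, config = generation_config(),
                         attribution = attribution_config(),
                         stratum = c("both", "healthy", "patient"),
                         stages = c("simulate", "gate", "assay",
                                    "attribute", "classify", "predict")) {
  stratum <- match.arg(stratum)
  strata <- if (stratum == "both") c("healthy", "patient") else stratum
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  attribution$seed <- config$seed
  results <- list()

  cohort <- generate_cohort(config)
  results$cohort <- cohort
  if ("simulate" %in% stages) write_cohort(cohort, out_dir)

  features <- cohort_features(cohort)
  results$features <- features
  if ("gate" %in% stages) {
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
  }
  cy <- product_cytotox(cohort, attribution$et_ratio_used)

  md <- cohort$metadata
  for (st in strata) {
    pid <- md$sample_id[md$stage == "product" & md$status == st]
    if ("attribute" %in% stages) {
      att <- attribute_cytotoxicity(cohort$samples[pid], cy[pid],
                                    attribution)
      results[[paste0("attribution_", st)]] <- att
      jsonlite::write_json(
        list(seed = config$seed, stratum = st, selected_k = att$selected_k,
             trace = att$trace, clusters = att$clusters,
             product_fractions = att$product_fractions),
        file.path(out_dir, paste0("attribution_", st, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      utils::write.csv(att$class_profiles,
                       file.path(out_dir, paste0("heatmap_", st, ".csv")))
    }
    if ("classify" %in% stages) {
      pf <- features[features$stage == "product" & features$status == st, ]
      bf <- features[features$stage == "blood" & features$status == st, ]
      pfz <- zscore_features(pf)
      cl <- cluster_products(pfz, k = 5, seed = config$seed)
      bfz <- zscore_features(bf)
      i <- match(pf$donor_id, bfz$donor_id)
      x <- bfz[i, feature_columns(bfz), drop = FALSE]
      x$dose_pg_per_cell <- pf$dose_pg_per_cell
      rep <- train_classifiers(x, factor(cl$labels[pf$sample_id]),
                               seed = config$seed)
      results[[paste0("classifier_", st)]] <- rep
      imp <- feature_importance(rep)
      jsonlite::write_json(
        list(seed = config$seed, stratum = st,
             cluster_var_explained = cl$var_explained,
             results = rep$results, importance = imp,
             top5_nondose = attr(imp, "top5_nondose")),
        file.path(out_dir, paste0("classifier_report_", st, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }

  if ("predict" %in% stages) {
    pf <- features[features$stage == "product" & features$status == "patient" &
                     features$stim_type == "APC-ms", ]
    bf <- features[features$stage == "blood" & features$status == "patient", ]
    frame <- dose_model_frame(zscore_features(bf), {
      z <- zscore_features(pf)
      z$dose_pg_per_cell <- pf$dose_pg_per_cell
      z
    })
    report <- leave_one_donor_out(frame, seed = config$seed)
    results$dose_report <- report
    jsonlite::write_json(
      list(seed = config$seed, per_donor = report$per_donor,
           predictions = report$predictions,
           mean_r_squared = report$mean_r_squared,
           mean_r_squared_pct = report$mean_r_squared_pct),
      file.path(out_dir, "dose_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(results)
}
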