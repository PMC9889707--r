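#' Default 12-channel T-cell phenotyping marker panel
#'
#' Ordered marker names matching the columns of the event matrices the
#' package generates and gates. The viability channel is a dead-cell dye:
#' events *above* its threshold are excluded as non-viable.
#'
#' @param markers character vector of unique marker names.
#' @return A character vector of class `marker_panel`.
#' @export
marker_panel <- function(markers = c("CD3", "CD4", "CD8", "PD1", "TIM3",
                                     "CD25", "CD45RA", "CCR7", "CAR",
                                     "CD95", "CD137", "Viability")) {
  markers <- as.character(markers)
  if (anyDuplicated(markers)) stop("marker names must be unique")
  structure(markers, class = "marker_panel")
}

#' Threshold gating strategy
#'
#' One scalar intensity threshold per marker defines a hierarchy of gates:
#' viable (below the viability-dye threshold) -> CD3+ -> {CD4+, CD8+} ->
#' per-parent CD45RA x CCR7 and PD-1 x TIM-3 quadrants plus CD25/CD137/CD95
#' positivity, with CAR+ measured among CD3+ events.
#'
#' @param panel a [marker_panel()].
#' @param thresholds named numeric vector of per-marker thresholds; a single
#'   unnamed value is recycled to every marker. Default 224, the geometric
#'   midpoint of the generator's negative (50) and positive (1000) intensity
#'   modes.
#' @param viability_marker name of the dead-cell dye channel.
#' @return An object of class `gating_strategy`.
#' @export
gating_strategy <- function(panel = marker_panel(), thresholds = 224,
                            viability_marker = "Viability") {
  if (length(thresholds) == 1L && is.null(names(thresholds))) {
    thresholds <- stats::setNames(rep(as.numeric(thresholds), length(panel)),
                                  as.character(panel))
  }
  if (!all(as.character(panel) %in% names(thresholds))) {
    stop("thresholds must cover every marker in the panel")
  }
  thresholds <- thresholds[as.character(panel)]
  if (!all(is.finite(thresholds))) stop("gate thresholds must be finite")
  if (!viability_marker %in% as.character(panel)) {
    stop("viability marker '", viability_marker, "' absent from panel")
  }
  structure(list(panel = panel, thresholds = thresholds,
                 viability_marker = viability_marker),
            class = "gating_strategy")
}

#' Single-cell marker-intensity matrix
#'
#' @param intensities numeric matrix, events x markers, raw linear-scale
#'   intensities; column names are the marker panel.
#' @param sample_id sample identifier.
#' @param labels optional per-event data.frame of ground-truth labels
#'   (testing only).
#' @return An object of class `single_cell_matrix`.
#' @export
single_cell_matrix <- function(intensities, sample_id, labels = NULL) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) < 1L) stop("need at least one event")
  if (any(intensities < 0)) stop("negative intensities not allowed")
  if (is.null(colnames(intensities))) stop("intensity columns must be named")
  if (!is.null(labels)) stopifnot(nrow(labels) == nrow(intensities))
  structure(list(sample_id = as.character(sample_id),
                 intensities = intensities, labels = labels),
            class = "single_cell_matrix")
}

#' @export
print.single_cell_matrix <- function(x, ...) {
  cat("Single-cell matrix '", x$sample_id, "': ", nrow(x$intensities),
      " events x ", ncol(x$intensities), " markers\n", sep = "")
  invisible(x)
}

# Canonical metadata columns of a feature table; everything else is a feature.
METADATA_COLS <- c("sample_id", "donor_id", "status", "stage", "stim_type",
                   "dose_mol_pct", "dose_pg_per_cell")

#' Names of the feature columns of a feature table
#'
#' @param table a feature table (data.frame) as produced by [gate_features()].
#' @return Character vector of non-metadata column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), METADATA_COLS)
}

# subpopulation frequency (% of parent); empty parent => 0 + flag
.freq <- function(child, parent, name, flags) {
  np <- sum(parent)
  if (np == 0L) {
    flags$empty <- c(flags$empty, name)
    return(list(value = 0, flags = flags))
  }
  list(value = 100 * sum(child & parent) / np, flags = flags)
}

#' Gate a single-cell matrix into a feature vector
#'
#' Applies the threshold-gating hierarchy and returns one feature-table row
#' of subpopulation frequencies (percent of parent, 0-100) and the CD4:CD8
#' ratio. Frequencies with an empty parent gate are recorded as 0 and listed
#' in the `"empty_parents"` attribute so downstream matrices stay
#' rectangular.
#'
#' @param cells a [single_cell_matrix()].
#' @param strategy a [gating_strategy()]; markers must match the matrix
#'   columns.
#' @return A one-row data.frame of gated features with attribute
#'   `empty_parents`.
#' @export
apply_gating <- function(cells, strategy = gating_strategy()) {
  stopifnot(inherits(cells, "single_cell_matrix"),
            inherits(strategy, "gating_strategy"))
  x <- cells$intensities
  need <- as.character(strategy$panel)
  if (!all(need %in% colnames(x))) {
    stop("markers missing from event matrix: ",
         paste(setdiff(need, colnames(x)), collapse = ", "))
  }
  pos <- sweep(x[, need, drop = FALSE], 2, strategy$thresholds, `>`)
  flags <- new.env()
  flags$empty <- character(0)

  viable <- !pos[, strategy$viability_marker]
  cd3 <- viable & pos[, "CD3"]
  cd4 <- cd3 & pos[, "CD4"]
  cd8 <- cd3 & pos[, "CD8"]

  out <- list()
  g <- function(child, parent, name) {
    r <- .freq(child, parent, name, flags)
    out[[name]] <<- r$value
  }
  g(cd3, viable, "pct_CD3")
  g(cd4, cd3, "pct_CD4")
  g(cd8, cd3, "pct_CD8")
  g(cd3 & pos[, "CAR"], cd3, "pct_CAR")

  n4 <- sum(cd4); n8 <- sum(cd8)
  if (n8 == 0L) {
    flags$empty <- c(flags$empty, "CD4_CD8_ratio")
    out[["CD4_CD8_ratio"]] <- 0
  } else {
    out[["CD4_CD8_ratio"]] <- n4 / n8
  }

  for (parent_name in c("CD4", "CD8")) {
    parent <- if (parent_name == "CD4") cd4 else cd8
    ra <- pos[, "CD45RA"]; ccr7 <- pos[, "CCR7"]
    pd1 <- pos[, "PD1"]; tim3 <- pos[, "TIM3"]
    pre <- function(nm) paste0(parent_name, "_", nm)
    g(parent & ra & ccr7,   parent, pre("CD45RAposCCR7pos"))
    g(parent & ra & !ccr7,  parent, pre("CD45RAposCCR7neg"))
    g(parent & !ra & ccr7,  parent, pre("CD45RAnegCCR7pos"))
    g(parent & !ra & !ccr7, parent, pre("CD45RAnegCCR7neg"))
    g(parent & pd1 & tim3,   parent, pre("PD1posTIM3pos"))
    g(parent & pd1 & !tim3,  parent, pre("PD1posTIM3neg"))
    g(parent & !pd1 & tim3,  parent, pre("PD1negTIM3pos"))
    g(parent & !pd1 & !tim3, parent, pre("PD1negTIM3neg"))
    g(parent & pos[, "CD25"],  parent, pre("CD25pos"))
    g(parent & pos[, "CD137"], parent, pre("CD137pos"))
    g(parent & pos[, "CD95"],  parent, pre("CD95pos"))
  }

  res <- as.data.frame(out, check.names = FALSE)
  attr(res, "empty_parents") <- flags$empty
  res
}

#' Gate every sample of a cohort into a feature table
#'
#' @param samples named list of [single_cell_matrix()] objects.
#' @param metadata data.frame with one row per sample (matched on
#'   `sample_id`) carrying donor_id, status, stage, stim_type,
#'   dose_mol_pct, dose_pg_per_cell.
#' @param strategy a [gating_strategy()].
#' @return A feature table: metadata columns followed by gated features.
#' @export
gate_features <- function(samples, metadata, strategy = gating_strategy()) {
  rows <- lapply(samples, apply_gating, strategy = strategy)
  feats <- do.call(rbind, rows)
  ids <- vapply(samples, function(s) s$sample_id, "")
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(md) <- rownames(feats) <- NULL
  cbind(md, feats)
}

#' Z-score the feature columns of a feature table
#'
#' Standardizes every feature column to mean 0 and SD 1 using the population
#' (`ddof = 0`) convention; metadata columns are untouched. Zero-variance
#' columns carry no information for the downstream models and are dropped
#' with a warning; their names are recorded in the `"dropped"` attribute.
#'
#' @param table a feature table.
#' @return The standardized table, with attributes `dropped` (names of
#'   removed constant columns), `center`, `scale` and
#'   `sd_convention = "population"`.
#' @export
zscore_features <- function(table) {
  if (nrow(table) < 2L) stop("need at least 2 samples to z-score")
  fc <- feature_columns(table)
  x <- as.matrix(table[, fc, drop = FALSE])
  mu <- colMeans(x)
  sdp <- sqrt(colMeans(sweep(x, 2, mu)^2))
  drop <- fc[sdp == 0]
  if (length(drop)) {
    warning("dropping zero-variance feature(s): ",
            paste(drop, collapse = ", "))
  }
  keep <- fc[sdp > 0]
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdp[keep], `/`)
  out <- cbind(table[, intersect(METADATA_COLS, names(table)), drop = FALSE],
               as.data.frame(z, check.names = FALSE))
  attr(out, "dropped") <- drop
  attr(out, "center") <- mu[keep]
  attr(out, "scale") <- sdp[keep]
  attr(out, "sd_convention") <- "population"
  out
}

#' Fold expansion of a T-cell culture
#'
#' Number of live cells at harvest divided by the number seeded at the start
#' of culture.
#'
#' @param live_count live cells at harvest.
#' @param seeded_count cells seeded (> 0).
#' @return live / seeded.
#' @export
#' @examples
#' fold_expansion(2e6, 1e5)  # 20
fold_expansion <- function(live_count, seeded_count) {
  if (any(seeded_count <= 0)) stop("seeded_count must be > 0")
  live_count / seeded_count
}

#' Split a feature table into training and test partitions
#'
#' Rows are shuffled under the given seed; the first
#' `ceiling(train_fraction * n)` rows form the training set. The ceiling
#' convention reproduces 35-of-49 and 40-of-56 training counts at a 70%
#' fraction.
#'
#' @param table feature table (>= 2 rows).
#' @param train_fraction fraction in (0, 1); default 0.7.
#' @param seed integer seed for the shuffle.
#' @return list with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(table, train_fraction = 0.7, seed = 1L) {
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  n_train <- as.integer(ceiling(train_fraction * n))
  idx <- with_seed(seed, sample.int(n))
  list(train = table[sort(idx[seq_len(n_train)]), , drop = FALSE],
       test = table[sort(idx[-seq_len(n_train)]), , drop = FALSE])
}
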