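#' Configuration for single-cell cytotoxicity attribution
#'
#' @param k_grid ordered candidate cluster numbers. The default is a
#'   geometric subsample (about 25 values) of the full 2..320 range, which
#'   preserves the argmax in practice at a fraction of the cost; set
#'   `full_sweep = TRUE` to iterate every k from 2 to `max(k_grid)`.
#' @param full_sweep iterate every integer k up to `max(k_grid)`.
#' @param et_ratio_used E:T ratio whose percent cytotoxicity is attributed
#'   to events (default 1.25, i.e. the 1.25:1 point).
#' @param compartment which gated compartment to pool: `"CD8"` (default),
#'   `"CD4"` or `"all"` (all viable CD3+ events).
#' @param event_cap subsample ceiling applied once to the pooled events
#'   before the sweep.
#' @param num_trees trees per random-forest regression in the
#'   explained-variance criterion.
#' @param nstart,iter_max k-means restarts and iteration cap.
#' @param z_threshold |z| cut between moderate and high/low cytotoxic
#'   classes (default 1: mean +/- 1 SD).
#' @param seed seed for subsampling, k-means and forests.
#' @return Object of class `attribution_config`.
#' @export
attribution_config <- function(k_grid = unique(round(exp(seq(log(2), log(320),
                                                             length.out = 25)))),
                               full_sweep = FALSE,
                               et_ratio_used = 1.25,
                               compartment = c("CD8", "CD4", "all"),
                               event_cap = 5000, num_trees = 500,
                               nstart = 3, iter_max = 100,
                               z_threshold = 1, seed = 1L) {
  compartment <- match.arg(compartment)
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 2)) stop("k_grid values must be >= 2")
  if (full_sweep) k_grid <- seq(2L, max(k_grid))
  structure(list(k_grid = k_grid, et_ratio_used = et_ratio_used,
                 compartment = compartment, event_cap = as.integer(event_cap),
                 num_trees = num_trees, nstart = nstart, iter_max = iter_max,
                 z_threshold = z_threshold, seed = as.integer(seed)),
            class = "attribution_config")
}

#' Pool gated events from several samples into one event matrix
#'
#' Applies the gating hierarchy and keeps viable CD3+ events of the
#' requested compartment, tracking each event's sample of origin.
#'
#' @param samples named list of [single_cell_matrix()] objects.
#' @param strategy a [gating_strategy()].
#' @param compartment `"CD8"`, `"CD4"` or `"all"`.
#' @return list with `x` (events x markers raw intensities), `sample_id`
#'   (per-event origin) and, when the matrices carry truth labels,
#'   `labels` (per-event label data.frame).
#' @export
pool_events <- function(samples, strategy = gating_strategy(),
                        compartment = c("CD8", "CD4", "all")) {
  compartment <- match.arg(compartment)
  xs <- list(); ids <- list(); labs <- list()
  for (s in samples) {
    x <- s$intensities
    thr <- strategy$thresholds
    keep <- x[, strategy$viability_marker] <= thr[strategy$viability_marker] &
      x[, "CD3"] > thr["CD3"]
    if (compartment != "all") {
      keep <- keep & x[, compartment] > thr[compartment]
    }
    if (!any(keep)) next
    xs[[s$sample_id]] <- x[keep, , drop = FALSE]
    ids[[s$sample_id]] <- rep(s$sample_id, sum(keep))
    if (!is.null(s$labels)) {
      labs[[s$sample_id]] <- s$labels[keep, , drop = FALSE]
    }
  }
  list(x = do.call(rbind, xs), sample_id = unlist(ids, use.names = FALSE),
       labels = if (length(labs) == length(xs)) {
         do.call(rbind, c(labs, make.row.names = FALSE))
       })
}

#' Attach each product's observed percent cytotoxicity to its events
#'
#' Every event inherits the experimentally observed product-level
#' cytotoxicity of the sample it came from; healthy and patient pools are
#' intended to be processed separately.
#'
#' @param pool an event pool from [pool_events()].
#' @param product_cytotox named numeric: sample_id -> percent cytotoxicity
#'   (at the configured E:T ratio).
#' @return The pool with a per-event `cytotox` vector added.
#' @export
assign_cell_cytotoxicity <- function(pool, product_cytotox) {
  ids <- unique(pool$sample_id)
  missing <- setdiff(ids, names(product_cytotox))
  if (length(missing)) {
    stop("no cytotoxicity value for product(s): ",
         paste(missing, collapse = ", "))
  }
  pool$cytotox <- unname(product_cytotox[pool$sample_id])
  pool
}

# per-marker population z-scoring of the pooled event matrix
.standardize_events <- function(x) {
  mu <- colMeans(x)
  sdp <- sqrt(colMeans(sweep(x, 2, mu)^2))
  sdp[sdp == 0] <- 1
  sweep(sweep(x, 2, mu), 2, sdp, `/`)
}

.seeded_kmeans <- function(z, k, nstart, iter_max, seed) {
  for (attempt in 0:4) {
    fit <- try(with_seed(seed + attempt,
                         suppressWarnings(
                           stats::kmeans(z, centers = k, nstart = nstart,
                                         iter.max = iter_max))),
               silent = TRUE)
    if (!inherits(fit, "try-error")) return(fit)
  }
  stop("k-means failed for k = ", k, ": ", attr(fit, "condition")$message)
}

#' Sweep k-means clusterings over a grid of cluster numbers
#'
#' Events are standardized per marker (k-means is scale-sensitive),
#' subsampled once to the event cap, and clustered at every k in the grid.
#' Each cluster model records its centroids, assignments, sizes and the
#' mean experimentally assigned cytotoxicity of its member events.
#'
#' @param pool event pool with assigned cytotoxicity
#'   ([assign_cell_cytotoxicity()]).
#' @param config an [attribution_config()].
#' @return list with `models` (one cluster model per k), the subsampled
#'   standardized matrix `z`, `sample_id` and `cytotox` aligned to its rows.
#' @export
kmeans_sweep <- function(pool, config = attribution_config()) {
  if (is.null(pool$cytotox)) stop("pool has no assigned cytotoxicity")
  n <- nrow(pool$x)
  idx <- seq_len(n)
  if (n > config$event_cap) {
    idx <- sort(with_seed(substream_seed(config$seed, "event_cap"),
                          sample.int(n, config$event_cap)))
  }
  z <- .standardize_events(pool$x[idx, , drop = FALSE])
  ids <- pool$sample_id[idx]
  cy <- pool$cytotox[idx]
  k_grid <- config$k_grid[config$k_grid < nrow(z)]
  if (!length(k_grid)) stop("every k in the grid is >= the number of events")
  models <- lapply(k_grid, function(k) {
    fit <- .seeded_kmeans(z, k, config$nstart, config$iter_max,
                          substream_seed(config$seed, "kmeans", k))
    mean_cy <- as.numeric(tapply(cy, fit$cluster, mean))
    list(k = k, centers = fit$centers, cluster = fit$cluster,
         sizes = as.integer(fit$size), mean_cytotox = mean_cy)
  })
  list(models = models, z = z, sample_id = ids, cytotox = cy)
}

#' Out-of-sample explained variance of cluster-level cytotoxicity
#'
#' Fits a random-forest regression of cluster-mean cytotoxicity on the
#' cluster centroids (mean marker features) and returns an out-of-sample
#' explained-variance (R squared) estimate: leave-one-cluster-out for
#' k < 10, out-of-bag otherwise. An in-sample forest R squared would be
#' trivially near 1, so an out-of-sample convention is required. Returns
#' `NA` (flagged, excluded from model selection) when the clusters carry
#' fewer than two distinct cytotoxicity values.
#'
#' @param model one cluster model from [kmeans_sweep()].
#' @param config an [attribution_config()].
#' @return Explained variance (may be negative), or `NA` when flagged.
#' @export
cluster_explained_variance <- function(model,
                                       config = attribution_config()) {
  y <- model$mean_cytotox
  x <- as.data.frame(model$centers)
  k <- model$k
  if (length(unique(round(y, 9))) < 2L) return(NA_real_)
  seed <- substream_seed(config$seed, "ev", k)
  if (k < 10) {
    preds <- vapply(seq_len(k), function(i) {
      tr_x <- x[-i, , drop = FALSE]; tr_y <- y[-i]
      if (nrow(tr_x) < 2L || length(unique(round(tr_y, 9))) < 2L) {
        return(mean(tr_y))
      }
      fit <- ranger::ranger(x = tr_x, y = tr_y,
                            num.trees = config$num_trees,
                            mtry = ncol(tr_x),  # few observations: bag
                            seed = seed + i, num.threads = 1)
      stats::predict(fit, x[i, , drop = FALSE])$predictions
    }, 0)
    1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  } else {
    fit <- ranger::ranger(x = x, y = y, num.trees = config$num_trees,
                          mtry = ncol(x), seed = seed, num.threads = 1)
    fit$r.squared
  }
}

#' Select the optimal number of clusters by explained variance
#'
#' Argmax of the explained-variance trace over the k grid; flagged (NA)
#' values are excluded and ties break toward smaller k (parsimony).
#'
#' @param sweep result of [kmeans_sweep()].
#' @param config an [attribution_config()].
#' @param ev optional precomputed explained-variance vector (one value per
#'   model, `NA` = flagged); computed from the sweep when omitted.
#' @return list with `model` (the selected cluster model) and `trace`
#'   (data.frame of k and explained variance).
#' @export
select_optimal_k <- function(sweep, config = attribution_config(),
                             ev = NULL) {
  if (is.null(ev)) {
    ev <- vapply(sweep$models, cluster_explained_variance, 0, config = config)
  }
  ks <- vapply(sweep$models, function(m) m$k, 0L)
  trace <- data.frame(k = ks, explained_variance = ev)
  if (all(is.na(ev))) {
    stop("explained variance is undefined at every k ",
         "(no variation in cluster cytotoxicity)")
  }
  best <- which(!is.na(ev) & ev == max(ev, na.rm = TRUE))[1]
  list(model = sweep$models[[best]], trace = trace)
}

#' Classify clusters into low / moderate / high cytotoxic potential
#'
#' Cluster-mean cytotoxicity is z-scored across clusters (unweighted,
#' population SD; defined as all-zero when the SD is zero) and thresholded:
#' z >= threshold is "high", z <= -threshold "low", otherwise "moderate".
#' Per-product class fractions are each product's share of events falling
#' in clusters of each class; per-class marker means are computed over
#' member events (standardized scale).
#'
#' @param model selected cluster model.
#' @param sweep the [kmeans_sweep()] result the model came from.
#' @param z_threshold class threshold (default 1).
#' @return list with `clusters` (data.frame: k rows with size, mean
#'   cytotoxicity, z, class), `product_fractions` (data.frame: sample_id,
#'   high, moderate, low), `class_profiles` (class x marker mean
#'   standardized expression).
#' @export
classify_clusters <- function(model, sweep, z_threshold = 1) {
  if (model$k < 2L) stop("need at least 2 clusters to classify")
  y <- model$mean_cytotox
  sdp <- sqrt(mean((y - mean(y))^2))
  z <- if (sdp == 0) rep(0, length(y)) else (y - mean(y)) / sdp
  cls <- ifelse(z >= z_threshold, "high",
                ifelse(z <= -z_threshold, "low", "moderate"))
  clusters <- data.frame(cluster = seq_along(y), size = model$sizes,
                         mean_cytotox = y, z = z, class = cls)
  ev_class <- cls[model$cluster]
  tab <- table(sweep$sample_id,
               factor(ev_class, levels = c("high", "moderate", "low")))
  frac <- sweep(tab, 1, rowSums(tab), `/`)
  product_fractions <- data.frame(sample_id = rownames(frac),
                                  high = as.numeric(frac[, "high"]),
                                  moderate = as.numeric(frac[, "moderate"]),
                                  low = as.numeric(frac[, "low"]),
                                  stringsAsFactors = FALSE)
  rownames(product_fractions) <- NULL
  prof <- do.call(rbind, lapply(c("high", "moderate", "low"), function(cl) {
    colMeans(sweep$z[ev_class == cl, , drop = FALSE])
  }))
  rownames(prof) <- c("high", "moderate", "low")
  list(clusters = clusters, product_fractions = product_fractions,
       class_profiles = prof)
}

#' Attribute product-level cytotoxicity to single-cell phenotypes
#'
#' The full attribution procedure: pool gated events of the chosen
#' compartment across products, tag every event with its product's observed
#' percent cytotoxicity (taken at the configured E:T ratio), sweep k-means
#' clusterings over the k grid, pick the k whose cluster-level
#' random-forest regression best explains cytotoxicity out of sample, and
#' threshold the z-scored cluster cytotoxicities into low / moderate /
#' high classes. Run healthy-donor and patient product pools separately.
#'
#' @param samples named list of product [single_cell_matrix()] objects.
#' @param curves list of [build_curve()] cytotoxicity curves (one per
#'   product), or a named numeric vector sample_id -> percent cytotoxicity.
#' @param config an [attribution_config()].
#' @param strategy a [gating_strategy()].
#' @return Object of class `cart_attribution` with the selected cluster
#'   model, explained-variance trace, cluster classification table,
#'   per-product class fractions and per-class marker profiles.
#' @export
attribute_cytotoxicity <- function(samples, curves,
                                   config = attribution_config(),
                                   strategy = gating_strategy()) {
  if (is.list(curves) && !is.numeric(curves)) {
    cy <- vapply(curves, curve_at, 0, et_ratio = config$et_ratio_used)
    names(cy) <- vapply(curves, attr, "", which = "sample_id")
  } else {
    cy <- curves
  }
  pool <- pool_events(samples, strategy, config$compartment)
  pool <- assign_cell_cytotoxicity(pool, cy)
  sweep_res <- kmeans_sweep(pool, config)
  sel <- select_optimal_k(sweep_res, config)
  cls <- classify_clusters(sel$model, sweep_res, config$z_threshold)
  structure(list(selected_k = sel$model$k, model = sel$model,
                 trace = sel$trace, clusters = cls$clusters,
                 product_fractions = cls$product_fractions,
                 class_profiles = cls$class_profiles,
                 n_events = nrow(sweep_res$z), config = config),
            class = "cart_attribution")
}

#' @export
print.cart_attribution <- function(x, ...) {
  cat("Single-cell cytotoxicity attribution (", x$config$compartment,
      " compartment, ", x$n_events, " events)\n", sep = "")
  cat("  selected k = ", x$selected_k, " (explained variance ",
      signif(x$trace$explained_variance[x$trace$k == x$selected_k], 3),
      ")\n", sep = "")
  tab <- table(x$clusters$class)
  cat("  clusters: ", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.cart_attribution <- function(object, ...) {
  cat("Explained-variance trace:\n")
  print(object$trace, row.names = FALSE)
  cat("\nPer-product class fractions:\n")
  print(object$product_fractions, row.names = FALSE)
  invisible(object)
}
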