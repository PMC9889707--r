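#' Coefficient of determination
#'
#' Standard closed form `1 - SS_res / SS_tot`. Negative values (predictions
#' worse than the mean) are reported as-is, never clipped.
#'
#' @param actual observed values.
#' @param predicted predicted values.
#' @return R squared (undefined — `NA` — when `actual` is constant).
#' @export
r_squared <- function(actual, predicted) {
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Assemble the dose-model design frame
#'
#' One row per product: the donor's blood-sample features joined with that
#' product's features, and the product's actual stimulation dose (pg/cell)
#' as the target. Blood and product columns are prefixed `blood_` /
#' `product_` to keep the two phenotypes distinguishable.
#'
#' @param blood_features feature table of blood samples (stage "blood").
#' @param product_features feature table of products (stage "product")
#'   with `dose_pg_per_cell` metadata.
#' @return list with `x` (predictor data.frame), `y` (pg/cell),
#'   `donor_id` and `sample_id` aligned to rows.
#' @export
dose_model_frame <- function(blood_features, product_features) {
  fb <- feature_columns(blood_features)
  fp <- feature_columns(product_features)
  i <- match(product_features$donor_id, blood_features$donor_id)
  if (anyNA(i)) {
    stop("product donor(s) missing a blood sample: ",
         paste(unique(product_features$donor_id[is.na(i)]), collapse = ", "))
  }
  xb <- blood_features[i, fb, drop = FALSE]
  names(xb) <- paste0("blood_", fb)
  xp <- product_features[, fp, drop = FALSE]
  names(xp) <- paste0("product_", fp)
  x <- cbind(xb, xp)
  rownames(x) <- NULL
  list(x = x, y = product_features$dose_pg_per_cell,
       donor_id = product_features$donor_id,
       sample_id = product_features$sample_id)
}

#' Dose-regressor configuration
#'
#' Random-forest regression settings; the defaults start from the tuned
#' classifier tuple (800 trees, depth 10, minimum node size 2).
#'
#' @param num_trees,max_depth,min_node_size forest shape.
#' @param mtry per-split feature count (`NULL` = ranger's regression
#'   default).
#' @param dev_holdout_donors number of donors set aside from
#'   hyperparameter development (configurable analogue of holding out
#'   three healthy donors).
#' @return list of class `dose_config`.
#' @export
dose_config <- function(num_trees = 800, max_depth = 10, min_node_size = 2,
                        mtry = NULL, dev_holdout_donors = 3) {
  structure(list(num_trees = num_trees, max_depth = max_depth,
                 min_node_size = min_node_size, mtry = mtry,
                 dev_holdout_donors = dev_holdout_donors),
            class = "dose_config")
}

#' Train the stimulation-dose random-forest regressor
#'
#' @param x predictor data.frame (blood + product features).
#' @param y pg/cell dose targets (>= 2 distinct values).
#' @param config a [dose_config()].
#' @param seed integer seed.
#' @return A fitted `ranger` regression forest.
#' @export
train_dose_regressor <- function(x, y, config = dose_config(), seed = 1L) {
  if (length(unique(y)) < 2) stop("need >= 2 distinct dose values")
  ranger::ranger(x = x, y = y, num.trees = config$num_trees,
                 max.depth = config$max_depth,
                 min.node.size = config$min_node_size,
                 mtry = config$mtry, seed = seed, num.threads = 1)
}

#' Leave-one-donor-out validation of dose prediction
#'
#' For every donor in turn, the regressor is trained on all other donors'
#' rows and asked to predict the held-out donor's dose at each of their
#' dose levels; the score is the R squared between predicted and actual
#' doses over that donor's series. All of a donor's rows stay on one side
#' of every split (no donor leakage; asserted). Donors with fewer than two
#' distinct dose levels have no defined R squared and are excluded with a
#' warning. The cross-donor mean is the unweighted average of per-donor
#' R squared values.
#'
#' @param frame a [dose_model_frame()].
#' @param config a [dose_config()].
#' @param seed integer seed.
#' @return Object of class `dose_prediction_report`: `per_donor`
#'   (donor_id, n, r_squared), `predictions` (donor_id, sample_id, actual,
#'   predicted), `mean_r_squared` (also echoed as a percent in
#'   `mean_r_squared_pct`).
#' @export
leave_one_donor_out <- function(frame, config = dose_config(), seed = 1L) {
  donors <- unique(frame$donor_id)
  if (length(donors) < 3) stop("need >= 3 donors for leave-one-donor-out")
  usable <- donors[vapply(donors, function(d) {
    length(unique(frame$y[frame$donor_id == d])) >= 2
  }, TRUE)]
  dropped <- setdiff(donors, usable)
  if (length(dropped)) {
    warning("excluding donor(s) with a single dose level (R^2 undefined): ",
            paste(dropped, collapse = ", "))
  }
  preds <- list(); per <- list()
  for (d in usable) {
    hold <- frame$donor_id == d
    stopifnot(!any(frame$donor_id[!hold] == d))  # donor exclusivity
    fit <- train_dose_regressor(frame$x[!hold, , drop = FALSE],
                                frame$y[!hold], config,
                                seed = substream_seed(seed, "lodo", d))
    p <- stats::predict(fit, frame$x[hold, , drop = FALSE])$predictions
    preds[[d]] <- data.frame(donor_id = d,
                             sample_id = frame$sample_id[hold],
                             actual = frame$y[hold], predicted = p)
    per[[d]] <- data.frame(donor_id = d, n = sum(hold),
                           r_squared = r_squared(frame$y[hold], p))
  }
  per <- do.call(rbind, c(per, make.row.names = FALSE))
  structure(list(per_donor = per,
                 predictions = do.call(rbind, c(preds,
                                                make.row.names = FALSE)),
                 mean_r_squared = mean(per$r_squared),
                 mean_r_squared_pct = 100 * mean(per$r_squared),
                 excluded = dropped, config = config, seed = seed),
            class = "dose_prediction_report")
}

#' @export
print.dose_prediction_report <- function(x, ...) {
  cat("Leave-one-donor-out dose prediction (", nrow(x$per_donor),
      " donors)\n", sep = "")
  df <- x$per_donor
  df$r_squared <- round(df$r_squared, 3)
  print(df, row.names = FALSE)
  cat("Cross-donor mean R^2: ", round(x$mean_r_squared, 3), " (",
      round(x$mean_r_squared_pct, 1), "%)\n", sep = "")
  invisible(x)
}

#' Predict the stimulation dose for a desired product phenotype
#'
#' Point prediction of pg/cell from a blood-sample phenotype and a desired
#' product phenotype, with the nearest achievable mol% biotin reported via
#' inverse conversion-table lookup. Predictions outside the table's range
#' are flagged and carry no mol% value.
#'
#' @param regressor a trained [train_dose_regressor()] forest.
#' @param newdata predictor data.frame with the training schema
#'   (`blood_*` and `product_*` columns).
#' @param table a [dose_conversion_table()].
#' @return data.frame with `pg_per_cell`, `mol_pct`, `out_of_range`.
#' @export
predict_dose <- function(regressor, newdata,
                         table = dose_conversion_table()) {
  need <- regressor$forest$independent.variable.names
  if (!all(need %in% names(newdata))) {
    stop("newdata is missing feature(s): ",
         paste(setdiff(need, names(newdata)), collapse = ", "))
  }
  pg <- stats::predict(regressor,
                       newdata[, need, drop = FALSE])$predictions
  pg_per_cell_to_mol_pct(pg, table)
}
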