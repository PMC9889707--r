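#' Cluster CAR-T products into broad phenotypes
#'
#' Seeded k-means on z-scored product features, grouping phenotypically
#' similar products across stimulation dose and donor. Healthy and patient
#' strata are clustered separately.
#'
#' @param product_features z-scored feature table of products (one row per
#'   product; metadata columns ignored).
#' @param k number of phenotype clusters (>= 2; default 5).
#' @param seed integer seed.
#' @return Object of class `product_cluster_model`: `k`, `centers`,
#'   `labels` (named integer vector, sample_id -> cluster) and
#'   `var_explained` (between-cluster / total sum of squares).
#' @export
cluster_products <- function(product_features, k = 5, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(product_features)) stop("k exceeds the number of products")
  fc <- feature_columns(product_features)
  x <- as.matrix(product_features[, fc, drop = FALSE])
  fit <- .seeded_kmeans(x, k, nstart = 10, iter_max = 100,
                        seed = substream_seed(seed, "cluster_products", k))
  labels <- stats::setNames(fit$cluster, product_features$sample_id)
  structure(list(k = k, centers = fit$centers, labels = labels,
                 var_explained = fit$betweenss / fit$totss),
            class = "product_cluster_model")
}

#' @export
print.product_cluster_model <- function(x, ...) {
  cat("Product phenotype clustering: k = ", x$k, ", ",
      round(100 * x$var_explained, 1), "% of feature variance explained\n",
      sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Choose the product-cluster number by variance explained
#'
#' Reports the fraction of total feature variance explained by the cluster
#' assignment (between-cluster over total sum of squares) for each
#' candidate k, and returns the smallest k exceeding the threshold. When no
#' candidate reaches it, `k` is `NA` (flagged) and the trace is still
#' returned.
#'
#' @param product_features z-scored product feature table.
#' @param k_candidates candidate cluster numbers (>= 2).
#' @param threshold variance-explained target (default 0.9).
#' @param seed integer seed.
#' @return list with `k` and `trace` (data.frame of k, var_explained).
#' @export
choose_k_by_variance <- function(product_features, k_candidates = 2:8,
                                 threshold = 0.9, seed = 1L) {
  k_candidates <- sort(unique(as.integer(k_candidates)))
  ve <- vapply(k_candidates, function(k) {
    cluster_products(product_features, k, seed)$var_explained
  }, 0)
  trace <- data.frame(k = k_candidates, var_explained = ve)
  hit <- k_candidates[ve >= threshold]
  list(k = if (length(hit)) hit[1] else NA_integer_, trace = trace)
}

# --- classifier battery -----------------------------------------------------

# Each algorithm is a (grid, fit, predict) triple. MLP and kNN standardize
# inputs on training statistics inside fit.
.scale_fit <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  list(mu = mu, s = s)
}
.scale_apply <- function(x, sc) sweep(sweep(as.matrix(x), 2, sc$mu), 2, sc$s, `/`)

.algorithms <- function(p) {
  list(
    random_forest = list(
      # printed tuned values: 800 trees, Gini, min node size 2, depth 10;
      # the grid tunes the per-split feature count
      grid = expand.grid(mtry = unique(c(max(1, floor(sqrt(p))),
                                         max(1, floor(p / 3)), p))),
      fit = function(x, y, params, seed) {
        ranger::ranger(x = x, y = y, num.trees = 800, mtry = params$mtry,
                       min.node.size = 2, max.depth = 10,
                       splitrule = "gini", importance = "impurity",
                       seed = seed, num.threads = 1)
      },
      predict = function(model, x) stats::predict(model, x)$predictions
    ),
    mlp = list(
      grid = expand.grid(size = c(1, 2, 4, 8), decay = c(0.01, 0.1, 0.5)),
      fit = function(x, y, params, seed) {
        sc <- .scale_fit(as.matrix(x))
        # small-n nets are sensitive to the weight init: keep the best of
        # three seeded restarts by training objective
        nets <- lapply(1:3, function(r) {
          with_seed(seed + r, nnet::nnet(.scale_apply(x, sc),
                                         nnet::class.ind(y),
                                         size = params$size,
                                         decay = params$decay,
                                         softmax = TRUE, maxit = 500,
                                         MaxNWts = 5000,
                                         trace = FALSE))
        })
        net <- nets[[which.min(vapply(nets, `[[`, 0, "value"))]]
        list(net = net, sc = sc, levels = levels(y))
      },
      predict = function(model, x) {
        pr <- stats::predict(model$net, .scale_apply(x, model$sc))
        factor(model$levels[max.col(pr)], levels = model$levels)
      }
    ),
    decision_tree = list(
      grid = expand.grid(cp = c(0.01, 0.001)),
      fit = function(x, y, params, seed) {
        df <- data.frame(x, check.names = TRUE)
        df$.y <- y
        with_seed(seed, rpart::rpart(.y ~ ., data = df, method = "class",
                                     cp = params$cp, minsplit = 2))
      },
      predict = function(model, x) {
        stats::predict(model, data.frame(x, check.names = TRUE),
                       type = "class")
      }
    ),
    naive_bayes = list(
      grid = expand.grid(laplace = 0),
      fit = function(x, y, params, seed) {
        e1071::naiveBayes(as.data.frame(x), y, laplace = params$laplace)
      },
      predict = function(model, x) {
        stats::predict(model, as.data.frame(x))
      }
    ),
    nearest_neighbors = list(
      grid = expand.grid(k = c(3, 5, 7)),
      fit = function(x, y, params, seed) {
        sc <- .scale_fit(as.matrix(x))
        list(x = .scale_apply(x, sc), y = y, k = params$k, sc = sc)
      },
      predict = function(model, x) {
        class::knn(model$x, .scale_apply(x, model$sc), model$y,
                   k = min(model$k, nrow(model$x)))
      }
    )
  )
}

# stratified fold assignment: within each class, shuffled then dealt
# round-robin
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  })
  folds
}

.cv_accuracy <- function(alg, x, y, params, folds, seed) {
  accs <- c()
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (!any(tr) || !any(!tr)) next
    model <- alg$fit(x[tr, , drop = FALSE], droplevels(y[tr]), params,
                     seed = substream_seed(seed, "fold", f))
    pred <- as.character(alg$predict(model, x[!tr, , drop = FALSE]))
    accs <- c(accs, mean(pred == as.character(y[!tr])))
  }
  c(mean = mean(accs), sd = stats::sd(accs))
}

# 70/30 split of row indices with every class present in training;
# stratified re-draw (logged) when the random draw drops a class
.class_safe_split <- function(y, train_fraction, seed) {
  n <- length(y)
  n_train <- as.integer(ceiling(train_fraction * n))
  idx <- with_seed(seed, sample.int(n))
  train <- sort(idx[seq_len(n_train)])
  if (!all(levels(droplevels(y)) %in% levels(droplevels(y[train])))) {
    message("class absent from training partition; re-drawing stratified")
    folds <- stratified_folds(y, n_folds = round(1 / (1 - train_fraction)),
                              seed = substream_seed(seed, "redraw"))
    train <- sort(which(folds != 1))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Train and cross-validate a battery of product-phenotype classifiers
#'
#' Each product is represented by its donor's blood-sample features plus
#' the product's stimulation dose (pg/cell); the label is its phenotype
#' cluster. Rows are split 70/30 at random (no donor restriction), a small
#' grid search is tuned per algorithm by stratified tenfold
#' cross-validation on the training partition, and the best setting is
#' refit on the whole training partition and scored on the held-out test
#' rows. The random forest is pinned to 800 trees, Gini impurity, minimum
#' node size 2 and maximum depth 10.
#'
#' @param x data.frame of predictors (blood features + dose column).
#' @param labels factor of product-cluster labels (one per row of `x`).
#' @param algorithms subset of `"random_forest"`, `"mlp"`,
#'   `"decision_tree"`, `"naive_bayes"`, `"nearest_neighbors"`.
#' @param train_fraction training share (default 0.7, ceiling convention).
#' @param n_folds CV folds (default 10).
#' @param seed integer seed driving the split, folds and fits.
#' @return Object of class `classifier_report`: `results` data.frame
#'   (algorithm, cv_mean, cv_sd, test_accuracy, best_params), `fits`
#'   (trained best models), `split` and `folds`.
#' @export
train_classifiers <- function(x, labels,
                              algorithms = c("random_forest", "mlp",
                                             "decision_tree", "naive_bayes",
                                             "nearest_neighbors"),
                              train_fraction = 0.7, n_folds = 10,
                              seed = 1L) {
  labels <- droplevels(factor(labels))
  stopifnot(nrow(x) == length(labels))
  algs <- .algorithms(ncol(x))
  algorithms <- match.arg(algorithms, names(algs), several.ok = TRUE)
  sp <- .class_safe_split(labels, train_fraction, seed)
  x_tr <- x[sp$train, , drop = FALSE]; y_tr <- droplevels(labels[sp$train])
  x_te <- x[sp$test, , drop = FALSE]; y_te <- labels[sp$test]
  folds <- stratified_folds(y_tr, n_folds,
                            seed = substream_seed(seed, "folds"))
  rows <- list(); fits <- list()
  for (a in algorithms) {
    alg <- algs[[a]]
    scores <- lapply(seq_len(nrow(alg$grid)), function(g) {
      .cv_accuracy(alg, x_tr, y_tr, alg$grid[g, , drop = FALSE], folds,
                   seed = substream_seed(seed, a, g))
    })
    means <- vapply(scores, `[[`, 0, "mean")
    best <- which.max(means)
    params <- alg$grid[best, , drop = FALSE]
    fit <- alg$fit(x_tr, y_tr, params,
                   seed = substream_seed(seed, a, "final"))
    test_acc <- mean(as.character(alg$predict(fit, x_te)) ==
                       as.character(y_te))
    rows[[a]] <- data.frame(
      algorithm = a, cv_mean = scores[[best]]["mean"],
      cv_sd = scores[[best]]["sd"], test_accuracy = test_acc,
      best_params = paste(names(params), unlist(params), sep = "=",
                          collapse = ","))
    fits[[a]] <- fit
  }
  structure(list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
                 fits = fits, split = sp, folds = folds,
                 algorithms = algorithms, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Product-phenotype classifier battery (10-fold CV on 70% training",
      "split)\n")
  df <- x$results
  df$cv_mean <- round(df$cv_mean, 3)
  df$cv_sd <- round(df$cv_sd, 3)
  df$test_accuracy <- round(df$test_accuracy, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Ranked random-forest feature importances
#'
#' Impurity-based importances of the trained random-forest classifier,
#' normalized to sum to one and ranked; the top five features excluding
#' the stimulation dose are reported separately.
#'
#' @param report a `classifier_report` containing a `random_forest` fit,
#'   or a `ranger` model with impurity importance.
#' @param dose_col name of the dose feature.
#' @return data.frame (feature, importance) sorted decreasing, with
#'   attribute `top5_nondose`.
#' @export
feature_importance <- function(report, dose_col = "dose_pg_per_cell") {
  model <- if (inherits(report, "classifier_report")) {
    report$fits[["random_forest"]]
  } else {
    report
  }
  if (!inherits(model, "ranger")) {
    stop("feature importance requires a trained random-forest model")
  }
  imp <- ranger::importance(model)
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  out <- data.frame(feature = names(imp), importance = as.numeric(imp))
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "top5_nondose") <-
    utils::head(out$feature[out$feature != dose_col], 5)
  out
}

#' Paired full-feature versus dose-only classification accuracies
#'
#' Trains the same classifier twice under identical split, folds and seeds:
#' once on the full feature set and once with the stimulation dose as the
#' only predictor, and reports both accuracies and their difference.
#'
#' @param x predictor data.frame containing `dose_col`.
#' @param labels factor of cluster labels.
#' @param dose_col dose column name.
#' @param algorithm single algorithm name (default random forest).
#' @inheritParams train_classifiers
#' @return list with `full`, `dose_only` (classifier_report rows) and
#'   `difference` (full minus dose-only CV accuracy).
#' @export
dose_only_ablation <- function(x, labels, dose_col = "dose_pg_per_cell",
                               algorithm = "random_forest",
                               train_fraction = 0.7, n_folds = 10,
                               seed = 1L) {
  if (!dose_col %in% names(x)) stop("missing dose column '", dose_col, "'")
  full <- train_classifiers(x, labels, algorithm, train_fraction, n_folds,
                            seed)
  dose <- train_classifiers(x[, dose_col, drop = FALSE], labels, algorithm,
                            train_fraction, n_folds, seed)
  list(full = full$results, dose_only = dose$results,
       difference = full$results$cv_mean - dose$results$cv_mean)
}

#' Healthy-versus-patient status classifier
#'
#' Tenfold cross-validated random-forest accuracy for predicting donor
#' health status from product phenotype alone.
#'
#' @param product_features z-scored product feature table (with `status`
#'   metadata) or a plain predictor data.frame.
#' @param status factor/character of statuses when `product_features` has
#'   no status column.
#' @param n_folds CV folds.
#' @param seed integer seed.
#' @return list with `accuracy` (fold-mean CV accuracy) and
#'   `fold_accuracies`.
#' @export
status_classifier <- function(product_features, status = NULL,
                              n_folds = 10, seed = 1L) {
  if (is.null(status)) {
    if (!"status" %in% names(product_features)) {
      stop("no status column and no status argument")
    }
    status <- product_features$status
  }
  y <- droplevels(factor(status))
  if (nlevels(y) < 2) stop("need both statuses present")
  x <- product_features[, feature_columns(product_features), drop = FALSE]
  alg <- .algorithms(ncol(x))$random_forest
  folds <- stratified_folds(y, n_folds, seed = substream_seed(seed, "status"))
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- alg$fit(x[tr, , drop = FALSE], droplevels(y[tr]),
                   data.frame(mtry = max(1, floor(sqrt(ncol(x))))),
                   seed = substream_seed(seed, "status", f))
    mean(as.character(alg$predict(fit, x[!tr, , drop = FALSE])) ==
           as.character(y[!tr]))
  }, 0)
  list(accuracy = mean(accs), fold_accuracies = accs)
}
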