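test_that("event pooling respects the compartment gate and cytotoxicity
           broadcasts per product", {
  co <- small_cohort()
  ids <- co$metadata$sample_id[co$metadata$stage == "product"][1:2]
  pool <- pool_events(co$samples[ids], compartment = "CD8")
  expect_true(all(pool$labels$compartment == "CD8"))
  expect_setequal(unique(pool$sample_id), ids)

  cy <- c(20, 80)
  names(cy) <- ids
  pool <- assign_cell_cytotoxicity(pool, cy)
  expect_setequal(unique(pool$cytotox), c(20, 80))
  expect_true(all(pool$cytotox[pool$sample_id == ids[1]] == 20))
  expect_error(assign_cell_cytotoxicity(pool, cy[1]),
               "no cytotoxicity value")
})

test_that("the k-means sweep recovers planted blobs, saturates at tiny
           pools and is seeded", {
  markers <- as.character(marker_panel())
  blobs <- with_seed(2, {
    x <- rbind(matrix(stats::rnorm(300 * 12, 0, 0.1), 300),
               matrix(stats::rnorm(300 * 12, 5, 0.1), 300))
    colnames(x) <- markers
    x <- exp(x / 3)
    truth <- rep(1:2, each = 300)
    list(x = x, truth = truth)
  })
  pool <- list(x = blobs$x, sample_id = rep(c("A", "B"), each = 300),
               cytotox = rep(c(10, 90), each = 300))
  cfg <- attribution_config(k_grid = 2, seed = 7)
  sw <- kmeans_sweep(pool, cfg)
  expect_identical(sw$models[[1]]$k, 2L)
  expect_equal(mclust::adjustedRandIndex(sw$models[[1]]$cluster,
                                         blobs$truth), 1)
  sw2 <- kmeans_sweep(pool, cfg)
  expect_identical(sw$models[[1]]$centers, sw2$models[[1]]$centers)

  tiny <- list(x = blobs$x[1:10, ], sample_id = rep("A", 10),
               cytotox = stats::runif(10))
  sw3 <- kmeans_sweep(tiny, attribution_config(k_grid = c(9, 64), seed = 1))
  expect_identical(vapply(sw3$models, `[[`, 0L, "k"), 9L)  # k >= n dropped
  expect_error(kmeans_sweep(tiny, attribution_config(k_grid = 64)),
               ">= the number of events")
})

test_that("explained variance is high for planted functional structure,
           low for noise, and flagged for constant targets", {
  mk_model <- function(y) {
    k <- length(y)
    centers <- with_seed(3, matrix(stats::rnorm(k * 5), k))
    colnames(centers) <- paste0("m", 1:5)
    list(k = k, centers = centers, cluster = rep(seq_len(k), each = 10),
         sizes = rep(10L, k), mean_cytotox = y)
  }
  cfg <- attribution_config(seed = 2)
  # cytotoxicity a smooth function of one centroid coordinate
  m <- mk_model(numeric(20))
  m$mean_cytotox <- 50 + 30 * m$centers[, "m1"]
  expect_gte(cluster_explained_variance(m, cfg), 0.9)

  # constant cytotoxicity: flagged
  expect_true(is.na(cluster_explained_variance(mk_model(rep(42, 20)), cfg)))

  # pure-noise cytotoxicity: median explained variance near or below zero
  evs <- vapply(1:20, function(s) {
    m <- mk_model(with_seed(s, stats::rnorm(20, 50, 20)))
    cluster_explained_variance(m, attribution_config(seed = s))
  }, 0)
  expect_lte(stats::median(evs), 0.2)
})

test_that("k selection takes the argmax, breaks ties toward smaller k and
           refuses all-flagged traces", {
  sweep_stub <- list(models = list(list(k = 2L), list(k = 4L),
                                   list(k = 8L)))
  sel <- select_optimal_k(sweep_stub, ev = c(0.1, 0.8, 0.7))
  expect_identical(sel$model$k, 4L)
  sel_tie <- select_optimal_k(sweep_stub, ev = c(0.1, 0.8, 0.8))
  expect_identical(sel_tie$model$k, 4L)
  expect_identical(sel_tie$trace$explained_variance, c(0.1, 0.8, 0.8))
  expect_error(select_optimal_k(sweep_stub, ev = rep(NA_real_, 3)),
               "undefined at every k")
})

test_that("cluster classification thresholds z-scored cytotoxicity and
           aggregates per-product fractions", {
  model <- list(k = 3L, mean_cytotox = c(10, 50, 90),
                cluster = rep(1:3, each = 4), sizes = rep(4L, 3))
  sweepd <- list(sample_id = rep(c("A", "B", "C"), each = 4),
                 z = matrix(0, 12, 2, dimnames = list(NULL, c("m1", "m2"))))
  cls <- classify_clusters(model, sweepd, z_threshold = 1)
  expect_equal(cls$clusters$z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_identical(cls$clusters$class, c("low", "moderate", "high"))
  # product A sits entirely in the low cluster
  a <- cls$product_fractions[cls$product_fractions$sample_id == "A", ]
  expect_equal(a$low, 1)
  expect_equal(rowSums(cls$product_fractions[, c("high", "moderate",
                                                 "low")]),
               rep(1, 3))

  # zero spread: all clusters moderate
  model0 <- model
  model0$mean_cytotox <- c(50, 50, 50)
  cls0 <- classify_clusters(model0, sweepd)
  expect_true(all(cls0$clusters$class == "moderate"))
  expect_true(all(cls0$clusters$z == 0))
})

test_that("end-to-end attribution on planted blobs recovers blob classes
           exactly and deterministically", {
  pl <- planted_blob_pool()
  cfg <- attribution_config(k_grid = c(2, 3, 4, 6, 8, 12), seed = 2)
  att <- attribute_cytotoxicity(pl$cells, pl$cytotox, cfg)
  pf <- att$product_fractions
  for (p in names(pl$blob)) {
    row <- pf[pf$sample_id == p, c("high", "moderate", "low")]
    expect_equal(row[[pl$blob_class[[p]]]], 1)
  }
  expect_equal(rowSums(pf[, c("high", "moderate", "low")]), rep(1, 6))

  att2 <- attribute_cytotoxicity(pl$cells, pl$cytotox, cfg)
  expect_identical(att$selected_k, att2$selected_k)
  expect_identical(att$trace, att2$trace)
  expect_identical(att$product_fractions, att2$product_fractions)
})
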