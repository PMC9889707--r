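test_that("product clustering recovers planted archetypes and validates k", {
  arch <- with_seed(4, {
    centers <- matrix(stats::rnorm(5 * 8, 0, 4), 5)
    x <- centers[rep(1:5, each = 10), ] + stats::rnorm(50 * 8, 0, 0.2)
    colnames(x) <- paste0("f", 1:8)
    df <- data.frame(sample_id = paste0("P", 1:50), x,
                     stringsAsFactors = FALSE, check.names = FALSE)
    list(df = df, truth = rep(1:5, each = 10))
  })
  cl <- cluster_products(arch$df, k = 5, seed = 1)
  expect_equal(mclust::adjustedRandIndex(cl$labels, arch$truth), 1)
  expect_gt(cl$var_explained, 0.9)
  expect_identical(cluster_products(arch$df, k = 5, seed = 1)$labels,
                   cl$labels)
  expect_error(cluster_products(arch$df, k = 1), ">= 2")
  expect_error(cluster_products(arch$df[1:3, ], k = 5), "exceeds")

  # k chosen by variance explained: archetypes need k = 5, not k = 2
  kv <- choose_k_by_variance(arch$df, 2:6, threshold = 0.9, seed = 1)
  expect_identical(kv$k, 5L)
  expect_lt(kv$trace$var_explained[kv$trace$k == 2], 0.9)
  # single archetype plus noise: nothing reaches the threshold
  null_df <- with_seed(5, {
    x <- matrix(stats::rnorm(40 * 8), 40)
    colnames(x) <- paste0("f", 1:8)
    data.frame(sample_id = paste0("P", 1:40), x, check.names = FALSE)
  })
  kv0 <- choose_k_by_variance(null_df, 2:5, threshold = 0.9, seed = 1)
  expect_true(is.na(kv0$k))
  expect_identical(nrow(kv0$trace), 4L)
  # degenerate threshold returns the smallest candidate
  expect_identical(choose_k_by_variance(null_df, 2:5, threshold = 0,
                                        seed = 1)$k, 2L)
})

test_that("dose-separable labels are learned almost perfectly by every
           algorithm and permuted labels fall to chance", {
  doses <- rep(c(2, 5, 10, 15, 30), each = 10)
  x <- data.frame(dose_pg_per_cell = doses)
  y <- factor(rep(1:5, each = 10))
  rep_all <- train_classifiers(x, y, seed = 4)
  expect_identical(nrow(rep_all$results), 5L)
  expect_true(all(rep_all$results$cv_mean >= 0.95))

  one <- train_classifiers(x, y, algorithms = "naive_bayes", seed = 4)
  expect_identical(nrow(one$results), 1L)

  accs <- vapply(1:10, function(s) {
    yp <- with_seed(100 + s, sample(y))
    train_classifiers(x, yp, algorithms = "random_forest",
                      seed = s)$results$cv_mean
  }, 0)
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 5), 3 * se + 1e-9)
})

test_that("most of the classifier battery clears 0.7 cross-validated
           accuracy on the default healthy cohort", {
  des <- classifier_design(default_cohort(), "healthy", seed = 1)
  rep <- train_classifiers(des$x, des$labels, seed = 1)
  expect_gte(sum(rep$results$cv_mean > 0.7), 3)
  expect_true(all(rep$results$cv_mean >= 0 & rep$results$cv_mean <= 1))
})

test_that("training splits are reproducible and keep every class in the
           training partition", {
  y <- factor(c(rep(1, 20), rep(2, 2)))  # rare class
  for (s in 1:5) {
    sp <- carstim:::.class_safe_split(y, 0.7, s)
    expect_true(all(levels(y) %in% levels(droplevels(y[sp$train]))))
    expect_setequal(c(sp$train, sp$test), seq_along(y))
  }
})

test_that("forest importances are normalized, rank a planted dose driver
           first and place noise features low", {
  doses <- rep(c(2, 5, 10, 15, 30), each = 10)
  y <- factor(rep(1:5, each = 10))
  x <- with_seed(8, data.frame(dose_pg_per_cell = doses,
                               noise1 = stats::rnorm(50),
                               noise2 = stats::rnorm(50)))
  rep1 <- train_classifiers(x, y, algorithms = "random_forest", seed = 2)
  imp <- feature_importance(rep1)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_identical(imp$feature[1], "dose_pg_per_cell")
  expect_gt(imp$importance[1], 0.5)
  expect_false("dose_pg_per_cell" %in% attr(imp, "top5_nondose"))
  expect_error(feature_importance(structure(list(), class = "lm")),
               "random-forest")

  # a pure-noise feature ranks below informative features across seeds
  ranks <- vapply(1:10, function(s) {
    xx <- with_seed(s, data.frame(
      inf1 = as.numeric(y) + stats::rnorm(50, 0, 0.3),
      inf2 = as.numeric(y) * 2 + stats::rnorm(50, 0, 0.3),
      pure_noise = stats::rnorm(50)))
    ii <- feature_importance(
      train_classifiers(xx, y, algorithms = "random_forest",
                        seed = s)$fits$random_forest)
    ii$importance[ii$feature == "pure_noise"] <
      stats::median(ii$importance[ii$feature != "pure_noise"])
  }, TRUE)
  expect_gte(mean(ranks), 0.9)
})

test_that("the dose-only ablation shares folds across arms, detects a
           planted phenotype interaction and is null when dose alone
           drives labels", {
  mk <- function(seed) {
    with_seed(seed, {
      doses <- rep(c(2, 5, 10, 15, 30), each = 10)
      pheno <- rep(stats::rnorm(10), times = 5)  # donor-level feature
      # labels need both the dose band and the donor phenotype sign
      y <- factor(paste0(findInterval(doses, c(0, 8, 18)), pheno > 0))
      x <- data.frame(dose_pg_per_cell = doses, pheno = pheno,
                      nuisance = stats::rnorm(50))
      list(x = x, y = y)
    })
  }
  diffs <- vapply(1:10, function(s) {
    d <- mk(s)
    dose_only_ablation(d$x, d$y, seed = s)$difference
  }, 0)
  expect_gte(mean(diffs > 0), 0.8)  # sign test: interaction detected
  expect_gt(mean(diffs), 0)

  # dose-only labels: no significant full-vs-dose-only difference
  doses <- rep(c(2, 5, 10, 15, 30), each = 10)
  y0 <- factor(findInterval(doses, c(0, 8, 18)))
  diffs0 <- vapply(1:10, function(s) {
    x0 <- with_seed(s, data.frame(dose_pg_per_cell = doses,
                                  nuisance = stats::rnorm(50)))
    dose_only_ablation(x0, y0, seed = s)$difference
  }, 0)
  se0 <- stats::sd(diffs0) / sqrt(length(diffs0))
  expect_lt(abs(mean(diffs0)), 3 * se0 + 1e-9)
  expect_error(dose_only_ablation(data.frame(a = 1:5), factor(1:5)),
               "missing dose column")
})

test_that("the status classifier is perfect on a separable toy and at
           chance on shuffled labels", {
  df <- data.frame(sample_id = paste0("P", 1:40),
                   f1 = rep(c(-2, 2), each = 20),
                   status = rep(c("healthy", "patient"), each = 20),
                   stringsAsFactors = FALSE)
  df$f2 <- with_seed(1, stats::rnorm(40))
  expect_equal(status_classifier(df, seed = 1)$accuracy, 1)
  expect_error(status_classifier(df[df$status == "healthy", ]),
               "both statuses")

  accs <- vapply(1:5, function(s) {
    df$status <- with_seed(200 + s, sample(df$status))
    status_classifier(df, seed = s)$accuracy
  }, 0)
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.05)
})
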