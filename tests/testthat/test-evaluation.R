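test_that("variant assembly yields the published dimensionalities", {
  feats <- autonomic_features()
  n_feat <- function(tab) length(setdiff(names(tab),
                                         c("subject", "ad", "label")))
  expect_equal(n_feat(assemble_variant("GSR", feats)), 10)
  expect_equal(n_feat(assemble_variant("RSP", feats)), 6)
  expect_equal(n_feat(assemble_variant("HRV", feats)), 56)
  expect_equal(n_feat(assemble_variant("GSR+HRV", feats)), 66)
})

test_that("combined variants keep only coincident instances", {
  feats <- autonomic_features()
  # drop one subject's HRV rows: that subject leaves every HRV variant
  drop_subj <- feats$hrv$subject[1]
  feats2 <- feats
  feats2$hrv <- dplyr::filter(feats2$hrv, subject != drop_subj)
  tab <- assemble_variant("GSR+HRV", feats2)
  expect_false(drop_subj %in% tab$subject)
  expect_true(drop_subj %in% assemble_variant("GSR", feats2)$subject)
  expect_equal(nrow(tab), nrow(feats2$hrv))
})

test_that("standardization centres, scales, warns and is idempotent", {
  tab <- toy_feature_table()
  std <- standardize_features(tab)
  for (c in c("signal", "noise1")) {
    expect_lt(abs(mean(std[[c]])), 1e-9)
    expect_lt(abs(var(std[[c]]) - 1), 1e-9)
  }
  std2 <- standardize_features(std)
  expect_equal(std2$signal, std$signal, tolerance = 1e-9)
  tab$flatline <- 7
  expect_warning(sf <- standardize_features(tab), "constant")
  expect_true(all(sf$flatline == 0))
})

test_that("SMOTE balances classes with convex-combination points", {
  tab <- toy_feature_table(n_per_class = 20)
  unb <- tab[c(1:20, 21:30, 41:50), ] # counts 20 / 10 / 10
  bal <- smote_balance(unb, k = 5, seed = 3)
  expect_equal(unname(table(bal$label)), rep(20L, 3), ignore_attr = TRUE)
  # every synthetic point lies on a segment between two real class members
  cols <- c("signal", paste0("noise", 1:3))
  synth <- bal[grepl("^synthetic_", bal$subject), ]
  real <- unb
  for (i in seq_len(nrow(synth))) {
    cls <- synth$label[i]
    x <- as.numeric(synth[i, cols])
    peers <- as.matrix(real[real$label == cls, cols])
    resid <- apply(utils::combn(nrow(peers), 2), 2, function(pr) {
      a <- peers[pr[1], ]; b <- peers[pr[2], ]
      ab <- b - a
      if (sum(ab^2) < 1e-12) return(sqrt(sum((x - a)^2)))
      u <- sum((x - a) * ab) / sum(ab^2)
      if (u < -1e-9 || u > 1 + 1e-9) return(Inf)
      sqrt(sum((x - (a + u * ab))^2))
    })
    expect_lt(min(resid), 1e-8)
  }
  # already balanced: unchanged
  expect_identical(smote_balance(tab, seed = 1), tab)
})

test_that("stratified folds spread classes within one instance", {
  labels <- rep(c("a", "b", "c"), c(40, 25, 17))
  folds <- stratified_folds(labels, k = 10, seed = 2)
  for (cls in unique(labels)) {
    per_fold <- table(factor(folds[labels == cls], levels = 1:10))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("cross-validation scores separable data and baselines correctly", {
  tab <- standardize_features(toy_feature_table(n_per_class = 20, sep = 6))
  cv <- cross_validate(tab, classifier_spec("RF", seed = 1), k = 10,
                       seed = 1)
  expect_gte(cv$average, 95)
  expect_equal(sum(cv$confusion), nrow(tab))
  # Zero Rule on a balanced table: one class at 100, the rest at 0
  cv0 <- cross_validate(tab, classifier_spec("ZERO_RULE", seed = 1),
                        k = 10, seed = 1)
  expect_equal(sort(unname(cv0$per_class$accuracy)), c(0, 0, 100))
  expect_equal(cv0$average, 100 / 3, tolerance = 1e-9)
  expect_equal(round(cv0$average, 2), 33.33)
})

test_that("label permutation stays inside the chance band", {
  tab <- toy_feature_table(n_per_class = 20, sep = 6)
  tab$label <- withr::with_seed(8, sample(tab$label))
  cv <- cross_validate(standardize_features(tab),
                       classifier_spec("RF", seed = 2), k = 10, seed = 2)
  half_width <- 1.96 * sqrt((1 / 3) * (2 / 3) / nrow(tab)) * 100
  expect_lt(abs(cv$average - 100 / 3), half_width)
})

test_that("the wrapper finds a single perfectly predictive feature", {
  tab <- standardize_features(toy_feature_table(n_per_class = 15,
                                                sep = 10))
  sel <- wrapper_select(tab, seed = 4)
  expect_true("signal" %in% sel)
  expect_lte(length(sel), 4)
  # deterministic on re-run; subset of columns
  expect_identical(sel, wrapper_select(tab, seed = 4))
  expect_true(all(sel %in% setdiff(names(tab),
                                   c("subject", "ad", "label"))))
})

test_that("every cascade token trains and predicts", {
  tab <- standardize_features(toy_feature_table(n_per_class = 12, sep = 5))
  for (cas in c("RF", "MCC+RF", "BAG+RF", "AB+RF", "MCC+AB+RF", "SVM",
                "MLP", "LOGISTIC", "NB", "CART", "KNN", "ONE_RULE")) {
    cv <- cross_validate(tab, classifier_spec(cas, seed = 3), k = 5,
                         seed = 3)
    expect_gte(cv$average, 60) # well-separated data: far above chance
  }
})

test_that("holdout prediction aggregates a majority vote", {
  tab <- standardize_features(toy_feature_table(n_per_class = 15, sep = 6))
  model <- fit_cascade(classifier_spec("RF", seed = 5), tab)
  hold <- tab[tab$label == "positive", ][1:5, ]
  hold$label <- "unlabeled"
  res <- predict_holdout(model, hold)
  expect_equal(sum(res$shares), 1)
  expect_equal(res$majority, "positive")
  one <- predict_holdout(model, hold[1, ])
  expect_equal(one$majority, one$instances$predicted[1])
})

test_that("cv_result and protocol accessors tidy cleanly", {
  tab <- standardize_features(toy_feature_table(n_per_class = 12, sep = 6))
  cv <- cross_validate(tab, classifier_spec("RF", seed = 1), k = 5,
                       seed = 1)
  td <- tidy(cv)
  expect_equal(nrow(td), 3)
  gl <- glance(cv)
  expect_equal(gl$average, cv$average)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})
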