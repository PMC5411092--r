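# Training-set construction, imputation, random-forest training, CV metrics.

test_that("genotype expansion follows the mode of inheritance", {
  v <- tibble::tibble(id = 1:3, moi = c("Recessive", "Dominant", "Other"))
  out <- expand_genotypes(v)
  expect_equal(nrow(out), 5)
  expect_equal(out$genotype[out$id == 1], "hom")
  expect_equal(out$genotype[out$id == 2], c("het", "hom"))
  expect_equal(out$genotype[out$id == 3], c("het", "hom"))
  expect_error(expand_genotypes(tibble::tibble(moi = "AutosomalWeird")),
               "AutosomalWeird")
})

test_that("training-set composition matches the negative-sampling modes", {
  w <- acc_world()
  res <- list(hierarchy = w$hierarchy, corpus = w$corpus, panel = w$panel,
              ic = w$ic, res = w$res)
  lab <- make_labeled_table(w, n_benign = 10L, per_disease = 1L, seed = 5L)

  tp <- make_training_set(lab, w$diseases, "pathogenic", seed = 6L,
                          resources = res)
  n_pos <- sum(tp$label == "causative")
  expect_equal(sum(tp$provenance == "pathogenic-non-causative"), n_pos)
  expect_equal(sum(tp$provenance == "benign-non-causative"), 0)
  # each positive's expansion respects its disease's MOI
  n_rec <- sum(w$diseases$moi == "Recessive")
  expect_equal(n_pos, n_rec + 2 * (nrow(w$diseases) - n_rec))

  tb <- make_training_set(lab, w$diseases, "benign", seed = 6L,
                          resources = res)
  expect_equal(sum(tb$provenance == "pathogenic-non-causative"), 0)
  expect_gt(sum(tb$provenance == "benign-non-causative"), 0)

  tm <- make_training_set(lab, w$diseases, "mixed", seed = 6L,
                          resources = res)
  n_pnc <- sum(tm$provenance == "pathogenic-non-causative")
  n_bnc <- sum(tm$provenance == "benign-non-causative")
  expect_equal(n_pnc, n_bnc) # 50/50 by subsampling the larger pool
  # mismatched diseases always differ from the variant's own disease
  own <- lab$disease_id[match(
    paste(tm$chrom, tm$pos, tm$ref, tm$alt),
    paste(lab$chrom, lab$pos, lab$ref, lab$alt))]
  pnc <- tm$provenance == "pathogenic-non-causative"
  expect_true(all(tm$disease_id[pnc] != own[pnc]))
  # determinism
  tm2 <- make_training_set(lab, w$diseases, "mixed", seed = 6L,
                           resources = res)
  expect_identical(as.data.frame(tm), as.data.frame(tm2))
  # fewer than two diseases cannot be mismatched
  expect_error(make_training_set(lab, w$diseases[1, ], "pathogenic",
                                 seed = 1L, resources = res),
               "at least 2")
})

test_that("imputation uses label-conditional medians at training time", {
  ex <- acc_training_set("mixed")[1:20, ]
  ex$score_1[1:3] <- NA
  known <- ex$score_1[!is.na(ex$score_1) & ex$label == ex$label[1]]
  out <- impute_missing(ex)
  expect_false(anyNA(out[feature_names()]))
  for (i in 1:3) {
    lb <- ex$label[i]
    expect_equal(out$score_1[i],
                 median(ex$score_1[!is.na(ex$score_1) & ex$label == lb]))
  }
  # no missing values: identity on the feature block
  clean <- acc_training_set("mixed")
  expect_equal(as.data.frame(impute_missing(clean)[feature_names()]),
               as.data.frame(clean[feature_names()]), ignore_attr = TRUE)
  # a feature missing everywhere is an error naming it
  ex2 <- acc_training_set("mixed")
  ex2$score_2 <- NA_real_
  expect_error(impute_missing(ex2), "score_2")
})

test_that("prediction-time missing values fall back to stored statistics", {
  m <- acc_model("mixed")
  ex <- acc_training_set("mixed")[1:5, ]
  ex$score_1 <- NA_real_
  p1 <- predict(m, ex)
  ex$score_1 <- m$imputer$pooled[["score_1"]]
  p2 <- predict(m, ex)
  expect_equal(p1, p2)
})

test_that("the forest separates a separable training set and is deterministic", {
  ex <- acc_training_set("mixed")
  m1 <- train_model(ex, "mixed", seed = 11L)
  p <- predict(m1, ex)
  expect_true(min(p[ex$label == "causative"]) >
                max(p[ex$label != "causative"]))
  expect_equal(roc_auc(p, ex$label == "causative"), 1.0)
  m2 <- train_model(ex, "mixed", seed = 11L)
  expect_identical(predict(m2, ex), p)
  expect_error(train_model(ex[ex$label == "causative", ]), "both")
})

test_that("the pathogenic-mode model is monotone in similarity on a probe grid", {
  m <- acc_model("pathogenic")
  probe <- acc_training_set("pathogenic")[1, ]
  grid <- probe[rep(1, 11), ]
  grid$similarity <- seq(0, 1, by = 0.1)
  p <- predict(m, grid)
  expect_gte(cor(grid$similarity, p, method = "spearman"), 0.9)
  expect_gt(p[11], p[1])
})

test_that("the model family shows the stated emphasis asymmetry", {
  mp <- acc_model("pathogenic")
  mb <- acc_model("benign")
  base <- acc_training_set("mixed")[1, ]
  # vary only the pathogenicity scores
  gs <- base[rep(1, 11), ]
  for (f in c("score_1", "score_2", "score_3")) gs[[f]] <- seq(0, 1, 0.1)
  spread_scores <- function(m) diff(range(predict(m, gs)))
  # vary only the similarity
  gv <- base[rep(1, 11), ]
  gv$similarity <- seq(0, 1, 0.1)
  spread_sim <- function(m) diff(range(predict(m, gv)))
  expect_gt(spread_scores(mb), spread_scores(mp))
  expect_gt(spread_sim(mp), spread_sim(mb))
})

test_that("rank-based AUC equals brute-force pairwise comparison and pROC", {
  set.seed(9)
  scores <- round(runif(60), 2) # rounding forces ties
  labels <- rbinom(60, 1, 0.4)
  expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
               tolerance = 1e-12)
  expect_equal(roc_auc(scores, labels),
               as.numeric(suppressMessages(pROC::auc(labels, scores))),
               tolerance = 1e-9)
  expect_error(roc_auc(scores, rep(1, 60)), "both")
})

test_that("cross-validation is stratified and behaves at the extremes", {
  ex <- acc_training_set("mixed")
  cv <- crossvalidate(ex, k = 5L, seed = 3L)
  expect_equal(nrow(cv), 5)
  expect_equal(mean(cv$auc), 1.0) # separable signal
  g <- glance(cv)
  # pooled scores mix fold calibrations, so pooled AUC may dip slightly
  expect_gte(g$pooled_auc, 0.95)
  # shuffled labels: permutation null around 0.5
  set.seed(4)
  big <- ex[sample(nrow(ex), 600, replace = TRUE), ]
  big$label <- sample(big$label)
  cv0 <- crossvalidate(big, k = 5L, seed = 5L)
  expect_gt(mean(cv0$auc), 0.4)
  expect_lt(mean(cv0$auc), 0.6)
  # k = 2 on a 5/5 set: both folds balanced
  ten <- ex[c(which(ex$label == "causative")[1:5],
              which(ex$label != "causative")[1:5]), ]
  cv2 <- crossvalidate(ten, k = 2L, seed = 6L)
  expect_equal(nrow(cv2), 2)
  expect_error(crossvalidate(ten[1:6, ], k = 5L), "stratify")
})

test_that("models survive a serialization round-trip with signature checks", {
  m <- acc_model("mixed")
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(m, path)
  m2 <- read_model(path)
  ex <- acc_training_set("mixed")[1:10, ]
  expect_identical(predict(m, ex), predict(m2, ex))
  saveRDS(list(not = "a model"), path)
  expect_error(read_model(path), "signature")
})
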