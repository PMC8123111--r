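skew <- function(x) mean((x - mean(x))^3) / sd(x)^3

test_that("normalization: power transform tames skew, coordinates untouched", {
  tab <- synth_feature_table(30, seed = 3)
  set.seed(4)
  tab$`Surface area` <- rlnorm(nrow(tab), 1, 0.9)      # heavily right-skewed
  tab$Height <- rnorm(nrow(tab), 10, 2)                # already Gaussian
  nf <- suppressWarnings(normalize_features(tab))
  out <- nf$table
  expect_lt(abs(skew(out$`Surface area`)), abs(skew(tab$`Surface area`)))
  expect_lt(abs(skew(out$Height)), 0.3)
  for (cn in coordinate_columns())
    expect_identical(out[[cn]], tab[[cn]])             # bit-exact exemption
  # standardized scale
  expect_equal(mean(out$`Surface area`), 0, tolerance = 1e-8)
  expect_equal(sd(out$`Surface area`), 1, tolerance = 1e-8)
  # constant feature: identity with a warning
  tab$Base <- 1
  expect_warning(fit_normalizer(tab), "constant feature 'Base'")
  # stored parameters reproduce the transform on new data
  out2 <- apply_normalizer(nf$norm, tab[1:10, ])
  expect_equal(out2$`Surface area`, out$`Surface area`[1:10])
})

test_that("label extension fills objects, respects majorities, flags ties", {
  tab <- data.frame(object_id = c(1, 1, 1, 1, 1, 2, 2, 3, 3),
                    label = c("FISH", NA, NA, NA, NA, NA, NA, "GAS", "NOISE"))
  before <- sum(!is.na(tab$label))
  out <- extend_labels(tab)
  expect_equal(out$label[1:5], rep("FISH", 5))         # 1 labelled -> 5
  expect_true(all(is.na(out$label[6:7])))              # unlabelled object
  expect_gte(sum(!is.na(out$label)), before)           # monotone
  # tie within object 3: left unlabelled, reported
  expect_message(extend_labels(data.frame(object_id = c(3, 3, 3),
                                          label = c("GAS", "NOISE", NA))),
                 "tied")
  # existing labels never altered
  expect_equal(out$label[8:9], c("GAS", "NOISE"))
})

test_that("mutual information: zero for independent, maximal for the label itself", {
  tab <- synth_feature_table(60, seed = 7)
  tab$label <- tab$truth
  tab$`Sv_UNCAL diff` <- rnorm(nrow(tab))              # independent feature
  tab$Beams <- as.numeric(factor(tab$label))           # the label, recoded
  mi <- mutual_info_scores(tab)
  expect_true(all(mi >= 0))
  # independent feature: near zero up to the plug-in bias,
  # ~ (bins - 1)(classes - 1) / (2 n) nats
  expect_lt(mi[["Sv_UNCAL diff"]], 0.12)
  expect_gte(mi[["Beams"]], max(mi) - 1e-9)  # maximal among features
  # plug-in oracle for the label-recoded feature: H(Y) = log(4)
  expect_equal(unname(mi[["Beams"]]), log(4), tolerance = 0.01)
  expect_error(mutual_info_scores(data.frame(label = c("A", "A"))), "2 classes")
})

test_that("pseudo-labelling recovers well-separated classes from 10% labels", {
  tab <- synth_feature_table(50, seed = 11)
  set.seed(12)
  lab_idx <- unlist(lapply(split(seq_len(nrow(tab)), tab$truth),
                           function(i) sample(i, 5)))  # 10% per class
  tab$label <- NA_character_
  tab$label[lab_idx] <- tab$truth[lab_idx]
  nf <- suppressWarnings(normalize_features(tab))
  ps <- pseudo_label(nf$table, k = 5, seed = 2)
  filled <- ps$table
  expect_true(all(!is.na(filled$label)))
  # operator labels never altered
  expect_equal(filled$label[lab_idx], tab$truth[lab_idx])
  # pseudo-label accuracy against the ground truth
  un <- setdiff(seq_len(nrow(tab)), lab_idx)
  expect_gte(mean(filled$label[un] == tab$truth[un]), 0.95)
  # report in the per-class layout; supports sum to the evaluated count
  expect_true(all(c("Precision", "Recall", "F1-Score", "Support") %in%
                    names(ps$report)))
  sup <- ps$report$Support[ps$report$Class %in% unique(tab$truth)]
  expect_equal(sum(sup), ps$report$Support[ps$report$Class == "accuracy"])
  # fully labelled input passes through unchanged
  full <- nf$table; full$label <- tab$truth
  ps2 <- pseudo_label(full, k = 5, seed = 2)
  expect_equal(ps2$table$label, tab$truth)
  # agreement with an unweighted kNN on clean data (independent cross-check)
  if (requireNamespace("class", quietly = TRUE)) {
    cols <- setdiff(feature_schema(), coordinate_columns())
    X <- scale(as.matrix(nf$table[cols]))
    ref <- class::knn(X[lab_idx, ], X[un, ], factor(tab$truth[lab_idx]), k = 5)
    expect_gte(mean(as.character(ref) == filled$label[un]), 0.9)
  }
})

test_that("stratified split preserves class proportions and is reproducible", {
  tab <- data.frame(label = rep(c("FISH", "GAS", "NOISE", "PLATFORM"), each = 25))
  sp <- stratified_split(tab, ratio = 0.7, seed = 4)
  expect_setequal(c(sp$train, sp$test), seq_len(100))
  expect_length(intersect(sp$train, sp$test), 0)
  for (cl in unique(tab$label)) {
    n_tr <- sum(tab$label[sp$train] == cl)
    expect_true(n_tr %in% 17:18)                       # 70% of 25
    expect_true(sum(tab$label[sp$test] == cl) %in% 7:8)
  }
  sp2 <- stratified_split(tab, ratio = 0.7, seed = 4)
  expect_identical(sp, sp2)
  expect_error(stratified_split(data.frame(label = c("A", "B", NA)), 0.7, 1),
               "labelled")
  expect_error(stratified_split(data.frame(label = c("A", "A", "B")), 0.7, 1),
               "at least 2 rows")
})

test_that("grid-searched ensemble separates synthetic classes and is deterministic", {
  tab <- synth_feature_table(40, seed = 21)
  tab$label <- tab$truth
  nf <- suppressWarnings(normalize_features(tab))
  sp <- stratified_split(nf$table, 0.7, seed = 3)
  grid <- expand.grid(eta = 0.1, nrounds = c(30, 60), max_depth = 2)
  m <- train_ensemble(nf$table[sp$train, ], grid = grid, seed = 3, nfold = 3)
  # coordinates excluded from the fitted feature space
  expect_length(intersect(m$feature_cols, coordinate_columns()), 0)
  expect_length(m$feature_cols, 18L)
  ev <- evaluate_model(m, nf$table[sp$test, ])
  expect_gte(ev$accuracy, 0.95)
  # determinism: same seed and grid give the same chosen point
  m2 <- train_ensemble(nf$table[sp$train, ], grid = grid, seed = 3, nfold = 3)
  expect_identical(m$best, m2$best)
  expect_identical(m$cv_accuracy, m2$cv_accuracy)
  # degenerate single-class training refused
  one <- nf$table[sp$train, ]; one$label <- "FISH"
  expect_error(train_ensemble(one, grid = grid, seed = 1), "single class")
})

test_that("label-shuffled training collapses CV accuracy to chance", {
  tab <- synth_feature_table(30, seed = 31)
  set.seed(32)
  tab$label <- sample(tab$truth)                        # permutation null
  nf <- suppressWarnings(normalize_features(tab))
  grid <- expand.grid(eta = 0.1, nrounds = 30, max_depth = 2)
  m <- train_ensemble(nf$table, grid = grid, seed = 5, nfold = 3)
  expect_lt(max(m$cv_accuracy), 0.4)                    # ~0.25 +- sampling
  expect_gt(max(m$cv_accuracy), 0.1)
})

test_that("classification report matches a hand-computed fixture", {
  truth <- c(rep("A", 8), rep("B", 7), rep("C", 5))
  pred <- c(rep("A", 6), "B", "C", rep("B", 6), "A", rep("C", 4), "B")
  cr <- classification_report(truth, pred)
  r <- cr$report
  # hand-computed: A tp=6 fp=1 fn=2; B tp=6 fp=2 fn=1; C tp=4 fp=1 fn=1
  expect_equal(r$Precision[r$Class == "A"], 6 / 7)
  expect_equal(r$Recall[r$Class == "A"], 6 / 8)
  expect_equal(r$Precision[r$Class == "B"], 6 / 8)
  expect_equal(r$Recall[r$Class == "C"], 4 / 5)
  acc <- (6 + 6 + 4) / 20
  expect_equal(cr$accuracy, acc)
  # accuracy equals trace(confusion) / total
  expect_equal(sum(diag(cr$confusion)) / sum(cr$confusion), acc)
  # weighted F1 equals the support-weighted mean of class F1
  cls <- r[r$Class %in% c("A", "B", "C"), ]
  expect_equal(r$`F1-Score`[r$Class == "weighted avg"],
               sum(cls$`F1-Score` * cls$Support) / sum(cls$Support),
               tolerance = 1e-12)
  # perfect predictions: all ones, diagonal confusion
  crp <- classification_report(truth, truth)
  expect_true(all(crp$report$Precision[1:3] == 1))
  expect_true(all(crp$confusion[upper.tri(crp$confusion)] == 0))
  # all-one-class predictions: that class has recall 1, others 0
  cra <- classification_report(truth, rep("A", 20))
  expect_equal(cra$report$Recall[cra$report$Class == "A"], 1)
  expect_equal(cra$report$Recall[cra$report$Class == "B"], 0)
})

test_that("prediction validates the schema and ignores column order", {
  tab <- synth_feature_table(30, seed = 41)
  tab$label <- tab$truth
  fit <- suppressWarnings(train_wc_classifier(tab, seed = 2,
    grid = expand.grid(eta = 0.1, nrounds = 30, max_depth = 2)))
  p1 <- predict(fit$model, tab)
  # replaying the training table reproduces the evaluation-stage labels
  expect_gte(mean(as.character(p1) == tab$truth), 0.95)
  # column-permuted input gives identical predictions
  perm <- tab[, sample(names(tab))]
  expect_identical(as.character(predict(fit$model, perm)), as.character(p1))
  # missing column named in the error
  broken <- tab[, setdiff(names(tab), "Height")]
  expect_error(predict(fit$model, broken), "Height")
  # probabilities: one row per slice, classes as columns, rows sum to 1
  pr <- predict(fit$model, tab, type = "prob")
  expect_equal(dim(pr), c(nrow(tab), 4L))
  expect_equal(unname(rowSums(pr)), rep(1, nrow(tab)), tolerance = 1e-6)
  # object-level majority vote
  mv <- object_majority_labels(c("GAS", "GAS", "FISH"), c(1, 1, 2))
  expect_equal(unname(mv[order(names(mv))]), c("GAS", "FISH"))
})

test_that("a transferred model finds no gas in a gas-free unseen survey", {
  cfgA <- tiny_config(seed = 7, area_side = 60)
  tgA <- list(
    target_spec("FISH", c(0, 5, 18), c(10, 10, 6), 25, velocity = c(0.5, 0, 0)),
    target_spec("GAS", c(14, -4, 30), c(2.4, 2.4, 4), 30, velocity = c(0, 0, 1.5)),
    target_spec("PLATFORM", c(-14, 2, 1), c(2.5, 2.5, 30), 35),
    target_spec("NOISE", c(-22, -5, 13), c(8, 6, 4), 18))
  runA <- suppressWarnings(run_pipeline(cfgA, targets = tgA,
                                        label_fraction = 0.3))
  # a second survey over a different scene without any seep
  cfgB <- tiny_config(seed = 31, area_side = 60)
  tgB <- list(
    target_spec("FISH", c(-5, 4, 16), c(11, 9, 6), 25),
    target_spec("PLATFORM", c(12, -2, 1), c(2.5, 2.5, 30), 35),
    target_spec("NOISE", c(-18, 3, 14), c(7, 7, 3), 18))
  runB <- suppressWarnings(run_pipeline(cfgB, targets = tgB, run_ml = FALSE))
  predB <- predict(runA$ml$model, runB$metrics)
  mv <- object_majority_labels(as.character(predB), runB$metrics$object_id)
  expect_false("GAS" %in% mv)
  # the transferred model still recognises the dominant classes
  expect_gte(mean(as.character(predB)[runB$truth == "FISH"] == "FISH"), 0.8)
})
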