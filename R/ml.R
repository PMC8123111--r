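#' @title Semi-supervised slice classification
#'
#' @description
#' Normalization (Yeo-Johnson + standardization, coordinates exempt), label
#' extension within multi-ping objects, mutual-information feature scores,
#' distance-weighted kNN pseudo-labelling, a stratified 70:30 split, a
#' grid-searched gradient-boosted ensemble, evaluation reports, and
#' transfer prediction on unseen surveys.
#'
#' @name ml_pipeline
NULL

.WC_CLASSES <- c("FISH", "GAS", "NOISE", "PLATFORM")

metric_feature_cols <- function() setdiff(feature_schema(), coordinate_columns())

# ---- normalization ----------------------------------------------------------

#' Fit the feature normalizer
#'
#' Per-feature Yeo-Johnson power transform (maximum-likelihood lambda)
#' followed by standardization, fitted on the given (training) rows.
#' Coordinate columns are exempt and pass through untouched; constant
#' features fall back to the identity transform with a warning.
#'
#' @param table feature data.frame containing the schema columns.
#' @return an object of class `wc_normalizer`.
#' @export
fit_normalizer <- function(table) {
  cols <- metric_feature_cols()
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  par <- lapply(cols, function(cn) {
    x <- as.numeric(table[[cn]])
    if (any(!is.finite(x)))
      stop(sprintf("feature '%s' contains non-finite values", cn))
    if (length(unique(x)) < 2 || stats::sd(x) == 0) {
      warning(sprintf("constant feature '%s': identity transform", cn))
      return(list(lambda = 1, mean = mean(x), sd = 1))
    }
    lam <- tryCatch(
      as.numeric(car::powerTransform(x, family = "yjPower")$lambda),
      error = function(e) 1)
    if (!is.finite(lam)) lam <- 1
    y <- car::yjPower(x, lam)
    s <- stats::sd(y)
    list(lambda = lam, mean = mean(y), sd = if (s > 0) s else 1)
  })
  names(par) <- cols
  z <- list(params = par, exempt = coordinate_columns())
  class(z) <- "wc_normalizer"
  z
}

#' Apply a fitted normalizer to a feature table
#'
#' @param norm a `wc_normalizer` from [fit_normalizer()].
#' @param table feature data.frame.
#' @return the table with non-coordinate features transformed.
#' @export
apply_normalizer <- function(norm, table) {
  for (cn in names(norm$params)) {
    p <- norm$params[[cn]]
    table[[cn]] <- (car::yjPower(as.numeric(table[[cn]]), p$lambda) - p$mean) / p$sd
  }
  table
}

#' Normalize features (fit + apply on the same table)
#'
#' @param table feature data.frame.
#' @return list with `table` (normalized) and `norm` (the fitted
#'   `wc_normalizer`).
#' @export
normalize_features <- function(table) {
  norm <- fit_normalizer(table)
  list(table = apply_normalizer(norm, table), norm = norm)
}

# ---- label extension --------------------------------------------------------

#' Extend labels within multi-ping objects
#'
#' Slices sharing a multi-ping object with a labelled slice inherit its
#' label, on the assumption that contiguous slices on the same track belong
#' to the same target. Conflicting labels within an object resolve by
#' majority; ties are left unlabelled (and reported via a message).
#'
#' @param table feature table with `object_id` and `label` columns.
#' @return the table with extended labels; existing labels are never
#'   altered.
#' @export
extend_labels <- function(table) {
  lab <- table$label
  ties <- 0L
  for (oid in unique(table$object_id[!is.na(lab)])) {
    idx <- which(table$object_id == oid)
    have <- lab[idx]
    have <- have[!is.na(have)]
    if (!length(have)) next
    tb <- sort(table(have), decreasing = TRUE)
    if (length(tb) > 1 && tb[1] == tb[2]) { ties <- ties + 1L; next }
    fill <- idx[is.na(lab[idx])]
    lab[fill] <- names(tb)[1]
  }
  if (ties > 0) message(sprintf("%d object(s) with tied labels left unlabelled", ties))
  table$label <- lab
  table
}

# ---- mutual information -----------------------------------------------------

#' Mutual information between each feature and the class label
#'
#' Plug-in MI estimate on labelled rows, with features discretized into
#' (up to) `bins` equal-frequency bins. Scores are non-negative nats.
#'
#' @param table feature table with a `label` column.
#' @param bins number of quantile bins.
#' @return named numeric vector, one score per schema feature.
#' @export
mutual_info_scores <- function(table, bins = 10) {
  lab <- table$label[!is.na(table$label)]
  if (length(unique(lab)) < 2) stop("need labelled rows from at least 2 classes")
  rows <- !is.na(table$label)
  out <- vapply(feature_schema(), function(cn) {
    x <- as.numeric(table[[cn]][rows])
    if (length(unique(x)) <= bins) {
      d <- factor(x)                       # discrete feature: use its values
    } else {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
      if (length(br) < 2) return(0)
      d <- cut(x, breaks = br, include.lowest = TRUE)
    }
    ct <- table(d, lab)
    p <- ct / sum(ct)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  }, 0)
  pmax(out, 0)
}

# ---- distance-weighted kNN --------------------------------------------------

wknn_fit <- function(X, y) {
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  mns <- colMeans(X)
  list(X = scale(X, mns, sds), y = factor(y), center = mns, scale = sds)
}

wknn_predict <- function(fit, Xnew, k = 5) {
  Xn <- scale(Xnew, fit$center, fit$scale)
  k <- min(k, nrow(fit$X))
  lev <- levels(fit$y)
  yi <- as.integer(fit$y)
  out <- character(nrow(Xn))
  tr2 <- rowSums(fit$X^2)
  for (i in seq_len(nrow(Xn))) {
    d2 <- tr2 - 2 * as.numeric(fit$X %*% Xn[i, ]) + sum(Xn[i, ]^2)
    nn <- order(d2)[seq_len(k)]
    w <- 1 / (sqrt(pmax(d2[nn], 0)) + 1e-9)
    sc <- tapply(w, yi[nn], sum)
    out[i] <- lev[as.integer(names(sc))[which.max(sc)]]
  }
  factor(out, levels = lev)
}

#' Pseudo-label unlabelled slices with distance-weighted kNN
#'
#' A k-nearest-neighbour classifier (Euclidean on internally standardized
#' non-coordinate features, inverse-distance weights) is fitted on the
#' labelled rows and assigns a pseudo-label to every unlabelled row.
#' Quality is reported on a stratified hold-out of the labelled rows.
#' Existing labels are never altered.
#'
#' @param table feature table with a `label` column (NA = unlabelled).
#' @param k number of neighbours.
#' @param holdout fraction of labelled rows held out for the quality report.
#' @param seed RNG seed for the hold-out split.
#' @param min_confidence optional threshold in (0, 1]: pseudo-labels whose
#'   weighted vote share falls below it are withheld (off by default,
#'   matching a single unconditional pass).
#' @return list with `table` (labels filled in, plus a `label_source`
#'   column), `report` and `confusion` (hold-out quality, Tables-3 layout).
#' @export
pseudo_label <- function(table, k = 5, holdout = 0.3, seed = 1L,
                         min_confidence = NULL) {
  lab_idx <- which(!is.na(table$label))
  if (!length(lab_idx)) stop("no labelled rows")
  cols <- metric_feature_cols()
  X <- as.matrix(table[cols])
  y <- table$label[lab_idx]
  if (length(unique(y)) < 2) stop("need labelled rows in at least 2 classes")

  # hold-out quality report
  rep_out <- NULL; conf_out <- NULL
  cnt <- table(y)
  if (all(cnt >= 2) && length(lab_idx) >= 8) {
    sp <- stratified_split(data.frame(label = y), ratio = 1 - holdout, seed = seed)
    fit_h <- wknn_fit(X[lab_idx[sp$train], , drop = FALSE], y[sp$train])
    pred_h <- wknn_predict(fit_h, X[lab_idx[sp$test], , drop = FALSE], k)
    cr <- classification_report(y[sp$test], as.character(pred_h))
    rep_out <- cr$report; conf_out <- cr$confusion
  }

  src <- ifelse(is.na(table$label), NA_character_, "labelled")
  un_idx <- which(is.na(table$label))
  if (length(un_idx)) {
    fit <- wknn_fit(X[lab_idx, , drop = FALSE], y)
    pred <- wknn_predict(fit, X[un_idx, , drop = FALSE], k)
    keep <- rep(TRUE, length(un_idx))
    if (!is.null(min_confidence)) {
      # recompute vote shares for the confidence gate
      keep <- vapply(seq_along(un_idx), function(i) {
        Xi <- scale(X[un_idx[i], , drop = FALSE], fit$center, fit$scale)
        d2 <- rowSums((fit$X - matrix(Xi, nrow(fit$X), ncol(fit$X), byrow = TRUE))^2)
        nn <- order(d2)[seq_len(min(k, nrow(fit$X)))]
        w <- 1 / (sqrt(pmax(d2[nn], 0)) + 1e-9)
        sc <- tapply(w, fit$y[nn], sum)
        max(sc, na.rm = TRUE) / sum(sc, na.rm = TRUE) >= min_confidence
      }, TRUE)
    }
    table$label[un_idx[keep]] <- as.character(pred)[keep]
    src[un_idx[keep]] <- "pseudo"
  }
  table$label_source <- src
  list(table = table, report = rep_out, confusion = conf_out)
}

# ---- split / train / evaluate ----------------------------------------------

#' Stratified train/test split
#'
#' Disjoint, exhaustive split preserving per-class proportions to within
#' one row.
#'
#' @param table data.frame with a `label` column (all rows labelled).
#' @param ratio training fraction.
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(table, ratio = 0.7, seed = 1L) {
  lab <- table$label
  if (any(is.na(lab))) stop("all rows must be labelled before splitting")
  if (any(table(lab) < 2)) stop("every class needs at least 2 rows")
  set.seed(derive_seed(seed, "split"))
  train <- integer(0)
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(ratio * length(idx))))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(table)), train))
}

default_gbc_grid <- function() expand.grid(
  eta = c(0.05, 0.1), nrounds = c(100, 300), max_depth = c(2, 3))

xgb_fit <- function(X, y_int, n_class, eta, nrounds, max_depth, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y_int)
  xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = n_class,
                  eta = eta, max_depth = max_depth, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

xgb_predict_class <- function(booster, X, classes) {
  pr <- predict(booster, xgboost::xgb.DMatrix(X))
  pr <- matrix(as.numeric(pr), nrow = nrow(X))
  colnames(pr) <- classes
  list(class = classes[max.col(pr, ties.method = "first")], prob = pr)
}

#' Train the gradient-boosted ensemble with a brute-force grid search
#'
#' Exhaustive search over the hyperparameter grid with stratified k-fold
#' cross-validation on the training table (coordinate features removed);
#' the best setting (ties broken toward fewer trees, then shallower depth)
#' is refitted on the full training set.
#'
#' @param train feature table with a complete `label` column (normalized,
#'   pseudo-labelled).
#' @param grid data.frame of `eta`, `nrounds`, `max_depth` combinations.
#' @param seed RNG seed (folds and booster).
#' @param nfold cross-validation folds.
#' @param norm optional fitted `wc_normalizer` stored for transfer.
#' @param knn_k the pseudo-labeller k recorded in the bundle.
#' @param cluster_seed seed recorded for per-survey cluster refits.
#' @return an object of class `wc_model`.
#' @export
train_ensemble <- function(train, grid = default_gbc_grid(), seed = 1L,
                           nfold = 5, norm = NULL, knn_k = 5,
                           cluster_seed = seed) {
  classes <- sort(unique(train$label))
  if (length(classes) < 2) stop("degenerate training set: a single class")
  cols <- metric_feature_cols()
  X <- as.matrix(train[cols])
  y <- factor(train$label, levels = classes)
  y_int <- as.integer(y) - 1L

  set.seed(derive_seed(seed, "cvfolds"))
  fold <- integer(nrow(X))
  for (cl in seq_along(classes)) {
    idx <- which(y_int == cl - 1L)
    fold[idx] <- sample(rep(seq_len(nfold), length.out = length(idx)))
  }

  cv_acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    acc <- numeric(nfold)
    for (f in seq_len(nfold)) {
      tr <- fold != f
      booster <- xgb_fit(X[tr, , drop = FALSE], y_int[tr], length(classes),
                         grid$eta[gi], grid$nrounds[gi], grid$max_depth[gi],
                         derive_seed(seed, sprintf("xgb%d_%d", gi, f)))
      pred <- xgb_predict_class(booster, X[!tr, , drop = FALSE], classes)$class
      acc[f] <- mean(pred == as.character(y)[!tr])
    }
    cv_acc[gi] <- mean(acc)
  }
  best <- order(-cv_acc, grid$nrounds, grid$max_depth, grid$eta)[1]
  booster <- xgb_fit(X, y_int, length(classes), grid$eta[best],
                     grid$nrounds[best], grid$max_depth[best],
                     derive_seed(seed, "xgbfinal"))
  m <- list(booster = booster, classes = classes,
            feature_cols = cols, schema = feature_schema(),
            excluded = coordinate_columns(), norm = norm,
            knn = list(k = knn_k, distance = "euclidean", weighted = TRUE),
            grid = grid, cv_accuracy = cv_acc, best = grid[best, ],
            cluster = list(k = 4, seed = cluster_seed),
            seed = seed, n_train = nrow(X))
  class(m) <- "wc_model"
  m
}

#' @export
print.wc_model <- function(x, ...) {
  cat("Water-column target classifier (gradient-boosted ensemble)\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  features: %d (coordinates excluded: %d)\n",
              length(x$feature_cols), length(x$excluded)))
  cat(sprintf("  best grid point: eta=%g, trees=%d, depth=%d (CV acc %.3f)\n",
              x$best$eta, x$best$nrounds, x$best$max_depth, max(x$cv_accuracy)))
  cat(sprintf("  trained on %d slices; seed %d\n", x$n_train, x$seed))
  invisible(x)
}

#' @export
summary.wc_model <- function(object, ...) {
  print(object)
  cat("\nGrid search (mean CV accuracy):\n")
  g <- object$grid
  g$cv_accuracy <- round(object$cv_accuracy, 4)
  print(g, row.names = FALSE)
  invisible(object)
}

#' Classification report in the standard per-class layout
#'
#' Per-class precision, recall, F1 and support, plus accuracy, macro and
#' support-weighted averages, and the confusion matrix (rows = truth).
#'
#' @param truth,pred character/factor vectors of equal length.
#' @param classes class set (defaults to the union observed).
#' @return list with `report` (data.frame), `confusion` (matrix),
#'   `accuracy`.
#' @export
classification_report <- function(truth, pred,
                                  classes = sort(unique(c(as.character(truth),
                                                          as.character(pred))))) {
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  cm <- table(truth = truth, pred = pred)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  acc <- sum(tp) / sum(cm)
  n <- sum(support)
  rep <- data.frame(
    Class = c(classes, "accuracy", "macro avg", "weighted avg"),
    Precision = c(prec, NA, mean(prec), sum(prec * support) / n),
    Recall = c(rec, NA, mean(rec), sum(rec * support) / n),
    `F1-Score` = c(f1, acc, mean(f1), sum(f1 * support) / n),
    Support = c(support, n, n, n),
    check.names = FALSE)
  list(report = rep, confusion = unclass(cm), accuracy = acc)
}

#' Evaluate a fitted model on a labelled test table
#'
#' @param model a `wc_model`.
#' @param test feature table with a complete `label` column, already on the
#'   model's normalized scale.
#' @return a [classification_report()] result.
#' @export
evaluate_model <- function(model, test) {
  pred <- xgb_predict_class(model$booster,
                            as.matrix(test[model$feature_cols]),
                            model$classes)$class
  classification_report(test$label, pred, classes = model$classes)
}

#' Predict classes for a (possibly unseen) survey feature table
#'
#' Validates the schema (order-insensitive; missing or extra metric columns
#' raise an error naming them), optionally refits the k-means cluster
#' feature for the new survey (stored k and seed), applies the stored
#' normalization, removes the coordinate features and predicts.
#'
#' @param object a `wc_model`.
#' @param newdata raw (un-normalized) feature table with the 24 schema
#'   columns.
#' @param recompute_cluster refit the cluster feature per survey (the
#'   stored centroids are site-specific).
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return factor of labels (with a `"prob"` matrix attribute), or the
#'   probability matrix when `type = "prob"`.
#' @export
predict.wc_model <- function(object, newdata, recompute_cluster = TRUE,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$schema, names(newdata))
  if (length(miss))
    stop("schema error; missing columns: ", paste(miss, collapse = ", "))
  if (recompute_cluster)
    newdata$Cluster <- cluster_feature(newdata, k = object$cluster$k,
                                       seed = object$cluster$seed)
  if (!is.null(object$norm)) newdata <- apply_normalizer(object$norm, newdata)
  res <- xgb_predict_class(object$booster,
                           as.matrix(newdata[object$feature_cols]),
                           object$classes)
  if (type == "prob") return(res$prob)
  out <- factor(res$class, levels = object$classes)
  attr(out, "prob") <- res$prob
  out
}

#' Majority-vote labels at the multi-ping object level
#'
#' @param labels per-slice labels.
#' @param object_id per-slice object ids.
#' @return named character vector, one label per object id.
#' @export
object_majority_labels <- function(labels, object_id) {
  vapply(split(as.character(labels), object_id),
         function(v) names(sort(table(v), decreasing = TRUE))[1], "")
}

#' Run the full semi-supervised classification stage
#'
#' Label extension within objects, normalization (fitted on all rows of the
#' training survey), pseudo-labelling, stratified 70:30 split, grid-searched
#' ensemble training and held-out evaluation.
#'
#' @param table raw feature table with partial `label` column and
#'   `object_id`.
#' @param seed RNG seed driving split, folds and boosters.
#' @param knn_k pseudo-labeller neighbours.
#' @param ratio training fraction of the stratified split.
#' @param grid hyperparameter grid for [train_ensemble()].
#' @return list: `model` (`wc_model`), `table` (normalized, fully
#'   labelled), `pseudo_report`, `eval_report`, `split`, `mi_scores`.
#' @export
train_wc_classifier <- function(table, seed = 1L, knn_k = 5, ratio = 0.7,
                                grid = default_gbc_grid()) {
  table <- extend_labels(table)
  nf <- normalize_features(table)
  mi <- mutual_info_scores(nf$table)
  ps <- pseudo_label(nf$table, k = knn_k, seed = seed)
  full <- ps$table
  sp <- stratified_split(full, ratio = ratio, seed = seed)
  model <- train_ensemble(full[sp$train, ], grid = grid, seed = seed,
                          norm = nf$norm, knn_k = knn_k, cluster_seed = seed)
  ev <- evaluate_model(model, full[sp$test, ])
  list(model = model, table = full, pseudo_report = ps,
       eval_report = ev, split = sp, mi_scores = mi)
}
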