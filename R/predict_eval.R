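# Classifiers, threshold metrics, tie-grouped ROC/PR curves, stratified
# k-fold cross-validation, external hold-out scoring, and candidate ranking.

#' Train a binary classifier on a pair dataset
#'
#' `gbdt` is a gradient-boosted tree ensemble (the classifier used
#' downstream); the baselines are Gaussian naive Bayes, L2 logistic
#' regression, k-nearest neighbours, and AdaBoost over decision stumps.
#'
#' @param dataset `pair_dataset` (or list with `features`, `labels`).
#' @param kind one of `"gbdt"`, `"naive_bayes"`, `"logistic"`, `"knn"`,
#'   `"adaboost"`.
#' @param params named list of overrides: gbdt `nrounds` (200), `max_depth`
#'   (6), `eta` (0.1); knn `k` (5); adaboost `nrounds` (100).
#' @param seed integer seed for kinds with randomness.
#' @return `hinmir_classifier` with a `$predict_prob(features)` closure.
#' @export
train_classifier <- function(dataset,
                             kind = c("gbdt", "naive_bayes", "logistic",
                                      "knn", "adaboost"),
                             params = list(), seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(dataset$features)
  y <- as.integer(dataset$labels)
  if (length(unique(y)) < 2L) stop("dataset contains a single class")
  set.seed(seed)
  predict_prob <- switch(
    kind,
    gbdt = {
      p <- utils::modifyList(list(nrounds = 200L, max_depth = 6L, eta = 0.1),
                             params)
      booster <- xgboost::xgboost(
        x, factor(y, levels = c(0L, 1L)),
        objective = "binary:logistic", nrounds = p$nrounds,
        max_depth = p$max_depth, learning_rate = p$eta,
        nthreads = 1L, seed = as.integer(seed), verbosity = 0L)
      function(newx) {
        as.numeric(predict(booster, as.matrix(newx), type = "response"))
      }
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x, factor(y, levels = c(0L, 1L)))
      function(newx) {
        as.numeric(predict(fit, as.data.frame(as.matrix(newx)),
                           type = "raw")[, "1"])
      }
    },
    logistic = {
      df <- data.frame(y = y, x)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      function(newx) {
        nd <- as.data.frame(as.matrix(newx))
        names(nd) <- names(df)[-1L]
        as.numeric(suppressWarnings(
          stats::predict(fit, newdata = nd, type = "response")))
      }
    },
    knn = {
      p <- utils::modifyList(list(k = 5L), params)
      train_x <- x; train_y <- factor(y, levels = c(0L, 1L))
      function(newx) {
        pr <- class::knn(train_x, as.matrix(newx), train_y, k = p$k,
                         prob = TRUE)
        vote <- attr(pr, "prob")
        ifelse(pr == "1", vote, 1 - vote)
      }
    },
    adaboost = {
      p <- utils::modifyList(list(nrounds = 100L), params)
      fit <- .adaboost_fit(x, y, nrounds = p$nrounds)
      function(newx) .adaboost_prob(fit, as.matrix(newx))
    })
  structure(list(kind = kind, predict_prob = predict_prob, seed = seed),
            class = "hinmir_classifier")
}

# AdaBoost.M1 with depth-1 rpart stumps; score mapped to [0,1] via the
# normalized weighted vote margin.
.adaboost_fit <- function(x, y, nrounds = 100L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1L, 1, -1)
  df <- data.frame(x)
  stumps <- list()
  alphas <- numeric(0)
  for (t in seq_len(nrounds)) {
    fit <- rpart::rpart(
      yf ~ ., data = cbind(df, yf = factor(yy, levels = c(-1, 1))),
      weights = w,
      control = rpart::rpart.control(maxdepth = 1L, cp = -1, minsplit = 2L,
                                     xval = 0L))
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5 && t > 1L) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, colnames = colnames(df))
}

.adaboost_prob <- function(fit, newx) {
  df <- data.frame(newx)
  names(df) <- fit$colnames
  margin <- rep(0, nrow(df))
  for (t in seq_along(fit$stumps)) {
    pred <- ifelse(predict(fit$stumps[[t]], df, type = "class") == "1", 1, -1)
    margin <- margin + fit$alphas[t] * pred
  }
  margin <- margin / sum(abs(fit$alphas))
  (margin + 1) / 2
}

#' Tie-grouped ROC and PR curves
#'
#' Predictions are sorted by decreasing score and equal scores are grouped
#' into a single operating point, so the curves are invariant to row order.
#'
#' @param labels binary vector; `scores` numeric vector.
#' @return list `roc` (data.frame `fpr`, `tpr`) and `pr` (data.frame
#'   `recall`, `precision`), each starting at the empty-prediction point.
#' @export
score_curves <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0L || N == 0L) stop("labels must contain both classes")
  o <- order(-scores)
  s <- scores[o]; l <- labels[o]
  grp_last <- which(diff(s) != 0)
  cut_idx <- c(grp_last, length(s)) # last index of each tie group
  tp <- cumsum(l)[cut_idx]
  fp <- cut_idx - tp
  roc <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
  pr <- data.frame(recall = c(0, tp / P),
                   precision = c(1, tp / (tp + fp)))
  list(roc = roc, pr = pr)
}

#' Six evaluation metrics at a probability threshold
#'
#' Recall, precision, accuracy and F1 are computed at `threshold`
#' (prediction positive when score >= threshold); AUC is the area under the
#' tie-grouped ROC curve by the trapezoid rule; AUPR is the step-wise
#' integral of precision over recall (no interpolation smoothing).
#' Precision and F1 are 0 when their denominators are 0.
#'
#' @param labels binary vector; `scores` probability vector;
#'   `threshold` default 0.5.
#' @return named list `recall`, `precision`, `accuracy`, `f1`, `auc`, `aupr`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  curves <- score_curves(labels, scores)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  recall <- tp / (tp + fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  accuracy <- (tp + tn) / length(labels)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  roc <- curves$roc
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  pr <- curves$pr
  aupr <- sum(diff(pr$recall) * utils::tail(pr$precision, -1))
  list(recall = recall, precision = precision, accuracy = accuracy,
       f1 = f1, auc = auc, aupr = aupr)
}

#' Stratified k-fold cross-validation of a pair classifier
#'
#' Pairs are split at the pair level, stratified by label. Fold assignment is
#' keyed on the pair ids (rows are sorted by id before the seeded
#' permutation), so shuffling the input row order does not change any pair's
#' fold. Reports per-fold metrics, their means, and per-fold ROC/PR
#' coordinates.
#'
#' @param dataset `pair_dataset`.
#' @param k number of folds (default 10).
#' @param kind,params classifier spec (see [train_classifier()]).
#' @param threshold probability threshold for the threshold metrics.
#' @param seed integer seed (fold permutation and classifier).
#' @return `cv_report`: `per_fold` (data.frame of six metrics), `means`,
#'   `roc_points`, `pr_points`, `fold_of_pair`, `config_hash`.
#' @export
kfold_cv <- function(dataset, k = 10L, kind = "gbdt", params = list(),
                     threshold = 0.5, seed = 1L) {
  stopifnot(inherits(dataset, "pair_dataset") ||
              all(c("features", "labels", "pairs") %in% names(dataset)))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  y <- as.integer(dataset$labels)
  if (min(table(y)) < k) stop("k exceeds the size of the smaller class")
  key <- paste(dataset$pairs$sm, dataset$pairs$mirna, sep = "\r")
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in c(0L, 1L)) {
    rows <- which(y == cls)
    rows <- rows[order(key[rows], method = "radix")]
    rows <- rows[sample.int(length(rows))]
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  per_fold <- vector("list", k)
  roc_points <- vector("list", k)
  pr_points <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    train_set <- list(features = dataset$features[tr, , drop = FALSE],
                      labels = y[tr])
    clf <- train_classifier(train_set, kind = kind, params = params,
                            seed = seed + f)
    scores <- clf$predict_prob(dataset$features[!tr, , drop = FALSE])
    per_fold[[f]] <- as.data.frame(
      compute_metrics(y[!tr], scores, threshold = threshold))
    curves <- score_curves(y[!tr], scores)
    roc_points[[f]] <- curves$roc
    pr_points[[f]] <- curves$pr
  }
  per_fold <- do.call(rbind, per_fold)
  means <- as.list(colMeans(per_fold))
  structure(list(per_fold = per_fold, means = means,
                 roc_points = roc_points, pr_points = pr_points,
                 fold_of_pair = stats::setNames(fold, key),
                 config_hash = rlang::hash(list(k = k, kind = kind,
                                                params = params,
                                                threshold = threshold,
                                                seed = seed))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d folds>\n", nrow(x$per_fold)))
  cat("mean metrics:\n")
  print(vapply(x$means, round, numeric(1), digits = 4))
  invisible(x)
}

#' Score an external hold-out set with a trained classifier
#'
#' Pairs with endpoints missing from the embedding are listed and skipped
#' with a warning; metrics are computed on the remainder.
#'
#' @param classifier `hinmir_classifier`.
#' @param embeddings numeric matrix with ids as rownames.
#' @param pairs data.frame `sm`, `mirna`; `labels` binary vector.
#' @param pair_fn pair-vector function name.
#' @param threshold probability threshold.
#' @return list `metrics` (six metrics), `scores`, `used` (logical vector),
#'   `skipped` (data.frame of skipped pairs).
#' @export
evaluate_external <- function(classifier, embeddings, pairs, labels,
                              pair_fn = "hadamard", threshold = 0.5) {
  stopifnot(inherits(classifier, "hinmir_classifier"), nrow(pairs) >= 1)
  sm <- as.character(pairs$sm)
  mi <- normalize_mirna_name(as.character(pairs$mirna))
  ok <- sm %in% rownames(embeddings) & mi %in% rownames(embeddings)
  skipped <- data.frame(sm = sm[!ok], mirna = mi[!ok],
                        stringsAsFactors = FALSE)
  if (any(!ok)) {
    warning(sprintf("skipping %d pair(s) with unembedded endpoints", sum(!ok)))
  }
  if (!any(ok)) stop("no external pair has embedded endpoints")
  feats <- .pair_features(embeddings, sm[ok], mi[ok], pair_fn)
  scores <- classifier$predict_prob(feats)
  list(metrics = compute_metrics(as.integer(labels)[ok], scores,
                                 threshold = threshold),
       scores = scores, used = ok, skipped = skipped)
}

#' Rank candidate miRNAs for one small molecule
#'
#' Scores every embedded candidate miRNA that is not already a known partner
#' of `sm_id` and returns the top of the list by descending probability,
#' ties broken by miRNA id.
#'
#' @param classifier `hinmir_classifier`.
#' @param embeddings numeric matrix with ids as rownames.
#' @param sm_id small-molecule id (must be embedded).
#' @param mirna_ids candidate miRNA ids.
#' @param known_positives miRNA ids already associated with `sm_id`.
#' @param pair_fn pair-vector function name.
#' @param top_n entries to keep (fewer if fewer candidates).
#' @return `ranked_candidates`: data.frame `rank`, `mirna_id`, `probability`.
#' @export
rank_candidates <- function(classifier, embeddings, sm_id, mirna_ids,
                            known_positives = character(0),
                            pair_fn = "hadamard", top_n = 50L) {
  if (!sm_id %in% rownames(embeddings)) {
    stop(sprintf("unknown small molecule '%s'", sm_id))
  }
  mirna_ids <- normalize_mirna_name(unique(as.character(mirna_ids)))
  known_positives <- if (length(known_positives)) {
    normalize_mirna_name(as.character(known_positives))
  } else character(0)
  cand <- setdiff(intersect(mirna_ids, rownames(embeddings)), known_positives)
  if (!length(cand)) {
    return(structure(data.frame(rank = integer(0), mirna_id = character(0),
                                probability = numeric(0)),
                     class = c("ranked_candidates", "data.frame")))
  }
  feats <- .pair_features(embeddings, rep(sm_id, length(cand)), cand, pair_fn)
  prob <- classifier$predict_prob(feats)
  o <- order(-prob, cand, method = "radix")
  n_keep <- min(as.integer(top_n), length(cand))
  out <- data.frame(rank = seq_len(n_keep), mirna_id = cand[o][seq_len(n_keep)],
                    probability = prob[o][seq_len(n_keep)],
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_candidates", "data.frame"))
}
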