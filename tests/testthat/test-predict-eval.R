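test_that("threshold metrics and curve areas match hand-worked cases", {
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1), 0.5)
  expect_equal(m[c("recall", "precision", "accuracy", "f1", "auc", "aupr")],
               list(recall = 1, precision = 1, accuracy = 1, f1 = 1,
                    auc = 1, aupr = 1))

  # 3 of 4 pos-neg pairs concordant
  m <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1), 0.5)
  expect_equal(m$auc, 0.75)

  # all-tied scores collapse to one operating point
  m <- compute_metrics(c(1, 0, 1, 0), rep(0.4, 4), 0.5)
  expect_equal(m$auc, 0.5)
  expect_equal(m$aupr, 0.5) # precision at the single point = prevalence

  expect_error(compute_metrics(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC and AUPR match brute-force oracles on random sets", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE)) # both classes present
    # duplicate scores with prob 1/2 to exercise tie grouping
    scores <- if (i %% 2 == 0) {
      sample(round(runif(5), 2), n, TRUE)
    } else {
      runif(n)
    }
    m <- compute_metrics(labels, scores, 0.5)
    expect_equal(m$auc, oracle_auc(labels, scores), tolerance = 1e-12)
    expect_equal(m$aupr, oracle_aupr(labels, scores), tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- sample(0:1, 80, TRUE)
  labels[1:2] <- 0:1
  scores <- runif(80)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(compute_metrics(labels, scores, 0.5)$auc, ref,
               tolerance = 1e-12)
})

test_that("each classifier kind yields calibrated-range scorers", {
  set.seed(11)
  x <- rbind(matrix(rnorm(60 * 3, -1.5), 60, 3),
             matrix(rnorm(60 * 3, 1.5), 60, 3))
  y <- rep(0:1, each = 60)
  ds <- list(features = x, labels = y,
             pairs = data.frame(sm = paste0("s", 1:120),
                                mirna = paste0("m", 1:120)))
  for (kind in c("gbdt", "naive_bayes", "logistic", "knn", "adaboost")) {
    clf <- train_classifier(ds, kind, seed = 4)
    p <- clf$predict_prob(x)
    expect_true(all(p >= 0 & p <= 1), info = kind)
    expect_gt(mean(p[y == 1]), mean(p[y == 0]))
  }
  # separable data: boosted trees fit the training set
  clf <- train_classifier(ds, "gbdt", seed = 4)
  expect_equal(as.integer(clf$predict_prob(x) >= 0.5), y)
  # 1-nearest-neighbour memorises the training labels
  clf <- train_classifier(ds, "knn", params = list(k = 1), seed = 4)
  expect_equal(as.integer(clf$predict_prob(x) >= 0.5), y)
  # gbdt is deterministic under its seed
  p1 <- train_classifier(ds, "gbdt", seed = 9)$predict_prob(x)
  p2 <- train_classifier(ds, "gbdt", seed = 9)$predict_prob(x)
  expect_identical(p1, p2)
  expect_error(train_classifier(list(features = x, labels = rep(1, 120)),
                                "gbdt"), "single class")
})

test_that("stratified folds are keyed on pair ids and average correctly", {
  set.seed(21)
  n <- 60
  x <- matrix(rnorm(n * 4), n, 4)
  y <- rep(0:1, each = n / 2)
  x[y == 1, 1] <- x[y == 1, 1] + 3
  ds <- structure(list(
    features = x, labels = y,
    pairs = data.frame(sm = paste0("DB", seq_len(n)),
                       mirna = paste0("hsa-mir-", seq_len(n)))),
    class = "pair_dataset")
  rep1 <- kfold_cv(ds, k = 5, kind = "logistic", seed = 3)
  expect_equal(nrow(rep1$per_fold), 5L)
  expect_true(all(as.matrix(rep1$per_fold) >= 0 &
                    as.matrix(rep1$per_fold) <= 1))
  expect_equal(unlist(rep1$means), colMeans(rep1$per_fold),
               tolerance = 1e-12)
  # per-class fold sizes balanced
  expect_true(all(abs(table(rep1$fold_of_pair[seq_len(n / 2)]) -
                        (n / 2) / 5) <= 1))

  # shuffling rows leaves each pair's fold unchanged
  perm <- sample(n)
  ds_shuf <- structure(list(features = x[perm, ], labels = y[perm],
                            pairs = ds$pairs[perm, ]),
                       class = "pair_dataset")
  rep2 <- kfold_cv(ds_shuf, k = 5, kind = "logistic", seed = 3)
  expect_equal(rep2$fold_of_pair[names(rep1$fold_of_pair)],
               rep1$fold_of_pair)
  expect_error(kfold_cv(ds, k = 40, kind = "logistic", seed = 1),
               "smaller class")

  # separable 4-sample set: both folds perfect
  tiny <- structure(list(
    features = matrix(c(-2, -2.1, 2, 2.1), 4, 1),
    labels = c(0L, 0L, 1L, 1L),
    pairs = data.frame(sm = paste0("s", 1:4), mirna = paste0("m", 1:4))),
    class = "pair_dataset")
  rep3 <- kfold_cv(tiny, k = 2, kind = "logistic", seed = 2)
  expect_equal(rep3$per_fold$auc, c(1, 1))
})

test_that("external scoring skips unembedded pairs and matches metrics", {
  set.seed(31)
  ids <- c(paste0("DB", 1:6), paste0("hsa-mir-", 1:8))
  emb <- matrix(rnorm(length(ids) * 5), length(ids), 5,
                dimnames = list(ids, NULL))
  pos <- data.frame(sm = rep(paste0("DB", 1:6), 2),
                    mirna = sample(paste0("hsa-mir-", 1:8), 12, TRUE))
  pos <- unique(pos)
  ds <- build_dataset(pos, paste0("DB", 1:6), paste0("hsa-mir-", 1:8), emb,
                      seed = 5)
  clf <- train_classifier(ds, "logistic", seed = 5)
  res <- evaluate_external(clf, emb, ds$pairs, ds$labels)
  direct <- compute_metrics(ds$labels, clf$predict_prob(ds$features), 0.5)
  expect_equal(res$metrics, direct, tolerance = 1e-12)

  with_unknown <- rbind(ds$pairs,
                        data.frame(sm = "DB1", mirna = "hsa-mir-99"))
  expect_warning(
    res2 <- evaluate_external(clf, emb, with_unknown, c(ds$labels, 1L)),
    "skipping 1")
  expect_equal(res2$skipped$mirna, "hsa-mir-99")
  expect_error(
    suppressWarnings(
      evaluate_external(clf, emb,
                        data.frame(sm = "nope", mirna = "hsa-mir-99"), 1L)))
})

test_that("candidate ranking excludes known partners and orders by score", {
  set.seed(41)
  ids <- c(paste0("DB", 1:4), paste0("hsa-mir-", 1:10))
  emb <- matrix(rnorm(length(ids) * 6), length(ids), 6,
                dimnames = list(ids, NULL))
  pos <- data.frame(sm = sample(paste0("DB", 1:4), 10, TRUE),
                    mirna = sample(paste0("hsa-mir-", 1:10), 10, TRUE))
  pos <- unique(pos)
  ds <- build_dataset(pos, paste0("DB", 1:4), paste0("hsa-mir-", 1:10), emb,
                      seed = 2)
  clf <- train_classifier(ds, "logistic", seed = 2)
  known <- pos$mirna[pos$sm == "DB1"]
  rk <- rank_candidates(clf, emb, "DB1", paste0("hsa-mir-", 1:10),
                        known_positives = known, top_n = 50)
  expect_equal(nrow(rk), 10L - length(known)) # top_n larger than pool
  expect_length(intersect(rk$mirna_id, known), 0L)
  expect_true(all(diff(rk$probability) <= 0))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  rk3 <- rank_candidates(clf, emb, "DB1", paste0("hsa-mir-", 1:10),
                         known_positives = known, top_n = 3)
  expect_equal(nrow(rk3), 3L)
  expect_equal(rk3$mirna_id, rk$mirna_id[1:3])
  expect_error(rank_candidates(clf, emb, "DB99", paste0("hsa-mir-", 1:10)),
               "unknown small molecule")
})

test_that("planted partners of a probe SM rank above median non-partners", {
  percentiles <- numeric(0)
  for (seed in 1:5) {
    d <- quick_synth(seed = seed, holdout_frac = 0.15)
    g <- assemble_heterograph(prepare_networks(d))
    emb <- hin2vec_train(g, quick_h2_cfg(seed = seed))$embeddings
    assoc <- g$edges[g$edges$type == "sm-mi", ]
    is_sm <- g$nodes$type[match(assoc$from, g$nodes$id)] == "SM"
    pos <- data.frame(sm = ifelse(is_sm, assoc$from, assoc$to),
                      mirna = ifelse(is_sm, assoc$to, assoc$from))
    mis <- sort(unique(pos$mirna))
    ds <- build_dataset(pos, sort(unique(pos$sm)), mis, emb, seed = seed)
    clf <- train_classifier(ds, "gbdt", seed = seed)
    held <- d$holdout[d$holdout$sm %in% pos$sm &
                        d$holdout$mirna %in% mis, ]
    probe_sm <- names(sort(table(held$sm), decreasing = TRUE))[1]
    known <- pos$mirna[pos$sm == probe_sm]
    rk <- rank_candidates(clf, emb, probe_sm, mis, known_positives = known,
                          top_n = length(mis))
    truths <- held$mirna[held$sm == probe_sm]
    truths <- intersect(truths, rk$mirna_id)
    if (!length(truths)) next
    pct <- 1 - (match(truths, rk$mirna_id) - 0.5) / nrow(rk)
    percentiles <- c(percentiles, mean(pct))
  }
  expect_gt(mean(percentiles), 0.5)
})
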