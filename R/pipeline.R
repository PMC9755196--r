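# End-to-end orchestration: similarity processing, graph assembly, the two
# embedders, feature merging, dataset construction and cross-validated
# evaluation; plus the ablation and dimension-grid protocols.

# derive per-stage seeds from one master seed, staying within 32-bit range
.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + i * 1000003) %% 2147483629)
}

#' Turn raw inputs into the six sub-networks of the heterogeneous graph
#'
#' Computes disease semantic similarity from the tree table, integrates the
#' two miRNA similarity sources by average ensemble, and converts the three
#' similarity matrices to weighted edges under the chosen rule.
#'
#' @param data `synth_data` or a list with the same fields (`sm_mi`,
#'   `sm_dis`, `mi_dis`, `sm_sm`, `mi_sim_a`, `mi_sim_b`, `tree_table`).
#' @param delta semantic contribution factor.
#' @param sim_rule,tau,k similarity-to-edge rule (see
#'   [similarity_to_edges()]).
#' @param tau_dis threshold for the disease network. DAG semantic
#'   similarity between non-nested diseases is bounded above by
#'   `1 - 1/DV < 0.5` when `delta = 0.5`, so the generic `tau` of 0.5 would
#'   always empty this network; 0.42 keeps pairs that share their deepest
#'   category.
#' @return named list of six edge lists keyed `sm_mi`, `mi_dis`, `sm_dis`,
#'   `mi_mi`, `sm_sm`, `dis_dis`.
#' @export
prepare_networks <- function(data, delta = 0.5, sim_rule = "threshold",
                             tau = 0.5, k = 5L, tau_dis = 0.42) {
  dis_sim <- disease_similarity_matrix(build_disease_dags(data$tree_table),
                                       semantic_params(delta))
  mi_sim <- integrate_mirna_similarity(data$mi_sim_a, data$mi_sim_b)
  list(
    sm_mi = data$sm_mi,
    mi_dis = data$mi_dis,
    sm_dis = data$sm_dis,
    mi_mi = similarity_to_edges(mi_sim, sim_rule, tau = tau, k = k),
    sm_sm = similarity_to_edges(data$sm_sm, sim_rule, tau = tau, k = k),
    dis_dis = similarity_to_edges(dis_sim, sim_rule, tau = tau_dis, k = k)
  )
}

#' Run the full association-prediction pipeline
#'
#' Assembles the heterogeneous graph, trains both embedders, merges their
#' embeddings, builds a balanced pair dataset from the SM-miRNA association
#' edges, and evaluates a classifier under stratified k-fold
#' cross-validation. `features = "merged"` uses the merged matrix;
#' `"hegan"`/`"hin2vec"` use a single embedder (the ablation arms).
#'
#' @param data input networks (see [prepare_networks()]).
#' @param mode `"HIN-3N"` or `"HIN-2N"`.
#' @param dim_hegan,dim_hin2vec embedding dimensions.
#' @param merge_method,pair_fn,classifier,k,threshold,ratio pipeline knobs.
#' @param features `"merged"`, `"hegan"` or `"hin2vec"`.
#' @param hegan_opts,hin2vec_opts named lists of config overrides.
#' @param delta,sim_rule,tau similarity-stage knobs.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list: `graph`, `emb_hegan`, `emb_hin2vec`, `embeddings` (the
#'   feature matrix used), `dataset`, `cv` (`cv_report`), `positives`,
#'   `sm_ids`, `mirna_ids`.
#' @export
run_pipeline <- function(data, mode = "HIN-3N", dim_hegan = 32L,
                         dim_hin2vec = 32L, merge_method = "connection",
                         pair_fn = "hadamard", classifier = "gbdt",
                         features = c("merged", "hegan", "hin2vec"),
                         k = 10L, threshold = 0.5, ratio = 1.0,
                         hegan_opts = list(), hin2vec_opts = list(),
                         delta = 0.5, sim_rule = "threshold", tau = 0.5,
                         seed = 1L) {
  features <- match.arg(features)
  networks <- prepare_networks(data, delta = delta, sim_rule = sim_rule,
                               tau = tau)
  graph <- assemble_heterograph(networks, mode = mode)
  he_cfg <- do.call(hegan_config, utils::modifyList(
    list(dim = dim_hegan, seed = .derive_seed(seed, 1L)), hegan_opts))
  h2_cfg <- do.call(hin2vec_config, utils::modifyList(
    list(dim = dim_hin2vec, seed = .derive_seed(seed, 2L)), hin2vec_opts))
  emb_hegan <- NULL
  emb_hin2vec <- NULL
  if (features %in% c("merged", "hegan")) {
    emb_hegan <- hegan_train(graph, he_cfg)$embeddings
  }
  if (features %in% c("merged", "hin2vec")) {
    emb_hin2vec <- hin2vec_train(graph, h2_cfg)$embeddings
  }
  emb <- switch(features,
                merged = merge_embeddings(emb_hegan, emb_hin2vec,
                                          method = merge_method),
                hegan = emb_hegan,
                hin2vec = emb_hin2vec)
  assoc <- graph$edges[graph$edges$type == "sm-mi", , drop = FALSE]
  sm_is_from <- graph$nodes$type[match(assoc$from, graph$nodes$id)] == "SM"
  positives <- data.frame(
    sm = ifelse(sm_is_from, assoc$from, assoc$to),
    mirna = ifelse(sm_is_from, assoc$to, assoc$from),
    stringsAsFactors = FALSE)
  sm_ids <- sort(unique(positives$sm), method = "radix")
  mirna_ids <- sort(unique(positives$mirna), method = "radix")
  dataset <- build_dataset(positives, sm_ids, mirna_ids, emb,
                           pair_fn = pair_fn, ratio = ratio,
                           seed = .derive_seed(seed, 3L))
  cv <- kfold_cv(dataset, k = k, kind = classifier, threshold = threshold,
                 seed = .derive_seed(seed, 4L))
  list(graph = graph, emb_hegan = emb_hegan, emb_hin2vec = emb_hin2vec,
       embeddings = emb, dataset = dataset, cv = cv, positives = positives,
       sm_ids = sm_ids, mirna_ids = mirna_ids, seed = seed)
}

#' Feature-source ablation: each embedder alone versus merged
#'
#' Runs the pipeline three times on shared inputs with identical seeds,
#' differing only in the feature source.
#'
#' @param data input networks; `...` passed to [run_pipeline()].
#' @return list of three `cv_report`s: `hegan`, `hin2vec`, `merged`.
#' @export
ablation_features <- function(data, ...) {
  args <- list(...)
  run <- function(src) {
    do.call(run_pipeline, c(list(data = data, features = src), args))$cv
  }
  list(hegan = run("hegan"), hin2vec = run("hin2vec"),
       merged = run("merged"))
}

#' Node-type ablation: two-type versus three-type graph
#'
#' @param data input networks; `...` passed to [run_pipeline()].
#' @return list of two `cv_report`s: `hin2n`, `hin3n`.
#' @export
ablation_modes <- function(data, ...) {
  args <- list(...)
  list(hin2n = do.call(run_pipeline,
                       c(list(data = data, mode = "HIN-2N"), args))$cv,
       hin3n = do.call(run_pipeline,
                       c(list(data = data, mode = "HIN-3N"), args))$cv)
}

#' Embedding-dimension grid
#'
#' Cross-validates every combination of the two embedders' dimensions and
#' tabulates the six mean metrics per combination.
#'
#' @param data input networks.
#' @param dims_hegan,dims_hin2vec dimension grids (default 16/32/64/128).
#' @param ... passed to [run_pipeline()].
#' @return data.frame: `combination`, `dim_hegan`, `dim_hin2vec` and the six
#'   mean metrics.
#' @export
dimension_grid <- function(data, dims_hegan = c(16L, 32L, 64L, 128L),
                           dims_hin2vec = c(16L, 32L, 64L, 128L), ...) {
  args <- list(...)
  rows <- list()
  for (dh in dims_hegan) {
    for (d2 in dims_hin2vec) {
      cv <- do.call(run_pipeline,
                    c(list(data = data, dim_hegan = dh, dim_hin2vec = d2),
                      args))$cv
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(combination = sprintf("HeGAN%dHIN2V%d", dh, d2),
                   dim_hegan = dh, dim_hin2vec = d2),
        as.data.frame(cv$means))
    }
  }
  do.call(rbind, rows)
}
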