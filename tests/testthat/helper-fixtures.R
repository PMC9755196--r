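# Shared fixtures: toy graphs, random DAGs, and brute-force oracles.

# small fully-specified heterogeneous network
toy_networks <- function() {
  list(
    sm_mi = data.frame(from = c("DB1", "DB1", "DB2"),
                       to = c("hsa-miR-21-5p", "hsa-mir-155", "hsa-mir-155"),
                       weight = 1),
    mi_dis = data.frame(from = c("hsa-mir-21", "hsa-mir-155"),
                        to = c("melanoma", "leukemia"), weight = 1),
    sm_dis = data.frame(from = "DB2", to = "melanoma", weight = 1),
    mi_mi = data.frame(from = "hsa-mir-21", to = "hsa-mir-155",
                       weight = 0.8),
    sm_sm = data.frame(from = "DB1", to = "DB2", weight = 0.6),
    dis_dis = data.frame(from = "melanoma", to = "leukemia", weight = 0.55)
  )
}

toy_graph <- function(mode = "HIN-3N") {
  assemble_heterograph(toy_networks(), mode = mode)
}

# random ancestor DAG: node 1 is the disease, every later node gets 1-3
# children among earlier nodes, so the graph is acyclic and every node
# reaches the disease
random_dag <- function(n_nodes, seed) {
  set.seed(seed)
  ids <- paste0("t", seq_len(n_nodes))
  parent <- character(0)
  child <- character(0)
  for (i in seq_len(n_nodes)[-1]) {
    kids <- sample.int(i - 1L, size = min(i - 1L, sample(1:3, 1L)))
    parent <- c(parent, rep(ids[i], length(kids)))
    child <- c(child, ids[kids])
  }
  structure(list(disease_id = ids[1L], nodes = ids,
                 edges = data.frame(parent = parent, child = child,
                                    stringsAsFactors = FALSE)),
            class = "disease_dag")
}

# brute-force contribution oracle: enumerate every directed path from t down
# to the disease and take the max of delta^length over paths
oracle_contributions <- function(dag, delta) {
  d <- dag$disease_id
  paths_max <- function(node, depth) {
    if (node == d) return(delta^depth)
    kids <- dag$edges$child[dag$edges$parent == node]
    if (!length(kids)) return(-Inf)
    max(vapply(kids, paths_max, numeric(1), depth = depth + 1L))
  }
  vapply(stats::setNames(dag$nodes, dag$nodes), paths_max, numeric(1),
         depth = 0L)
}

# pair-counting AUC oracle: concordant pairs + half ties over all pos x neg
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# step-integration AUPR oracle: walk distinct thresholds from high to low
oracle_aupr <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  area <- 0
  prev_rec <- 0
  for (s in thr) {
    sel <- scores >= s
    tp <- sum(labels[sel] == 1)
    rec <- tp / P
    prec <- tp / sum(sel)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# random tiny relation-network model for gradient checks
random_hin2vec_model <- function(seed, dim = NULL) {
  set.seed(seed)
  d <- if (is.null(dim)) sample(1:5, 1L) else dim
  n_nodes <- sample(2:6, 1L)
  n_rel <- sample(1:4, 1L)
  structure(list(
    W_M = matrix(rnorm(n_nodes * d), n_nodes, d),
    W_N = matrix(rnorm(n_nodes * d), n_nodes, d),
    W_R = matrix(rnorm(n_rel * d), n_rel, d),
    node_ids = paste0("n", seq_len(n_nodes)),
    relations = paste0("r", seq_len(n_rel)),
    dim = d), class = "hin2vec_model")
}

central_diff <- function(f, x, h = 1e-5) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# small synthetic dataset used by the quicker pipeline tests
quick_synth <- function(seed = 1L, holdout_frac = 0) {
  synth_generate(synth_config(n_sm = 30L, n_mirna = 45L, n_disease = 16L,
                              assoc_density = 0.1, holdout_frac = holdout_frac,
                              seed = seed))
}

quick_h2_cfg <- function(seed = 1L, dim = 16L) {
  hin2vec_config(dim = dim, walks_per_node = 5L, walk_length = 30L,
                 epochs = 3L, seed = seed)
}
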