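# Relation-typed random-walk embedding learner: uniform random walks over the
# typed graph, <m, n, relation, label> training samples with type-preserving
# negative sampling, and a three-layer logistic network whose hidden layer is
# the Hadamard product of the two node vectors and a squashed relation vector.

#' Configuration for the relation-typed random-walk learner
#'
#' @param dim embedding dimension.
#' @param walks_per_node random walks started from every node.
#' @param walk_length nodes per walk.
#' @param window maximum hop distance (meta-path length) between sample pairs.
#' @param neg_per_pos negatives drawn per positive sample.
#' @param epochs passes over the training samples.
#' @param learning_rate initial SGD step size (decays linearly to ~0).
#' @param tie_weights share one node matrix for both node roles.
#' @param seed integer seed controlling walks, sampling and initialization.
#' @return `hin2vec_config` list.
#' @export
hin2vec_config <- function(dim = 32L, walks_per_node = 10L, walk_length = 80L,
                           window = 2L, neg_per_pos = 5L, epochs = 5L,
                           learning_rate = 0.025, tie_weights = FALSE,
                           seed = 1L) {
  stopifnot(dim >= 1, walks_per_node >= 1, walk_length >= 1, window >= 1,
            neg_per_pos >= 0, epochs >= 0, learning_rate > 0)
  structure(list(dim = as.integer(dim),
                 walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 window = as.integer(window),
                 neg_per_pos = as.integer(neg_per_pos),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 tie_weights = isTRUE(tie_weights),
                 seed = as.integer(seed)),
            class = "hin2vec_config")
}

#' Generate uniform random walks over the heterogeneous graph
#'
#' Every node starts `walks_per_node` walks; each step moves to a uniformly
#' random neighbour regardless of node or edge type. Nodes without
#' neighbours yield singleton walks. Deterministic under `seed`.
#'
#' @param graph `hetero_graph`.
#' @param walks_per_node,walk_length,seed see [hin2vec_config()].
#' @return list of character vectors of node ids.
#' @export
generate_walks <- function(graph, walks_per_node = 10L, walk_length = 80L,
                           seed = 1L) {
  stopifnot(inherits(graph, "hetero_graph"), nrow(graph$nodes) > 0)
  if (walk_length < 1) stop("walk_length must be >= 1")
  if (walks_per_node < 1) stop("walks_per_node must be >= 1")
  set.seed(seed)
  ids <- graph$nodes$id
  n <- length(ids)
  adj <- graph$adj
  deg <- lengths(adj)
  starts <- rep(seq_len(n), times = walks_per_node)
  n_walks <- length(starts)
  W <- matrix(NA_integer_, n_walks, walk_length)
  W[, 1L] <- starts
  alive <- deg[starts] > 0L
  cur <- starts
  if (walk_length > 1L) {
    for (step in 2:walk_length) {
      live <- which(alive)
      if (!length(live)) break
      groups <- split(live, cur[live])
      for (k in names(groups)) {
        node <- as.integer(k)
        nb <- adj[[node]]
        slots <- groups[[k]]
        cur[slots] <- nb[sample.int(length(nb), length(slots), replace = TRUE)]
      }
      W[live, step] <- cur[live]
    }
  }
  lapply(seq_len(n_walks), function(i) {
    row <- W[i, ]
    ids[row[!is.na(row)]]
  })
}

# edge-type index lookup by (node-type idx, node-type idx)
.edge_type_lookup <- function() {
  lk <- matrix(NA_integer_, 3L, 3L)
  for (a in 1:3) for (b in 1:3) {
    lk[a, b] <- match(edge_type_for(NODE_TYPES[a], NODE_TYPES[b]), EDGE_TYPES)
  }
  lk
}

#' Extract relation-typed training samples from walks
#'
#' For every ordered pair of nodes at most `window` hops apart inside a walk,
#' a positive sample is emitted whose relation is the sequence of edge types
#' traversed between them (edge types are implied by the endpoint node
#' types). Each positive spawns `neg_per_pos` negatives by replacing the
#' second node with a uniformly random node of the same node type, resampling
#' when the corrupted triple coincides with an observed positive.
#'
#' @param walks list of node-id walks from [generate_walks()].
#' @param graph `hetero_graph`.
#' @param window,neg_per_pos,seed see [hin2vec_config()].
#' @return `hin2vec_samples`: list with integer columns `m_idx`, `n_idx`,
#'   `r_idx`, binary `label`, plus `node_ids` and `relations` lookup tables.
#' @export
extract_samples <- function(walks, graph, window = 2L, neg_per_pos = 5L,
                            seed = 1L) {
  stopifnot(inherits(graph, "hetero_graph"), window >= 1, neg_per_pos >= 0)
  set.seed(seed)
  ids <- graph$nodes$id
  tyi <- graph$node_type_idx
  lk <- .edge_type_lookup()
  flat <- match(unlist(walks), ids)
  wid <- rep(seq_along(walks), lengths(walks))
  n_flat <- length(flat)
  # edge type of the step t -> t+1 (NA across walk boundaries)
  if (n_flat > 1L) {
    same <- wid[-n_flat] == wid[-1L]
    step_et <- ifelse(same, lk[cbind(tyi[flat[-n_flat]], tyi[flat[-1L]])],
                      NA_integer_)
  } else {
    step_et <- integer(0)
  }
  et_names <- EDGE_TYPES
  m_pos <- integer(0); n_pos <- integer(0); rel_pos <- character(0)
  for (o in seq_len(window)) {
    if (n_flat <= o) break
    t0 <- seq_len(n_flat - o)
    ok <- wid[t0] == wid[t0 + o]
    t0 <- t0[ok]
    if (!length(t0)) next
    rel <- et_names[step_et[t0]]
    if (o > 1L) {
      for (j in seq_len(o - 1L)) {
        rel <- paste(rel, et_names[step_et[t0 + j]], sep = ">")
      }
    }
    m_pos <- c(m_pos, flat[t0])
    n_pos <- c(n_pos, flat[t0 + o])
    rel_pos <- c(rel_pos, rel)
  }
  relations <- sort(unique(rel_pos), method = "radix")
  r_pos <- match(rel_pos, relations)
  n_nodes <- length(ids)
  n_rel <- length(relations)
  pos_key <- (as.numeric(m_pos) - 1) * n_nodes * n_rel +
    (as.numeric(n_pos) - 1) * n_rel + r_pos
  # negatives: corrupt n, type-preserving, avoiding observed positives
  nodes_by_type <- lapply(1:3, function(t) which(tyi == t))
  np <- length(m_pos)
  if (neg_per_pos > 0L && np > 0L) {
    m_neg <- rep(m_pos, each = neg_per_pos)
    r_neg <- rep(r_pos, each = neg_per_pos)
    n_type <- rep(tyi[n_pos], each = neg_per_pos)
    n_neg <- integer(length(m_neg))
    todo <- seq_along(m_neg)
    for (iter in 1:100) {
      if (!length(todo)) break
      for (t in 1:3) {
        sel <- todo[n_type[todo] == t]
        if (!length(sel)) next
        pool <- nodes_by_type[[t]]
        n_neg[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
      }
      key <- (as.numeric(m_neg[todo]) - 1) * n_nodes * n_rel +
        (as.numeric(n_neg[todo]) - 1) * n_rel + r_neg[todo]
      todo <- todo[key %in% pos_key]
    }
  } else {
    m_neg <- integer(0); n_neg <- integer(0); r_neg <- integer(0)
  }
  structure(list(
    m_idx = c(m_pos, m_neg),
    n_idx = c(n_pos, n_neg),
    r_idx = c(r_pos, r_neg),
    label = c(rep(1L, np), rep(0L, length(m_neg))),
    node_ids = ids,
    relations = relations
  ), class = "hin2vec_samples")
}

.init_emb <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -0.5 / nc, 0.5 / nc), nr, nc)
}

#' Probability that relation r holds between nodes m and n
#'
#' `sigmoid( sum_k W_M[m]_k * W_N[n]_k * f01(W_R[r])_k )` where `f01` is the
#' elementwise logistic squashing that keeps relation-vector entries in
#' \[0,1\]. No bias term is used.
#'
#' @param model `hin2vec_model`.
#' @param m,n node ids or integer row indices.
#' @param r relation string or integer index.
#' @return probability strictly inside (0, 1).
#' @export
hin2vec_forward <- function(model, m, n, r) {
  i <- .resolve_idx(m, model$node_ids, "node")
  j <- .resolve_idx(n, model$node_ids, "node")
  k <- .resolve_idx(r, model$relations, "relation")
  s <- sum(model$W_M[i, ] * model$W_N[j, ] * stats::plogis(model$W_R[k, ]))
  stats::plogis(s)
}

.resolve_idx <- function(x, table, what) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (x < 1L || x > length(table)) stop(sprintf("unknown %s index %d", what, x))
    return(x)
  }
  i <- match(x, table)
  if (is.na(i)) stop(sprintf("unknown %s '%s'", what, x))
  i
}

#' Analytic per-sample gradients of the log-objective
#'
#' Gradient of `L*log P + (1-L)*log(1-P)` with respect to the two node rows
#' and the relation row; SGD ascends these.
#'
#' @param model `hin2vec_model`; `m,n,r` as in [hin2vec_forward()];
#'   `label` 0 or 1.
#' @return list `d_m`, `d_n`, `d_r` (numeric vectors of length `dim`).
#' @export
hin2vec_gradients <- function(model, m, n, r, label) {
  i <- .resolve_idx(m, model$node_ids, "node")
  j <- .resolve_idx(n, model$node_ids, "node")
  k <- .resolve_idx(r, model$relations, "relation")
  a <- model$W_M[i, ]; b <- model$W_N[j, ]
  cr <- stats::plogis(model$W_R[k, ])
  p <- stats::plogis(sum(a * b * cr))
  g <- label - p
  list(d_m = g * b * cr,
       d_n = g * a * cr,
       d_r = g * a * b * cr * (1 - cr))
}

#' Per-sample log-objective value
#' @inheritParams hin2vec_gradients
#' @return `label*log(P) + (1-label)*log(1-P)`.
#' @export
hin2vec_log_objective <- function(model, m, n, r, label) {
  p <- hin2vec_forward(model, m, n, r)
  if (label == 1) log(p) else log(1 - p)
}

#' Train the relation-typed random-walk embedder
#'
#' Runs walk generation, sample extraction and stochastic gradient ascent on
#' the per-sample log-objective. The node embedding is the start-role matrix
#' `W_M`. Deterministic under the config seed.
#'
#' @param graph `hetero_graph`.
#' @param config `hin2vec_config`.
#' @return `hin2vec_model`: `embeddings` (matrix, rownames = node ids),
#'   weight matrices `W_M`, `W_N`, `W_R`, `relations`, `node_ids`,
#'   `loss_per_epoch`, `config`.
#' @export
hin2vec_train <- function(graph, config = hin2vec_config()) {
  stopifnot(inherits(graph, "hetero_graph"), nrow(graph$nodes) > 0,
            inherits(config, "hin2vec_config"))
  walks <- generate_walks(graph, config$walks_per_node, config$walk_length,
                          seed = config$seed)
  samples <- extract_samples(walks, graph, window = config$window,
                             neg_per_pos = config$neg_per_pos,
                             seed = config$seed + 1L)
  hin2vec_fit(samples, config)
}

#' Fit the three-layer logistic network on prepared samples
#'
#' @param samples `hin2vec_samples` from [extract_samples()].
#' @param config `hin2vec_config`.
#' @return `hin2vec_model` (see [hin2vec_train()]).
#' @export
hin2vec_fit <- function(samples, config = hin2vec_config()) {
  stopifnot(inherits(samples, "hin2vec_samples"))
  d <- config$dim
  n_nodes <- length(samples$node_ids)
  n_rel <- length(samples$relations)
  set.seed(config$seed + 2L)
  W_M <- .init_emb(n_nodes, d)
  W_N <- if (config$tie_weights) W_M else .init_emb(n_nodes, d)
  W_R <- .init_emb(max(n_rel, 1L), d)
  fit <- hin2vec_sgd_cpp(W_M, W_N, W_R,
                         samples$m_idx, samples$n_idx, samples$r_idx,
                         samples$label, config$epochs, config$learning_rate,
                         config$seed + 3L, config$tie_weights)
  emb <- fit$W_M
  rownames(emb) <- samples$node_ids
  rownames(fit$W_M) <- rownames(fit$W_N) <- samples$node_ids
  rownames(fit$W_R) <- if (n_rel) samples$relations else NULL
  if (any(!is.finite(emb))) stop("non-finite embedding values after training")
  structure(list(embeddings = emb, W_M = fit$W_M, W_N = fit$W_N,
                 W_R = fit$W_R, node_ids = samples$node_ids,
                 relations = samples$relations,
                 loss_per_epoch = as.numeric(fit$loss),
                 dim = d, config = config),
            class = "hin2vec_model")
}
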