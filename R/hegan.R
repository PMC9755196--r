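# Adversarial heterogeneous-network embedding: a relation-aware bilinear
# discriminator against a generalized generator that fabricates neighbour
# embeddings which need not correspond to existing nodes.

#' Configuration for the adversarial embedder
#'
#' @param dim embedding dimension.
#' @param epochs alternating training epochs.
#' @param disc_steps,gen_steps minibatches per epoch for discriminator and
#'   generator (the epoch's shuffled edge pass is split into this many
#'   batches).
#' @param lr_d,lr_g learning rates.
#' @param noise_sigma standard deviation of the Gaussian noise injected into
#'   generated neighbour embeddings; 0 makes the generator deterministic.
#' @param samples_per_edge passes over the edge list per epoch.
#' @param seed integer seed.
#' @return `hegan_config` list.
#' @export
hegan_config <- function(dim = 32L, epochs = 20L, disc_steps = 5L,
                         gen_steps = 5L, lr_d = 0.05, lr_g = 0.05,
                         noise_sigma = 0.1, samples_per_edge = 1L,
                         seed = 1L) {
  stopifnot(dim >= 1, epochs >= 0, disc_steps >= 1, gen_steps >= 1,
            lr_d > 0, lr_g > 0, noise_sigma >= 0, samples_per_edge >= 1)
  structure(list(dim = as.integer(dim), epochs = as.integer(epochs),
                 disc_steps = as.integer(disc_steps),
                 gen_steps = as.integer(gen_steps),
                 lr_d = lr_d, lr_g = lr_g, noise_sigma = noise_sigma,
                 samples_per_edge = as.integer(samples_per_edge),
                 seed = as.integer(seed)),
            class = "hegan_config")
}

#' Initialize an adversarial embedding model for a graph
#'
#' Discriminator and generator each hold one embedding row per node and one
#' square relation matrix per edge type present in the graph. Embeddings
#' start from small Gaussian values, relation matrices from the identity.
#'
#' @param graph `hetero_graph`.
#' @param config `hegan_config`.
#' @return `hegan_model`.
#' @export
hegan_init <- function(graph, config = hegan_config()) {
  stopifnot(inherits(graph, "hetero_graph"), nrow(graph$nodes) > 0)
  d <- config$dim
  ids <- graph$nodes$id
  rels <- sort(unique(graph$edges$type), method = "radix")
  set.seed(config$seed)
  n <- length(ids)
  mk_emb <- function() {
    m <- matrix(stats::rnorm(n * d, 0, 0.1), n, d)
    rownames(m) <- ids
    m
  }
  mk_rel <- function() {
    out <- lapply(rels, function(r) diag(1, d))
    names(out) <- rels
    out
  }
  structure(list(dim = d, node_ids = ids, relations = rels,
                 disc_node_emb = mk_emb(), disc_rel = mk_rel(),
                 gen_node_emb = mk_emb(), gen_rel = mk_rel(),
                 noise_sigma = config$noise_sigma, config = config,
                 disc_loss_per_epoch = numeric(0),
                 gen_loss_per_epoch = numeric(0)),
            class = "hegan_model")
}

#' Discriminator probability that relation r links node u to an embedding
#'
#' `sigmoid( e_u^T M_r v )` with `e_u` the discriminator embedding of `u` and
#' `M_r` its relation matrix.
#'
#' @param model `hegan_model`.
#' @param u node id (or integer index).
#' @param v_emb numeric vector of length `dim` (a real node's discriminator
#'   embedding or a generated one).
#' @param r edge type.
#' @return probability strictly inside (0, 1).
#' @export
discriminator_score <- function(model, u, v_emb, r) {
  i <- .resolve_idx(u, model$node_ids, "node")
  if (length(v_emb) != model$dim) {
    stop(sprintf("v_emb has length %d, expected %d", length(v_emb), model$dim))
  }
  M <- model$disc_rel[[r]]
  if (is.null(M)) stop(sprintf("unknown relation '%s'", r))
  stats::plogis(drop(model$disc_node_emb[i, ] %*% M %*% v_emb))
}

#' Generate a fake neighbour embedding for a node under a relation
#'
#' The generator maps its own embedding of `u` through the relation matrix,
#' adds Gaussian noise of standard deviation `noise_sigma`, and squashes the
#' result elementwise with tanh. With `noise_sigma = 0` the output is
#' deterministic; otherwise it is deterministic under `seed`.
#'
#' @param model `hegan_model`; `u` node id; `r` edge type; `seed` integer.
#' @return numeric vector of length `dim`.
#' @export
generator_sample <- function(model, u, r, seed = 1L) {
  i <- .resolve_idx(u, model$node_ids, "node")
  M <- model$gen_rel[[r]]
  if (is.null(M)) stop(sprintf("unknown relation '%s'", r))
  set.seed(seed)
  z <- drop(model$gen_node_emb[i, ] %*% M)
  if (model$noise_sigma > 0) {
    z <- z + stats::rnorm(model$dim, 0, model$noise_sigma)
  }
  tanh(z)
}

#' Analytic gradients of the discriminator's per-sample loss
#'
#' The per-sample loss is binary cross-entropy of
#' `D = sigmoid(e_u^T M_r v)` against `label`; gradients are with respect to
#' `e_u`, `M_r` and `v`.
#'
#' @param model `hegan_model`; `u` node id; `v_emb` numeric vector;
#'   `r` edge type; `label` 0 or 1.
#' @return list `loss`, `d_eu`, `d_M`, `d_v`.
#' @export
hegan_disc_gradients <- function(model, u, v_emb, r, label) {
  i <- .resolve_idx(u, model$node_ids, "node")
  e_u <- model$disc_node_emb[i, ]
  M <- model$disc_rel[[r]]
  s <- drop(e_u %*% M %*% v_emb)
  p <- stats::plogis(s)
  g <- p - label # d loss / d s
  loss <- if (label == 1) -log(p) else -log(1 - p)
  list(loss = loss,
       d_eu = g * drop(M %*% v_emb),
       d_M = g * tcrossprod(e_u, v_emb),
       d_v = g * drop(crossprod(M, e_u)))
}

#' Discriminator binary cross-entropy on a fixed probe batch
#'
#' @param model `hegan_model`.
#' @param probe list with `u` (node ids), `v` (node ids), `r` (edge types),
#'   `label` (0/1); the v endpoint is looked up in the discriminator
#'   embedding.
#' @return mean loss.
#' @export
hegan_probe_loss <- function(model, probe) {
  n <- length(probe$u)
  losses <- vapply(seq_len(n), function(k) {
    j <- .resolve_idx(probe$v[[k]], model$node_ids, "node")
    p <- discriminator_score(model, probe$u[[k]],
                             model$disc_node_emb[j, ], probe$r[[k]])
    if (probe$label[[k]] == 1) -log(p) else -log(1 - p)
  }, numeric(1))
  mean(losses)
}

#' Train the adversarial embedder
#'
#' Alternates per epoch between discriminator updates — ascending the
#' likelihood of (i) real (u, v, r) triples as true, (ii) real pairs with a
#' corrupted relation as false, (iii) generator fakes as false — and
#' generator updates ascending the discriminator score of its fakes. Returns
#' the model whose discriminator node embeddings are used downstream.
#' Deterministic under the config seed.
#'
#' @param graph `hetero_graph`.
#' @param config `hegan_config`.
#' @return `hegan_model` with `embeddings` (discriminator node matrix) and
#'   per-epoch loss traces.
#' @export
hegan_train <- function(graph, config = hegan_config()) {
  model <- hegan_init(graph, config)
  ids <- model$node_ids
  eu <- match(graph$edges$from, ids)
  ev <- match(graph$edges$to, ids)
  er <- match(graph$edges$type, model$relations)
  rel_mats_d <- array(unlist(model$disc_rel), dim = c(config$dim, config$dim,
                                                      length(model$relations)))
  rel_mats_g <- array(unlist(model$gen_rel), dim = dim(rel_mats_d))
  fit <- hegan_train_cpp(model$disc_node_emb, rel_mats_d,
                         model$gen_node_emb, rel_mats_g,
                         eu, ev, er, length(model$relations),
                         config$epochs, config$disc_steps, config$gen_steps,
                         config$lr_d, config$lr_g, config$noise_sigma,
                         config$samples_per_edge, config$seed + 1L)
  if (any(!is.finite(fit$disc_emb))) {
    stop("non-finite discriminator embeddings after training")
  }
  model$disc_node_emb <- fit$disc_emb
  rownames(model$disc_node_emb) <- ids
  model$gen_node_emb <- fit$gen_emb
  rownames(model$gen_node_emb) <- ids
  for (k in seq_along(model$relations)) {
    model$disc_rel[[k]] <- fit$disc_rel[, , k]
    model$gen_rel[[k]] <- fit$gen_rel[, , k]
  }
  model$disc_loss_per_epoch <- as.numeric(fit$disc_loss)
  model$gen_loss_per_epoch <- as.numeric(fit$gen_loss)
  model$embeddings <- model$disc_node_emb
  model
}
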