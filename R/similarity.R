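# Disease semantic similarity from MeSH-style tree numbers, miRNA similarity
# integration, and conversion of similarity matrices to graph edges.

#' Build per-disease ancestor DAGs from a tree-number table
#'
#' Each MeSH-style tree number is a dot-delimited code locating a disease in
#' the disease hierarchy; every proper prefix of a tree number denotes an
#' ancestor category. For each disease this builds the union DAG over all of
#' its tree numbers: the node set is the disease itself plus every
#' prefix-ancestor, and each position is connected to its direct prefix
#' parent. Internal positions that are not themselves diseases in the table
#' are kept as anonymous nodes named by their prefix string; a position that
#' coincides exactly with another disease's tree number is relabelled with
#' that disease's id, so related diseases share nodes across their DAGs.
#'
#' @param tree_table data.frame with columns `disease_id` and `tree_number`
#'   (one row per disease/tree-number pair; a disease may have several).
#' @return Named list of `disease_dag` objects, one per distinct disease.
#'   Each has fields `disease_id`, `nodes` (character), and `edges`
#'   (data.frame `parent`, `child`).
#' @export
build_disease_dags <- function(tree_table) {
  tree_table <- as.data.frame(tree_table)
  stopifnot(all(c("disease_id", "tree_number") %in% names(tree_table)))
  tns <- as.character(tree_table$tree_number)
  ids <- as.character(tree_table$disease_id)
  segs <- strsplit(tns, ".", fixed = TRUE)
  bad <- vapply(segs, function(s) length(s) == 0L || any(!nzchar(s)), logical(1)) |
    !nzchar(tns)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("malformed tree number '%s' for disease '%s' (row %d)",
                 tns[i], ids[i], i))
  }
  # positions owned by exactly one disease are relabelled to that disease id
  owner <- tapply(ids, tns, function(x) if (length(unique(x)) == 1L) x[[1L]] else NA_character_)
  relabel <- function(pos, self_id, self_tns) {
    if (pos %in% self_tns) return(self_id)
    o <- if (pos %in% names(owner)) owner[[pos]] else NA_character_
    if (!is.na(o)) o else pos
  }
  out <- list()
  for (d in unique(ids)) {
    d_tns <- tns[ids == d]
    nodes <- character(0)
    parent <- character(0)
    child <- character(0)
    for (tn in d_tns) {
      s <- strsplit(tn, ".", fixed = TRUE)[[1L]]
      pos <- vapply(seq_along(s), function(k) paste(s[1:k], collapse = "."),
                    character(1))
      lab <- vapply(pos, relabel, character(1), self_id = d, self_tns = d_tns)
      nodes <- c(nodes, lab)
      if (length(lab) > 1L) {
        parent <- c(parent, lab[-length(lab)])
        child <- c(child, lab[-1L])
      }
    }
    edges <- unique(data.frame(parent = parent, child = child,
                               stringsAsFactors = FALSE))
    out[[d]] <- structure(
      list(disease_id = d, nodes = unique(nodes), edges = edges),
      class = "disease_dag")
  }
  out
}

#' Semantic-similarity parameters
#'
#' @param delta semantic contribution factor in (0,1): the per-generation
#'   decay applied to an ancestor's contribution. Default 0.5.
#' @return `semantic_params` object.
#' @export
semantic_params <- function(delta = 0.5) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0, delta < 1)
  structure(list(delta = delta), class = "semantic_params")
}

# Kahn topological order of dag nodes; errors (naming an offending edge) on a
# cycle. Returns nodes ordered parents-before-children.
.topo_order <- function(dag) {
  nodes <- dag$nodes
  edges <- dag$edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(factor(edges$child, levels = nodes))
    indeg[names(tab)] <- as.integer(tab)
  }
  order_out <- character(0)
  queue <- nodes[indeg == 0L]
  indeg_left <- indeg
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    if (nrow(edges)) {
      ch <- edges$child[edges$parent == v]
      for (c0 in ch) {
        indeg_left[[c0]] <- indeg_left[[c0]] - 1L
        if (indeg_left[[c0]] == 0L) queue <- c(queue, c0)
      }
    }
  }
  if (length(order_out) < length(nodes)) {
    left <- setdiff(nodes, order_out)
    e <- edges[edges$parent %in% left & edges$child %in% left, , drop = FALSE]
    stop(sprintf("cycle detected in DAG of '%s' (edge %s -> %s)",
                 dag$disease_id, e$parent[1L], e$child[1L]))
  }
  order_out
}

#' Semantic contribution profile of a disease DAG
#'
#' The contribution of the disease to itself is 1; the contribution of an
#' ancestor t is `delta` times the maximum contribution among t's children
#' within the DAG, which equals `delta^L` with L the shortest directed path
#' length from t down to the disease (maximising over multiple paths). The
#' semantic value DV is the sum of all contributions.
#'
#' @param dag `disease_dag`.
#' @param params `semantic_params`.
#' @return `semantic_profile` with fields `disease_id`, `dv`,
#'   `contributions` (named numeric), and `delta`.
#' @export
semantic_contribution <- function(dag, params = semantic_params()) {
  stopifnot(inherits(dag, "disease_dag"), inherits(params, "semantic_params"))
  ord <- .topo_order(dag)
  delta <- params$delta
  d <- dag$disease_id
  contrib <- stats::setNames(rep(NA_real_, length(dag$nodes)), dag$nodes)
  contrib[[d]] <- 1
  # children-before-parents: walk reverse topological order
  for (v in rev(ord)) {
    if (v == d) next
    ch <- dag$edges$child[dag$edges$parent == v]
    vals <- contrib[ch]
    vals <- vals[!is.na(vals)]
    if (length(vals)) contrib[[v]] <- delta * max(vals)
  }
  if (anyNA(contrib)) {
    stop(sprintf("node(s) %s have no directed path to disease '%s'",
                 paste(names(contrib)[is.na(contrib)], collapse = ", "), d))
  }
  structure(list(disease_id = d, dv = sum(contrib), contributions = contrib,
                 delta = delta),
            class = "semantic_profile")
}

#' Semantic similarity between two disease profiles
#'
#' Sum over shared DAG nodes of both diseases' contributions to that node,
#' divided by the sum of the two semantic values. Symmetric; 1 for a profile
#' against itself; 0 for disjoint DAGs.
#'
#' @param profile_i,profile_j `semantic_profile` objects computed with the
#'   same `delta`.
#' @return similarity in \[0, 1\].
#' @export
disease_similarity <- function(profile_i, profile_j) {
  stopifnot(inherits(profile_i, "semantic_profile"),
            inherits(profile_j, "semantic_profile"))
  if (!isTRUE(all.equal(profile_i$delta, profile_j$delta))) {
    stop("profiles were computed with different delta values")
  }
  shared <- intersect(names(profile_i$contributions),
                      names(profile_j$contributions))
  if (!length(shared)) return(0)
  num <- sum(profile_i$contributions[shared] + profile_j$contributions[shared])
  num / (profile_i$dv + profile_j$dv)
}

#' Construct a similarity matrix object
#'
#' @param ids character vector of node ids.
#' @param values square numeric matrix aligned with `ids`.
#' @return `similarity_matrix` (list of `ids`, `values`), validated:
#'   symmetric within 1e-12, entries in \[0,1\], unit diagonal.
#' @export
similarity_matrix <- function(ids, values) {
  ids <- as.character(ids)
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(ids), ncol(values) == length(ids))
  dimnames(values) <- list(ids, ids)
  if (any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stop("similarity values outside [0, 1]")
  }
  values[values < 0] <- 0
  values[values > 1] <- 1
  if (max(abs(values - t(values))) > 1e-12) stop("similarity matrix not symmetric")
  if (any(abs(diag(values) - 1) > 1e-12)) stop("similarity diagonal must equal 1")
  structure(list(ids = ids, values = values), class = "similarity_matrix")
}

#' Pairwise disease semantic-similarity matrix
#'
#' @param dags named list from [build_disease_dags()].
#' @param params `semantic_params`.
#' @return `similarity_matrix` over all disease ids in `dags`.
#' @export
disease_similarity_matrix <- function(dags, params = semantic_params()) {
  stopifnot(length(dags) > 0)
  profiles <- lapply(dags, semantic_contribution, params = params)
  ids <- vapply(profiles, `[[`, character(1), "disease_id")
  n <- length(ids)
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        s <- disease_similarity(profiles[[i]], profiles[[j]])
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  similarity_matrix(ids, m)
}

#' Integrate two miRNA similarity matrices by average ensemble
#'
#' For a pair of miRNAs covered by both sources the integrated value is the
#' arithmetic mean; for a pair covered by only one source that source's value
#' is kept as the final result; pairs covered by neither get 0. The output id
#' set is the union of the two input id sets.
#'
#' @param sim_a,sim_b `similarity_matrix` objects (possibly different id sets).
#' @return `similarity_matrix` over the union of ids.
#' @export
integrate_mirna_similarity <- function(sim_a, sim_b) {
  stopifnot(inherits(sim_a, "similarity_matrix"),
            inherits(sim_b, "similarity_matrix"))
  ids <- union(sim_a$ids, sim_b$ids)
  n <- length(ids)
  acc <- matrix(0, n, n, dimnames = list(ids, ids))
  cnt <- matrix(0L, n, n)
  for (s in list(sim_a, sim_b)) {
    idx <- match(s$ids, ids)
    acc[idx, idx] <- acc[idx, idx] + s$values
    cnt[idx, idx] <- cnt[idx, idx] + 1L
  }
  out <- acc
  out[cnt > 0L] <- acc[cnt > 0L] / cnt[cnt > 0L]
  diag(out) <- 1
  similarity_matrix(ids, out)
}

#' Convert a similarity matrix to a weighted undirected edge list
#'
#' Two rules are supported: `threshold` emits an edge for every off-diagonal
#' pair with similarity at or above `tau`; `top_k` emits, for each node, edges
#' to its `k` most similar neighbours (ties broken by id order), taking the
#' union over endpoints and deduplicating. Edge weight is the similarity
#' value; self-loops are never emitted.
#'
#' @param sim `similarity_matrix`.
#' @param rule `"threshold"` or `"top_k"`.
#' @param tau threshold in \[0,1\] (threshold rule; default 0.5).
#' @param k neighbours per node (top_k rule).
#' @return data.frame `from`, `to`, `weight` with `from < to` lexicographically.
#' @export
similarity_to_edges <- function(sim, rule = c("threshold", "top_k"),
                                tau = 0.5, k = 5L) {
  stopifnot(inherits(sim, "similarity_matrix"))
  rule <- match.arg(rule)
  ids <- sim$ids
  v <- sim$values
  n <- length(ids)
  keep <- matrix(FALSE, n, n)
  if (rule == "threshold") {
    if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1) {
      stop("tau must be a number in [0, 1]")
    }
    keep <- v >= tau
  } else {
    if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
    k <- as.integer(k)
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      if (!length(others)) next
      ord <- others[order(-v[i, others], ids[others])]
      best <- ord[seq_len(min(k, length(ord)))]
      keep[i, best] <- TRUE
    }
    keep <- keep | t(keep)
  }
  diag(keep) <- FALSE
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  a <- ids[idx[, 1L]]
  b <- ids[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(from = a, to = b, weight = v[idx],
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Read / write a similarity matrix as TSV
#'
#' The dialect is a header row of ids, then one row per id with the id in the
#' first column.
#'
#' @param sim `similarity_matrix`; `path` file path.
#' @return `read_similarity_matrix` returns a `similarity_matrix`.
#' @export
write_similarity_matrix <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  df <- data.frame(id = sim$ids, sim$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  similarity_matrix(ids, as.matrix(df[, -1L, drop = FALSE]))
}
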