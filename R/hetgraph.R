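# Typed heterogeneous graph: node-type registry, the six sub-networks,
# miRNA name normalization, TSV readers/writers, word2vec-text embeddings.

# edge types, keyed by the unordered pair of endpoint node types
EDGE_TYPES <- c("sm-mi", "mi-dis", "sm-dis", "mi-mi", "sm-sm", "dis-dis")
NODE_TYPES <- c("SM", "miRNA", "disease")

.type_pair_key <- function(ta, tb) {
  # order by NODE_TYPES index, not locale collation
  i <- match(c(ta, tb), NODE_TYPES)
  paste(NODE_TYPES[sort(i)], collapse = "+")
}

.EDGE_TYPE_BY_PAIR <- c(
  "SM+miRNA"        = "sm-mi",
  "miRNA+disease"   = "mi-dis",
  "SM+disease"      = "sm-dis",
  "miRNA+miRNA"     = "mi-mi",
  "SM+SM"           = "sm-sm",
  "disease+disease" = "dis-dis"
)

#' Edge type implied by a pair of node types
#' @param ta,tb node types (`"SM"`, `"miRNA"`, `"disease"`).
#' @return edge type string.
#' @export
edge_type_for <- function(ta, tb) {
  unname(.EDGE_TYPE_BY_PAIR[.type_pair_key(ta, tb)])
}

#' Normalize a miRNA identifier to its precursor form
#'
#' Mature miRNAs produced from the same precursor hairpin (the -5p and -3p
#' arms) are merged to the precursor name: the id is lowercased (so `miR`
#' becomes `mir`) and a trailing `-5p`/`-3p` arm suffix is stripped. Numeric
#' paralog suffixes (e.g. `hsa-mir-125b-2`) are preserved. Idempotent.
#'
#' @param raw character vector of miRNA identifiers.
#' @return normalized character vector.
#' @export
normalize_mirna_name <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    stop("empty miRNA identifier")
  }
  x <- tolower(trimws(raw))
  sub("-(3p|5p)$", "", x)
}

.normalize_disease_name <- function(x) tolower(trimws(x))

#' Assemble the heterogeneous information network
#'
#' Combines the three association networks (SM-miRNA, miRNA-disease,
#' SM-disease) and the three similarity-derived networks (miRNA-miRNA, SM-SM,
#' disease-disease) into one typed undirected graph. `HIN-3N` keeps all six
#' sub-networks and all three node types; `HIN-2N` keeps only the SM-miRNA
#' association network and the two SM/miRNA similarity networks. miRNA ids
#' are normalized to precursor form, disease names are matched
#' case-insensitively after trimming, duplicate (pair, edge-type) entries and
#' self-loops are removed.
#'
#' @param networks named list with any of `sm_mi`, `mi_dis`, `sm_dis`,
#'   `mi_mi`, `sm_sm`, `dis_dis`; each a data.frame `from`, `to` and
#'   optionally `weight` (default 1). `from`/`to` column roles follow the
#'   network name (e.g. `sm_mi$from` are SMs, `$to` miRNAs).
#' @param mode `"HIN-3N"` (default) or `"HIN-2N"`.
#' @return `hetero_graph` object: `nodes` (data.frame `id`, `type`), `edges`
#'   (data.frame `from`, `to`, `type`, `weight`), plus integer adjacency
#'   indexes used by the random-walk and adversarial trainers.
#' @export
assemble_heterograph <- function(networks, mode = c("HIN-3N", "HIN-2N")) {
  mode <- match.arg(mode)
  roles <- list(
    sm_mi   = c("SM", "miRNA"),
    mi_dis  = c("miRNA", "disease"),
    sm_dis  = c("SM", "disease"),
    mi_mi   = c("miRNA", "miRNA"),
    sm_sm   = c("SM", "SM"),
    dis_dis = c("disease", "disease")
  )
  use <- names(roles)
  if (mode == "HIN-2N") use <- c("sm_mi", "sm_sm", "mi_mi")
  from <- character(0); to <- character(0)
  etype <- character(0); weight <- numeric(0)
  tfrom <- character(0); tto <- character(0)
  for (nm in use) {
    el <- networks[[nm]]
    if (is.null(el) || !nrow(el)) next
    a <- as.character(el$from); b <- as.character(el$to)
    w <- if ("weight" %in% names(el)) as.numeric(el$weight) else rep(1, nrow(el))
    r <- roles[[nm]]
    norm1 <- switch(r[1L], miRNA = normalize_mirna_name,
                    disease = .normalize_disease_name, identity)
    norm2 <- switch(r[2L], miRNA = normalize_mirna_name,
                    disease = .normalize_disease_name, identity)
    a <- norm1(a); b <- norm2(b)
    from <- c(from, a); to <- c(to, b)
    etype <- c(etype, rep(.EDGE_TYPE_BY_PAIR[[.type_pair_key(r[1L], r[2L])]],
                          nrow(el)))
    weight <- c(weight, w)
    tfrom <- c(tfrom, rep(r[1L], nrow(el)))
    tto <- c(tto, rep(r[2L], nrow(el)))
  }
  # node type registry; conflicting assignments are an input error
  node_id <- c(from, to)
  node_ty <- c(tfrom, tto)
  tab <- unique(data.frame(id = node_id, type = node_ty,
                           stringsAsFactors = FALSE))
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup)) {
    stop(sprintf("node id(s) with conflicting types: %s",
                 paste(unique(dup), collapse = ", ")))
  }
  # drop self-loops (arm merging can collapse a mi-mi pair onto one node)
  keep <- from != to
  from <- from[keep]; to <- to[keep]; etype <- etype[keep]; weight <- weight[keep]
  # canonical unordered orientation, then dedup on (pair, type)
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(from, to, etype, sep = "\r")
  keep <- !duplicated(key)
  edges <- data.frame(from = from[keep], to = to[keep], type = etype[keep],
                      weight = weight[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  used <- unique(c(edges$from, edges$to))
  iso <- setdiff(tab$id, used)
  if (length(iso)) {
    warning(sprintf("dropping %d isolated node(s): %s", length(iso),
                    paste(utils::head(iso, 5L), collapse = ", ")))
  }
  nodes <- tab[tab$id %in% used, , drop = FALSE]
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  g <- structure(list(nodes = nodes, edges = edges, mode = mode),
                 class = "hetero_graph")
  .index_graph(g)
}

# integer adjacency: for node i, adj[[i]] = neighbour indices, adj_et[[i]] =
# matching edge-type indices into EDGE_TYPES
.index_graph <- function(g) {
  ids <- g$nodes$id
  n <- length(ids)
  ei <- match(g$edges$from, ids)
  ej <- match(g$edges$to, ids)
  et <- match(g$edges$type, EDGE_TYPES)
  adj <- vector("list", n)
  adj_et <- vector("list", n)
  src <- c(ei, ej); dst <- c(ej, ei); ety <- c(et, et)
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]; ety <- ety[o]
  runs <- split(seq_along(src), src)
  for (k in names(runs)) {
    i <- as.integer(k)
    adj[[i]] <- dst[runs[[k]]]
    adj_et[[i]] <- ety[runs[[k]]]
  }
  for (i in seq_len(n)) {
    if (is.null(adj[[i]])) { adj[[i]] <- integer(0); adj_et[[i]] <- integer(0) }
  }
  g$adj <- adj
  g$adj_edge_type <- adj_et
  g$node_type_idx <- match(g$nodes$type, NODE_TYPES)
  g
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("<hetero_graph %s: %d nodes (%s), %d edges>\n", x$mode,
              nrow(x$nodes),
              paste(sprintf("%s=%d", names(table(x$nodes$type)),
                            as.integer(table(x$nodes$type))), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Read a TSV edge list
#'
#' Dialect: `id_a<TAB>id_b<TAB>weight` with a header row; the weight column
#' is optional for association lists. Ragged rows and non-numeric weights are
#' reported with their line number.
#'
#' @param path file path.
#' @param weighted logical; require a weight column.
#' @return data.frame `from`, `to`, `weight`.
#' @export
read_edge_list <- function(path, weighted = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) <= 1L) {
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  want <- if (weighted) 3L else 2L
  len <- lengths(parts)
  if (any(len != want)) {
    i <- which(len != want)[1L]
    stop(sprintf("%s: line %d has %d column(s), expected %d",
                 path, i + 1L, len[i], want))
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  if (weighted) {
    wraw <- vapply(parts, `[[`, character(1), 3L)
    w <- suppressWarnings(as.numeric(wraw))
    if (anyNA(w)) {
      i <- which(is.na(w))[1L]
      stop(sprintf("%s: line %d has non-numeric weight '%s'",
                   path, i + 1L, wraw[i]))
    }
  } else {
    w <- rep(1, length(from))
  }
  data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE)
}

#' Write a TSV edge list
#'
#' @param edges data.frame `from`, `to`, `weight`; `path` file path.
#' @export
write_edge_list <- function(edges, path) {
  df <- data.frame(id_a = edges$from, id_b = edges$to,
                   weight = edges$weight, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write node embeddings in word2vec text format
#'
#' First line `<n_nodes> <dim>`, then one line per node:
#' `<id> v1 ... vdim`, space-separated, 8 significant digits (values
#' round-trip within 1e-7).
#'
#' @param emb numeric matrix with node ids as rownames; `path` file path.
#' @return `read_embeddings` returns such a matrix.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(is.matrix(emb), !is.null(rownames(emb)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb), ncol(emb)), con)
  vals <- apply(emb, 1L, function(v)
    paste(sprintf("%.8g", v), collapse = " "))
  writeLines(paste(rownames(emb), vals), con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("malformed embedding header")
  n <- hdr[1L]; d <- hdr[2L]
  if (n == 0L) return(matrix(numeric(0), 0L, d))
  parts <- strsplit(lines[1L + seq_len(n)], " ", fixed = TRUE)
  if (any(lengths(parts) != d + 1L)) {
    i <- which(lengths(parts) != d + 1L)[1L]
    stop(sprintf("%s: line %d malformed", path, i + 1L))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  m <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(d)))
  m <- matrix(m, nrow = n, ncol = d)
  rownames(m) <- ids
  m
}

#' Serialize / load a heterogeneous graph as a directory of TSVs
#'
#' One edge-list TSV per sub-network present, plus `node_types.tsv`
#' (`id<TAB>type`).
#'
#' @param g `hetero_graph`; `dir` directory path.
#' @export
write_heterograph <- function(g, dir) {
  stopifnot(inherits(g, "hetero_graph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (et in unique(g$edges$type)) {
    sel <- g$edges[g$edges$type == et, , drop = FALSE]
    write_edge_list(sel, file.path(dir, paste0(gsub("-", "_", et), ".tsv")))
  }
  utils::write.table(
    data.frame(id = g$nodes$id, type = g$nodes$type),
    file.path(dir, "node_types.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
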