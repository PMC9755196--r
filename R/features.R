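# Merge the two embedding matrices, form SM-miRNA pair vectors, and build
# balanced labelled datasets for classification.

#' Merge two embedding matrices into one feature matrix
#'
#' `connection` concatenates the rows (output dimension is the sum of the
#' input dimensions) and is the default used downstream; `averaging` and
#' `multiplication` combine elementwise and require equal dimensions. Both
#' inputs must cover exactly the same node ids; the output keeps the row
#' order of `u`.
#'
#' @param u,v numeric matrices with node ids as rownames.
#' @param method `"connection"`, `"averaging"` or `"multiplication"`.
#' @return merged matrix with the same rownames as `u` and attribute
#'   `source = "merged"`.
#' @export
merge_embeddings <- function(u, v,
                             method = c("connection", "averaging",
                                        "multiplication")) {
  method <- match.arg(method)
  stopifnot(is.matrix(u), is.matrix(v),
            !is.null(rownames(u)), !is.null(rownames(v)))
  if (!setequal(rownames(u), rownames(v))) {
    d1 <- setdiff(rownames(u), rownames(v))
    d2 <- setdiff(rownames(v), rownames(u))
    stop(sprintf("embedding id mismatch: only in u: %s; only in v: %s",
                 paste(utils::head(d1, 5L), collapse = ","),
                 paste(utils::head(d2, 5L), collapse = ",")))
  }
  v <- v[rownames(u), , drop = FALSE]
  if (method != "connection" && ncol(u) != ncol(v)) {
    stop(sprintf("%s requires equal dimensions (%d vs %d)",
                 method, ncol(u), ncol(v)))
  }
  out <- switch(method,
                connection = cbind(u, v),
                averaging = (u + v) / 2,
                multiplication = u * v)
  colnames(out) <- NULL
  attr(out, "source") <- "merged"
  out
}

#' Combine an SM vector and a miRNA vector into one pair vector
#'
#' `hadamard` is the elementwise product (the function used downstream),
#' `average` the elementwise mean, `minus` the difference, `abs_minus` the
#' absolute difference.
#'
#' @param sm_vec,mi_vec equal-length numeric vectors.
#' @param method one of `"hadamard"`, `"average"`, `"minus"`, `"abs_minus"`.
#' @return numeric vector of the same length.
#' @export
pair_vector <- function(sm_vec, mi_vec,
                        method = c("hadamard", "average", "minus",
                                   "abs_minus")) {
  method <- match.arg(method)
  if (length(sm_vec) != length(mi_vec)) {
    stop(sprintf("vector length mismatch: %d vs %d",
                 length(sm_vec), length(mi_vec)))
  }
  switch(method,
         hadamard = sm_vec * mi_vec,
         average = (sm_vec + mi_vec) / 2,
         minus = sm_vec - mi_vec,
         abs_minus = abs(sm_vec - mi_vec))
}

# row-wise pair features for aligned id vectors
.pair_features <- function(embeddings, sm_ids, mi_ids, method) {
  A <- embeddings[sm_ids, , drop = FALSE]
  B <- embeddings[mi_ids, , drop = FALSE]
  out <- switch(method,
                hadamard = A * B,
                average = (A + B) / 2,
                minus = A - B,
                abs_minus = abs(A - B))
  rownames(out) <- NULL
  out
}

#' Build a balanced labelled SM-miRNA pair dataset
#'
#' Known associations are the positives; negatives are drawn uniformly
#' without replacement from all remaining SM x miRNA combinations, with
#' `floor(ratio * n_positives)` negatives. Pair features are computed from
#' the embedding rows with the chosen pair-vector function. Endpoints
#' lacking an embedding row are dropped with a warning.
#'
#' @param positives data.frame with columns `sm` and `mirna`.
#' @param all_sms,all_mirnas candidate id vectors for negative sampling.
#' @param embeddings numeric matrix with ids as rownames.
#' @param pair_fn pair-vector function name (see [pair_vector()]).
#' @param ratio negatives per positive (default 1).
#' @param seed integer seed.
#' @return `pair_dataset`: `pairs` (data.frame `sm`, `mirna`), `features`
#'   matrix, `labels` 0/1 vector.
#' @export
build_dataset <- function(positives, all_sms, all_mirnas, embeddings,
                          pair_fn = "hadamard", ratio = 1.0, seed = 1L) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)),
            ratio >= 0)
  pair_fn <- match.arg(pair_fn, c("hadamard", "average", "minus", "abs_minus"))
  emb_ids <- rownames(embeddings)
  all_sms <- unique(as.character(all_sms))
  all_mirnas <- unique(as.character(all_mirnas))
  miss <- setdiff(c(all_sms, all_mirnas), emb_ids)
  if (length(miss)) {
    warning(sprintf("excluding %d id(s) without embedding rows: %s",
                    length(miss), paste(utils::head(miss, 5L), collapse = ", ")))
    all_sms <- intersect(all_sms, emb_ids)
    all_mirnas <- intersect(all_mirnas, emb_ids)
  }
  pos <- data.frame(sm = as.character(positives$sm),
                    mirna = as.character(positives$mirna),
                    stringsAsFactors = FALSE)
  keep <- pos$sm %in% all_sms & pos$mirna %in% all_mirnas
  if (!all(keep)) {
    warning(sprintf("dropping %d positive pair(s) with unembedded endpoints",
                    sum(!keep)))
    pos <- pos[keep, , drop = FALSE]
  }
  pos <- unique(pos)
  n_pos <- nrow(pos)
  if (!n_pos) stop("no usable positive pairs")
  n_neg <- floor(ratio * n_pos)
  # candidate grid indexed as (sm_index - 1) * n_mirna + mirna_index
  n_sm <- length(all_sms); n_mi <- length(all_mirnas)
  pos_code <- (match(pos$sm, all_sms) - 1) * n_mi + match(pos$mirna, all_mirnas)
  n_cand <- n_sm * n_mi - n_pos
  if (n_neg > n_cand) {
    stop(sprintf("cannot draw %d negatives from %d non-positive combinations",
                 n_neg, n_cand))
  }
  set.seed(seed)
  neg_code <- integer(0)
  if (n_neg > 0) {
    candidates <- setdiff(seq_len(n_sm * n_mi), pos_code)
    neg_code <- sort(candidates[sample.int(length(candidates), n_neg)])
  }
  neg <- data.frame(
    sm = all_sms[(neg_code - 1L) %/% n_mi + 1L],
    mirna = all_mirnas[(neg_code - 1L) %% n_mi + 1L],
    stringsAsFactors = FALSE)
  pairs <- rbind(pos, neg)
  labels <- c(rep(1L, n_pos), rep(0L, nrow(neg)))
  features <- .pair_features(embeddings, pairs$sm, pairs$mirna, pair_fn)
  structure(list(pairs = pairs, features = features, labels = labels,
                 pair_fn = pair_fn, seed = as.integer(seed)),
            class = "pair_dataset")
}

#' Write a pair dataset as TSV
#'
#' Dialect: `sm_id<TAB>mirna_id<TAB>label<TAB>f1,...,fd` (features
#' comma-joined).
#'
#' @param dataset `pair_dataset`; `path` file path.
#' @export
write_pair_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pair_dataset"))
  feats <- apply(dataset$features, 1L, function(v)
    paste(sprintf("%.8g", v), collapse = ","))
  df <- data.frame(sm_id = dataset$pairs$sm, mirna_id = dataset$pairs$mirna,
                   label = dataset$labels, features = feats,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
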