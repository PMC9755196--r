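# Synthetic six-network generator with planted low-rank structure: entities
# sharing latent factors are co-associated and mutually similar, so the
# downstream pipeline has a recoverable signal without any external data.

#' Configuration for the synthetic network generator
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: 60 SMs, 100 miRNAs, 40 diseases, 4 latent dimensions, association
#' density 0.05, similarity noise 0.1.
#'
#' @param n_sm,n_mirna,n_disease entity counts.
#' @param latent_dim dimension of the planted latent factors.
#' @param assoc_density expected fraction of associated pairs in each
#'   association network.
#' @param noise standard deviation of the Gaussian noise added to similarity
#'   values.
#' @param holdout_frac fraction of SM-miRNA positives withheld from the
#'   emitted network and returned separately.
#' @param seed integer seed.
#' @return `synth_config` list.
#' @export
synth_config <- function(n_sm = 60L, n_mirna = 100L, n_disease = 40L,
                         latent_dim = 4L, assoc_density = 0.05, noise = 0.1,
                         holdout_frac = 0, seed = 1L) {
  stopifnot(n_sm >= 1, n_mirna >= 1, n_disease >= 2,
            latent_dim >= 1, assoc_density > 0, assoc_density < 1,
            noise >= 0, holdout_frac >= 0, holdout_frac < 1)
  if (assoc_density * n_sm * n_mirna < 20) {
    stop("assoc_density * n_sm * n_mirna must be >= 20 (too few positives)")
  }
  structure(list(n_sm = as.integer(n_sm), n_mirna = as.integer(n_mirna),
                 n_disease = as.integer(n_disease),
                 latent_dim = as.integer(latent_dim),
                 assoc_density = assoc_density, noise = noise,
                 holdout_frac = holdout_frac, seed = as.integer(seed)),
            class = "synth_config")
}

.unit_rows <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

# solve the intercept b of p = logistic(a * cos + b) so that mean(p) equals
# the target density; slope a fixed at 6 for a clear planted contrast
.calibrate_intercept <- function(cos_vals, density, slope = 6) {
  f <- function(b) mean(stats::plogis(slope * cos_vals + b)) - density
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) stop("target density unreachable")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

.sample_assoc <- function(lat_a, lat_b, ids_a, ids_b, density, slope = 6) {
  cosm <- tcrossprod(lat_a, lat_b)
  b <- .calibrate_intercept(as.vector(cosm), density, slope)
  p <- stats::plogis(slope * cosm + b)
  hit <- which(matrix(stats::runif(length(p)), nrow(p)) < p, arr.ind = TRUE)
  data.frame(from = ids_a[hit[, 1L]], to = ids_b[hit[, 2L]], weight = 1,
             stringsAsFactors = FALSE)
}

.noisy_similarity <- function(lat, ids, noise) {
  s <- tcrossprod(lat)
  n <- nrow(s)
  if (noise > 0) {
    e <- matrix(stats::rnorm(n * n, 0, noise), n, n)
    s <- s + (e + t(e)) / 2
  }
  s <- pmin(pmax(s, 0), 1)
  diag(s) <- 1
  similarity_matrix(ids, s)
}

# depth-3 binary prefix tree over disease latents; diseases with similar
# latents share tree-number prefixes, so DAG semantic similarity correlates
# with the planted similarity
.disease_tree <- function(lat, ids) {
  n <- nrow(lat)
  split2 <- function(rows) {
    if (length(rows) < 2L) return(stats::setNames(rep(1L, length(rows)),
                                                  rows))
    hc <- stats::hclust(stats::dist(lat[rows, , drop = FALSE]), "average")
    stats::setNames(stats::cutree(hc, k = 2L), rows)
  }
  path <- matrix(1L, n, 3L)
  lvl1 <- split2(seq_len(n))
  path[as.integer(names(lvl1)), 1L] <- lvl1
  for (b1 in unique(path[, 1L])) {
    rows <- which(path[, 1L] == b1)
    lvl2 <- split2(rows)
    path[as.integer(names(lvl2)), 2L] <- lvl2
    for (b2 in unique(path[rows, 2L])) {
      rows2 <- which(path[, 1L] == b1 & path[, 2L] == b2)
      lvl3 <- split2(rows2)
      path[as.integer(names(lvl3)), 3L] <- lvl3
    }
  }
  tn <- sprintf("C%02d.%02d%02d.%02d%02d%02d.D%03d",
                path[, 1L], path[, 1L], path[, 2L],
                path[, 1L], path[, 2L], path[, 3L], seq_len(n))
  data.frame(disease_id = ids, tree_number = tn, stringsAsFactors = FALSE)
}

#' Generate the six synthetic input networks
#'
#' Draws one latent unit vector per entity; association edges (SM-miRNA,
#' SM-disease, miRNA-disease) are sampled with probability
#' `logistic(6*cos + b)`, with the intercept calibrated so the expected
#' density matches `assoc_density`; SM-SM similarity and two miRNA
#' similarity sources are clipped noisy latent cosines (the second miRNA
#' source covers a random 80% subset, exercising the average-ensemble
#' fallback); the disease tree table is a depth-3 binary prefix hierarchy
#' clustered on the disease latents. A fraction of the SM-miRNA positives
#' can be withheld and returned separately. Fully deterministic under the
#' seed.
#'
#' @param config `synth_config`.
#' @return `synth_data` list: `sm_mi`, `sm_dis`, `mi_dis` (edge lists),
#'   `sm_sm`, `mi_sim_a`, `mi_sim_b` (similarity matrices), `tree_table`,
#'   `holdout` (data.frame `sm`, `mirna`), `latents`, `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  sm_ids <- sprintf("DB%05d", seq_len(config$n_sm))
  mi_ids <- sprintf("hsa-mir-%d", seq_len(config$n_mirna))
  dis_ids <- sprintf("disease_%03d", seq_len(config$n_disease))
  lat_sm <- .unit_rows(config$n_sm, config$latent_dim)
  lat_mi <- .unit_rows(config$n_mirna, config$latent_dim)
  lat_dis <- .unit_rows(config$n_disease, config$latent_dim)
  sm_mi <- .sample_assoc(lat_sm, lat_mi, sm_ids, mi_ids, config$assoc_density)
  sm_dis <- .sample_assoc(lat_sm, lat_dis, sm_ids, dis_ids,
                          config$assoc_density)
  mi_dis <- .sample_assoc(lat_mi, lat_dis, mi_ids, dis_ids,
                          config$assoc_density)
  # emit mature-arm names for about half the SM-miRNA rows so that name
  # normalization is exercised end to end
  if (nrow(sm_mi)) {
    arm <- sample(c("", "-5p", "-3p"), nrow(sm_mi), replace = TRUE,
                  prob = c(0.5, 0.25, 0.25))
    sm_mi$to <- paste0(sm_mi$to, arm)
  }
  sm_sm <- .noisy_similarity(lat_sm, sm_ids, config$noise)
  mi_sim_a <- .noisy_similarity(lat_mi, mi_ids, config$noise)
  sub <- sort(sample.int(config$n_mirna, max(2L, floor(0.8 * config$n_mirna))))
  mi_sim_b_full <- .noisy_similarity(lat_mi, mi_ids, config$noise)
  mi_sim_b <- similarity_matrix(mi_ids[sub],
                                mi_sim_b_full$values[sub, sub, drop = FALSE])
  tree_table <- .disease_tree(lat_dis, dis_ids)
  holdout <- data.frame(sm = character(0), mirna = character(0),
                        stringsAsFactors = FALSE)
  if (config$holdout_frac > 0 && nrow(sm_mi)) {
    n_hold <- floor(config$holdout_frac * nrow(sm_mi))
    if (n_hold > 0) {
      idx <- sort(sample.int(nrow(sm_mi), n_hold))
      holdout <- data.frame(sm = sm_mi$from[idx],
                            mirna = normalize_mirna_name(sm_mi$to[idx]),
                            stringsAsFactors = FALSE)
      sm_mi <- sm_mi[-idx, , drop = FALSE]
      rownames(sm_mi) <- NULL
    }
  }
  structure(list(sm_mi = sm_mi, sm_dis = sm_dis, mi_dis = mi_dis,
                 sm_sm = sm_sm, mi_sim_a = mi_sim_a, mi_sim_b = mi_sim_b,
                 tree_table = tree_table, holdout = holdout,
                 latents = list(sm = lat_sm, mirna = lat_mi,
                                disease = lat_dis),
                 config = config),
            class = "synth_data")
}

#' Write a synthetic dataset as a directory of TSVs plus a manifest
#'
#' Emits exactly the dialects the readers consume: three association edge
#' lists, one SM similarity matrix, two miRNA similarity matrices, the
#' disease tree table, the hold-out list (if any), and `manifest.json`
#' recording the configuration.
#'
#' @param data `synth_data`; `dir` output directory.
#' @export
write_synth_data <- function(data, dir) {
  stopifnot(inherits(data, "synth_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_edge_list(data$sm_mi, file.path(dir, "sm_mi.tsv"))
  write_edge_list(data$sm_dis, file.path(dir, "sm_dis.tsv"))
  write_edge_list(data$mi_dis, file.path(dir, "mi_dis.tsv"))
  write_similarity_matrix(data$sm_sm, file.path(dir, "sm_sm.tsv"))
  write_similarity_matrix(data$mi_sim_a, file.path(dir, "mi_sim_a.tsv"))
  write_similarity_matrix(data$mi_sim_b, file.path(dir, "mi_sim_b.tsv"))
  utils::write.table(data$tree_table, file.path(dir, "disease_tree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(data$holdout)) {
    utils::write.table(data$holdout, file.path(dir, "holdout.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(unclass(data$config),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a synthetic dataset directory written by [write_synth_data()]
#'
#' @param dir directory path.
#' @return `synth_data`-shaped list (without latents).
#' @export
read_synth_data <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  holdout_path <- file.path(dir, "holdout.tsv")
  holdout <- if (file.exists(holdout_path)) {
    utils::read.table(holdout_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    data.frame(sm = character(0), mirna = character(0))
  }
  structure(list(
    sm_mi = read_edge_list(file.path(dir, "sm_mi.tsv")),
    sm_dis = read_edge_list(file.path(dir, "sm_dis.tsv")),
    mi_dis = read_edge_list(file.path(dir, "mi_dis.tsv")),
    sm_sm = read_similarity_matrix(file.path(dir, "sm_sm.tsv")),
    mi_sim_a = read_similarity_matrix(file.path(dir, "mi_sim_a.tsv")),
    mi_sim_b = read_similarity_matrix(file.path(dir, "mi_sim_b.tsv")),
    tree_table = utils::read.table(file.path(dir, "disease_tree.tsv"),
                                   sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE),
    holdout = holdout, config = cfg), class = "synth_data")
}
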