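test_that("tree tables build union prefix DAGs", {
  dags <- build_disease_dags(data.frame(disease_id = "A",
                                        tree_number = "C01.100"))
  expect_named(dags, "A")
  expect_setequal(dags$A$nodes, c("A", "C01"))
  expect_equal(nrow(dags$A$edges), 1L)
  expect_equal(dags$A$edges$parent, "C01")
  expect_equal(dags$A$edges$child, "A")

  # two tree numbers -> union DAG with two roots
  dags <- build_disease_dags(
    data.frame(disease_id = c("B", "B"),
               tree_number = c("C01.100.200", "C02.300.200")))
  expect_setequal(dags$B$nodes, c("B", "C01", "C01.100", "C02", "C02.300"))
  expect_equal(nrow(dags$B$edges), 4L)
  roots <- setdiff(dags$B$edges$parent, dags$B$edges$child)
  expect_setequal(roots, c("C01", "C02"))

  # nested diseases share nodes: a prefix owned by a disease is relabelled
  dags <- build_disease_dags(
    data.frame(disease_id = c("g", "p", "d"),
               tree_number = c("R", "R.01", "R.01.02")))
  expect_setequal(dags$d$nodes, c("d", "p", "g"))
  expect_setequal(dags$p$nodes, c("p", "g"))

  expect_error(
    build_disease_dags(data.frame(disease_id = "X", tree_number = "C01..2")),
    "malformed.*X")
})

test_that("diamond tree numbers give an acyclic 4-node DAG", {
  dags <- build_disease_dags(
    data.frame(disease_id = c("d", "d"),
               tree_number = c("G.p1.d", "G.p2.d")))
  dag <- dags$d
  expect_length(dag$nodes, 4L)
  expect_equal(nrow(dag$edges), 4L)
  expect_no_error(semantic_contribution(dag)) # topological sort succeeds
})

test_that("semantic contributions follow the shortest-path max rule", {
  chain <- build_disease_dags(
    data.frame(disease_id = c("g", "p", "d"),
               tree_number = c("R", "R.01", "R.01.02")))
  prof <- semantic_contribution(chain$d, semantic_params(0.5))
  expect_equal(prof$contributions[["d"]], 1)
  expect_equal(prof$contributions[["p"]], 0.5)
  expect_equal(prof$contributions[["g"]], 0.25)
  expect_equal(prof$dv, 1.75)

  # diamond: two length-2 paths, max picks delta^2
  diamond <- structure(list(
    disease_id = "d", nodes = c("d", "p1", "p2", "g"),
    edges = data.frame(parent = c("g", "g", "p1", "p2"),
                       child = c("p1", "p2", "d", "d"))),
    class = "disease_dag")
  prof <- semantic_contribution(diamond, semantic_params(0.5))
  expect_equal(prof$contributions[["g"]], 0.25)
  expect_equal(prof$dv, 2.25)

  singleton <- structure(list(disease_id = "d", nodes = "d",
                              edges = data.frame(parent = character(0),
                                                 child = character(0))),
                         class = "disease_dag")
  prof <- semantic_contribution(singleton)
  expect_equal(unname(prof$contributions), 1)
  expect_equal(prof$dv, 1)

  cyclic <- structure(list(disease_id = "d", nodes = c("d", "a", "b"),
                           edges = data.frame(parent = c("a", "b", "d"),
                                              child = c("b", "a", "a"))),
                      class = "disease_dag")
  expect_error(semantic_contribution(cyclic), "cycle")
})

test_that("contributions match the all-paths brute-force oracle", {
  for (i in 1:100) {
    dag <- random_dag(n_nodes = sample(2:15, 1L), seed = 1000 + i)
    delta <- sample(c(0.3, 0.5, 0.8), 1L)
    prof <- semantic_contribution(dag, semantic_params(delta))
    oracle <- oracle_contributions(dag, delta)
    expect_equal(prof$contributions[dag$nodes], oracle[dag$nodes],
                 tolerance = 1e-12)
    expect_equal(prof$dv, sum(oracle), tolerance = 1e-12)
  }
})

test_that("pairwise similarity reproduces the hand-worked values", {
  # two diseases sharing only a root ancestor
  tab <- data.frame(disease_id = c("d1", "d2"),
                    tree_number = c("R.01", "R.02"))
  dags <- build_disease_dags(tab)
  p1 <- semantic_contribution(dags$d1)
  p2 <- semantic_contribution(dags$d2)
  expect_equal(disease_similarity(p1, p2), 1 / 3, tolerance = 0)
  expect_equal(disease_similarity(p1, p2), disease_similarity(p2, p1))
  expect_equal(disease_similarity(p1, p1), 1)

  # nested chain: Sim(d, p) = (0.5+1 + 0.25+0.5) / (1.75+1.5)
  chain <- build_disease_dags(
    data.frame(disease_id = c("g", "p", "d"),
               tree_number = c("R", "R.01", "R.01.02")))
  pd <- semantic_contribution(chain$d)
  pp <- semantic_contribution(chain$p)
  expect_equal(disease_similarity(pd, pp), 9 / 13, tolerance = 0)

  expect_error(
    disease_similarity(pd, semantic_contribution(chain$p,
                                                 semantic_params(0.3))),
    "different delta")
})

test_that("similarity matrices satisfy symmetry, range and diagonal", {
  one <- disease_similarity_matrix(
    build_disease_dags(data.frame(disease_id = "A", tree_number = "C01")))
  expect_equal(one$values, matrix(1, 1, 1, dimnames = list("A", "A")))

  disjoint <- disease_similarity_matrix(
    build_disease_dags(data.frame(disease_id = c("A", "B"),
                                  tree_number = c("C01.1", "D02.1"))))
  expect_equal(disjoint$values["A", "B"], 0)

  tab <- data.frame(disease_id = c("d1", "d2"),
                    tree_number = c("R.01", "R.02"))
  m <- disease_similarity_matrix(build_disease_dags(tab))
  expect_equal(m$values["d1", "d2"], 1 / 3)

  # random DAG batch: matrix invariants hold
  set.seed(42)
  tabs <- data.frame(
    disease_id = paste0("dis", 1:8),
    tree_number = replicate(8, paste(sample(LETTERS[1:4],
                                            sample(1:3, 1), replace = TRUE),
                                     collapse = ".")))
  m <- disease_similarity_matrix(build_disease_dags(tabs))
  expect_true(all(m$values >= 0 & m$values <= 1))
  expect_equal(m$values, t(m$values))
  expect_equal(unname(diag(m$values)), rep(1, 8))
})

test_that("average-ensemble integration keeps single-source values", {
  a <- similarity_matrix(c("m1", "m2"),
                         matrix(c(1, 0.4, 0.4, 1), 2, 2))
  b <- similarity_matrix(c("m1", "m2"),
                         matrix(c(1, 0.6, 0.6, 1), 2, 2))
  merged <- integrate_mirna_similarity(a, b)
  expect_equal(merged$values["m1", "m2"], 0.5)

  # a pair present in only one source keeps that value
  b2 <- similarity_matrix(c("m1", "m3"),
                          matrix(c(1, 0.7, 0.7, 1), 2, 2))
  merged <- integrate_mirna_similarity(a, b2)
  expect_setequal(merged$ids, c("m1", "m2", "m3"))
  expect_equal(merged$values["m1", "m2"], 0.4)
  expect_equal(merged$values["m1", "m3"], 0.7)
  expect_equal(merged$values["m2", "m3"], 0) # in neither source

  # idempotent on identical inputs, commutative in its arguments
  expect_equal(integrate_mirna_similarity(a, a)$values, a$values)
  expect_equal(integrate_mirna_similarity(a, b2)$values,
               integrate_mirna_similarity(b2, a)$values[merged$ids,
                                                        merged$ids])
})

test_that("similarity matrices convert to edges under both rules", {
  m <- similarity_matrix(c("a", "b", "c"),
                         matrix(c(1, 0.5, 0.5,
                                  0.5, 1, 0.5,
                                  0.5, 0.5, 1), 3, 3))
  expect_equal(nrow(similarity_to_edges(m, "threshold", tau = 0)), 3L)
  expect_error(similarity_to_edges(m, "threshold", tau = 1.1), "tau")
  expect_error(similarity_to_edges(m, "top_k", k = 0), "k must be")

  v <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.2,
                0.1, 0.2, 1), 3, 3)
  m2 <- similarity_matrix(c("a", "b", "c"), v)
  top1 <- similarity_to_edges(m2, "top_k", k = 1)
  expect_true(any(top1$from == "a" & top1$to == "b"))
  # c's best neighbour is b, so (b, c) also survives the union
  expect_true(any(top1$from == "b" & top1$to == "c"))
  expect_false(any(top1$from == top1$to))

  thr <- similarity_to_edges(m2, "threshold", tau = 0.85)
  expect_equal(nrow(thr), 1L)
  expect_equal(thr$weight, 0.9)
})

test_that("similarity matrix TSV round-trips", {
  m <- similarity_matrix(c("x", "y"), matrix(c(1, 0.25, 0.25, 1), 2, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(m, path)
  back <- read_similarity_matrix(path)
  expect_equal(back$ids, m$ids)
  expect_equal(back$values, m$values)
})
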