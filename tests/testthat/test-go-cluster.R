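test_that("induced term sets close over ancestors up to the root", {
  dag <- toy_dag()
  ann <- go_annotations(c("p1", "p2", "p3"), c("GO:C", "GO:B", "GO:R"),
                        rep("BP", 3))
  expect_setequal(induced_terms("p1", "BP", dag, ann),
                  c("GO:C", "GO:A", "GO:R"))
  expect_setequal(induced_terms("p3", "BP", dag, ann), "GO:R")
  expect_error(induced_terms("p9", "BP", dag, ann), "no BP annotation")

  # random DAGs: closure equals the brute-force fixpoint oracle
  set.seed(5)
  for (rep in 1:5) {
    n_terms <- 50
    ids <- sprintf("GO:%03d", seq_len(n_terms))
    parent <- vapply(2:n_terms, function(i) sample(ids[seq_len(i - 1)], 1),
                     character(1))
    dag_r <- go_dag(
      data.frame(id = ids, name = ids, namespace = "biological_process"),
      data.frame(child = ids[-1], parent = parent, relation = "is_a"))
    for (p in 1:20) {
      direct <- sample(ids, sample(1:4, 1))
      ann_r <- go_annotations(rep("px", length(direct)), direct,
                              rep("BP", length(direct)))
      expect_setequal(induced_terms("px", "BP", dag_r, ann_r),
                      closure_oracle(direct, dag_r$edges))
    }
  }
})

test_that("part_of edges are followed by default and excludable by flag", {
  dag <- go_dag(
    terms = data.frame(id = c("GO:R", "GO:A", "GO:B"),
                       name = c("r", "a", "b"),
                       namespace = "biological_process"),
    edges = data.frame(child = c("GO:A", "GO:B", "GO:B"),
                       parent = c("GO:R", "GO:R", "GO:A"),
                       relation = c("is_a", "is_a", "part_of")))
  ann <- go_annotations("p", "GO:B", "BP")
  expect_setequal(induced_terms("p", "BP", dag, ann),
                  c("GO:B", "GO:A", "GO:R"))
  expect_setequal(induced_terms("p", "BP", dag, ann,
                                include_part_of = FALSE),
                  c("GO:B", "GO:R"))
})

test_that("simUI similarity follows the union-intersection definition", {
  dag <- toy_dag()
  ann <- go_annotations(c("p1", "p2", "p3"), c("GO:C", "GO:B", "GO:C"),
                        rep("BP", 3))
  # induced {C,A,R} vs {B,R}: intersection {R}, union {C,A,B,R}
  expect_equal(simui_similarity("p1", "p2", "BP", dag, ann), 0.25)
  expect_equal(simui_similarity("p1", "p3", "BP", dag, ann), 1)
  expect_equal(simui_similarity("p1", "p2", "BP", dag, ann),
               simui_similarity("p2", "p1", "BP", dag, ann))
})

test_that("simUI matches a set-ratio oracle and satisfies its invariants", {
  sim <- simulate_go_corpus(go_sim_config(n_groups = 4,
                                          proteins_per_group = 5,
                                          noise_p = 0.3, seed = 17))
  prot <- sim$truth$protein_id
  parents <- sim$dag$edges
  set.seed(1)
  for (r in 1:100) {
    pair <- sample(prot, 2)
    direct_a <- sim$annotations$term_id[sim$annotations$protein_id == pair[1]]
    direct_b <- sim$annotations$term_id[sim$annotations$protein_id == pair[2]]
    ind_a <- closure_oracle(direct_a, parents)
    ind_b <- closure_oracle(direct_b, parents)
    oracle <- length(intersect(ind_a, ind_b)) / length(union(ind_a, ind_b))
    s <- simui_similarity(pair[1], pair[2], "BP", sim$dag, sim$annotations)
    expect_equal(s, oracle, tolerance = 1e-12)
    expect_true(s >= 0 && s <= 1)
  }
  # adding the same direct term to both proteins never lowers similarity
  ann <- sim$annotations
  pair <- prot[1:2]
  s0 <- simui_similarity(pair[1], pair[2], "BP", sim$dag, ann)
  extra <- setdiff(sim$dag$terms$id, "GO:0000001")[1]
  ann2 <- go_annotations(c(ann$protein_id, pair),
                         c(ann$term_id, extra, extra),
                         c(ann$aspect, "BP", "BP"))
  expect_gte(simui_similarity(pair[1], pair[2], "BP", sim$dag, ann2), s0)
})

test_that("dissimilarity matrices are 1 - simUI with the star closed form", {
  star <- star_corpus(6)
  d <- dissimilarity_matrix(star$proteins, "BP", star$dag,
                            star$annotations)
  off <- d[upper.tri(d)]
  expect_equal(off, rep(1 - 1 / 3, length(off)))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))

  # duplicate annotation profiles give d = 0
  star$annotations$term_id[2] <- star$annotations$term_id[1]
  d2 <- dissimilarity_matrix(star$proteins, "BP", star$dag,
                             star$annotations)
  expect_equal(d2[1, 2], 0)

  # element-wise consistency with simui_similarity
  sim <- simulate_go_corpus(go_sim_config(seed = 2))
  prot <- sim$truth$protein_id[1:6]
  d3 <- dissimilarity_matrix(prot, "BP", sim$dag, sim$annotations)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(d3[i, j],
                   1 - simui_similarity(prot[i], prot[j], "BP", sim$dag,
                                        sim$annotations))
    }
  }

  # unannotated proteins are excluded with a message, small sets error
  expect_message(
    d4 <- dissimilarity_matrix(c(prot, "ghost"), "BP", sim$dag,
                               sim$annotations),
    "ghost")
  expect_equal(nrow(d4), 6)
  expect_error(
    suppressMessages(dissimilarity_matrix(c(prot[1:2], "ghost"), "BP",
                                          sim$dag, sim$annotations)),
    "fewer than 3")
})

test_that("PAM trivial cases and determinism behave as specified", {
  set.seed(3)
  d <- random_diss(7)
  rownames(d) <- colnames(d) <- sprintf("p%d", 1:7)

  # k = n: every point its own medoid, zero cost
  sol_n <- pam_cluster(d, 7)
  expect_equal(sol_n$cost, 0)
  expect_setequal(sol_n$medoids, rownames(d))

  # k = 1: medoid minimises total dissimilarity
  sol_1 <- pam_cluster(d, 1)
  expect_equal(sol_1$medoid_index, unname(which.min(colSums(d))))
  expect_equal(sol_1$cost, min(colSums(d)))

  # deterministic, medoids belong to their own clusters, cost recomputes
  sol_3 <- pam_cluster(d, 3)
  expect_identical(sol_3, pam_cluster(d, 3))
  expect_equal(unname(sol_3$assignment[sol_3$medoids]),
               seq_along(sol_3$medoids))
  expect_equal(sol_3$cost,
               sum(d[cbind(1:7, sol_3$medoid_index[sol_3$assignment])]))
  expect_error(pam_cluster(d, 8), "k must satisfy")
})

test_that("PAM agrees with cluster::pam on structured data", {
  skip_if_not_installed("cluster")
  set.seed(9)
  for (r in 1:10) {
    x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 4), 10))
    d <- as.matrix(dist(x))
    sol <- pam_cluster(d, 2)
    ref <- cluster::pam(stats::as.dist(d), 2)
    expect_equal(sol$cost, ref$objective[["swap"]] * nrow(d),
                 tolerance = 1e-10)
  }
})

test_that("silhouette widths match hand-worked and library values", {
  # 4 points, 2 clusters {1,2} and {3,4}
  d <- matrix(c(0, 0.2, 0.9, 0.8,
                0.2, 0, 0.7, 1.0,
                0.9, 0.7, 0, 0.4,
                0.8, 1.0, 0.4, 0), 4, 4)
  s <- silhouette_widths(d, c(1L, 1L, 2L, 2L))
  expect_equal(unname(s),
               c((0.85 - 0.2) / 0.85, (0.85 - 0.2) / 0.85,
                 (0.8 - 0.4) / 0.8, (0.9 - 0.4) / 0.9))
  expect_true(all(s >= -1 & s <= 1))

  # singleton cluster gets width 0
  s2 <- silhouette_widths(d, c(1L, 1L, 2L, 3L))
  expect_equal(unname(s2[4]), 0)

  skip_if_not_installed("cluster")
  set.seed(21)
  d3 <- random_diss(9)
  cl <- c(rep(1L, 3), rep(2L, 3), rep(3L, 3))
  ref <- cluster::silhouette(cl, stats::as.dist(d3))
  expect_equal(unname(silhouette_widths(d3, cl)),
               unname(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("silhouette-based k selection finds clean block structure", {
  # two tight pairs far apart: best k = 2 with near-perfect silhouette
  d <- matrix(1, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.02
  d[3, 4] <- d[4, 3] <- 0.02
  sel <- select_k(d, 2, 3)
  expect_equal(sel$k, 2)
  expect_gt(sel$solution$avg_silhouette, 0.9)
  expect_equal(nrow(sel$profile), 2)
  expect_error(select_k(d, 1, 3), "k_min")
})

test_that("cluster networks respect strict edge thresholds", {
  sim <- simulate_go_corpus(go_sim_config(seed = 4))
  d <- dissimilarity_matrix(sim$truth$protein_id, "BP", sim$dag,
                            sim$annotations)
  sol <- pam_cluster(d, 3)

  # aspect MF keeps d = 0.4 and drops d = 0.41 ("above" is strict)
  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d3[1, 2] <- d3[2, 1] <- 0.1
  d3[1, 3] <- d3[3, 1] <- 0.4
  d3[2, 3] <- d3[3, 2] <- 0.41
  sol3 <- pam_cluster(d3, 1)
  net3 <- cluster_network(d3, sol3, "MF")
  kept <- sort(net3$edges$dissimilarity)
  expect_equal(kept, c(0.1, 0.4))

  # all d = 0.5 under the CC threshold 0.3: no edges, nodes unaffected
  d5 <- matrix(0.5, 4, 4); diag(d5) <- 0
  dimnames(d5) <- list(letters[1:4], letters[1:4])
  net5 <- cluster_network(d5, pam_cluster(d5, 2), "CC")
  expect_equal(nrow(net5$edges), 0)
  expect_equal(nrow(net5$nodes), 4)

  # exactly one medoid per cluster; widths shrink with dissimilarity
  net <- cluster_network(d, sol, "BP")
  medoids_per_cluster <- tapply(net$nodes$is_medoid, net$nodes$cluster, sum)
  expect_true(all(medoids_per_cluster == 1))
  if (nrow(net$edges) > 1) {
    o <- order(net$edges$dissimilarity)
    expect_true(all(diff(net$edges$width[o]) <= 0))
  }
  expect_true(all(net$edges$dissimilarity <= net$edge_threshold))
  expect_error(cluster_network(d, sol, "XX"), "unknown aspect")
})

test_that("network exports produce valid GraphML and SIF", {
  sim <- simulate_go_corpus(go_sim_config(seed = 6))
  d <- dissimilarity_matrix(sim$truth$protein_id, "BP", sim$dag,
                            sim$annotations)
  net <- cluster_network(d, pam_cluster(d, 3), "BP")
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  attr_path <- withr::local_tempfile(fileext = ".tsv")
  write_network_graphml(net, gml)
  write_network_sif(net, sif, attr_path)

  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_true("cluster" %in% igraph::vertex_attr_names(g))

  sif_lines <- readLines(sif)
  expect_equal(sum(grepl("\tsim\t", sif_lines)), nrow(net$edges))
  attrs <- read.delim(attr_path, stringsAsFactors = FALSE)
  expect_setequal(attrs$protein, net$nodes$protein)
})

test_that("cluster labels pick the most informative medoid term", {
  dag <- toy_dag()
  # p1 is the medoid, annotated to the root and to leaf C; root has IC 0
  ann <- go_annotations(c("p1", "p1", "p2", "p3", "p4"),
                        c("GO:R", "GO:C", "GO:C", "GO:B", "GO:B"),
                        rep("BP", 5))
  d <- dissimilarity_matrix(c("p1", "p2", "p3", "p4"), "BP", dag, ann)
  sol <- pam_cluster(d, 2)
  cl_p1 <- unname(sol$assignment["p1"])
  expect_true("p1" %in% sol$medoids)
  expect_equal(label_cluster(sol, cl_p1, "BP", dag, ann), "c")
  expect_equal(label_cluster(sol, cl_p1, "BP", dag, ann,
                             overrides = setNames("Custom", cl_p1)),
               "Custom")

  # information content equals brute-force frequency counting
  ic <- term_ic(c("p1", "p2", "p3", "p4"), "BP", dag, ann)
  sets <- lapply(list(c("GO:R", "GO:C"), "GO:C", "GO:B", "GO:B"),
                 closure_oracle, edges = dag$edges)
  for (t in names(ic)) {
    freq <- mean(vapply(sets, function(s) t %in% s, logical(1)))
    expect_equal(unname(ic[t]), -log(freq))
  }
  expect_equal(unname(ic["GO:R"]), 0)
})
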