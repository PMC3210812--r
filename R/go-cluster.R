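#' Induced annotation term set of a protein
#'
#' The protein's direct annotations in an aspect together with all their
#' ancestors via \code{is_a} (and, by default, \code{part_of}) relations, up
#' to and including the aspect root. This induced set is the object the
#' simUI similarity compares.
#'
#' @param protein protein identifier.
#' @param aspect one of \code{"BP"}, \code{"MF"}, \code{"CC"}.
#' @param dag a [go_dag()].
#' @param annotations a [go_annotations()] data frame.
#' @param include_part_of follow \code{part_of} edges as well as
#'   \code{is_a}.
#' @return Character vector of term ids (unordered set).
#' @export
induced_terms <- function(protein, aspect, dag, annotations,
                          include_part_of = TRUE) {
  direct <- annotations$term_id[annotations$protein_id == protein &
                                  annotations$aspect == aspect]
  if (!length(direct))
    stop("lookup error: protein ", protein, " has no ", aspect,
         " annotation", call. = FALSE)
  .ancestral_closure(direct, dag, include_part_of)
}

.parent_map <- function(dag, include_part_of) {
  e <- dag$edges
  if (!include_part_of) e <- e[e$relation == "is_a", , drop = FALSE]
  split(e$parent, e$child)
}

.ancestral_closure <- function(direct, dag, include_part_of = TRUE,
                               parents = NULL) {
  if (is.null(parents)) parents <- .parent_map(dag, include_part_of)
  seen <- unique(direct)
  frontier <- seen
  while (length(frontier)) {
    up <- unique(unlist(parents[frontier], use.names = FALSE))
    frontier <- setdiff(up, seen)
    seen <- c(seen, frontier)
  }
  seen
}

# induced sets for many proteins, sharing one parent map
.induced_sets <- function(proteins, aspect, dag, annotations,
                          include_part_of = TRUE) {
  parents <- .parent_map(dag, include_part_of)
  ann <- annotations[annotations$aspect == aspect, , drop = FALSE]
  direct <- split(ann$term_id, ann$protein_id)
  setNames(lapply(proteins, function(p) {
    d <- direct[[p]]
    if (is.null(d))
      stop("lookup error: protein ", p, " has no ", aspect, " annotation",
           call. = FALSE)
    .ancestral_closure(d, dag, parents = parents)
  }), proteins)
}

#' simUI annotation similarity between two proteins
#'
#' Graph-based union-intersection similarity: the size of the intersection
#' of the two proteins' induced annotation term sets divided by the size of
#' their union. Ranges over \code{[0, 1]}; equals 1 exactly when the induced
#' sets coincide.
#'
#' @inheritParams induced_terms
#' @param protein_a,protein_b protein identifiers.
#' @return Similarity in \code{[0, 1]}.
#' @export
simui_similarity <- function(protein_a, protein_b, aspect, dag, annotations,
                             include_part_of = TRUE) {
  sets <- .induced_sets(c(protein_a, protein_b), aspect, dag, annotations,
                        include_part_of)
  length(intersect(sets[[1]], sets[[2]])) / length(union(sets[[1]], sets[[2]]))
}

#' Pairwise simUI dissimilarity matrix
#'
#' Computes \code{1 - simUI} for every pair of proteins in an aspect.
#' Proteins with no annotation in the aspect are excluded with a message.
#'
#' @inheritParams induced_terms
#' @param proteins character vector of protein identifiers.
#' @return Symmetric numeric matrix with zero diagonal, dimnames set to the
#'   (annotated) proteins.
#' @export
dissimilarity_matrix <- function(proteins, aspect, dag, annotations,
                                 include_part_of = TRUE) {
  proteins <- unique(proteins)
  annotated <- unique(annotations$protein_id[annotations$aspect == aspect])
  dropped <- setdiff(proteins, annotated)
  if (length(dropped)) {
    message("dissimilarity_matrix: excluding ", length(dropped),
            " protein(s) without ", aspect, " annotation: ",
            paste(dropped, collapse = ", "))
    proteins <- setdiff(proteins, dropped)
  }
  if (length(proteins) < 3L)
    stop("processing error: fewer than 3 annotated proteins", call. = FALSE)
  sets <- .induced_sets(proteins, aspect, dag, annotations, include_part_of)
  n <- length(proteins)
  d <- matrix(0, n, n, dimnames = list(proteins, proteins))
  sizes <- lengths(sets)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      s <- inter / (sizes[i] + sizes[j] - inter)
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  d
}

.check_diss <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("dissimilarity matrix must be square", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop("dissimilarity matrix must be symmetric with zero diagonal",
         call. = FALSE)
  d
}

# minimum over columns of d[, idx]
.row_min <- function(d, idx) {
  do.call(pmin, lapply(idx, function(j) d[, j]))
}

#' Partitioning Around Medoids on a dissimilarity matrix
#'
#' Classical PAM: a greedy BUILD phase adds the medoid that most reduces the
#' total dissimilarity-to-nearest-medoid cost, then a steepest-descent SWAP
#' phase exchanges a medoid for a non-medoid whenever that strictly lowers
#' the cost, iterating to a local optimum. Fully deterministic: all ties are
#' broken by the lowest point index.
#'
#' @param d square symmetric dissimilarity matrix (zero diagonal).
#' @param k number of clusters, \code{1 <= k <= n}.
#' @param seed accepted for interface symmetry; the algorithm is
#'   deterministic and does not consume randomness.
#' @return Object of class \code{pam_solution}: list with \code{k},
#'   \code{medoids} (ids), \code{medoid_index}, \code{assignment} (named
#'   integer vector, protein -> cluster), \code{cost} (sum of
#'   dissimilarities to assigned medoids) and \code{avg_silhouette}
#'   (\code{NA} for \code{k = 1}).
#' @export
pam_cluster <- function(d, k, seed = NULL) {
  d <- .check_diss(d)
  n <- nrow(d)
  if (k < 1L || k > n)
    stop("usage error: k must satisfy 1 <= k <= n", call. = FALSE)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  # BUILD: start from the 1-medoid optimum, then greedy additions
  med <- which.min(colSums(d))
  while (length(med) < k) {
    dmin <- .row_min(d, med)
    best_j <- 0L; best_cost <- Inf
    for (j in setdiff(seq_len(n), med)) {
      cost_j <- sum(pmin(dmin, d[, j]))
      if (cost_j < best_cost) { best_cost <- cost_j; best_j <- j }
    }
    med <- c(med, best_j)
  }

  cost_of <- function(m) sum(.row_min(d, m))
  cost <- cost_of(med)

  # SWAP: steepest descent over all (medoid, non-medoid) exchanges; the
  # min-distance excluding each medoid is precomputed so a candidate swap
  # costs one pmin over the points
  repeat {
    best <- NULL; best_cost <- cost
    non_med <- setdiff(seq_len(n), med)
    for (mi in seq_along(med)) {
      dmin_excl <- if (length(med) > 1L) .row_min(d, med[-mi])
                   else rep(Inf, n)
      for (h in non_med) {
        cc <- sum(pmin(dmin_excl, d[, h]))
        if (cc < best_cost - 1e-12) { best_cost <- cc; best <- c(med[-mi], h) }
      }
    }
    if (is.null(best)) break
    med <- best; cost <- best_cost
  }
  med <- sort(med)

  assignment <- apply(d[, med, drop = FALSE], 1L, which.min)
  assignment[med] <- seq_along(med)  # a medoid belongs to its own cluster
  names(assignment) <- ids
  cost <- sum(d[cbind(seq_len(n), med[assignment])])
  avg_sil <- if (k > 1L && k < n)
    mean(silhouette_widths(d, assignment)) else if (k == n) 0 else NA_real_
  structure(list(k = as.integer(k), medoids = ids[med],
                 medoid_index = as.integer(med), assignment = assignment,
                 cost = cost, avg_silhouette = avg_sil),
            class = "pam_solution")
}

#' @export
print.pam_solution <- function(x, ...) {
  cat(sprintf("PAM solution: k = %d, cost = %.4f, avg silhouette = %s\n",
              x$k, x$cost,
              if (is.na(x$avg_silhouette)) "NA"
              else sprintf("%.3f", x$avg_silhouette)))
  cat("medoids:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

#' Silhouette widths of a clustering
#'
#' For each point, \code{s = (b - a) / max(a, b)} where \code{a} is the mean
#' dissimilarity to the other members of its own cluster and \code{b} the
#' smallest mean dissimilarity to any other cluster. Points in singleton
#' clusters receive \code{s = 0}.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param assignment integer cluster labels, one per row of \code{d}.
#' @return Numeric vector of widths in \code{[-1, 1]}, named like the rows
#'   of \code{d}.
#' @export
silhouette_widths <- function(d, assignment) {
  d <- .check_diss(d)
  n <- nrow(d)
  stopifnot(length(assignment) == n)
  clusters <- sort(unique(assignment))
  if (length(clusters) < 2L)
    stop("usage error: silhouette needs at least 2 clusters", call. = FALSE)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignment == assignment[i])
    own <- own[own != i]
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(clusters, assignment[i]), function(cl) {
      mean(d[i, assignment == cl])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  names(s) <- rownames(d)
  s
}

#' Select the number of clusters by average silhouette width
#'
#' Runs [pam_cluster()] for each candidate \code{k} and keeps the solution
#' with the largest average silhouette width (ties resolved toward the
#' smaller \code{k}).
#'
#' @param d square symmetric dissimilarity matrix.
#' @param k_min,k_max candidate range; \code{k_max} defaults to
#'   \code{min(15, n - 1)}.
#' @return List with \code{k} (selected), \code{solution} (the winning
#'   \code{pam_solution}) and \code{profile} (data frame of \code{k} and
#'   \code{avg_silhouette}).
#' @export
select_k <- function(d, k_min = 2L, k_max = NULL) {
  d <- .check_diss(d)
  n <- nrow(d)
  if (is.null(k_max)) k_max <- min(15L, n - 1L)
  if (!(2L <= k_min && k_min <= k_max && k_max <= n - 1L))
    stop("usage error: need 2 <= k_min <= k_max <= n - 1", call. = FALSE)
  ks <- seq.int(k_min, k_max)
  sols <- lapply(ks, function(k) pam_cluster(d, k))
  sil <- vapply(sols, `[[`, numeric(1), "avg_silhouette")
  best <- which.max(sil)  # first maximum = smallest k on ties
  list(k = ks[best], solution = sols[[best]],
       profile = data.frame(k = ks, avg_silhouette = sil))
}

.default_edge_threshold <- function(aspect) {
  switch(aspect, BP = 0.4, MF = 0.4, CC = 0.3,
         stop("usage error: unknown aspect '", aspect, "'", call. = FALSE))
}

#' Build a thresholded cluster network
#'
#' Nodes are the clustered proteins (medoids flagged and drawn larger);
#' edges connect every pair whose dissimilarity does not exceed the aspect's
#' edge threshold (edges strictly above the threshold are removed; the
#' default thresholds are 0.4 for BP and MF, 0.3 for CC). Edge display
#' width decreases linearly with dissimilarity so that near-identical
#' proteins are joined by thick dark edges.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param solution a \code{pam_solution} computed on \code{d}.
#' @param aspect one of \code{"BP"}, \code{"MF"}, \code{"CC"}.
#' @param edge_threshold override the aspect default.
#' @return Object of class \code{cluster_network}: list with \code{nodes}
#'   (protein, cluster, is_medoid, size), \code{edges} (from, to,
#'   dissimilarity, width), \code{aspect}, \code{edge_threshold}.
#' @export
cluster_network <- function(d, solution, aspect, edge_threshold = NULL) {
  d <- .check_diss(d)
  stopifnot(inherits(solution, "pam_solution"))
  if (is.null(edge_threshold))
    edge_threshold <- .default_edge_threshold(aspect)
  else .default_edge_threshold(aspect)  # still validates the aspect
  ids <- rownames(d)
  if (is.null(ids)) ids <- names(solution$assignment)
  nodes <- data.frame(
    protein = ids,
    cluster = as.integer(solution$assignment),
    is_medoid = ids %in% solution$medoids,
    stringsAsFactors = FALSE
  )
  nodes$size <- ifelse(nodes$is_medoid, 30, 15)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  keep <- d[pairs] <= edge_threshold
  pairs <- pairs[keep, , drop = FALSE]
  dv <- d[pairs]
  edges <- data.frame(
    from = ids[pairs[, 1]],
    to = ids[pairs[, 2]],
    dissimilarity = dv,
    width = 0.5 + 4.5 * (1 - dv),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges, aspect = aspect,
                 edge_threshold = edge_threshold),
            class = "cluster_network")
}

#' @export
print.cluster_network <- function(x, ...) {
  cat(sprintf("Cluster network (%s): %d nodes, %d edges (d <= %g)\n",
              x$aspect, nrow(x$nodes), nrow(x$edges), x$edge_threshold))
  invisible(x)
}

.network_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a cluster network as GraphML
#'
#' @param net a [cluster_network()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "cluster_network"))
  igraph::write_graph(.network_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Write a cluster network as SIF plus a node-attribute table
#'
#' The SIF file lists one \code{from sim to} line per retained edge;
#' isolated nodes appear as single-token lines. Node attributes (cluster,
#' medoid flag) are written alongside when \code{node_attr_path} is given.
#'
#' @param net a [cluster_network()].
#' @param path output SIF path.
#' @param node_attr_path optional TSV path for node attributes.
#' @return \code{path}, invisibly.
#' @export
write_network_sif <- function(net, path, node_attr_path = NULL) {
  stopifnot(inherits(net, "cluster_network"))
  lines <- sprintf("%s\tsim\t%s", net$edges$from, net$edges$to)
  isolated <- setdiff(net$nodes$protein,
                      unique(c(net$edges$from, net$edges$to)))
  writeLines(c(lines, isolated), path)
  if (!is.null(node_attr_path))
    write.table(net$nodes, node_attr_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Information content of terms over a protein set
#'
#' \code{IC(t) = -log(f(t))} where \code{f(t)} is the fraction of the given
#' proteins whose induced annotation set contains \code{t}. The aspect root
#' (induced for every protein) has IC 0.
#'
#' @inheritParams induced_terms
#' @param proteins proteins defining the corpus frequency.
#' @return Named numeric vector over the terms induced by at least one
#'   protein.
#' @export
term_ic <- function(proteins, aspect, dag, annotations,
                    include_part_of = TRUE) {
  sets <- .induced_sets(unique(proteins), aspect, dag, annotations,
                        include_part_of)
  counts <- table(unlist(sets, use.names = FALSE))
  setNames(-log(as.numeric(counts) / length(sets)), names(counts))
}

#' Label a cluster from its medoid's annotations
#'
#' The automated label is the name of the medoid's direct term with the
#' highest information content over the clustered proteins (ties to the
#' lexicographically smallest term id); a manual override table may replace
#' it, mirroring curated cluster naming.
#'
#' @inheritParams induced_terms
#' @param solution a \code{pam_solution}.
#' @param cluster cluster index.
#' @param overrides optional named character vector (cluster index as name
#'   -> label).
#' @return Label text.
#' @export
label_cluster <- function(solution, cluster, aspect, dag, annotations,
                          overrides = NULL, include_part_of = TRUE) {
  stopifnot(inherits(solution, "pam_solution"))
  if (!is.null(overrides) && as.character(cluster) %in% names(overrides))
    return(unname(overrides[[as.character(cluster)]]))
  medoid <- solution$medoids[cluster]
  direct <- annotations$term_id[annotations$protein_id == medoid &
                                  annotations$aspect == aspect]
  if (!length(direct))
    stop("lookup error: medoid ", medoid, " has no ", aspect,
         " annotation", call. = FALSE)
  ic <- term_ic(names(solution$assignment), aspect, dag, annotations,
                include_part_of)
  direct <- sort(unique(direct))
  best <- direct[which.max(ic[direct])]
  dag$terms$name[match(best, dag$terms$id)]
}
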