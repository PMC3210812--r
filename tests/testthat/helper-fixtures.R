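# Shared in-code fixtures and brute-force oracles.

# Chain-plus-branch DAG: R <- A <- C, R <- B (single BP root).
toy_dag <- function() {
  go_dag(
    terms = data.frame(
      id = c("GO:R", "GO:A", "GO:B", "GO:C"),
      name = c("root", "a", "b", "c"),
      namespace = "biological_process",
      stringsAsFactors = FALSE
    ),
    edges = data.frame(
      child = c("GO:A", "GO:B", "GO:C"),
      parent = c("GO:R", "GO:R", "GO:A"),
      relation = "is_a",
      stringsAsFactors = FALSE
    )
  )
}

# Depth-1 star: one root, one unique leaf per protein, each protein
# annotated only to its leaf.
star_corpus <- function(n) {
  leaves <- sprintf("GO:L%02d", seq_len(n))
  dag <- go_dag(
    terms = data.frame(
      id = c("GO:R", leaves),
      name = c("root", leaves),
      namespace = "biological_process",
      stringsAsFactors = FALSE
    ),
    edges = data.frame(child = leaves, parent = "GO:R", relation = "is_a",
                       stringsAsFactors = FALSE)
  )
  prot <- sprintf("p%02d", seq_len(n))
  list(dag = dag,
       annotations = go_annotations(prot, leaves, rep("BP", n)),
       proteins = prot)
}

# Brute-force ancestral closure: repeated parent-walking to fixpoint.
closure_oracle <- function(direct, edges) {
  seen <- unique(direct)
  repeat {
    up <- unique(edges$parent[edges$child %in% seen])
    new <- setdiff(up, seen)
    if (!length(new)) return(seen)
    seen <- c(seen, new)
  }
}

# Random symmetric dissimilarity matrix with zero diagonal.
random_diss <- function(n, values = stats::runif(n * (n - 1) / 2)) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- values
  d + t(d)
}

# Jaccard dissimilarity matrix from random subsets of a small universe.
random_jaccard_diss <- function(n, universe = 12L) {
  sets <- lapply(seq_len(n), function(i)
    sample(universe, sample(2:min(6, universe), 1)))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  d
}

# Global-optimum k-medoids cost by exhaustive enumeration of medoid subsets.
exhaustive_medoid_cost <- function(d, k) {
  n <- nrow(d)
  min(apply(utils::combn(n, k), 2, function(m)
    sum(apply(d[, m, drop = FALSE], 1, min))))
}

# Minimal hand-built slide: proteins in duplicate spots on one row-major
# grid, with explicit fg/bg/conc vectors (one value per spot).
toy_slide <- function(fg, bg, conc, proteins = NULL,
                      slide_id = "s1") {
  n <- length(fg)
  stopifnot(n %% 2 == 0)
  if (is.null(proteins))
    proteins <- rep(sprintf("pr%02d", seq_len(n / 2)), each = 2)
  data.frame(
    slide_id = slide_id, block = 1L, row = 1L, col = seq_len(n),
    protein_id = proteins, name = proteins,
    replicate_index = rep(c(1L, 2L), n / 2),
    fg = fg, bg = bg, conc = conc, stringsAsFactors = FALSE
  )
}

# Shipped printed C-termini of the arrayed PDZ-motif constructs.
array_ctermini_path <- function() {
  system.file("extdata", "lnx1_array_ctermini.tsv", package = "pdzscreen")
}
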