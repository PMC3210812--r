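#' Configuration for the synthetic GO annotation corpus
#'
#' Describes a toy ontology with latent protein groups: the single-root DAG
#' contains one subtree per group (a complete \code{branching}-ary tree of
#' \code{subtree_depth} levels hanging off the root), and each protein draws
#' its direct annotations from its own group's subtree except with
#' probability \code{noise_p} per annotation, when it draws from another
#' group's subtree.
#'
#' @param n_groups number of latent clusters.
#' @param proteins_per_group proteins per cluster.
#' @param subtree_depth levels per group subtree (the group's anchor term is
#'   level 1).
#' @param branching children per internal subtree term.
#' @param noise_p probability an annotation is drawn outside the group
#'   subtree.
#' @param terms_per_protein direct annotations per protein.
#' @param seed integer RNG seed.
#' @return Object of class \code{go_sim_config}.
#' @export
go_sim_config <- function(n_groups = 3L, proteins_per_group = 8L,
                          subtree_depth = 3L, branching = 3L,
                          noise_p = 0.05, terms_per_protein = 3L,
                          seed = 1L) {
  cfg <- list(
    n_groups = check_count(n_groups, "n_groups", min = 2L),
    proteins_per_group = check_count(proteins_per_group,
                                     "proteins_per_group", min = 1L),
    subtree_depth = check_count(subtree_depth, "subtree_depth", min = 1L),
    branching = check_count(branching, "branching", min = 1L),
    noise_p = check_number(noise_p, "noise_p", min = 0, max = 1),
    terms_per_protein = check_count(terms_per_protein, "terms_per_protein",
                                    min = 1L),
    seed = check_count(seed, "seed")
  )
  subtree_size <- sum(cfg$branching^(seq_len(cfg$subtree_depth) - 1L))
  if (subtree_size < cfg$terms_per_protein)
    stop_config("terms_per_protein",
                sprintf("exceeds the %d terms of each group subtree",
                        subtree_size))
  structure(cfg, class = "go_sim_config")
}

#' Simulate a group-structured GO annotation corpus
#'
#' Builds the ontology, the per-protein direct annotations (aspect BP) and
#' the latent group labels. With \code{noise_p = 0} every direct annotation
#' of every protein lies inside its group's subtree, so within-group simUI
#' similarity strictly dominates between-group similarity.
#'
#' @param cfg a [go_sim_config()].
#' @return List of class \code{go_simulation} with \code{dag} (a
#'   [go_dag()]), \code{annotations} (a [go_annotations()]), \code{truth}
#'   (data frame \code{protein_id}, \code{group}), \code{group_terms}
#'   (list of term ids per group) and \code{config}.
#' @export
simulate_go_corpus <- function(cfg) {
  if (!inherits(cfg, "go_sim_config"))
    stop_config("cfg", "must be a go_sim_config")
  withr::with_seed(cfg$seed, {
    root <- "GO:0000001"
    ids <- root
    names_ <- "biological_process"
    children <- character(); parents <- character()
    counter <- 1L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("GO:%07d", counter)
    }
    group_terms <- vector("list", cfg$n_groups)
    for (g in seq_len(cfg$n_groups)) {
      anchor <- new_id()
      ids <- c(ids, anchor)
      names_ <- c(names_, sprintf("group %d process", g))
      children <- c(children, anchor); parents <- c(parents, root)
      level <- anchor
      terms_g <- anchor
      depth <- 1L
      while (depth < cfg$subtree_depth) {
        nxt <- character()
        for (parent in level) {
          for (b in seq_len(cfg$branching)) {
            id <- new_id()
            ids <- c(ids, id)
            names_ <- c(names_, sprintf("group %d term %s", g, id))
            children <- c(children, id); parents <- c(parents, parent)
            nxt <- c(nxt, id)
          }
        }
        terms_g <- c(terms_g, nxt)
        level <- nxt
        depth <- depth + 1L
      }
      group_terms[[g]] <- terms_g
    }
    dag <- go_dag(
      data.frame(id = ids, name = names_,
                 namespace = "biological_process", stringsAsFactors = FALSE),
      data.frame(child = children, parent = parents, relation = "is_a",
                 stringsAsFactors = FALSE)
    )

    n_prot <- cfg$n_groups * cfg$proteins_per_group
    protein_id <- sprintf("PROT%03d", seq_len(n_prot))
    group <- rep(seq_len(cfg$n_groups), each = cfg$proteins_per_group)
    ann_protein <- character(); ann_term <- character()
    for (i in seq_len(n_prot)) {
      own <- group_terms[[group[i]]]
      other <- unlist(group_terms[-group[i]], use.names = FALSE)
      n_noise <- min(rbinom(1L, cfg$terms_per_protein, cfg$noise_p),
                     length(other))
      terms <- c(sample(own, cfg$terms_per_protein - n_noise),
                 if (n_noise > 0L) sample(other, n_noise))
      ann_protein <- c(ann_protein, rep(protein_id[i], length(terms)))
      ann_term <- c(ann_term, terms)
    }
    structure(list(
      dag = dag,
      annotations = go_annotations(ann_protein, ann_term,
                                   rep("BP", length(ann_term))),
      truth = data.frame(protein_id = protein_id, group = group,
                         stringsAsFactors = FALSE),
      group_terms = group_terms,
      config = cfg
    ), class = "go_simulation")
  })
}

#' @export
print.go_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated GO corpus: %d groups x %d proteins, %d terms, noise_p = %g\n",
    x$config$n_groups, x$config$proteins_per_group, nrow(x$dag$terms),
    x$config$noise_p))
  invisible(x)
}
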