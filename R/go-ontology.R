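#' Construct a GO DAG object
#'
#' Holds ontology terms, child-to-parent edges (\code{is_a} and optionally
#' \code{part_of}) and the root term of each namespace. Validates that the
#' graph is acyclic and that every non-root term reaches its namespace root.
#'
#' @param terms data frame with columns \code{id}, \code{name},
#'   \code{namespace} (one of \code{biological_process},
#'   \code{molecular_function}, \code{cellular_component}).
#' @param edges data frame with columns \code{child}, \code{parent},
#'   \code{relation} (\code{is_a} or \code{part_of}).
#' @return Object of class \code{go_dag} with elements \code{terms},
#'   \code{edges}, \code{roots} (named character, namespace -> root id).
#' @export
go_dag <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (anyDuplicated(terms$id))
    stop("integrity error: duplicated term ids", call. = FALSE)
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown))
    stop("integrity error: edges reference unknown terms: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       vertices = terms$id)
    if (!igraph::is_dag(g)) {
      cyc <- igraph::feedback_arc_set(g)
      member <- igraph::ends(g, cyc[1])[1]
      stop("integrity error: ontology contains a cycle involving term ",
           member, call. = FALSE)
    }
  }
  has_parent <- terms$id %in% edges$child
  roots <- vapply(split(terms$id[!has_parent], terms$namespace[!has_parent]),
                  function(ids) {
                    if (length(ids) != 1L)
                      stop("integrity error: namespace must have exactly one root, found: ",
                           paste(ids, collapse = ", "), call. = FALSE)
                    ids
                  }, character(1))
  structure(list(terms = terms, edges = edges, roots = roots),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO DAG: %d terms, %d edges, namespaces: %s\n",
              nrow(x$terms), nrow(x$edges),
              paste(names(x$roots), collapse = ", ")))
  invisible(x)
}

#' Write a GO DAG to an OBO 1.2 file
#'
#' @param dag a [go_dag()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  name_of <- setNames(dag$terms$name, dag$terms$id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", "ontology: synthetic-go", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    lines <- c("[Term]",
               paste0("id: ", id),
               paste0("name: ", dag$terms$name[i]),
               paste0("namespace: ", dag$terms$namespace[i]))
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, if (e$relation[j] == "is_a")
        paste0("is_a: ", e$parent[j], " ! ", name_of[[e$parent[j]]])
        else
        paste0("relationship: part_of ", e$parent[j], " ! ",
               name_of[[e$parent[j]]]))
    }
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads \code{[Term]} stanzas with their \code{is_a} and
#' \code{relationship: part_of} links. Obsolete terms are skipped with a
#' warning; acyclicity and single-root structure are verified.
#'
#' @param path OBO file path.
#' @return A [go_dag()].
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  ids <- character(); names_ <- character(); ns <- character()
  children <- character(); parents <- character(); relations <- character()
  n_obsolete <- 0L
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    stanza <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    other <- which(startsWith(stanza, "["))  # e.g. a trailing [Typedef]
    if (length(other)) stanza <- stanza[seq_len(other[1] - 1L)]
    stanza <- stanza[nzchar(stanza)]
    field <- function(tag) sub(paste0("^", tag, ": "), "",
                               grep(paste0("^", tag, ": "), stanza, value = TRUE))
    if (any(grepl("^is_obsolete: true", stanza))) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    id <- field("id")
    if (length(id) != 1L) next
    ids <- c(ids, id)
    nm <- field("name")
    names_ <- c(names_, if (length(nm)) nm[1] else id)
    nsp <- field("namespace")
    ns <- c(ns, if (length(nsp)) nsp[1] else "biological_process")
    for (p in field("is_a")) {
      children <- c(children, id)
      parents <- c(parents, sub(" !.*$", "", p))
      relations <- c(relations, "is_a")
    }
    rel <- grep("^relationship: part_of ", stanza, value = TRUE)
    for (p in rel) {
      children <- c(children, id)
      parents <- c(parents, sub(" !.*$", "",
                                sub("^relationship: part_of ", "", p)))
      relations <- c(relations, "part_of")
    }
  }
  if (n_obsolete > 0L)
    warning(n_obsolete, " obsolete term(s) skipped", call. = FALSE)
  keep <- parents %in% ids  # drop links into obsolete/unknown terms
  go_dag(data.frame(id = ids, name = names_, namespace = ns,
                    stringsAsFactors = FALSE),
         data.frame(child = children[keep], parent = parents[keep],
                    relation = relations[keep], stringsAsFactors = FALSE))
}

.ASPECT_NS <- c(BP = "biological_process", MF = "molecular_function",
                CC = "cellular_component")
.GAF_ASPECT <- c(P = "BP", F = "MF", C = "CC")

#' Construct an annotation set
#'
#' Direct GO annotations per protein and aspect.
#'
#' @param protein_id,term_id,aspect parallel vectors; \code{aspect} uses
#'   codes \code{BP}, \code{MF}, \code{CC}.
#' @return Data frame of class \code{go_annotations} with those columns,
#'   de-duplicated.
#' @export
go_annotations <- function(protein_id, term_id, aspect) {
  stopifnot(length(protein_id) == length(term_id),
            length(term_id) == length(aspect))
  if (!all(aspect %in% names(.ASPECT_NS)))
    stop("aspect must be one of BP, MF, CC", call. = FALSE)
  ann <- unique(data.frame(protein_id = as.character(protein_id),
                           term_id = as.character(term_id),
                           aspect = as.character(aspect),
                           stringsAsFactors = FALSE))
  class(ann) <- c("go_annotations", "data.frame")
  ann
}

#' Write annotations as a GAF 2.1 file
#'
#' @param annotations a [go_annotations()] data frame.
#' @param path output file path.
#' @param db database tag for column 1.
#' @param taxon taxon tag for column 13.
#' @return \code{path}, invisibly.
#' @export
write_gaf <- function(annotations, path, db = "SIM", taxon = "taxon:9606") {
  aspect_letter <- setNames(names(.GAF_ASPECT), .GAF_ASPECT)
  rows <- data.frame(
    db = db,
    id = annotations$protein_id,
    symbol = annotations$protein_id,
    qualifier = "",
    go_id = annotations$term_id,
    ref = "SIM:0000001",
    evidence = "IDA",
    with = "",
    aspect = aspect_letter[annotations$aspect],
    name = annotations$protein_id,
    synonym = "",
    type = "protein",
    taxon = taxon,
    date = "20110101",
    assigned_by = db,
    ext = "",
    form = "",
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  write.table(rows, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GAF 2.x annotation file
#'
#' Comment lines are skipped; rows with a \code{NOT} qualifier are dropped;
#' annotations to terms absent from the DAG are dropped with a warning.
#' Malformed rows (fewer than 15 columns) are skipped with their line
#' numbers logged; more than 10\% malformed rows is a format error.
#'
#' @param path GAF file path.
#' @param dag a [go_dag()]; used to validate term ids.
#' @return A [go_annotations()] data frame.
#' @export
read_gaf <- function(path, dag) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(inherits(dag, "go_dag"))
  lines <- readLines(path)
  data_idx <- which(!startsWith(lines, "!") & nzchar(lines))
  if (!length(data_idx))
    return(go_annotations(character(), character(), character()))
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  ok <- lengths(fields) >= 15L
  if (any(!ok)) {
    if (mean(!ok) > 0.10)
      stop("format error: more than 10% of GAF rows are malformed",
           call. = FALSE)
    message("read_gaf: skipped malformed line(s) ",
            paste(data_idx[!ok], collapse = ", "))
    fields <- fields[ok]
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  qualifier <- get(4L); go_id <- get(5L); aspect <- get(9L)
  protein <- get(2L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  unknown <- keep & !(go_id %in% dag$terms$id)
  if (any(unknown)) {
    warning("read_gaf: dropped ", sum(unknown),
            " annotation(s) to unknown terms", call. = FALSE)
    keep <- keep & !unknown
  }
  bad_aspect <- keep & !(aspect %in% names(.GAF_ASPECT))
  if (any(bad_aspect)) {
    warning("read_gaf: dropped ", sum(bad_aspect),
            " annotation(s) with unknown aspect", call. = FALSE)
    keep <- keep & !bad_aspect
  }
  go_annotations(protein[keep], go_id[keep],
                 unname(.GAF_ASPECT[aspect[keep]]))
}
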