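RECORD_STATUSES <- c("annotated", "utr3", "withdrawn",
                     "suppressed_noncoding", "nmd_candidate")
REMOVAL_STATUSES <- setdiff(RECORD_STATUSES, "annotated")

#' Keep only hits that correspond to annotated proteins
#'
#' Array spots can derive from cDNAs that do not encode an annotated
#' protein: 3' untranslated regions, records withdrawn during genome
#' annotation, records suppressed as non-coding, or nonsense-mediated-decay
#' candidates. This filter keeps records with status \code{annotated} and
#' tallies the removals by category; the tally always conserves the input
#' count.
#'
#' @param records data frame with a \code{record_status} column.
#' @return List with \code{kept} (the annotated records) and \code{tally}
#'   (named integer over the four removal statuses).
#' @export
filter_annotated <- function(records) {
  if (!"record_status" %in% names(records))
    stop("records must have a 'record_status' column", call. = FALSE)
  bad <- setdiff(unique(records$record_status), RECORD_STATUSES)
  if (length(bad))
    stop("validation error: unknown record_status value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  kept <- records[records$record_status == "annotated", , drop = FALSE]
  removed <- records$record_status[records$record_status != "annotated"]
  tally <- setNames(integer(length(REMOVAL_STATUSES)), REMOVAL_STATUSES)
  counts <- table(removed)
  tally[names(counts)] <- as.integer(counts)
  list(kept = kept, tally = tally)
}

.as_source_list <- function(x) {
  if (is.list(x)) return(lapply(x, as.character))
  strsplit(as.character(x), ";", fixed = TRUE)
}

#' Merge interactor lists from multiple sources
#'
#' Unifies records by gene identifier: the merged record carries the union
#' of provenance source tags; symbol and other fields resolve to the
#' first-seen non-missing value (conflicting symbols are logged). Merging
#' is idempotent and insensitive to list order up to record order.
#'
#' @param ... interactor data frames, each with at least \code{gene_id} and
#'   either a \code{source} column (single tag, or \code{;}-separated) or a
#'   \code{sources} list-column; a single list of such data frames is also
#'   accepted. Optional columns \code{symbol}, \code{species},
#'   \code{record_status}, \code{cterm} are carried through.
#' @return Data frame with one row per distinct \code{gene_id} (first-seen
#'   order) and a \code{sources} list-column of sorted unique tags.
#' @export
merge_sources <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1]]) && !is.data.frame(lists[[1]]))
    lists <- lists[[1]]
  optional <- c("symbol", "species", "record_status", "cterm")
  rows <- lapply(lists, function(l) {
    if (!"gene_id" %in% names(l) || anyNA(l$gene_id) ||
        any(!nzchar(as.character(l$gene_id))))
      stop("validation error: every record needs a gene_id", call. = FALSE)
    src <- if ("sources" %in% names(l)) .as_source_list(l$sources)
           else if ("source" %in% names(l)) .as_source_list(l$source)
           else stop("validation error: every record needs a source tag",
                     call. = FALSE)
    out <- data.frame(gene_id = as.character(l$gene_id),
                      stringsAsFactors = FALSE)
    for (col in optional)
      out[[col]] <- if (col %in% names(l)) as.character(l[[col]])
                    else NA_character_
    out$sources <- I(src)
    out
  })
  all_rows <- do.call(rbind, rows)
  ids <- unique(all_rows$gene_id)
  merged <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  first_non_na <- function(v) {
    v <- v[!is.na(v) & nzchar(v)]
    if (length(v)) v[1] else NA_character_
  }
  for (col in optional) {
    vals <- split(all_rows[[col]], factor(all_rows$gene_id, levels = ids))
    merged[[col]] <- vapply(vals, first_non_na, character(1))
  }
  conflicts <- vapply(
    split(all_rows$symbol, factor(all_rows$gene_id, levels = ids)),
    function(v) length(unique(v[!is.na(v) & nzchar(v)])) > 1L, logical(1))
  if (any(conflicts))
    message("merge_sources: symbol conflicts resolved first-seen for ",
            paste(ids[conflicts], collapse = ", "))
  src <- split(all_rows$sources, factor(all_rows$gene_id, levels = ids))
  merged$sources <- I(lapply(src, function(s)
    sort(unique(unlist(s, use.names = FALSE)))))
  rownames(merged) <- NULL
  merged
}

#' Write an interactor list as TSV
#'
#' @param records merged interactor data frame (see [merge_sources()]).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_interactors <- function(records, path) {
  out <- records
  if (is.list(out$sources))
    out$sources <- vapply(out$sources, paste, character(1), collapse = ";")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interactor list from TSV
#'
#' @param path input file with header (at least \code{gene_id}; a
#'   \code{source} or \code{;}-separated \code{sources} column).
#' @return Data frame with a \code{sources} list-column.
#' @export
read_interactors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene_id = "character"))
  if ("sources" %in% names(tab)) tab$sources <- I(.as_source_list(tab$sources))
  else if ("source" %in% names(tab)) tab$sources <- I(.as_source_list(tab$source))
  tab
}

#' Pairwise overlaps among named identifier sets
#'
#' @param sets named list (length >= 2) of identifier vectors.
#' @return List with \code{counts} (symmetric matrix of intersection sizes,
#'   diagonal = set sizes) and \code{shared_fraction} (per set, the fraction
#'   of its members found in at least one other set).
#' @export
overlap_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("usage error: overlap_counts needs >= 2 sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  k <- length(sets)
  m <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    m[i, i] <- length(sets[[i]])
    for (j in seq_len(k)) {
      if (j != i) m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  shared <- vapply(seq_len(k), function(i) {
    others <- unique(unlist(sets[-i], use.names = FALSE))
    if (!length(sets[[i]])) return(0)
    mean(sets[[i]] %in% others)
  }, numeric(1))
  list(counts = m, shared_fraction = setNames(shared, names(sets)))
}

#' Domain-category enrichment of a hit list
#'
#' Compares the proportion of hits in an annotation category (e.g. protein
#' kinases) with the proportion on the whole array, reporting percentages
#' rounded to one decimal (round-half-even) and fold change. As a
#' convenience beyond the raw proportions, an upper-tail hypergeometric
#' probability \code{P(X >= hits_in_category)} is attached (population =
#' background, successes = background members of the category, draws =
#' hits).
#'
#' @param hits character vector of hit identifiers (must be a subset of
#'   \code{background}).
#' @param category_ids identifiers belonging to the category, defined on
#'   the background.
#' @param background character vector of all assayed identifiers.
#' @return One-row data frame: \code{hits_in_category, hits_total,
#'   bg_in_category, bg_total, hit_pct, bg_pct, fold, p_value}.
#' @export
domain_enrichment <- function(hits, category_ids, background) {
  hits <- unique(hits); background <- unique(background)
  category_ids <- unique(category_ids)
  outside <- setdiff(hits, background)
  if (length(outside))
    stop("validation error: hit(s) not in background: ",
         paste(outside, collapse = ", "), call. = FALSE)
  k <- sum(hits %in% category_ids)
  n <- length(hits)
  m <- sum(background %in% category_ids)
  N <- length(background)
  hit_pct <- round(100 * k / n, 1)
  bg_pct <- round(100 * m / N, 1)
  data.frame(
    hits_in_category = k, hits_total = n,
    bg_in_category = m, bg_total = N,
    hit_pct = hit_pct, bg_pct = bg_pct,
    fold = if (bg_pct > 0) hit_pct / bg_pct else NA_real_,
    p_value = phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  )
}
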