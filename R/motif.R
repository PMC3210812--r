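#' Default hydrophobic residue set for the PDZ 0 position
#'
#' The residues accepted as "hydrophobic" at the C-terminal (0) position of
#' a PDZ ligand. Glycine is included — small C-terminal Gly termini behave
#' as the major hydrophobic-0 ligand class on arrays — and cysteine is
#' deliberately excluded because terminal-Cys ligands form their own,
#' non-canonical class.
#'
#' @return Character vector of one-letter codes.
#' @export
default_hydrophobic <- function() {
  c("A", "F", "G", "I", "L", "M", "V", "W", "Y")
}

#' Default conservative substitution groups
#'
#' Standard physicochemical residue classes used when matching C-termini
#' under conservative substitutions: hydroxyl (S/T), aliphatic
#' (A/V/L/I/M), aromatic (F/Y/W), basic (K/R/H), acidic (D/E), amide
#' (N/Q), and the singleton classes C, G, P.
#'
#' @return Named list of character vectors covering the 20 amino acids.
#' @export
default_substitution_groups <- function() {
  list(hydroxyl = c("S", "T"),
       aliphatic = c("A", "V", "L", "I", "M"),
       aromatic = c("F", "Y", "W"),
       basic = c("K", "R", "H"),
       acidic = c("D", "E"),
       amide = c("N", "Q"),
       cysteine = "C",
       glycine = "G",
       proline = "P")
}

.clean_seq <- function(x) {
  toupper(gsub("[*[:space:]]", "", x))
}

.check_residues <- function(x, what = "sequence") {
  letters_used <- unique(unlist(strsplit(x, ""), use.names = FALSE))
  bad <- setdiff(letters_used, AA20)
  if (length(bad))
    stop("validation error: non-standard residue(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Extract a C-terminal peptide
#'
#' Returns the last \code{n} residues of a protein sequence (the whole
#' sequence when shorter), after stripping whitespace and stop markers.
#' Position 0 is the C-terminal residue; positions count 0, -1, -2, ...
#' leftward.
#'
#' @param sequence protein sequence(s), one-letter code; may contain spaces
#'   and \code{*} stop markers.
#' @param n number of C-terminal residues to keep (default 12).
#' @return Character vector of C-terminal peptides.
#' @export
extract_cterm <- function(sequence, n = 12L) {
  n <- check_count(n, "n", min = 1L)
  s <- .clean_seq(sequence)
  if (any(!nzchar(s)))
    stop("validation error: empty sequence", call. = FALSE)
  str_suffix(s, n)
}

#' Classify a C-terminus into PDZ-binding motif classes
#'
#' Classes, in precedence order: \code{cys_terminal} (position 0 is Cys, a
#' non-canonical ligand class), \code{class1} (Ser/Thr at -2 and a
#' hydrophobic residue at 0, the classical S/T-X-Phi motif),
#' \code{hydrophobic_0} (hydrophobic 0 position without the -2 Ser/Thr),
#' and \code{other}.
#'
#' @param cterm C-terminal peptide(s), at least 3 residues.
#' @param hydrophobic_set residues accepted as hydrophobic at position 0.
#' @return Data frame: \code{sequence, residue_0, residue_minus2,
#'   motif_class} (factor-free character).
#' @export
classify_cterm <- function(cterm, hydrophobic_set = default_hydrophobic()) {
  s <- .clean_seq(cterm)
  if (any(nchar(s) < 3L))
    stop("validation error: C-terminus shorter than 3 residues",
         call. = FALSE)
  .check_residues(s, "C-terminus")
  r0 <- residue_at(s, 0L)
  r2 <- residue_at(s, -2L)
  cls <- ifelse(r0 == "C", "cys_terminal",
         ifelse(r2 %in% c("S", "T") & r0 %in% hydrophobic_set, "class1",
         ifelse(r0 %in% hydrophobic_set, "hydrophobic_0", "other")))
  out <- data.frame(sequence = s, residue_0 = r0, residue_minus2 = r2,
                    motif_class = cls, stringsAsFactors = FALSE)
  if (!is.null(names(cterm))) out <- cbind(protein_id = names(cterm), out)
  rownames(out) <- NULL
  out
}

#' Compare an arrayed construct's C-terminus to the wild-type terminus
#'
#' Array constructs made from partial cDNAs can carry artificially created
#' C-terminal tails. An entry whose wild-type field is the token \code{WT}
#' or an identical sequence is a \code{natural_terminus}; a differing
#' wild-type sequence marks an \code{artificial_tail}; the token
#' \dQuote{Not translated to protein} marks \code{not_translated}.
#'
#' @param array_cterm C-terminus as spotted on the array.
#' @param wildtype_entry wild-type field: a sequence, \code{"WT"}, or
#'   \code{"Not translated to protein"}.
#' @return Character vector of statuses: \code{natural_terminus},
#'   \code{artificial_tail} or \code{not_translated}.
#' @export
compare_to_wildtype <- function(array_cterm, wildtype_entry) {
  if (length(array_cterm) != length(wildtype_entry))
    stop("validation error: inputs must have equal length", call. = FALSE)
  if (anyNA(wildtype_entry) || any(!nzchar(trimws(wildtype_entry))))
    stop("validation error: missing wild-type field", call. = FALSE)
  wt <- trimws(wildtype_entry)
  is_wt_token <- toupper(wt) == "WT"
  is_nt <- grepl("not translated", wt, ignore.case = TRUE)
  a <- .clean_seq(array_cterm)
  w <- .clean_seq(wt)
  ifelse(is_nt, "not_translated",
         ifelse(is_wt_token | a == w, "natural_terminus", "artificial_tail"))
}

#' Match C-termini under conservative substitutions
#'
#' A candidate matches the query when, at each of the final three positions
#' (-2, -1, 0), its residue belongs to the same substitution group as the
#' query's residue. Exact matches always match; the relation is symmetric.
#'
#' @param query_cterm query C-terminus (>= 3 residues).
#' @param candidates character vector of candidate C-termini (>= 3
#'   residues), optionally named.
#' @param groups substitution groups; see
#'   [default_substitution_groups()].
#' @return The matching elements of \code{candidates} (named if
#'   \code{candidates} was named).
#' @export
conservative_match <- function(query_cterm, candidates,
                               groups = default_substitution_groups()) {
  group_of <- unlist(lapply(seq_along(groups), function(i)
    setNames(rep(i, length(groups[[i]])), groups[[i]])))
  lookup <- function(res, what) {
    g <- group_of[res]
    if (anyNA(g))
      stop("validation error: residue(s) not in any substitution group: ",
           paste(unique(res[is.na(g)]), collapse = ", "), call. = FALSE)
    g
  }
  q <- .clean_seq(query_cterm)
  cand <- .clean_seq(candidates)
  if (nchar(q) < 3L || any(nchar(cand) < 3L))
    stop("validation error: C-termini need >= 3 residues", call. = FALSE)
  qg <- lookup(strsplit(str_suffix(q, 3L), "")[[1]])
  ok <- vapply(cand, function(s) {
    all(lookup(strsplit(str_suffix(s, 3L), "")[[1]]) == qg)
  }, logical(1), USE.NAMES = FALSE)
  candidates[ok]
}

#' Binding-site identity between two PDZ domains and the transfer rule
#'
#' Percent identity over the 17 ligand-contacting binding-site residues.
#' Above 70\% identity (strict), the binding specificity of one domain is
#' predicted to transfer to the other.
#'
#' @param site_a,site_b 17-residue binding-site strings.
#' @return List with \code{identity} (percent) and \code{transfer}
#'   (logical).
#' @export
binding_site_identity <- function(site_a, site_b) {
  a <- .clean_seq(site_a); b <- .clean_seq(site_b)
  if (nchar(a) != 17L || nchar(b) != 17L)
    stop("validation error: binding sites must be exactly 17 residues",
         call. = FALSE)
  matches <- sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  identity <- 100 * matches / 17
  list(identity = identity, transfer = identity > 70)
}
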