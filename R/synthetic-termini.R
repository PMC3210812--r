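#' Configuration for the synthetic C-terminal peptide set
#'
#' Plants PDZ-binding motifs into random C-terminal peptides: Class I
#' sequences carry Ser/Thr at position -2 and a hydrophobic residue at
#' position 0; terminal-cysteine sequences end in Cys. Planted counts are
#' the fractions rounded down. When any planting fraction is positive the
#' remaining background sequences avoid all motif signatures (so planted
#' classes are recoverable exactly); with both fractions zero, sequences are
#' drawn uniformly over the twenty amino acids.
#'
#' @param n_seqs number of peptides.
#' @param frac_class1 fraction planted as Class I motifs.
#' @param frac_cys fraction planted with a terminal cysteine.
#' @param length peptide length in residues (default 12).
#' @param seed integer RNG seed.
#' @return Object of class \code{termini_sim_config}.
#' @export
termini_sim_config <- function(n_seqs, frac_class1 = 0, frac_cys = 0,
                               length = 12L, seed = 1L) {
  cfg <- list(
    n_seqs = check_count(n_seqs, "n_seqs", min = 1L),
    frac_class1 = check_number(frac_class1, "frac_class1", min = 0, max = 1),
    frac_cys = check_number(frac_cys, "frac_cys", min = 0, max = 1),
    length = check_count(length, "length", min = 3L),
    seed = check_count(seed, "seed")
  )
  if (cfg$frac_class1 + cfg$frac_cys > 1)
    stop_config("frac_class1", "plus frac_cys must not exceed 1")
  structure(cfg, class = "termini_sim_config")
}

#' Simulate C-terminal peptides with planted PDZ motifs
#'
#' @param cfg a [termini_sim_config()].
#' @return List of class \code{termini_simulation} with \code{sequences}
#'   (named character vector of peptides) and \code{truth} (data frame
#'   \code{protein_id}, \code{planted} with values \code{class1},
#'   \code{cys_terminal} or \code{background}), plus \code{config}.
#' @export
simulate_termini <- function(cfg) {
  if (!inherits(cfg, "termini_sim_config"))
    stop_config("cfg", "must be a termini_sim_config")
  withr::with_seed(cfg$seed, {
    n <- cfg$n_seqs
    n_c1 <- floor(cfg$frac_class1 * n)
    n_cys <- floor(cfg$frac_cys * n)
    planted_mode <- n_c1 + n_cys > 0L
    hyd <- default_hydrophobic()
    rand_seq <- function(len) {
      paste(sample(AA20, len, replace = TRUE), collapse = "")
    }
    label <- c(rep("class1", n_c1), rep("cys_terminal", n_cys),
               rep("background", n - n_c1 - n_cys))
    seqs <- vapply(seq_len(n), function(i) {
      s <- strsplit(rand_seq(cfg$length), "")[[1]]
      L <- cfg$length
      if (label[i] == "class1") {
        s[L - 2L] <- sample(c("S", "T"), 1L)
        s[L] <- sample(hyd, 1L)
      } else if (label[i] == "cys_terminal") {
        s[L] <- "C"
      } else if (planted_mode) {
        # background must classify as "other": terminal residue neither
        # hydrophobic nor cysteine
        s[L] <- sample(setdiff(AA20, c(hyd, "C")), 1L)
      }
      paste(s, collapse = "")
    }, character(1))
    protein_id <- sprintf("SEQ%04d", seq_len(n))
    names(seqs) <- protein_id
    structure(list(
      sequences = seqs,
      truth = data.frame(protein_id = protein_id, planted = label,
                         stringsAsFactors = FALSE),
      config = cfg
    ), class = "termini_simulation")
  })
}

#' Write peptides as a FASTA file
#'
#' @param sequences named character vector of peptide sequences.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_termini_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read C-termini from FASTA or two-column TSV
#'
#' @param path input file; FASTA when the first non-blank character is
#'   \code{>}, otherwise a header-less or headed two-column TSV
#'   (id, sequence).
#' @return Named character vector of sequences.
#' @export
read_ctermini <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (startsWith(trimws(first), ">")) {
    x <- Biostrings::readAAStringSet(path)
    return(setNames(as.character(x), names(x)))
  }
  first_fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- any(grepl("^(id|protein|name|symbol|seq|sequence|cterm)",
                          first_fields, ignore.case = TRUE))
  tab <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}
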