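#' Configuration for the synthetic protein-array experiment
#'
#' Describes a simulated single-channel protein microarray screen in which
#' every protein is printed twice per slide (adjacent duplicate spots) and a
#' small set of planted binders carries a multiplicative signal boost over
#' the slide background. The background is log-normal per spot, modulated by
#' a smooth low-frequency spatial surface; the specific signal scales with
#' the square root of the printed concentration (saturating, as real arrays
#' do), mean-normalised so that the average planted net signal is
#' \code{effect_size} times the average background.
#'
#' @param n_proteins number of distinct proteins printed on each slide.
#' @param n_planted number of planted true binders (\code{<= n_proteins}).
#' @param n_slides number of replicate slides (default 2, the duplicate-slide
#'   screen design).
#' @param effect_size multiplicative net-signal boost of planted binders
#'   relative to background (fold, must exceed 1).
#' @param bg_log_mean,bg_log_sd meanlog and sdlog of the per-spot log-normal
#'   background fluorescence.
#' @param spatial_amp amplitude of the smooth spatial trend, as a fraction of
#'   the background level (sum of two sinusoids in row and column).
#' @param replicate_noise_cv coefficient of variation of the per-spot
#'   multiplicative signal noise (drives the duplicate-spot CV).
#' @param conc_range length-2 range of printed concentrations (ng/uL); spot
#'   concentrations are drawn log-uniformly over this range.
#' @param seed integer RNG seed; identical seeds give byte-identical output.
#'
#' @return An object of class \code{array_sim_config}.
#' @seealso [simulate_array_experiment()]
#' @export
array_sim_config <- function(n_proteins, n_planted, n_slides = 2L,
                             effect_size = 8, bg_log_mean = log(200),
                             bg_log_sd = 0.35, spatial_amp = 0.3,
                             replicate_noise_cv = 0.10,
                             conc_range = c(4, 250), seed = 1L) {
  cfg <- list(
    n_proteins = check_count(n_proteins, "n_proteins", min = 1L),
    n_planted = check_count(n_planted, "n_planted", min = 0L),
    n_slides = check_count(n_slides, "n_slides", min = 1L),
    effect_size = check_number(effect_size, "effect_size", min = 1, strict_min = TRUE),
    bg_log_mean = check_number(bg_log_mean, "bg_log_mean"),
    bg_log_sd = check_number(bg_log_sd, "bg_log_sd", min = 0),
    spatial_amp = check_number(spatial_amp, "spatial_amp", min = 0, max = 0.95),
    replicate_noise_cv = check_number(replicate_noise_cv, "replicate_noise_cv", min = 0),
    seed = check_count(seed, "seed")
  )
  if (length(conc_range) != 2L || !is.numeric(conc_range) ||
      any(conc_range <= 0) || conc_range[1] > conc_range[2])
    stop_config("conc_range", "must be an increasing positive length-2 range")
  cfg$conc_range <- as.numeric(conc_range)
  if (cfg$n_planted > cfg$n_proteins)
    stop_config("n_planted", "must not exceed n_proteins")
  structure(cfg, class = "array_sim_config")
}

# mean of sqrt(C) for C log-uniform on [a, b]
.mean_sqrt_loguniform <- function(a, b) {
  if (a == b) return(sqrt(a))
  2 * (sqrt(b) - sqrt(a)) / (log(b) - log(a))
}

#' Simulate a duplicate-spot protein-array screen
#'
#' Generates spot-level fluorescence tables for \code{n_slides} replicate
#' slides, each printing every protein in two adjacent spots, together with
#' the identities of the planted binders. Reported local background equals
#' the realised background draw, so the expected net signal of a planted
#' binder is \code{effect_size} times the local background trend, while
#' non-planted proteins sit at background level (effect 1).
#'
#' @param cfg an [array_sim_config()].
#' @return A list of class \code{array_simulation} with elements
#'   \describe{
#'     \item{slides}{named list of per-slide spot data frames with columns
#'       \code{slide_id, block, row, col, protein_id, name,
#'       replicate_index, fg, bg, conc}.}
#'     \item{truth}{character vector of planted binder protein IDs.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_array_experiment(array_sim_config(50, 3, seed = 7))
#' nrow(sim$slides[[1]])  # 100: every protein spotted twice
#' @export
simulate_array_experiment <- function(cfg) {
  if (!inherits(cfg, "array_sim_config"))
    stop_config("cfg", "must be an array_sim_config")
  withr::with_seed(cfg$seed, {
    n <- cfg$n_proteins
    protein_id <- sprintf("P%04d", seq_len(n))
    planted <- sort(sample(protein_id, cfg$n_planted))

    # pair layout: one block, each protein in two adjacent columns of a row
    pair_cols <- ceiling(sqrt(n))
    n_rows <- ceiling(n / pair_cols)
    pair_row <- ((seq_len(n) - 1L) %/% pair_cols) + 1L
    pair_col <- ((seq_len(n) - 1L) %% pair_cols) + 1L

    # smooth spatial surface, identical for both members of a duplicate pair
    trend <- 1 + cfg$spatial_amp *
      (sin(2 * pi * pair_row / n_rows) + sin(2 * pi * pair_col / pair_cols)) / 2

    conc <- exp(runif(n, log(cfg$conc_range[1]), log(cfg$conc_range[2])))
    conc_fac <- sqrt(conc) /
      .mean_sqrt_loguniform(cfg$conc_range[1], cfg$conc_range[2])

    base <- exp(cfg$bg_log_mean + cfg$bg_log_sd^2 / 2)
    effect <- ifelse(protein_id %in% planted, cfg$effect_size, 1)
    expected_signal <- base * effect * conc_fac * trend

    sdlog_eps <- sqrt(log1p(cfg$replicate_noise_cv^2))

    slides <- lapply(seq_len(cfg$n_slides), function(s) {
      idx <- rep(seq_len(n), each = 2L)
      rep_i <- rep(c(1L, 2L), times = n)
      bg <- trend[idx] * rlnorm(2L * n, cfg$bg_log_mean, cfg$bg_log_sd)
      eps <- if (sdlog_eps == 0) rep(1, 2L * n)
             else rlnorm(2L * n, -sdlog_eps^2 / 2, sdlog_eps)
      fg <- bg + expected_signal[idx] * eps
      data.frame(
        slide_id = sprintf("slide_%02d", s),
        block = 1L,
        row = pair_row[idx],
        col = 2L * (pair_col[idx] - 1L) + rep_i,
        protein_id = protein_id[idx],
        name = protein_id[idx],
        replicate_index = rep_i,
        fg = fg,
        bg = bg,
        conc = conc[idx],
        stringsAsFactors = FALSE
      )
    })
    names(slides) <- vapply(slides, function(s) s$slide_id[1], character(1))
    structure(list(slides = slides, truth = planted, config = cfg),
              class = "array_simulation")
  })
}

#' Column dialect for GenePix-Results-style spot tables
#'
#' Maps the canonical spot-record fields onto the column headers of a
#' tab-separated results file. The default matches the headers written by
#' [write_spot_table()].
#'
#' @param block,row,col,protein_id,name,fg,bg,conc file column names.
#' @return Named character vector (canonical field -> file column).
#' @export
genepix_dialect <- function(block = "Block", row = "Row", col = "Column",
                            protein_id = "ID", name = "Name",
                            fg = "F635 Median", bg = "B635 Median",
                            conc = "Concentration") {
  c(block = block, row = row, col = col, protein_id = protein_id,
    name = name, fg = fg, bg = bg, conc = conc)
}

#' Write a spot table as a GenePix-Results-style TSV
#'
#' @param spots a per-slide spot data frame (see
#'   [simulate_array_experiment()]).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  out <- data.frame(
    Block = spots$block, Row = spots$row, Column = spots$col,
    ID = spots$protein_id, Name = spots$name,
    `F635 Median` = spots$fg, `B635 Median` = spots$bg,
    Concentration = spots$conc,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spot table
#'
#' Parses a tab-separated spot-level results file into the canonical
#' spot-record layout. Duplicate-pair replicate indices are assigned by
#' order of appearance within each protein.
#'
#' @param path file path.
#' @param slide_id slide identifier to attach; defaults to the file name
#'   without extension.
#' @param dialect column mapping, see [genepix_dialect()].
#' @return Spot data frame with columns \code{slide_id, block, row, col,
#'   protein_id, name, replicate_index, fg, bg, conc}.
#' @export
read_spot_table <- function(path, slide_id = NULL, dialect = genepix_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(slide_id)) slide_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing))
    stop("spot table format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0L) {
    warning("spot table has an empty data section: ", path, call. = FALSE)
    out <- data.frame(slide_id = character(), block = integer(),
                      row = integer(), col = integer(),
                      protein_id = character(), name = character(),
                      replicate_index = integer(), fg = numeric(),
                      bg = numeric(), conc = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(
    slide_id = slide_id,
    block = as.integer(raw[[dialect[["block"]]]]),
    row = as.integer(raw[[dialect[["row"]]]]),
    col = as.integer(raw[[dialect[["col"]]]]),
    protein_id = as.character(raw[[dialect[["protein_id"]]]]),
    name = as.character(raw[[dialect[["name"]]]]),
    fg = as.numeric(raw[[dialect[["fg"]]]]),
    bg = as.numeric(raw[[dialect[["bg"]]]]),
    conc = as.numeric(raw[[dialect[["conc"]]]]),
    stringsAsFactors = FALSE
  )
  key <- paste(out$block, out$row, out$col)
  if (anyDuplicated(key))
    stop("spot table integrity error: duplicate coordinates ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  out$replicate_index <- stats::ave(seq_len(nrow(out)), out$protein_id,
                                    FUN = seq_along)
  out[c("slide_id", "block", "row", "col", "protein_id", "name",
        "replicate_index", "fg", "bg", "conc")]
}

#' @export
print.array_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated array screen: %d proteins x %d slides, %d planted binder(s) at %g-fold\n",
    x$config$n_proteins, x$config$n_slides, length(x$truth),
    x$config$effect_size))
  invisible(x)
}
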