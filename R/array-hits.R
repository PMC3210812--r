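#' Background-correct spot fluorescence
#'
#' Subtracts the local background estimate from the foreground signal,
#' flooring the result at zero.
#'
#' @param spots spot data frame with \code{fg} and \code{bg} columns.
#' @return The input with an added \code{net} column.
#' @export
background_correct <- function(spots) {
  if (!all(c("fg", "bg") %in% names(spots)))
    stop("spots must contain 'fg' and 'bg' columns", call. = FALSE)
  spots$net <- pmax(spots$fg - spots$bg, 0)
  spots
}

# fitted lowess values mapped back to the original x order
.lowess_fit <- function(x, y, frac, iters) {
  fit <- lowess(x, y, f = frac, iter = iters)
  # lowess returns values sorted by x; map back via interpolation, which is
  # exact at the data points (ties averaged)
  stats::approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
}

#' De-trend log-signal against print order with LOWESS
#'
#' Fits a locally weighted regression of \code{log2(net + 1)} on row-major
#' print-order index within each slide and removes it, re-centring at the
#' median fit. Removes the smooth spatial/print drift that dominates
#' single-channel arrays. Blank spots (\code{conc == 0}) are excluded from
#' the fit and receive \code{NA}.
#'
#' @param spots spot data frame with a \code{net} column (one or more
#'   slides).
#' @param frac LOWESS smoother span (fraction of points).
#' @param iters number of robustifying iterations.
#' @return The input with an added \code{norm} column.
#' @export
lowess_detrend <- function(spots, frac = 0.3, iters = 3L) {
  if (!"net" %in% names(spots))
    stop("spots must contain a 'net' column (run background_correct first)",
         call. = FALSE)
  spots$norm <- NA_real_
  for (sl in unique(spots$slide_id)) {
    i <- which(spots$slide_id == sl)
    s <- spots[i, ]
    ord <- order(s$block, s$row, s$col)
    index <- integer(nrow(s))
    index[ord] <- seq_len(nrow(s))
    keep <- s$conc > 0
    if (sum(keep) < 10L)
      stop("processing error: fewer than 10 non-blank spots on slide ", sl,
           call. = FALSE)
    y <- log2(s$net[keep] + 1)
    yhat <- .lowess_fit(index[keep], y, frac, iters)
    spots$norm[i[keep]] <- y - yhat + median(yhat)
  }
  spots
}

#' Adjust normalised signal for printed protein concentration
#'
#' Removes the dependence of the de-trended log-signal on printed spot
#' concentration by subtracting a locally weighted fit of \code{norm} on
#' \code{log10(conc)} over all non-blank spots of each slide. When all
#' concentrations are identical the adjustment reduces to centring.
#'
#' @param spots spot data frame with a \code{norm} column.
#' @param frac LOWESS smoother span.
#' @return The input with an added \code{adj} column.
#' @export
concentration_adjust <- function(spots, frac = 0.5) {
  if (!"norm" %in% names(spots))
    stop("spots must contain a 'norm' column (run lowess_detrend first)",
         call. = FALSE)
  spots$adj <- NA_real_
  for (sl in unique(spots$slide_id)) {
    i <- which(spots$slide_id == sl & spots$conc > 0)
    x <- log10(spots$conc[i])
    y <- spots$norm[i]
    if (length(unique(x)) < 2L) {
      message("concentration_adjust: all concentrations identical on slide ",
              sl, "; centring only")
      spots$adj[i] <- y - mean(y)
    } else {
      spots$adj[i] <- y - .lowess_fit(x, y, frac, iters = 3L)
    }
  }
  spots
}

#' Slide-relative Z-scores of adjusted signal
#'
#' Standardises the concentration-adjusted values against the population of
#' all non-blank spots of each slide. The classical variant uses the mean
#' and sample standard deviation; the robust variant uses the median and
#' 1.4826 x MAD.
#'
#' @param spots spot data frame with an \code{adj} column.
#' @param robust use median/MAD instead of mean/sd.
#' @return The input with an added \code{z} column.
#' @export
slide_zscores <- function(spots, robust = FALSE) {
  if (!"adj" %in% names(spots))
    stop("spots must contain an 'adj' column (run concentration_adjust first)",
         call. = FALSE)
  spots$z <- NA_real_
  for (sl in unique(spots$slide_id)) {
    i <- which(spots$slide_id == sl & spots$conc > 0)
    if (length(i) < 3L)
      stop("processing error: fewer than 3 non-blank spots on slide ", sl,
           call. = FALSE)
    a <- spots$adj[i]
    if (robust) {
      ctr <- median(a); scl <- mad(a)
    } else {
      ctr <- mean(a); scl <- sd(a)
    }
    if (scl == 0)
      stop("processing error: zero variance of adjusted signal on slide ", sl,
           call. = FALSE)
    spots$z[i] <- (a - ctr) / scl
  }
  spots
}

#' Call duplicate-spot hits on each slide
#'
#' A protein is a hit on a slide when the average Z-score of its two
#' replicate spots exceeds \code{z_thresh} and the coefficient of variation
#' of the two replicate signals is below \code{cv_thresh} (both strict).
#' The CV uses the sample standard deviation (divisor n-1, i.e.
#' \code{|s1 - s2| / sqrt(2)} over the mean) computed by default on the
#' concentration-adjusted signals back-transformed to the linear scale.
#'
#' @param spots spot data frame with \code{z} (and \code{adj}) columns.
#' @param z_thresh average-Z threshold (default 3).
#' @param cv_thresh replicate-CV threshold (default 0.5).
#' @param cv_basis signal scale for the CV: linearised adjusted signal
#'   (\code{2^adj}, default), background-corrected \code{net}, or raw
#'   \code{fg}.
#' @return Data frame with one row per (slide, protein):
#'   \code{slide_id, protein_id, mean_z, cv, is_hit}.
#' @export
call_hits <- function(spots, z_thresh = 3, cv_thresh = 0.5,
                      cv_basis = c("adjusted", "net", "raw")) {
  cv_basis <- match.arg(cv_basis)
  if (!"z" %in% names(spots))
    stop("spots must contain a 'z' column (run slide_zscores first)",
         call. = FALSE)
  callable <- spots[spots$conc > 0, , drop = FALSE]
  counts <- table(callable$slide_id, callable$protein_id)
  bad <- which(counts != 2L & counts > 0L, arr.ind = TRUE)
  if (nrow(bad))
    stop("integrity error: protein(s) without exactly two replicate spots: ",
         paste(unique(colnames(counts)[bad[, 2]]), collapse = ", "),
         call. = FALSE)
  sig <- switch(cv_basis,
                adjusted = 2^callable$adj,
                net = callable$net,
                raw = callable$fg)
  key <- interaction(callable$slide_id, callable$protein_id, drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  first <- function(v) as.character(tapply(as.character(v), key, `[`, 1L))
  mean_z <- agg(callable$z, mean)
  m <- agg(sig, mean)
  cv <- agg(sig, sd) / m
  cv[m == 0] <- Inf
  out <- data.frame(
    slide_id = first(callable$slide_id),
    protein_id = first(callable$protein_id),
    mean_z = mean_z,
    cv = cv,
    stringsAsFactors = FALSE
  )
  out$is_hit <- out$mean_z > z_thresh & out$cv < cv_thresh
  out <- out[order(out$slide_id, out$protein_id), ]
  rownames(out) <- NULL
  out
}

#' Intersect hit lists across replicate slides
#'
#' Returns the proteins called as hits on every slide — the reproducible
#' hit set of the screen.
#'
#' @param hits a hit table from [call_hits()] covering at least two slides,
#'   or a list of per-slide hit tables.
#' @return Sorted character vector of reproducible hit protein IDs.
#' @export
reproducible_hits <- function(hits) {
  if (is.data.frame(hits)) hits <- split(hits, hits$slide_id)
  if (length(hits) < 2L)
    stop("usage error: reproducible_hits needs hit calls from >= 2 slides",
         call. = FALSE)
  sets <- lapply(hits, function(h) h$protein_id[h$is_hit])
  sort(Reduce(intersect, sets))
}

#' Run the full hit-calling pipeline on replicate slides
#'
#' Convenience wrapper: background correction, LOWESS de-trending,
#' concentration adjustment, slide Z-scores, duplicate-spot hit calling and
#' replicate-slide intersection.
#'
#' @param slides list of per-slide spot data frames (or a single combined
#'   data frame with a \code{slide_id} column).
#' @param frac_detrend,frac_conc LOWESS spans for the two fits.
#' @param robust use robust Z-scores.
#' @param ... passed to [call_hits()].
#' @return List with elements \code{spots} (processed spot table),
#'   \code{hits} (per-slide hit calls) and \code{reproducible} (protein IDs
#'   hit on every slide; \code{NULL} for a single slide).
#' @export
call_array_hits <- function(slides, frac_detrend = 0.3, frac_conc = 0.5,
                            robust = FALSE, ...) {
  spots <- if (is.data.frame(slides)) slides else do.call(rbind, slides)
  spots <- background_correct(spots)
  spots <- lowess_detrend(spots, frac = frac_detrend)
  spots <- concentration_adjust(spots, frac = frac_conc)
  spots <- slide_zscores(spots, robust = robust)
  hits <- call_hits(spots, ...)
  rep_hits <- if (length(unique(spots$slide_id)) >= 2L)
    reproducible_hits(hits) else NULL
  list(spots = spots, hits = hits, reproducible = rep_hits)
}
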