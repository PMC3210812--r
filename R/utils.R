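#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx ave lowess mad median phyper rbinom rlnorm runif sd setNames
#' @importFrom utils read.delim write.table
NULL

# Twenty standard amino acids, one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_number <- function(x, field, min = -Inf, max = Inf, strict_min = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop_config(field, "must be a single finite number")
  if (x < min || x > max || (strict_min && x == min))
    stop_config(field, sprintf("must be in %s%g, %g]",
                               if (strict_min) "(" else "[", min, max))
  as.numeric(x)
}

# last n characters of each element of a character vector
str_suffix <- function(x, n) {
  len <- nchar(x)
  substr(x, pmax(1L, len - n + 1L), len)
}

# residue at PDZ position pos (0 = C-terminal residue, negative leftward)
residue_at <- function(x, pos) {
  len <- nchar(x)
  i <- len + pos
  ifelse(i >= 1L, substr(x, i, i), NA_character_)
}
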