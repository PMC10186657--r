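## small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; human-readable outputs here follow
#' the half-up convention (e.g. Mbp to one decimal, percentages to one
#' decimal).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

## run-length merge of adjacent identical op kinds
merge_ops <- function(kind, len) {
  keep <- len > 0
  kind <- kind[keep]; len <- len[keep]
  if (length(kind) == 0L) {
    return(data.frame(kind = character(0), len = integer(0), stringsAsFactors = FALSE))
  }
  grp <- cumsum(c(TRUE, kind[-1] != kind[-length(kind)]))
  data.frame(kind = kind[!duplicated(grp)],
             len = as.integer(tapply(len, grp, sum)),
             stringsAsFactors = FALSE, row.names = NULL)
}

## deterministic sampling of a DNA string
DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
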