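## FASTA input/output.
##
## Parsing is delegated to Biostrings (readBStringSet) so record/line
## bookkeeping is robust; alphabet validation is done here so that errors
## name the offending record and character, which the B-string reader
## cannot do.

#' Read a multi-record FASTA file
#'
#' Residues are uppercased; any character outside `{A,C,G,T,N}` (case
#' insensitive) is rejected with an error naming the record.
#'
#' @param path FASTA file
#' @return list of [genome_sequence()] objects
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("read_fasta: no such file: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_fmt("read_fasta: %s is not readable FASTA (%s)",
                                               path, conditionMessage(e)))
  if (length(set) == 0L) stop_fmt("read_fasta: %s contains no records", path)
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) stop_fmt("read_fasta: record %d has an empty name",
                                 which(!nzchar(nm))[1])
  if (anyDuplicated(nm))
    stop_fmt("read_fasta: duplicate record name '%s'", nm[duplicated(nm)][1])
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- toupper(as.character(set[[i]]))
    bad <- regmatches(s, regexpr("[^ACGTN]", s))
    if (length(bad) && nzchar(bad))
      stop_fmt("read_fasta: record '%s' contains illegal character '%s'", nm[i], bad)
    out[[i]] <- genome_sequence(nm[i], s)
  }
  out
}

#' Write genome sequences as FASTA
#'
#' @param seqs a [genome_sequence()] or list of them
#' @param path output file
#' @param width line width
#' @return invisibly, `path`
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "genome_sequence")) seqs <- list(seqs)
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  for (s in seqs) {
    n <- s$length
    starts <- seq.int(1L, max(n, 1L), by = width)
    lines <- substring(s$seq, starts, pmin(starts + width - 1L, n))
    writeLines(c(paste0(">", s$name), lines), con, sep = "\n")
  }
  invisible(path)
}
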