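## Tabular I/O: pooled allele counts and interval (BED/TSV) tables.

#' Read a pooled allele-count table
#'
#' Expects a TSV with header `chrom,pos,ref,fA,fC,fG,fT,mA,mC,mG,mT` and
#' 1-based positions; positions are converted to 0-based and rows sorted
#' by `(chrom, pos)`.
#'
#' @param path TSV file
#' @return [pooled_counts()] data.frame (possibly zero rows)
#' @export
read_pool_counts <- function(path) {
  if (!file.exists(path)) stop_fmt("read_pool_counts: no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(POOL_COLS %in% names(df)))
    stop_fmt("read_pool_counts: %s: header must contain %s", path,
             paste(POOL_COLS, collapse = ","))
  if (nrow(df) == 0L) {
    df$pos <- integer(0)
    return(pooled_counts(df))
  }
  if (any(df$pos < 1L))
    stop_fmt("read_pool_counts: positions are 1-based in the file; got %d", min(df$pos))
  df$pos <- as.integer(df$pos) - 1L
  pooled_counts(df)
}

#' Write a pooled allele-count table
#'
#' Inverse of [read_pool_counts()]: positions written 1-based.
#'
#' @param pools [pooled_counts()] data.frame
#' @param path output TSV
#' @return invisibly, `path`
#' @export
write_pool_counts <- function(pools, path) {
  df <- as.data.frame(pools)
  df$pos <- df$pos + 1L
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an interval table as BED or TSV
#'
#' @param records data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) plus any named value columns
#' @param path output file
#' @param dialect `"bed"` (no header, tab-separated, value columns appended
#'   after the first three) or `"tsv"` (header retained)
#' @return invisibly, `path`
#' @export
write_interval_table <- function(records, path, dialect = c("bed", "tsv")) {
  dialect <- match.arg(dialect)
  records <- as.data.frame(records)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(records)))
    stop_fmt("write_interval_table: records need columns chrom,start,end")
  if (any(records$start >= records$end))
    stop_fmt("write_interval_table: empty/inverted interval at row %d (start >= end)",
             which(records$start >= records$end)[1])
  ord <- c(need, setdiff(names(records), need))
  records <- records[ord]
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = dialect == "tsv")
  invisible(path)
}

#' Read an interval table written by [write_interval_table()]
#'
#' @param path input file
#' @param dialect `"bed"` or `"tsv"`
#' @param col_names for `"bed"`: names of the value columns after
#'   chrom/start/end
#' @return data.frame
#' @export
read_interval_table <- function(path, dialect = c("bed", "tsv"), col_names = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:3] <- c("chrom", "start", "end")
    if (!is.null(col_names) && ncol(df) >= 4L)
      names(df)[4:(3 + length(col_names))] <- col_names
    df
  }
}
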