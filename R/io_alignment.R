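## Whole-chromosome alignment I/O: PAF (with cg:Z extended CIGAR),
## pairwise MAF, and the package's own TSV dialect. All readers return
## validated `alignment_block` lists in forward-reference orientation.

CIGAR_TO_KIND <- c("=" = "match", "X" = "mismatch", "I" = "insert", "D" = "delete")
KIND_TO_CIGAR <- setNames(names(CIGAR_TO_KIND), CIGAR_TO_KIND)

parse_extended_cigar <- function(cg, where = "") {
  m <- gregexpr("([0-9]+)([=XIDMSHNP])", cg)
  if (m[[1]][1] == -1L || sum(attr(m[[1]], "match.length")) != nchar(cg))
    stop_fmt("unparseable CIGAR '%s' %s", cg, where)
  toks <- regmatches(cg, m)[[1]]
  op <- substring(toks, nchar(toks), nchar(toks))
  if (any(op == "M"))
    stop_fmt("CIGAR '%s' %s uses plain 'M': mismatches are indistinguishable; re-align with an extended (=/X) CIGAR (minimap2 --eqx) or supply MAF", cg, where)
  if (any(!op %in% names(CIGAR_TO_KIND)))
    stop_fmt("CIGAR '%s' %s: unsupported operation '%s'", cg, where,
             setdiff(op, names(CIGAR_TO_KIND))[1])
  ## canonical form: adjacent runs of the same kind are merged
  merge_ops(unname(CIGAR_TO_KIND[op]), as.integer(sub(".$", "", toks)))
}

ops_to_cigar <- function(ops) {
  paste0(ops$len, KIND_TO_CIGAR[ops$kind], collapse = "")
}

read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) stop_fmt("PAF line %d: fewer than 12 fields", i)
    tags <- f[-(1:12)]
    cg <- tags[startsWith(tags, "cg:Z:")]
    if (length(cg) == 0L)
      stop_fmt("PAF line %d: missing cg:Z CIGAR tag", i)
    ops <- parse_extended_cigar(sub("^cg:Z:", "", cg[1]), sprintf("(PAF line %d)", i))
    ## PAF: query fields 1-4, target fields 6-9; target is our reference.
    ## cg runs along the forward target strand, so no op reversal is needed;
    ## query coordinates in PAF are already forward-strand.
    alignment_block(ref_name = f[6], ref_start = as.integer(f[8]), ref_end = as.integer(f[9]),
                    qry_name = f[1], qry_start = as.integer(f[3]), qry_end = as.integer(f[4]),
                    strand = f[5], ops = ops)
  })
}

write_paf <- function(blocks, path, qry_lengths = NULL, ref_lengths = NULL) {
  lines <- vapply(blocks, function(b) {
    nmatch <- sum(b$ops$len[b$ops$kind == "match"])
    alen <- sum(b$ops$len)
    ql <- qry_lengths[b$qry_name] %||% NULL
    rl <- ref_lengths[b$ref_name] %||% NULL
    paste(b$qry_name, ifelse(is.null(ql) || is.na(ql), b$qry_end, ql),
          b$qry_start, b$qry_end, b$strand,
          b$ref_name, ifelse(is.null(rl) || is.na(rl), b$ref_end, rl),
          b$ref_start, b$ref_end,
          nmatch, alen, 255L,
          paste0("cg:Z:", ops_to_cigar(b$ops)), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## ops from two equal-length aligned (gapped) strings
ops_from_gapped <- function(ref_aln, qry_aln, where = "") {
  r <- seq_chars(toupper(ref_aln)); q <- seq_chars(toupper(qry_aln))
  if (length(r) != length(q))
    stop_fmt("aligned rows differ in length %s", where)
  kind <- ifelse(r == "-" & q == "-", NA_character_,
          ifelse(r == "-", "insert",
          ifelse(q == "-", "delete",
          ifelse(r == q, "match", "mismatch"))))
  if (anyNA(kind)) stop_fmt("all-gap column in alignment %s", where)
  merge_ops(kind, rep(1L, length(kind)))
}

read_maf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  a_idx <- which(startsWith(lines, "a"))
  if (length(a_idx) == 0L) stop_fmt("MAF %s: no alignment blocks", path)
  bounds <- c(a_idx, length(lines) + 1L)
  lapply(seq_along(a_idx), function(i) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    s <- chunk[startsWith(chunk, "s ") | startsWith(chunk, "s\t")]
    if (length(s) != 2L)
      stop_fmt("MAF block %d: expected exactly 2 's' lines (pairwise), got %d", i, length(s))
    parse_s <- function(ln) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      list(name = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
           strand = f[5], src_size = as.integer(f[6]), text = f[7])
    }
    rs <- parse_s(s[1]); qs <- parse_s(s[2])
    if (rs$strand != "+")
      stop_fmt("MAF block %d: reference row must be on '+' strand", i)
    ops <- ops_from_gapped(rs$text, qs$text, sprintf("(MAF block %d)", i))
    ## MAF minus-strand starts count from the reverse-complement;
    ## normalize to forward-strand coordinates.
    q0 <- if (qs$strand == "-") qs$src_size - qs$start - qs$size else qs$start
    alignment_block(ref_name = rs$name, ref_start = rs$start, ref_end = rs$start + rs$size,
                    qry_name = qs$name, qry_start = q0, qry_end = q0 + qs$size,
                    strand = qs$strand, ops = ops)
  })
}

INTERNAL_ALN_COLS <- c("ref_name", "ref_start", "ref_end",
                       "qry_name", "qry_start", "qry_end", "strand", "cigar")

read_internal_alignment <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(INTERNAL_ALN_COLS %in% names(df)))
    stop_fmt("internal alignment %s: expected columns %s", path,
             paste(INTERNAL_ALN_COLS, collapse = ","))
  lapply(seq_len(nrow(df)), function(i) {
    alignment_block(df$ref_name[i], df$ref_start[i], df$ref_end[i],
                    df$qry_name[i], df$qry_start[i], df$qry_end[i],
                    df$strand[i],
                    parse_extended_cigar(df$cigar[i], sprintf("(row %d)", i)))
  })
}

write_internal_alignment <- function(blocks, path) {
  df <- data.frame(ref_name = vapply(blocks, `[[`, "", "ref_name"),
                   ref_start = vapply(blocks, `[[`, 0L, "ref_start"),
                   ref_end = vapply(blocks, `[[`, 0L, "ref_end"),
                   qry_name = vapply(blocks, `[[`, "", "qry_name"),
                   qry_start = vapply(blocks, `[[`, 0L, "qry_start"),
                   qry_end = vapply(blocks, `[[`, 0L, "qry_end"),
                   strand = vapply(blocks, `[[`, "", "strand"),
                   cigar = vapply(blocks, function(b) ops_to_cigar(b$ops), ""),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a whole-chromosome alignment
#'
#' @param path alignment file
#' @param dialect `"paf"` (requires a `cg:Z` extended CIGAR per line),
#'   `"maf"` (pairwise blocks only) or `"internal"` (the package's TSV)
#' @return list of [alignment_block()] objects
#' @export
read_alignment <- function(path, dialect = c("paf", "maf", "internal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("read_alignment: no such file: %s", path)
  switch(dialect,
         paf = read_paf(path),
         maf = read_maf(path),
         internal = read_internal_alignment(path))
}

#' Write a whole-chromosome alignment
#'
#' @param blocks list of [alignment_block()]
#' @param path output file
#' @param dialect `"paf"` or `"internal"`
#' @param qry_lengths,ref_lengths optional named full sequence lengths
#'   (PAF columns 2 and 7); defaults to interval ends
#' @return invisibly, `path`
#' @export
write_alignment <- function(blocks, path, dialect = c("paf", "internal"),
                            qry_lengths = NULL, ref_lengths = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
         paf = write_paf(blocks, path, qry_lengths, ref_lengths),
         internal = write_internal_alignment(blocks, path))
}
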