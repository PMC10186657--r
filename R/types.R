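## Core internal types. All coordinates are 0-based half-open; 1-based
## closed coordinates exist only at file boundaries (pool TSV in,
## human-readable report out).

#' Construct a genome sequence
#'
#' A named chromosome-scale DNA sequence over the alphabet `{A,C,G,T,N}`.
#' Residues are stored uppercase as a single string.
#'
#' @param name non-empty identifier
#' @param seq DNA string; lowercase accepted and uppercased
#' @return object of class `genome_sequence` with fields `name`, `seq`,
#'   `length`
#' @export
genome_sequence <- function(name, seq) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_fmt("genome_sequence: 'name' must be a non-empty string")
  if (!is.character(seq) || length(seq) != 1L)
    stop_fmt("genome_sequence: 'seq' must be a single string")
  seq <- toupper(seq)
  bad <- regmatches(seq, regexpr("[^ACGTN]", seq))
  if (length(bad) && nzchar(bad))
    stop_fmt("genome_sequence '%s': illegal character '%s' (alphabet is A,C,G,T,N)",
             name, bad)
  structure(list(name = name, seq = seq, length = nchar(seq)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %d bp\n", x$name, x$length))
  invisible(x)
}

#' @export
length.genome_sequence <- function(x) x$length

as_seq_string <- function(x) {
  if (inherits(x, "genome_sequence")) x$seq
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop_fmt("expected a genome_sequence or a single DNA string")
}

ALN_KINDS <- c("match", "mismatch", "insert", "delete")

#' Construct an alignment block
#'
#' A co-linear homology block between a reference and a query sequence,
#' stored as an ordered run-length operation list. `match`/`mismatch`
#' consume one base on both sequences per unit length, `insert` consumes
#' query only, `delete` consumes reference only.
#'
#' @param ref_name,ref_start,ref_end reference interval (0-based half-open)
#' @param qry_name,qry_start,qry_end query interval (0-based half-open)
#' @param strand `"+"` or `"-"`
#' @param ops data.frame with columns `kind`
#'   (`match|mismatch|insert|delete`) and positive integer `len`
#' @return object of class `alignment_block`
#' @export
alignment_block <- function(ref_name, ref_start, ref_end,
                            qry_name, qry_start, qry_end,
                            strand = "+", ops) {
  ops <- as.data.frame(ops, stringsAsFactors = FALSE)
  if (!all(c("kind", "len") %in% names(ops)))
    stop_fmt("alignment_block: ops needs columns 'kind' and 'len'")
  ops$len <- as.integer(ops$len)
  if (nrow(ops) == 0L) stop_fmt("alignment_block: empty ops")
  if (any(!ops$kind %in% ALN_KINDS))
    stop_fmt("alignment_block: unknown op kind '%s'",
             setdiff(unique(ops$kind), ALN_KINDS)[1])
  if (any(ops$len < 1L)) stop_fmt("alignment_block: run lengths must be >= 1")
  if (!strand %in% c("+", "-")) stop_fmt("alignment_block: strand must be '+' or '-'")
  b <- structure(list(ref_name = ref_name,
                      ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
                      qry_name = qry_name,
                      qry_start = as.integer(qry_start), qry_end = as.integer(qry_end),
                      strand = strand, ops = ops),
                 class = "alignment_block")
  validate_block(b)
  b
}

## the two length-consistency invariants
validate_block <- function(b) {
  rspan <- sum(b$ops$len[b$ops$kind %in% c("match", "mismatch", "delete")])
  qspan <- sum(b$ops$len[b$ops$kind %in% c("match", "mismatch", "insert")])
  if (rspan != b$ref_end - b$ref_start)
    stop_fmt("alignment_block %s:[%d,%d): ops reference span %d != interval length %d",
             b$ref_name, b$ref_start, b$ref_end, rspan, b$ref_end - b$ref_start)
  if (qspan != b$qry_end - b$qry_start)
    stop_fmt("alignment_block %s:[%d,%d): ops query span %d != interval length %d",
             b$qry_name, b$qry_start, b$qry_end, qspan, b$qry_end - b$qry_start)
  invisible(b)
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block> %s:[%d,%d) ~ %s:[%d,%d) %s, %d ops\n",
              x$ref_name, x$ref_start, x$ref_end,
              x$qry_name, x$qry_start, x$qry_end, x$strand, nrow(x$ops)))
  invisible(x)
}

POOL_COLS <- c("chrom", "pos", "ref", "fA", "fC", "fG", "fT", "mA", "mC", "mG", "mT")

#' Construct a pooled allele-count table
#'
#' One row per genomic site with A/C/G/T read counts in a female pool and
#' a male pool. Positions are 0-based internally.
#'
#' @param df data.frame with columns
#'   `chrom,pos,ref,fA,fC,fG,fT,mA,mC,mG,mT`
#' @return validated data.frame of class `pooled_counts`, sorted by
#'   `(chrom, pos)`
#' @export
pooled_counts <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(POOL_COLS %in% names(df)))
    stop_fmt("pooled_counts: missing columns: %s",
             paste(setdiff(POOL_COLS, names(df)), collapse = ","))
  df <- df[POOL_COLS]
  cnt <- as.matrix(df[, 4:11])
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop_fmt("pooled_counts: counts must be non-negative integers")
  if (any(!df$ref %in% DNA_BASES))
    stop_fmt("pooled_counts: ref base must be one of A,C,G,T (got '%s')",
             setdiff(unique(df$ref), DNA_BASES)[1])
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  dup <- duplicated(df[c("chrom", "pos")])
  if (any(dup))
    stop_fmt("pooled_counts: duplicate site %s:%d",
             df$chrom[dup][1], df$pos[dup][1])
  rownames(df) <- NULL
  class(df) <- c("pooled_counts", "data.frame")
  df
}
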