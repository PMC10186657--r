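## TE age landscape: CpG-adjusted Kimura 2-parameter distances per repeat
## copy, young-copy classification (K < 1 on the x100 scale) and spatial
## density tracks.

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Tally transitions and transversions of a repeat copy against its
#' family consensus
#'
#' Columns are taken over the pairwise alignment (all-match when `ops` is
#' omitted and the sequences have equal length). With
#' `cpg_mode = "adjusted"` a transition whose consensus position lies in a
#' CpG dinucleotide is down-weighted to 1/10, and when both positions of
#' one CpG carry transitions the pair contributes a single full
#' transition; this mirrors the standard CpG-corrected repeat divergence
#' convention (hypermutable CpG sites would otherwise inflate the age of
#' young copies).
#'
#' @param copy_seq,consensus_seq DNA strings (or [genome_sequence()])
#' @param ops optional op data.frame (`kind`,`len`) aligning consensus
#'   (reference) to copy (query)
#' @param cpg_mode `"adjusted"` or `"off"`
#' @return list with `p` (weighted transition proportion), `q`
#'   (transversion proportion), `n_aligned` and `n_cpg_transitions`
#' @export
count_substitutions <- function(copy_seq, consensus_seq, ops = NULL,
                                cpg_mode = c("adjusted", "off")) {
  cpg_mode <- match.arg(cpg_mode)
  cons <- seq_chars(as_seq_string(consensus_seq))
  copy <- seq_chars(as_seq_string(copy_seq))
  if (is.null(ops)) {
    if (length(cons) != length(copy))
      stop_fmt("count_substitutions: sequence lengths differ (%d vs %d) and no alignment ops given",
               length(cons), length(copy))
    cons_col <- cons; copy_col <- copy
    cons_pos <- seq_along(cons)
  } else {
    ops <- as.data.frame(ops)
    rspan <- sum(ops$len[ops$kind %in% c("match", "mismatch", "delete")])
    qspan <- sum(ops$len[ops$kind %in% c("match", "mismatch", "insert")])
    if (rspan != length(cons) || qspan != length(copy))
      stop_fmt("count_substitutions: ops (%d/%d) inconsistent with sequence lengths (%d/%d)",
               rspan, qspan, length(cons), length(copy))
    kinds <- rep(ops$kind, ops$len)
    ref_take <- kinds != "insert"
    qry_take <- kinds != "delete"
    cons_col <- ifelse(ref_take, NA, "-")
    cons_col[ref_take] <- cons
    copy_col <- ifelse(qry_take, NA, "-")
    copy_col[qry_take] <- copy
    cons_pos <- cumsum(ref_take)
    cons_pos[!ref_take] <- NA_integer_
  }
  aligned <- cons_col %in% DNA_BASES & copy_col %in% DNA_BASES
  n_aligned <- sum(aligned)
  diffc <- aligned & cons_col != copy_col
  is_ts <- diffc & copy_col == unname(TRANSITIONS[ifelse(diffc, cons_col, "A")])
  is_tv <- diffc & !is_ts

  ## consensus CpG membership (both the C and the G position count)
  n_cons <- length(cons)
  cpg_start <- which(cons[-n_cons] == "C" & cons[-1] == "G")
  in_cpg <- logical(n_cons)
  in_cpg[cpg_start] <- TRUE
  in_cpg[cpg_start + 1L] <- TRUE

  ts_pos <- cons_pos[is_ts]
  n_cpg_ts <- sum(in_cpg[ts_pos])
  if (cpg_mode == "off") {
    w_ts <- sum(is_ts)
  } else {
    w <- ifelse(in_cpg[ts_pos], 0.1, 1)
    ## a CpG whose C and G both carry transitions counts once, in full
    both <- intersect(cpg_start, ts_pos)
    both <- both[(both + 1L) %in% ts_pos]
    w_ts <- sum(w) + length(both) * (1 - 0.2)
  }
  list(p = if (n_aligned > 0) w_ts / n_aligned else NA_real_,
       q = if (n_aligned > 0) sum(is_tv) / n_aligned else NA_real_,
       n_aligned = n_aligned,
       n_cpg_transitions = n_cpg_ts)
}

#' Kimura 2-parameter distance
#'
#' `K = -1/2 * ln((1 - 2p - q) * sqrt(1 - 2q))` with `p` the transition
#' and `q` the transversion proportion. Only defined while
#' `1 - 2p - q > 0` and `1 - 2q > 0`; outside that domain the distance is
#' saturated.
#'
#' @param p,q transition/transversion proportions (vectorized)
#' @param scale100 report on the x100 scale used for young-TE
#'   thresholding
#' @param strict error on domain violations; otherwise return `NA` there
#' @return numeric vector of distances
#' @export
kimura2p <- function(p, q, scale100 = FALSE, strict = TRUE) {
  if (any(p < 0 | q < 0 | p + q > 1, na.rm = TRUE))
    stop_fmt("kimura2p: need p >= 0, q >= 0, p + q <= 1")
  a <- 1 - 2 * p - q
  b <- 1 - 2 * q
  bad <- !is.na(a) & (a <= 0 | b <= 0)
  if (any(bad)) {
    if (strict)
      stop_fmt("kimura2p: saturated distance (1-2p-q = %.4g, 1-2q = %.4g); copy cannot be scored",
               a[bad][1], b[bad][1])
    a[bad] <- NA_real_
  }
  k <- -0.5 * log(a * sqrt(b))
  if (scale100) 100 * k else k
}

#' Score a table of TE copies against their family consensus sequences
#'
#' @param copies data.frame with columns `chrom,start,end,family,strand`
#'   and `copy_seq` (the copy's sequence, consensus orientation)
#' @param consensus named list/vector of consensus sequences by family
#' @param cpg_mode passed to [count_substitutions()]
#' @return `copies` with columns `p`, `q`, `n_aligned`,
#'   `n_cpg_transitions`, `kimura` (x100 scale; `NA` when saturated) and
#'   `saturated`
#' @export
score_te_copies <- function(copies, consensus, cpg_mode = c("adjusted", "off")) {
  cpg_mode <- match.arg(cpg_mode)
  copies <- as.data.frame(copies, stringsAsFactors = FALSE)
  miss <- setdiff(unique(copies$family), names(consensus))
  if (length(miss))
    stop_fmt("score_te_copies: no consensus sequence for family '%s'", miss[1])
  n <- nrow(copies)
  p <- q <- k <- numeric(n); na <- ncg <- integer(n)
  for (i in seq_len(n)) {
    cs <- count_substitutions(copies$copy_seq[i],
                              as_seq_string(consensus[[copies$family[i]]]),
                              ops = NULL, cpg_mode = cpg_mode)
    p[i] <- cs$p; q[i] <- cs$q; na[i] <- cs$n_aligned; ncg[i] <- cs$n_cpg_transitions
    k[i] <- kimura2p(cs$p, cs$q, scale100 = TRUE, strict = FALSE)
  }
  copies$p <- p; copies$q <- q
  copies$n_aligned <- na; copies$n_cpg_transitions <- ncg
  copies$kimura <- k
  copies$saturated <- is.na(k)
  copies
}

#' Young-TE fraction per region
#'
#' A copy is "young" iff its Kimura value (x100 scale) is strictly below
#' `young_threshold`; copies are assigned to the region containing their
#' interval midpoint.
#'
#' @param copies scored copy table (needs `start`, `end`, `kimura`)
#' @param regions data.frame with `name,start,end` (disjoint)
#' @param young_threshold Kimura units on the x100 scale (default 1)
#' @return data.frame with `region,n_total,n_young,pct_young`
#'   (`pct_young` is `NA` where `n_total` is 0)
#' @export
young_fraction_by_region <- function(copies, regions, young_threshold = 1) {
  if (young_threshold <= 0) stop_fmt("young_fraction_by_region: threshold must be > 0")
  regions <- as.data.frame(regions)
  mid <- (copies$start + copies$end) / 2
  young <- !is.na(copies$kimura) & copies$kimura < young_threshold
  out <- lapply(seq_len(nrow(regions)), function(i) {
    sel <- mid >= regions$start[i] & mid < regions$end[i]
    n <- sum(sel); ny <- sum(young & sel)
    data.frame(region = regions$name[i], n_total = n, n_young = ny,
               pct_young = if (n > 0) 100 * ny / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Windowed TE density track
#'
#' @param copies scored copy table
#' @param chrom_length chromosome length
#' @param window window size
#' @param value `"count"` (all copies) or `"young_count"`
#' @param young_threshold Kimura x100 threshold for `"young_count"`
#' @return interval data.frame `chrom,start,end,count`
#' @export
te_density_windows <- function(copies, chrom_length, window = 100000L,
                               value = c("count", "young_count"),
                               young_threshold = 1) {
  value <- match.arg(value)
  win_start <- seq.int(0L, max(chrom_length - 1L, 0L), by = window)
  mid <- (copies$start + copies$end) / 2
  if (value == "young_count")
    mid <- mid[!is.na(copies$kimura) & copies$kimura < young_threshold]
  counts <- tabulate(floor(mid / window) + 1L, nbins = length(win_start))
  data.frame(chrom = if (nrow(copies)) copies$chrom[1] else "chrom",
             start = win_start,
             end = pmin(win_start + window, chrom_length),
             count = counts, stringsAsFactors = FALSE)
}

#' Bubble-chart table of scored copies
#'
#' Position, Kimura value and copy length, the table behind the classic
#' repeat-age bubble plot (bubble size = repeat length).
#'
#' @param copies scored copy table
#' @return data.frame `chrom,position,kimura,length`
#' @export
te_bubble_table <- function(copies) {
  data.frame(chrom = copies$chrom,
             position = (copies$start + copies$end) / 2,
             kimura = copies$kimura,
             length = copies$end - copies$start,
             stringsAsFactors = FALSE)
}

#' Read TE copy alignments
#'
#' Two dialects: the package's internal TSV
#' (`chrom,start,end,family,strand,copy_seq`) and RepeatMasker-style
#' `.align` files carrying per-column pairwise alignments. Summary `.out`
#' files are rejected: they have no per-column data, so transitions and
#' transversions cannot be recovered from them.
#'
#' @param path input file
#' @param dialect `"internal"` or `"align"`
#' @return data.frame of copies; for `"align"` the `copy_seq` and
#'   `consensus_seq` columns hold the gapped alignment rows
#' @export
read_te_alignments <- function(path, dialect = c("internal", "align")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("read_te_alignments: no such file: %s", path)
  if (dialect == "internal") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "family", "strand", "copy_seq")
    if (!all(need %in% names(df))) {
      if (grepl("\\.out$", path) || any(grepl("^\\s*SW\\s", readLines(path, n = 5))))
        stop_fmt("read_te_alignments: %s looks like a RepeatMasker .out summary; per-column alignments (.align) are required", path)
      stop_fmt("read_te_alignments: %s: expected columns %s", path, paste(need, collapse = ","))
    }
    df
  } else {
    read_rm_align(path)
  }
}

## Minimal RepeatMasker .align parser: header lines
##   <score> <div> <del> <ins> <chrom> <start> <end> (<left>) [C] <family> ...
## followed by interleaved "chrom start seq end" / "C? family start seq end"
## alignment rows. Coordinates in the file are 1-based closed.
read_rm_align <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^[0-9]+\\s", lines)
  if (length(hdr) == 0L)
    stop_fmt("read_te_alignments: %s: no alignment headers found", path)
  bounds <- c(hdr, length(lines) + 1L)
  recs <- lapply(seq_along(hdr), function(i) {
    h <- strsplit(trimws(lines[hdr[i]]), "\\s+")[[1]]
    chrom <- h[5]; start <- as.integer(h[6]); end <- as.integer(h[7])
    strand <- if (length(h) >= 9 && h[9] == "C") "-" else "+"
    family <- if (strand == "-") h[10] else h[9]
    body <- lines[(hdr[i] + 1L):(bounds[i + 1L] - 1L)]
    seq_rows <- grep("^\\s*C?\\s*\\S+\\s+[0-9]+\\s+[ACGTNacgtn-]+\\s+[0-9]+\\s*$", body,
                     value = TRUE)
    get_seq <- function(rows) {
      paste(vapply(rows, function(r) {
        f <- strsplit(trimws(r), "\\s+")[[1]]
        f[length(f) - 1L]
      }, character(1)), collapse = "")
    }
    odd <- seq_rows[seq_along(seq_rows) %% 2 == 1]
    even <- seq_rows[seq_along(seq_rows) %% 2 == 0]
    copy_aln <- toupper(get_seq(odd))
    cons_aln <- toupper(get_seq(even))
    if (nchar(copy_aln) != nchar(cons_aln))
      stop_fmt("read_te_alignments: %s: ragged alignment rows in block %d", path, i)
    data.frame(chrom = chrom, start = start - 1L, end = end, family = family,
               strand = strand, copy_seq = copy_aln, consensus_seq = cons_aln,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Score gapped copy/consensus alignment rows
#'
#' For `.align`-style input where both gapped rows are available; indel
#' columns are ignored, as in [count_substitutions()].
#'
#' @param copies data.frame with gapped `copy_seq` and `consensus_seq`
#' @param cpg_mode passed on
#' @return scored copy table as in [score_te_copies()]
#' @export
score_te_alignment_rows <- function(copies, cpg_mode = c("adjusted", "off")) {
  cpg_mode <- match.arg(cpg_mode)
  n <- nrow(copies)
  p <- q <- k <- numeric(n); na <- ncg <- integer(n)
  for (i in seq_len(n)) {
    ops <- ops_from_gapped(copies$consensus_seq[i], copies$copy_seq[i])
    cons <- gsub("-", "", copies$consensus_seq[i], fixed = TRUE)
    cop <- gsub("-", "", copies$copy_seq[i], fixed = TRUE)
    cs <- count_substitutions(cop, cons, ops = ops, cpg_mode = cpg_mode)
    p[i] <- cs$p; q[i] <- cs$q; na[i] <- cs$n_aligned; ncg[i] <- cs$n_cpg_transitions
    k[i] <- kimura2p(cs$p, cs$q, scale100 = TRUE, strict = FALSE)
  }
  copies$p <- p; copies$q <- q; copies$n_aligned <- na
  copies$n_cpg_transitions <- ncg; copies$kimura <- k
  copies$saturated <- is.na(k)
  copies
}
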