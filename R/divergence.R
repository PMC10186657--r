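## Windowed W-Z mutation statistic.
##
## The counting rule follows the source analysis: every SNP is one change,
## every indel event is one change regardless of length, and changes are
## expressed as a percentage per 10 kb window.

## 0-based N positions within [start, end) of a sequence string
n_positions <- function(seq_str, start, end) {
  if (end <= start) return(integer(0))
  frag <- substr(seq_str, start + 1L, end)
  m <- gregexpr("N", frag, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  start + as.integer(m) - 1L
}

#' Count changes in an alignment block
#'
#' Each mismatch base contributes one change (a SNP); each insert or
#' delete run contributes exactly one change regardless of length,
#' anchored at the reference position of the run's left edge. Positions
#' where either sequence carries an N are excluded from both the change
#' and the aligned-base counts.
#'
#' @param block [alignment_block()]
#' @param ref_seq,qry_seq optional [genome_sequence()] (or strings) used
#'   for N exclusion; without them no positions are excluded
#' @return list with `changes`, `aligned_bases` (reference span minus
#'   excluded positions), `change_pos` (0-based reference positions, one
#'   per change) and `excluded_ref_pos`
#' @export
block_changes <- function(block, ref_seq = NULL, qry_seq = NULL) {
  validate_block(block)
  ops <- block$ops
  ref_adv <- ops$len * (ops$kind != "insert")
  qry_adv <- ops$len * (ops$kind != "delete")
  op_ref0 <- block$ref_start + c(0L, cumsum(ref_adv))[seq_len(nrow(ops))]
  op_qry0 <- block$qry_start + c(0L, cumsum(qry_adv))[seq_len(nrow(ops))]
  span <- block$ref_end - block$ref_start

  mis <- ops$kind == "mismatch"
  snp_pos <- if (any(mis)) {
    rep(op_ref0[mis], ops$len[mis]) + sequence(ops$len[mis]) - 1L
  } else integer(0)
  indel <- ops$kind %in% c("insert", "delete")
  indel_pos <- pmin(op_ref0[indel], block$ref_end - 1L)

  excluded <- integer(0)
  if (!is.null(ref_seq)) {
    excluded <- n_positions(as_seq_string(ref_seq), block$ref_start, block$ref_end)
  }
  if (!is.null(qry_seq)) {
    qn <- n_positions(as_seq_string(qry_seq), block$qry_start, block$qry_end)
    if (length(qn)) {
      ## map query N positions onto the reference through the op list
      oi <- findInterval(qn, op_qry0)
      ok <- oi >= 1L & ops$kind[oi] %in% c("match", "mismatch") &
        qn < op_qry0[oi] + ops$len[oi]
      excluded <- c(excluded, op_ref0[oi[ok]] + (qn[ok] - op_qry0[oi[ok]]))
    }
  }
  excluded <- sort(unique(excluded))
  if (length(excluded)) {
    snp_pos <- snp_pos[!snp_pos %in% excluded]
    indel_pos <- indel_pos[!indel_pos %in% excluded]
  }
  change_pos <- sort(c(snp_pos, indel_pos))
  list(changes = length(change_pos),
       aligned_bases = span - length(excluded),
       change_pos = change_pos,
       excluded_ref_pos = excluded)
}

#' Windowed divergence along a reference chromosome
#'
#' Tiles windows from position 0 and assigns every change to the
#' window(s) containing its reference position. Windows whose aligned
#' fraction falls below `min_aligned_frac` are masked (`pct` is `NA`),
#' which keeps assembly N-gaps from reading as spurious 0% divergence.
#'
#' @param blocks list of [alignment_block()] on one reference chromosome
#' @param chrom_length reference length in bases
#' @param window window size in bases (default 10 kb)
#' @param step window step; defaults to `window` (non-overlapping tiling)
#' @param denominator `"window_size"` (literal percentage per window) or
#'   `"aligned_bases"`
#' @param min_aligned_frac windows with aligned_bases/width below this are
#'   masked
#' @param ref_seq,qry_seq optional sequences for N exclusion
#' @return data.frame of class `window_stats` with columns
#'   `chrom,start,end,aligned_bases,changes,pct,masked`
#' @export
window_divergence <- function(blocks, chrom_length, window = 10000L, step = window,
                              denominator = c("window_size", "aligned_bases"),
                              min_aligned_frac = 0.5,
                              ref_seq = NULL, qry_seq = NULL) {
  denominator <- match.arg(denominator)
  if (window <= 0L) stop_fmt("window_divergence: window must be > 0")
  if (step <= 0L) stop_fmt("window_divergence: step must be > 0")
  chroms <- unique(vapply(blocks, `[[`, "", "ref_name"))
  if (length(chroms) > 1L)
    stop_fmt("window_divergence: blocks span multiple reference chromosomes (%s)",
             paste(chroms, collapse = ","))
  chrom <- if (length(chroms)) chroms else "ref"

  win_start <- seq.int(0L, max(chrom_length - 1L, 0L), by = step)
  win_end <- pmin(win_start + window, chrom_length)
  nwin <- length(win_start)
  changes <- numeric(nwin)
  aligned <- numeric(nwin)

  win_hits <- function(pos) {
    ## indices (1-based) of all windows whose [start, start+window) holds pos
    lo <- pmax(0, ceiling((pos - window + 1) / step))
    hi <- pmin(nwin - 1, floor(pos / step))
    n <- pmax(0L, hi - lo + 1L)
    rep(lo, n) + sequence(n) - 1L + 1L
  }
  add_interval <- function(s, e, sign = 1) {
    ## add overlap of [s, e) to per-window aligned counts
    if (e <= s) return(invisible())
    lo <- max(0, ceiling((s - window + 1) / step))
    hi <- min(nwin - 1, floor((e - 1) / step))
    if (hi < lo) return(invisible())
    idx <- lo:hi
    ov <- pmin(e, win_start[idx + 1L] + window) - pmax(s, win_start[idx + 1L])
    aligned[idx + 1L] <<- aligned[idx + 1L] + sign * pmax(ov, 0)
    invisible()
  }

  for (b in blocks) {
    bc <- block_changes(b, ref_seq = ref_seq, qry_seq = qry_seq)
    if (length(bc$change_pos)) {
      idx <- win_hits(bc$change_pos)
      tab <- tabulate(idx, nbins = nwin)
      changes <- changes + tab
    }
    add_interval(b$ref_start, b$ref_end)
    for (p in bc$excluded_ref_pos) add_interval(p, p + 1L, sign = -1)
  }

  width <- win_end - win_start
  masked <- (aligned / width) < min_aligned_frac
  denom <- if (denominator == "window_size") width else aligned
  pct <- ifelse(masked | denom <= 0, NA_real_, 100 * changes / denom)
  out <- data.frame(chrom = chrom, start = win_start, end = win_end,
                    aligned_bases = as.integer(aligned),
                    changes = as.integer(changes),
                    pct = pct, masked = masked, stringsAsFactors = FALSE)
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Summarize window divergence over a region
#'
#' Mean, median and quartiles (linear interpolation, type 7) of the
#' window percentage over unmasked windows whose midpoint falls in
#' `[start, end)`.
#'
#' @param stats output of [window_divergence()]
#' @param start,end region interval (bases, 0-based half-open)
#' @return list with `start`, `end`, `n_windows`, `mean_pct`,
#'   `median_pct`, `q1_pct`, `q3_pct`
#' @export
region_summary <- function(stats, start, end) {
  mid <- (stats$start + stats$end) / 2
  sel <- !stats$masked & mid >= start & mid < end & !is.na(stats$pct)
  if (!any(sel))
    stop_fmt("region_summary: no unmasked windows with midpoint in [%s, %s)",
             format(start), format(end))
  p <- stats$pct[sel]
  q <- unname(quantile(p, c(0.25, 0.5, 0.75), type = 7))
  list(start = start, end = end, n_windows = sum(sel),
       mean_pct = mean(p), median_pct = q[2], q1_pct = q[1], q3_pct = q[3])
}
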