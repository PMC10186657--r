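## Built-in co-linear anchor aligner.
##
## Substitutes an external whole-genome aligner for synthetic chromosome
## pairs: unique shared k-mers are chained co-linearly (longest increasing
## subsequence), inter-anchor segments are closed by banded affine
## Needleman-Wunsch when small, and emitted as block boundaries when large
## (e.g. TE insertions, the centromeric N-gap). Rearranged sequences are
## out of scope; import a PAF from a real aligner for those.

## Global affine-gap alignment of two small character vectors, returning
## an op list. Scores: match +1, mismatch -1, gap open -3, gap extend
## -0.5. The gap-open penalty is deliberately high relative to mismatch:
## a compensating ins+del pair (even around a lucky one-base match) can
## then never beat plain substitution columns, so diverged co-linear
## segments stay gap-free and no phantom frameshifts appear downstream.
nw_ops <- function(a, b, match = 1, mismatch = -1, gap_open = -3, gap_ext = -0.5) {
  n <- length(a); m <- length(b)
  if (n == 0L && m == 0L)
    return(data.frame(kind = character(0), len = integer(0)))
  if (m == 0L) return(data.frame(kind = "delete", len = n))
  if (n == 0L) return(data.frame(kind = "insert", len = m))
  NEG <- -1e18
  ## state matrices: M diagonal, D gap-in-query (consumes ref), I gap-in-ref
  M <- matrix(NEG, n + 1L, m + 1L); D <- M; I <- M
  M[1, 1] <- 0
  D[2:(n + 1), 1] <- gap_open + gap_ext * (0:(n - 1))
  I[1, 2:(m + 1)] <- gap_open + gap_ext * (0:(m - 1))
  ## traceback pointers: which state each cell came from (1=M,2=D,3=I)
  pM <- matrix(0L, n + 1L, m + 1L); pD <- pM; pI <- pM
  for (i in 2:(n + 1)) {
    ai <- a[i - 1L]
    for (j in 2:(m + 1)) {
      s <- if (ai == b[j - 1L]) match else mismatch
      c3 <- c(M[i - 1L, j - 1L], D[i - 1L, j - 1L], I[i - 1L, j - 1L])
      w <- which.max(c3); M[i, j] <- c3[w] + s; pM[i, j] <- w
      d3 <- c(M[i - 1L, j] + gap_open, D[i - 1L, j] + gap_ext, I[i - 1L, j] + gap_open)
      w <- which.max(d3); D[i, j] <- d3[w]; pD[i, j] <- w
      i3 <- c(M[i, j - 1L] + gap_open, D[i, j - 1L] + gap_open, I[i, j - 1L] + gap_ext)
      w <- which.max(i3); I[i, j] <- i3[w]; pI[i, j] <- w
    }
  }
  ## traceback
  st <- which.max(c(M[n + 1L, m + 1L], D[n + 1L, m + 1L], I[n + 1L, m + 1L]))
  i <- n + 1L; j <- m + 1L
  kinds <- character(n + m); kk <- 0L
  while (i > 1L || j > 1L) {
    kk <- kk + 1L
    if (st == 1L) {
      kinds[kk] <- if (a[i - 1L] == b[j - 1L]) "match" else "mismatch"
      nxt <- pM[i, j]; i <- i - 1L; j <- j - 1L
      if (nxt == 0L) nxt <- if (i == 1L && j > 1L) 3L else 2L
    } else if (st == 2L) {
      kinds[kk] <- "delete"
      nxt <- pD[i, j]; i <- i - 1L
      if (nxt == 0L) nxt <- 2L
    } else {
      kinds[kk] <- "insert"
      nxt <- pI[i, j]; j <- j - 1L
      if (nxt == 0L) nxt <- 3L
    }
    st <- nxt
  }
  merge_ops(rev(kinds[seq_len(kk)]), rep(1L, kk))
}

## longest strictly-increasing subsequence (patience), returns indices
lis_indices <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  tails <- numeric(0); tidx <- integer(0); prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(v[i] - 0.5, tails) + 1L
    tails[j] <- v[i]; tidx[j] <- i
    prev[i] <- if (j > 1L) tidx[j - 1L] else 0L
  }
  out <- integer(0); i <- tidx[length(tails)]
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

#' Align two co-linear sequences by unique k-mer anchoring
#'
#' Finds k-mers occurring exactly once in each sequence, chains the shared
#' ones co-linearly, closes inter-anchor segments by banded global
#' alignment when both gaps are at most `band` bases, and splits blocks at
#' larger unaligned stretches.
#'
#' @param ref,qry [genome_sequence()] objects (or plain strings)
#' @param k anchor k-mer size
#' @param band maximum inter-anchor gap (on either sequence) closed by
#'   Needleman-Wunsch; larger gaps become block boundaries
#' @param min_chain minimum number of chained anchor runs required
#' @return list of [alignment_block()], sorted, non-overlapping on both
#'   sequences, forward strand
#' @export
anchor_align <- function(ref, qry, k = 15L, band = 500L, min_chain = 1L) {
  ref_name <- if (inherits(ref, "genome_sequence")) ref$name else "ref"
  qry_name <- if (inherits(qry, "genome_sequence")) qry$name else "qry"
  rs <- as_seq_string(ref); qs <- as_seq_string(qry)
  nr <- nchar(rs); nq <- nchar(qs)
  if (nr < k || nq < k) stop_fmt("anchor_align: no anchors found (sequence shorter than k)")

  unique_kmers <- function(s, n) {
    starts <- seq_len(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    keep <- !(duplicated(km) | duplicated(km, fromLast = TRUE)) &
      !grepl("N", km, fixed = TRUE)
    list(km = km[keep], pos = starts[keep])
  }
  ur <- unique_kmers(rs, nr)
  uq <- unique_kmers(qs, nq)
  hit <- match(ur$km, uq$km)
  sel <- !is.na(hit)
  if (!any(sel)) stop_fmt("anchor_align: no anchors found")
  r <- ur$pos[sel]; q <- uq$pos[hit[sel]]
  ## r is sorted; collapse exact diagonal runs of consecutive anchors
  brk <- c(TRUE, diff(r) != 1L | diff(q) != 1L)
  run_id <- cumsum(brk)
  r0 <- r[brk]; q0 <- q[brk]
  rl <- as.integer(tabulate(run_id)) + k - 1L  # run length in bases

  keep <- lis_indices(q0)
  if (length(keep) < max(1L, min_chain))
    stop_fmt("anchor_align: no co-linear anchor chain (found %d runs, need %d)",
             length(keep), min_chain)
  r0 <- r0[keep]; q0 <- q0[keep]; rl <- rl[keep]

  ## trim chained runs so they never overlap on either sequence
  prev_re <- 0L; prev_qe <- 0L
  drop <- logical(length(r0))
  for (i in seq_along(r0)) {
    ov <- max(0L, prev_re - r0[i], prev_qe - q0[i])
    r0[i] <- r0[i] + ov; q0[i] <- q0[i] + ov; rl[i] <- rl[i] - ov
    if (rl[i] <= 0L) { drop[i] <- TRUE; next }
    prev_re <- r0[i] + rl[i]; prev_qe <- q0[i] + rl[i]
  }
  r0 <- r0[!drop]; q0 <- q0[!drop]; rl <- rl[!drop]
  if (length(r0) == 0L) stop_fmt("anchor_align: no co-linear anchor chain")

  blocks <- list()
  ops_kind <- list(); ops_len <- list(); oi <- 0L
  blk_r <- r0[1]; blk_q <- q0[1]
  push <- function(kind, len) {
    oi <<- oi + 1L; ops_kind[[oi]] <<- kind; ops_len[[oi]] <<- len
  }
  close_block <- function(next_r, next_q) {
    if (oi > 0L) {
      ops <- merge_ops(unlist(ops_kind[seq_len(oi)]), unlist(ops_len[seq_len(oi)]))
      rspan <- sum(ops$len[ops$kind != "insert"])
      qspan <- sum(ops$len[ops$kind != "delete"])
      blocks[[length(blocks) + 1L]] <<- alignment_block(
        ref_name, blk_r - 1L, blk_r - 1L + rspan,
        qry_name, blk_q - 1L, blk_q - 1L + qspan, "+", ops)
    }
    oi <<- 0L; ops_kind <<- list(); ops_len <<- list()
    blk_r <<- next_r; blk_q <<- next_q
  }

  prev_re <- r0[1]; prev_qe <- q0[1]  # 1-based next-unaligned position
  for (i in seq_along(r0)) {
    dr <- r0[i] - prev_re; dq <- q0[i] - prev_qe
    if (dr > 0L || dq > 0L) {
      ## close a gap when it is small on both sides, or when the DP cost
      ## is still bounded (long-but-thin gaps, e.g. introns vs a CDS)
      if (max(dr, dq) > band && as.numeric(dr) * dq > as.numeric(band)^2) {
        close_block(r0[i], q0[i])
      } else if (dr == dq) {
        a <- seq_chars(substr(rs, prev_re, r0[i] - 1L))
        b <- seq_chars(substr(qs, prev_qe, q0[i] - 1L))
        eq <- a == b
        push(ifelse(eq, "match", "mismatch"), rep(1L, dr))
      } else if (dr == 0L) {
        push("insert", dq)
      } else if (dq == 0L) {
        push("delete", dr)
      } else {
        a <- seq_chars(substr(rs, prev_re, r0[i] - 1L))
        b <- seq_chars(substr(qs, prev_qe, q0[i] - 1L))
        sub <- nw_ops(a, b)
        push(sub$kind, sub$len)
      }
    }
    push("match", rl[i])
    prev_re <- r0[i] + rl[i]; prev_qe <- q0[i] + rl[i]
  }
  close_block(NA, NA)
  blocks
}
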