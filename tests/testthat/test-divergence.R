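# divergence_windows: anchor aligner, change counting, windowing,
# region summaries

test_that("anchor_align on identical sequences yields one all-match block", {
  set.seed(101)
  s <- rand_dna(10000)
  b <- anchor_align(s, s)
  expect_length(b, 1)
  expect_equal(b[[1]]$ops, data.frame(kind = "match", len = 10000L,
                                      stringsAsFactors = FALSE))
  expect_equal(c(b[[1]]$ref_start, b[[1]]$ref_end), c(0L, 10000L))
})

test_that("anchor_align recovers single planted substitutions and deletions", {
  set.seed(102)
  s <- rand_dna(10000)
  q <- s
  old <- substr(q, 5001, 5001)
  substr(q, 5001, 5001) <- setdiff(c("A", "C", "G", "T"), old)[1]
  b <- anchor_align(s, q)
  ops <- do.call(rbind, lapply(b, `[[`, "ops"))
  expect_equal(sum(ops$len[ops$kind == "mismatch"]), 1)
  ## exhaustive-comparison oracle
  expect_equal(sum(strsplit(s, "")[[1]] != strsplit(q, "")[[1]]), 1)

  q2 <- paste0(substr(s, 1, 4000), substr(s, 4008, 10000))
  b2 <- anchor_align(s, q2)
  ops2 <- do.call(rbind, lapply(b2, `[[`, "ops"))
  del <- ops2[ops2$kind == "delete", ]
  expect_equal(nrow(del), 1)
  expect_equal(del$len, 7L)
  expect_false(any(ops2$kind == "mismatch"))

  expect_error(anchor_align("ACGT", "ACGT", k = 15), "no anchors")
})

test_that("anchor_align blocks reconstruct the query (property)", {
  set.seed(103)
  for (case in 1:12) {
    s <- rand_dna(4000)
    ch <- strsplit(s, "")[[1]]
    idx <- sample(4000, 40)
    ch[idx] <- vapply(ch[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    q <- paste(ch, collapse = "")
    ## a couple of small indels
    q <- paste0(substr(q, 1, 1000), substr(q, 1004, 2500),
                rand_dna(5), substr(q, 2501, 4000))
    blocks <- anchor_align(s, q)
    for (b in blocks) {
      rch <- strsplit(substr(s, b$ref_start + 1, b$ref_end), "")[[1]]
      qch <- strsplit(substr(q, b$qry_start + 1, b$qry_end), "")[[1]]
      ri <- 0L; qi <- 0L
      for (oi in seq_len(nrow(b$ops))) {
        kind <- b$ops$kind[oi]; len <- b$ops$len[oi]
        if (kind == "match") {
          expect_identical(rch[ri + seq_len(len)], qch[qi + seq_len(len)])
          ri <- ri + len; qi <- qi + len
        } else if (kind == "mismatch") {
          expect_true(all(rch[ri + seq_len(len)] != qch[qi + seq_len(len)]))
          ri <- ri + len; qi <- qi + len
        } else if (kind == "delete") ri <- ri + len
        else qi <- qi + len
      }
      expect_equal(ri, b$ref_end - b$ref_start)
      expect_equal(qi, b$qry_end - b$qry_start)
    }
  }
})

test_that("block_changes applies the one-change-per-indel rule", {
  mk <- function(kinds, lens) {
    ops <- data.frame(kind = kinds, len = lens, stringsAsFactors = FALSE)
    rspan <- sum(lens[kinds %in% c("match", "mismatch", "delete")])
    qspan <- sum(lens[kinds %in% c("match", "mismatch", "insert")])
    alignment_block("r", 0, rspan, "q", 0, qspan, "+", ops)
  }
  expect_equal(block_changes(mk("match", 100))[c("changes", "aligned_bases")],
               list(changes = 0L, aligned_bases = 100L))
  b <- mk(c("match", "mismatch", "match", "delete", "match"),
          c(10, 3, 5, 7, 10))
  bc <- block_changes(b)
  expect_equal(bc$changes, 4L)
  expect_equal(bc$aligned_bases, 35L)
  ## an insertion of any length is one change
  b2 <- mk(c("match", "insert", "match"), c(10, 12, 10))
  expect_equal(block_changes(b2)$changes, 1L)
  expect_equal(block_changes(b2)$aligned_bases, 20L)
})

test_that("block_changes agrees with the brute-force op walker", {
  set.seed(104)
  for (i in 1:300) {
    b <- rand_block()
    bc <- block_changes(b)
    oc <- walk_changes_oracle(b)
    expect_equal(bc$changes, oc$changes)
    expect_equal(bc$aligned_bases, oc$aligned_bases)
  }
})

test_that("N positions are excluded from changes and aligned bases", {
  ref <- paste0(strrep("A", 50), strrep("N", 20), strrep("A", 30))
  qry <- paste0(strrep("A", 40), strrep("C", 10), strrep("N", 20), strrep("A", 30))
  ops <- data.frame(kind = c("match", "mismatch", "match"), len = c(40, 10, 50))
  b <- alignment_block("r", 0, 100, "q", 0, 100, "+", ops)
  bc <- block_changes(b, ref_seq = ref, qry_seq = qry)
  expect_equal(bc$aligned_bases, 80L)
  expect_equal(bc$changes, 10L)  # mismatches fall outside the N run
  ## mismatch inside the reference N run is excluded
  ops2 <- data.frame(kind = c("match", "mismatch", "match"), len = c(55, 5, 40))
  b2 <- alignment_block("r", 0, 100, "q", 0, 100, "+", ops2)
  expect_equal(block_changes(b2, ref_seq = ref)$changes, 0L)
})

test_that("window_divergence tiles, masks and conserves changes", {
  ops <- data.frame(kind = c("match", "mismatch", "match"),
                    len = c(4000, 52, 5948))
  b <- alignment_block("w", 0, 10000, "q", 0, 10000, "+", ops)
  wd <- window_divergence(list(b), 10000, window = 10000)
  expect_equal(wd$pct, 0.52)
  wd2 <- window_divergence(list(b), 10000, window = 10000,
                           denominator = "aligned_bases")
  expect_equal(wd2$pct, 0.52)

  ## zero divergence: all unmasked windows are exactly 0
  b0 <- alignment_block("w", 0, 50000, "q", 0, 50000, "+",
                        data.frame(kind = "match", len = 50000))
  wd0 <- window_divergence(list(b0), 50000)
  expect_true(all(!wd0$masked))
  expect_true(all(wd0$pct == 0))

  ## windows with aligned fraction < 0.5 are masked, not zero
  wd1 <- window_divergence(list(b0), 120000)
  expect_true(all(wd1$masked[wd1$start >= 50000]))
  expect_true(all(is.na(wd1$pct[wd1$masked])))

  expect_error(window_divergence(list(b0), 1e5, window = 0), "window")
  expect_error(window_divergence(list(b0), 1e5, step = -1), "step")
})

test_that("change counts are conserved and invariant to block splitting", {
  set.seed(105)
  for (i in 1:8) {
    b <- rand_block(ref_start = sample(0:200, 1))
    total <- block_changes(b)$changes
    wd <- window_divergence(list(b), b$ref_end + 10, window = 37)
    expect_equal(sum(wd$changes), total)

    ## split at a match-run boundary into two blocks
    mruns <- which(b$ops$kind == "match")
    if (length(mruns) >= 1 && nrow(b$ops) >= 2) {
      k <- mruns[1]
      pre <- b$ops[seq_len(k), , drop = FALSE]
      post <- b$ops[-seq_len(k), , drop = FALSE]
      if (nrow(post) > 0) {
        radv <- sum(pre$len[pre$kind %in% c("match", "mismatch", "delete")])
        qadv <- sum(pre$len[pre$kind %in% c("match", "mismatch", "insert")])
        b1 <- alignment_block("ref", b$ref_start, b$ref_start + radv,
                              "qry", b$qry_start, b$qry_start + qadv, "+", pre)
        b2 <- alignment_block("ref", b$ref_start + radv, b$ref_end,
                              "qry", b$qry_start + qadv, b$qry_end, "+", post)
        wd_split <- window_divergence(list(b1, b2), b$ref_end + 10, window = 37)
        expect_equal(wd_split$changes, wd$changes)
        expect_equal(wd_split$aligned_bases, wd$aligned_bases)
      }
    }
  }
})

test_that("region_summary interpolates quartiles (type 7)", {
  st <- data.frame(chrom = "w", start = seq(0, 3) * 100, end = seq(1, 4) * 100,
                   aligned_bases = 100, changes = 0,
                   pct = c(0.2, 0.4, 0.6, 0.8), masked = FALSE)
  class(st) <- c("window_stats", "data.frame")
  rs <- region_summary(st, 0, 400)
  expect_equal(rs$median_pct, 0.5)
  expect_equal(rs$q1_pct, 0.35)
  expect_equal(rs$q3_pct, 0.65)
  expect_equal(rs$n_windows, 4)

  st$pct <- 0
  rs0 <- region_summary(st, 0, 400)
  expect_true(all(c(rs0$mean_pct, rs0$median_pct, rs0$q1_pct, rs0$q3_pct) == 0))
  expect_error(region_summary(st, 5000, 6000), "no unmasked windows")
})
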