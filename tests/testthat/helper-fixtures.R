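# Shared fixtures: everything is generated in code, nothing on disk.

LESION_TO_CLASS <- c(none = "intact",
                     frameshift = "pseudogene(frameshift)",
                     premature_stop = "pseudogene(premature_stop)")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

## random valid op list (adjacent kinds may repeat; constructors merge)
rand_ops <- function(n_ops = sample(3:20, 1)) {
  kinds <- sample(c("match", "mismatch", "insert", "delete"), n_ops, TRUE,
                  prob = c(0.6, 0.2, 0.1, 0.1))
  data.frame(kind = kinds, len = sample(1:9, n_ops, TRUE),
             stringsAsFactors = FALSE)
}

rand_block <- function(ref_start = sample(0:5000, 1), qry_start = sample(0:5000, 1)) {
  ops <- rand_ops()
  rspan <- sum(ops$len[ops$kind %in% c("match", "mismatch", "delete")])
  qspan <- sum(ops$len[ops$kind %in% c("match", "mismatch", "insert")])
  alignment_block("ref", ref_start, ref_start + rspan,
                  "qry", qry_start, qry_start + qspan, "+", ops)
}

## independent brute-force oracle for block_changes: expand the op list
## to per-column records and count by first principles
walk_changes_oracle <- function(block) {
  ops <- block$ops
  kind_col <- rep(ops$kind, ops$len)
  run_col <- rep(seq_len(nrow(ops)), ops$len)
  rpos <- integer(length(kind_col))
  r <- block$ref_start
  for (i in seq_along(kind_col)) {
    rpos[i] <- r
    if (kind_col[i] != "insert") r <- r + 1L
  }
  n_snp <- sum(kind_col == "mismatch")
  indel_runs <- unique(run_col[kind_col %in% c("insert", "delete")])
  list(changes = n_snp + length(indel_runs),
       aligned_bases = sum(kind_col != "insert"))
}

## minimal gene-hit stand-in for arithmetic tests (no alignment behind it)
fake_hit <- function(gene_id, start, end, class = "intact") {
  list(gene_id = gene_id, chrom = "W", start = start, end = end, strand = "+",
       coverage = 1, identity = 1, score = end - start,
       qry_start = 0L, qry_end = end - start,
       frameshift = class == "pseudogene(frameshift)",
       premature_stop = class == "pseudogene(premature_stop)",
       cds_projection = "ATG", blocks = list())
}
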