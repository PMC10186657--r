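# synthetic_data: generator contracts, determinism, ground-truth
# consistency and parameter-recovery oracles

quiet_cfg <- function(...) {
  args <- utils::modifyList(
    list(z_length = 2e5, te_burst_rate_long = 0, te_rate_short = 0,
         n_genes = 0, gap_frac = 0, indel_rate = 0, base_divergence = 0,
         snp_rate_w_long = 0, snp_rate_background = 0),
    list(...))
  do.call(sim_config, args)
}

test_that("zero-mutation limit: W equals Z", {
  sim <- simulate_pair(quiet_cfg(seed = 1))
  expect_identical(sim$w$seq, sim$z$seq)
  expect_equal(nrow(sim$truth$planted_te), 0)
  expect_equal(nrow(sim$truth$planted_genes), 0)
})

test_that("identical seed gives byte-identical output", {
  cfg <- sim_config(seed = 5, z_length = 1e5, n_genes = 10,
                    te_burst_rate_long = 300, te_rate_short = 30)
  s1 <- simulate_pair(cfg)
  s2 <- simulate_pair(cfg)
  expect_identical(s1$w$seq, s2$w$seq)
  expect_identical(s1$truth$planted_te, s2$truth$planted_te)
  expect_identical(s1$truth$planted_snps, s2$truth$planted_snps)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(s1$w, f1); write_fasta(s2$w, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("substitution divergence matches the binomial oracle", {
  p <- 0.009; n <- 5e5
  sim <- simulate_pair(quiet_cfg(seed = 2, z_length = n, base_divergence = p))
  obs <- mean(strsplit(sim$z$seq, "")[[1]] != strsplit(sim$w$seq, "")[[1]])
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("homology map reproduces W from Z outside insertions and gap", {
  cfg <- sim_config(seed = 3, z_length = 1.5e5, base_divergence = 0,
                    indel_rate = 0, n_genes = 10,
                    te_burst_rate_long = 300, te_rate_short = 30)
  sim <- simulate_pair(cfg)
  hm <- sim$truth$homology_map
  expect_gt(nrow(hm), 1)
  for (i in seq_len(nrow(hm))) {
    expect_identical(substr(sim$z$seq, hm$z_start[i] + 1, hm$z_end[i]),
                     substr(sim$w$seq, hm$w_start[i] + 1, hm$w_end[i]))
  }
  ## homologous, TE, gene and gap bases fully account for W
  te_bases <- sum(sim$truth$planted_te$w_end - sim$truth$planted_te$w_start)
  gene_bases <- sum(sim$truth$planted_genes$w_end - sim$truth$planted_genes$w_start)
  hom_bases <- sum(hm$w_end - hm$w_start)
  gap_bases <- diff(sim$truth$gap_interval)
  expect_equal(hom_bases + te_bases + gene_bases + gap_bases, sim$w$length)
})

test_that("gap_interval is exactly the maximal N-run and arms tile W", {
  sim <- simulate_pair(sim_config(seed = 4, z_length = 1e5, n_genes = 0,
                                  te_burst_rate_long = 100, te_rate_short = 10))
  gaps <- find_n_gaps(sim$w, min_run = 100)
  expect_equal(nrow(gaps), 1)
  expect_equal(c(gaps$start, gaps$end), sim$truth$gap_interval)
  arms <- sim$truth$arms
  expect_equal(diff(arms$long_arm) + diff(arms$gap) + diff(arms$short_arm),
               sim$w$length)
})

test_that("plant_te_copies honours rates and the age mixture", {
  set.seed(42)
  fam <- list(TE01 = rand_dna(1000), TE02 = rand_dna(800))
  base <- rand_dna(2e5)

  out0 <- plant_te_copies(base, fam, rate_per_mbp = 0)
  expect_identical(out0$seq$seq, base)
  expect_equal(nrow(out0$truth), 0)

  ## young component: realized divergence within 3 SD of its mean
  out <- plant_te_copies(rand_dna(4e5), fam, rate_per_mbp = 400,
                         young_frac = 1, kimura_young = 0.005)
  tot_bases <- sum(nchar(out$truth$seq))
  expect_gt(nrow(out$truth), 50)
  expect_lt(abs(mean(out$truth$realized_divergence) - 0.005),
            3 * sqrt(0.005 * 0.995 / tot_bases) +
              3 * 0.005 / sqrt(nrow(out$truth)))

  ## 10x rate contrast recovered within Poisson error (conditional binomial)
  n1 <- nrow(plant_te_copies(rand_dna(2e5), fam, 500)$truth)
  n2 <- nrow(plant_te_copies(rand_dna(2e5), fam, 50)$truth)
  p_hat <- n1 / (n1 + n2)
  expect_lt(abs(p_hat - 10 / 11), 3 * sqrt((10 / 11) * (1 / 11) / (n1 + n2)))

  ## inserted copies are recoverable at their truth intervals
  expect_identical(substr(out0$seq$seq, 1, 10), substr(base, 1, 10))
  one <- plant_te_copies(rand_dna(5e4), fam, 100)
  for (i in seq_len(nrow(one$truth)))
    expect_identical(substr(one$seq$seq, one$truth$w_start[i] + 1,
                            one$truth$w_end[i]), one$truth$seq[i])
})

test_that("planted genes obey the CDS contract and lesion options", {
  set.seed(7)
  base <- rand_dna(2e5)
  clean <- plant_genes_and_pseudogenes(base, 12, pseudo_frac = 0)
  expect_true(all(clean$truth$lesion == "none"))
  for (cds in clean$cds) {
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    aa <- translate_string(cds)
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }
  forced <- plant_genes_and_pseudogenes(base, 10, pseudo_frac = 1,
                                        lesion_opts = "frameshift")
  expect_true(all(forced$truth$lesion == "frameshift"))

  set.seed(8)
  many <- plant_genes_and_pseudogenes(rand_dna(8e5), 200, pseudo_frac = 0.2)
  frac <- mean(many$truth$is_pseudogene)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 200))
})

test_that("pooled counts follow the planted-allele model", {
  cfg <- sim_config(seed = 9, z_length = 2e5, n_genes = 0,
                    te_burst_rate_long = 0, te_rate_short = 0,
                    snp_rate_w_long = 2, snp_rate_background = 0.1)
  sim <- simulate_pair(cfg)
  pools <- simulate_pools(sim$w, sim$truth, depth = 40, n_sites = 3000,
                          error_rate = 0, seed = 10)
  planted_pos <- sim$truth$planted_snps$pos
  bg <- !(pools$pos %in% planted_pos)
  cnt <- as.matrix(pools[, 4:11])
  ref_idx <- match(pools$ref, c("A", "C", "G", "T"))
  fdep <- rowSums(cnt[, 1:4]); mdep <- rowSums(cnt[, 5:8])
  f_ref <- cnt[cbind(seq_len(nrow(pools)), ref_idx)]
  m_ref <- cnt[cbind(seq_len(nrow(pools)), ref_idx + 4L)]
  ## error 0: non-planted sites carry only the reference allele
  expect_true(all(f_ref[bg] == fdep[bg]))
  expect_true(all(m_ref[bg] == mdep[bg]))
  ## planted sites: female alternate fraction ~ 0.5, male pool clean
  m <- merge(pools, sim$truth$planted_snps, by = c("chrom", "pos"))
  fmat <- as.matrix(m[, c("fA", "fC", "fG", "fT")])
  alt_reads <- fmat[cbind(seq_len(nrow(m)), match(m$allele, c("A", "C", "G", "T")))]
  tot <- sum(rowSums(fmat))
  expect_lt(abs(sum(alt_reads) / tot - 0.5), 3 * sqrt(0.25 / tot))
  mmat <- as.matrix(m[, c("mA", "mC", "mG", "mT")])
  expect_equal(sum(mmat[cbind(seq_len(nrow(m)), match(m$allele, c("A", "C", "G", "T")))]), 0)
  ## determinism
  pools2 <- simulate_pools(sim$w, sim$truth, depth = 40, n_sites = 3000,
                           error_rate = 0, seed = 10)
  expect_identical(as.data.frame(pools), as.data.frame(pools2))
})

test_that("write_simulation emits a consistent text bundle", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 12, z_length = 8e4, n_genes = 4,
                    te_burst_rate_long = 150, te_rate_short = 20,
                    pool_n_sites = 500)
  sim <- simulate_pair(cfg)
  pools <- simulate_pools(sim$w, sim$truth, n_sites = 500, seed = 13)
  write_simulation(sim, dir, pools = pools)
  expect_identical(read_fasta(file.path(dir, "w.fa"))[[1]]$seq, sim$w$seq)
  copies <- read_te_alignments(file.path(dir, "te_copies.tsv"), "internal")
  expect_equal(nrow(copies), nrow(sim$truth$planted_te))
  back <- read_pool_counts(file.path(dir, "pools.tsv"))
  expect_equal(back$pos, pools$pos)
})
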