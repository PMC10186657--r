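# gene_decay: projection, filtering, pseudogene calls, H-score clustering

make_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0("ATG", paste(sample(wzdiff:::NON_STOP_CODONS, n_codons - 2, TRUE),
                      collapse = ""), "TAA")
}

test_that("a verbatim planted query is recovered at full coverage/identity", {
  set.seed(301)
  cds <- make_cds(120)
  target <- genome_sequence("W", paste0(rand_dna(5000), cds, rand_dna(5000)))
  hits <- project_gene(cds, target, gene_id = "g1")
  expect_length(hits, 1)
  expect_equal(hits[[1]]$coverage, 1)
  expect_equal(hits[[1]]$identity, 1)
  expect_equal(hits[[1]]$start, 5000)
  expect_equal(classify_pseudogene(hits[[1]]), "intact")

  ## absent query: empty list, not an error
  expect_length(project_gene(make_cds(100), genome_sequence("W", rand_dna(8000))), 0)
  expect_error(project_gene(rand_dna(60), target), "90 nt")
})

test_that("identity reflects planted substitutions", {
  set.seed(302)
  cds <- make_cds(200)  # 600 nt
  ch <- strsplit(cds, "")[[1]]
  idx <- sample(10:590, 60)
  ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
  copy <- paste(ch, collapse = "")
  target <- genome_sequence("W", paste0(rand_dna(3000), copy, rand_dna(3000)))
  hits <- project_gene(cds, target)
  expect_length(hits, 1)
  expect_lt(abs(hits[[1]]$identity - 0.9), 0.02)
})

test_that("reverse-strand copies are found", {
  set.seed(303)
  cds <- make_cds(150)
  rc <- wzdiff:::revcomp(cds)
  target <- genome_sequence("W", paste0(rand_dna(4000), rc, rand_dna(4000)))
  hits <- project_gene(cds, target)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$strand, "-")
  expect_equal(hits[[1]]$identity, 1)
})

test_that("filtering is strict and resolves reciprocal overlaps by score", {
  h <- function(id, cov, ident, start = 0, end = 1000, score = 100) {
    x <- fake_hit(id, start, end)
    x$coverage <- cov; x$identity <- ident; x$score <- score
    x
  }
  hits <- list(h("a", 0.34, 0.90), h("b", 0.36, 0.51), h("c", 0.90, 0.50))
  kept <- filter_gene_alignments(hits)
  expect_equal(vapply(kept, `[[`, "", "gene_id"), "b")

  ## 90% reciprocal overlap: best score wins
  o1 <- h("x", 1, 1, 0, 1000, score = 100)
  o2 <- h("y", 1, 1, 100, 1100, score = 80)
  kept2 <- filter_gene_alignments(list(o1, o2))
  expect_equal(vapply(kept2, `[[`, "", "gene_id"), "x")
  ## small overlap: both kept
  o3 <- h("z", 1, 1, 900, 1900, score = 80)
  expect_length(filter_gene_alignments(list(o1, o3)), 2)
})

test_that("planted lesions are classified from projections", {
  ## Lesions abutting an exon/intron boundary can be absorbed into the
  ## intron gap by any spliced aligner (the gap merely changes length);
  ## recovery is therefore near-perfect, not perfect. The unambiguous
  ## mid-CDS cases are asserted exactly in the next test block.
  set.seed(304)
  base <- rand_dna(110000)
  fs <- plant_genes_and_pseudogenes(base, 12, pseudo_frac = 1,
                                    lesion_opts = "frameshift")
  hits <- filter_gene_alignments(project_genes(fs$cds, fs$seq))
  cls <- vapply(hits, classify_pseudogene, "")
  expect_gte(sum(cls == "pseudogene(frameshift)"), 9L)

  ps <- plant_genes_and_pseudogenes(rand_dna(110000), 12, pseudo_frac = 1,
                                    lesion_opts = "premature_stop")
  hits2 <- filter_gene_alignments(project_genes(ps$cds, ps$seq))
  cls2 <- vapply(hits2, classify_pseudogene, "")
  expect_gte(sum(cls2 == "pseudogene(premature_stop)"), 11L)

  ok <- plant_genes_and_pseudogenes(rand_dna(110000), 12, pseudo_frac = 0)
  hits3 <- filter_gene_alignments(project_genes(ok$cds, ok$seq))
  expect_true(all(vapply(hits3, classify_pseudogene, "") == "intact"))

  ## a missing projection is a contract violation
  broken <- fake_hit("g", 0, 300); broken$cds_projection <- NULL
  expect_error(classify_pseudogene(broken), "projection")
})

test_that("a TAC->TAA substitution mid-CDS is a premature stop", {
  set.seed(305)
  cds <- make_cds(120)  # 360 nt
  copy <- cds
  substr(copy, 3 * 39 + 1, 3 * 40) <- "TAA"  # codon 40 of 120
  target <- genome_sequence("W", paste0(rand_dna(2000), copy, rand_dna(2000)))
  hits <- project_gene(cds, target)
  expect_equal(classify_pseudogene(hits[[1]]), "pseudogene(premature_stop)")
  ## 1 bp deletion mid-CDS is a frameshift
  copy2 <- paste0(substr(cds, 1, 180), substr(cds, 182, nchar(cds)))
  target2 <- genome_sequence("W", paste0(rand_dna(2000), copy2, rand_dna(2000)))
  hits2 <- project_gene(cds, target2)
  expect_equal(classify_pseudogene(hits2[[1]]), "pseudogene(frameshift)")
})

test_that("pseudogene_fraction reproduces printed arithmetic", {
  mk_region_hits <- function(n, n_pseudo, start) {
    lapply(seq_len(n), function(i)
      fake_hit(sprintf("g%d_%d", start, i), start + i * 10, start + i * 10 + 5,
               class = if (i <= n_pseudo) "pseudogene(frameshift)" else "intact"))
  }
  hits <- c(mk_region_hits(690, 144, 0), mk_region_hits(594, 97, 3.05e4))
  regions <- data.frame(name = c("long_arm", "short_arm"),
                        start = c(0, 3e4), end = c(3e4, 7e4))
  pf <- pseudogene_fraction(hits, regions)
  expect_equal(pf$pct_1dp, c(20.9, 16.3))
  expect_equal(sum(pf$n_genes), length(hits))
  ## zero pseudogenes
  pf0 <- pseudogene_fraction(mk_region_hits(10, 0, 0), regions)
  expect_equal(pf0$pct_1dp[1], 0)
  ## classification commutes with filtering
  some <- mk_region_hits(20, 7, 0)
  cls_then_filter <- vapply(filter_gene_alignments(some), classify_pseudogene, "")
  pre <- vapply(some, classify_pseudogene, "")
  names(pre) <- vapply(some, `[[`, "", "gene_id")
  kept_ids <- vapply(filter_gene_alignments(some), `[[`, "", "gene_id")
  expect_equal(unname(pre[kept_ids]), cls_then_filter)
})

test_that("hscore is symmetric, 100 on self, low on unrelated pairs", {
  set.seed(306)
  a <- rand_dna(1000)
  expect_equal(hscore(a, a), 100)
  for (i in 1:10) {
    x <- rand_dna(500); y <- rand_dna(500)
    expect_equal(hscore(x, y), hscore(y, x), tolerance = 1e-9)
  }
  hmax <- max(vapply(1:100, function(i) hscore(rand_dna(1000), rand_dna(1000)), 0))
  expect_lt(hmax, 30)
})

test_that("cluster_duplicates reports multi-copy genes with arm counts", {
  set.seed(307)
  cdsA <- make_cds(130); cdsB <- make_cds(140)
  target <- genome_sequence("W", paste0(
    rand_dna(3000), cdsA, rand_dna(5000), cdsA, rand_dna(5000), cdsB, rand_dna(3000)))
  z_cds <- c(geneA = cdsA, geneB = cdsB)
  hits <- filter_gene_alignments(project_genes(z_cds, target))
  regions <- data.frame(name = c("long_arm", "short_arm"),
                        start = c(0, 10000), end = c(10000, target$length))
  cl <- cluster_duplicates(z_cds, hits, target, h_threshold = 90, regions = regions)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$source_gene_id, "geneA")
  expect_equal(cl$n_copies, 2)
  expect_equal(cl$n_long_arm + cl$n_short_arm, cl$n_copies)
  ## single-ortholog genes are never reported
  hitsB <- hits[vapply(hits, `[[`, "", "gene_id") == "geneB"]
  expect_equal(nrow(cluster_duplicates(z_cds, hitsB, target)), 0)
})
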