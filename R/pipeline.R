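## End-to-end convenience pipeline for a simulated (or equivalently
## structured) Z/W pair: align, window, score TE ages, project genes,
## call sex-specific SNPs, partition arms, and build the integrated
## report.

#' Run the full W/Z differentiation pipeline on a simulated pair
#'
#' Individual stages can be switched off; missing stages appear as
#' `"absent"` in the report, never as zero.
#'
#' @param sim [simulate_pair()] result
#' @param pools optional [simulate_pools()] table for the SNP stage
#' @param window divergence window size (bases)
#' @param denominator passed to [window_divergence()]
#' @param snp_params [snp_call_params()]
#' @param do_divergence,do_te,do_genes run/skip stages
#' @param gap_min_run minimum N-run treated as an assembly gap
#' @return list with `report` ([build_report()] output) and the
#'   intermediate objects (`blocks`, `windows`, `te_scored`, `gene_hits`,
#'   `snp_calls`, `partition`)
#' @export
run_wz_pipeline <- function(sim, pools = NULL, window = 10000L,
                            denominator = "window_size",
                            snp_params = snp_call_params(),
                            do_divergence = TRUE, do_te = TRUE, do_genes = TRUE,
                            gap_min_run = 1000L) {
  stopifnot(inherits(sim, "wz_sim"))
  cfg <- sim$truth$config

  ## karyotype: gap-delimited arm partition of W
  gaps <- find_n_gaps(sim$w, min_run = gap_min_run)
  partition <- if (nrow(gaps) > 0L) {
    partition_arms(sim$w$length, gaps = gaps)
  } else if (!is.null(sim$truth$arms)) {
    sim$truth$arms
  } else {
    stop_fmt("run_wz_pipeline: no N-gap found and no partition in truth")
  }
  w_regions <- arm_regions(partition)

  blocks <- NULL; windows <- NULL; div_summaries <- NULL
  if (do_divergence) {
    blocks <- anchor_align(sim$z, sim$w)
    windows <- window_divergence(blocks, sim$z$length, window = window,
                                 denominator = denominator,
                                 ref_seq = sim$z, qry_seq = sim$w)
    ## divergence windows live on Z; arm regions map to the Z homologs
    L1 <- round(cfg$w_long_frac * cfg$z_length)
    div_summaries <- list(
      long_arm = region_summary(windows, 0, L1),
      short_arm = region_summary(windows, L1, sim$z$length))
  }

  te_scored <- NULL; te_young <- NULL
  if (do_te && nrow(sim$truth$planted_te) > 0L) {
    copies <- data.frame(chrom = sim$truth$planted_te$chrom,
                         start = sim$truth$planted_te$w_start,
                         end = sim$truth$planted_te$w_end,
                         family = sim$truth$planted_te$family,
                         strand = "+",
                         copy_seq = sim$truth$planted_te$seq,
                         stringsAsFactors = FALSE)
    te_scored <- score_te_copies(copies, sim$truth$te_families, cpg_mode = "adjusted")
    te_young <- young_fraction_by_region(te_scored, w_regions)
  }

  gene_hits <- NULL; gene_fracs <- NULL
  if (do_genes && length(sim$truth$gene_cds) > 0L) {
    hits <- project_genes(sim$truth$gene_cds, sim$w)
    gene_hits <- filter_gene_alignments(hits)
    gene_fracs <- pseudogene_fraction(gene_hits, w_regions)
  }

  snp_calls <- NULL
  if (!is.null(pools)) snp_calls <- call_sex_specific_sites(pools, snp_params)

  report <- build_report(partition,
                         divergence = div_summaries,
                         te = te_young,
                         genes = gene_fracs,
                         snps = snp_calls,
                         chrom_lengths = c(W = sim$w$length, Z = sim$z$length),
                         config = unclass(cfg),
                         autosome_pseudo_pct = 100 * cfg$pseudo_frac_autosome)
  list(report = report, blocks = blocks, windows = windows,
       divergence = div_summaries, te_scored = te_scored, te_young = te_young,
       gene_hits = gene_hits, gene_fracs = gene_fracs,
       snp_calls = snp_calls, partition = partition)
}
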