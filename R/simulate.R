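## Synthetic Z/W chromosome-pair generator.
##
## Emulates, at a configurable scale (default 1/10 of the real system: a
## ~2.8 Mbp acrocentric Z), the statistical structure of a young
## differentiating W: co-linear homology at ~0.9% divergence, a
## centromeric N-gap between long and short arm, a long-arm burst of
## young TE copies, planted multi-exon genes with elevated long-arm
## pseudogenization, and an excess of female-specific SNPs on the long
## arm. All rates are per-base so results are scale-free. One RNG stream,
## seeded from the config, drives every draw in documented order:
## Z sequence, TE family consensuses, then per arm (long first)
## substitutions, indels, TE events, gene events, and finally SNP sites.

#' Simulation configuration
#'
#' Defaults state the emulated system at 1/10 scale: Z 2.8 Mbp, W long
#' arm expanded to ~2.75 Mbp by a TE burst (600 insertions/Mbp, ~1% of
#' them young), a 300 kb centromeric N-gap, a ~1.45 Mbp short arm, 200
#' planted genes with pseudogene fractions 20.9% (long) / 16.3% (short),
#' and female-specific SNPs at 1.5/kb on the long arm versus 0.1/kb
#' background (15-fold).
#'
#' @param seed RNG seed (single integer)
#' @param z_length Z chromosome length in bases
#' @param w_long_frac fraction of Z (from its start) homologous to the W
#'   long arm
#' @param gap_frac centromeric N-gap length as a fraction of `z_length`
#' @param w_short_scale fraction of the distal Z retained as the W short
#'   arm homolog
#' @param base_divergence per-base substitution probability between
#'   homologous Z/W positions
#' @param indel_rate indel events per base
#' @param indel_length_geom_p geometric parameter; lengths are
#'   `1 + rgeom(p)`
#' @param n_te_families number of TE families
#' @param te_consensus_len_range consensus length range (bases)
#' @param te_burst_rate_long,te_rate_short TE insertions per Mbp per arm
#' @param te_age_young_frac_long,te_age_young_frac_short fraction of
#'   copies drawn from the young age component
#' @param kimura_young_mean,kimura_old_mean expected per-copy divergence
#'   from consensus for the two age components (raw proportion scale)
#' @param n_genes planted genes (split between arms by homolog length)
#' @param gene_divergence per-base substitution rate applied to planted
#'   gene copies (codon-aware: never creates an in-frame stop)
#' @param pseudo_frac_long,pseudo_frac_short planted pseudogene fraction
#'   per arm
#' @param pseudo_frac_autosome autosome reference pseudogene fraction
#'   (used only in report arithmetic)
#' @param snp_rate_w_long,snp_rate_background female-specific SNP
#'   planting rates per kb (long arm vs elsewhere)
#' @param pool_depth mean reads per site per pool
#' @param pool_error_rate per-read sequencing error probability
#' @param pool_n_sites total sites emitted in the pooled count table
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       z_length = 2.8e6,
                       w_long_frac = 0.5,
                       gap_frac = 3 / 28,
                       w_short_scale = 1,
                       base_divergence = 0.009,
                       indel_rate = 5e-4,
                       indel_length_geom_p = 0.5,
                       n_te_families = 10L,
                       te_consensus_len_range = c(300L, 3000L),
                       te_burst_rate_long = 600,
                       te_rate_short = 60,
                       te_age_young_frac_long = 0.01,
                       te_age_young_frac_short = 0.0039,
                       kimura_young_mean = 0.005,
                       kimura_old_mean = 0.15,
                       n_genes = 200L,
                       gene_divergence = 0.009,
                       pseudo_frac_long = 0.209,
                       pseudo_frac_short = 0.163,
                       pseudo_frac_autosome = 0.125,
                       snp_rate_w_long = 1.5,
                       snp_rate_background = 0.1,
                       pool_depth = 40,
                       pool_error_rate = 0.002,
                       pool_n_sites = 20000L) {
  cfg <- as.list(environment())
  rates <- c(base_divergence, indel_rate, te_burst_rate_long, te_rate_short,
             snp_rate_w_long, snp_rate_background, gene_divergence,
             kimura_young_mean, kimura_old_mean)
  if (any(rates < 0)) stop_fmt("sim_config: rates must be >= 0")
  fracs <- c(w_long_frac, gap_frac, w_short_scale, te_age_young_frac_long,
             te_age_young_frac_short, pseudo_frac_long, pseudo_frac_short,
             pseudo_frac_autosome)
  if (any(fracs < 0 | fracs > 1)) stop_fmt("sim_config: fractions must be in [0,1]")
  if (z_length <= 0) stop_fmt("sim_config: z_length must be positive")
  if (!(indel_length_geom_p > 0 && indel_length_geom_p <= 1))
    stop_fmt("sim_config: indel_length_geom_p must be in (0,1]")
  if (pool_depth <= 0) stop_fmt("sim_config: pool_depth must be positive")
  structure(cfg, class = "sim_config")
}

TS_MAP <- c(A = "G", G = "A", C = "T", T = "C")
TV_MAP1 <- c(A = "C", G = "C", C = "A", T = "A")
TV_MAP2 <- c(A = "T", G = "T", C = "G", T = "G")
STOP_CODONS <- c("TAA", "TAG", "TGA")

## substitute bases at per-base rate; transitions twice as likely as each
## transversion pathway combined is not biological dogma here, just a
## fixed 2:1 ts:tv convention so Kimura p and q are both exercised
mutate_string <- function(s, rate) {
  if (rate <= 0) return(list(seq = s, n_sub = 0L))
  ch <- seq_chars(s)
  idx <- which(runif(length(ch)) < rate & ch != "N")
  if (length(idx) == 0L) return(list(seq = s, n_sub = 0L))
  cur <- ch[idx]
  is_ts <- runif(length(idx)) < 2 / 3
  pick <- runif(length(idx)) < 0.5
  ch[idx] <- ifelse(is_ts, TS_MAP[cur], ifelse(pick, TV_MAP1[cur], TV_MAP2[cur]))
  list(seq = paste(ch, collapse = ""), n_sub = length(idx))
}

## codon-aware, stop-free substitution of a CDS: the terminal stop codon
## is preserved and any mutation creating an internal in-frame stop is
## reverted, so planted "intact" genes stay translatable and lesion truth
## labels stay meaningful
mutate_cds_stopfree <- function(cds, rate) {
  n <- nchar(cds)
  if (rate <= 0 || n < 6L) return(cds)
  body <- substr(cds, 1L, n - 3L)
  mut <- mutate_string(body, rate)$seq
  nc <- nchar(mut) %/% 3L
  st <- 3L * (seq_len(nc) - 1L) + 1L
  codons <- substring(mut, st, st + 2L)
  bad <- which(codons %in% STOP_CODONS)
  if (length(bad)) {
    orig <- substring(body, st, st + 2L)
    codons[bad] <- orig[bad]
    mut <- paste(codons, collapse = "")
  }
  paste0(mut, substr(cds, n - 2L, n))
}

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")  # utils.R may not be loaded yet at collation time
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

## one multi-exon gene model; returns the inserted genomic sequence, the
## ancestral (query) CDS and the lesion applied
make_gene <- function(is_pseudo, gene_divergence,
                      lesion_opts = c("frameshift", "premature_stop")) {
  n_codons <- sample(100:500, 1L)
  cds0 <- paste0("ATG",
                 paste(sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
                       collapse = ""),
                 sample(STOP_CODONS, 1L))
  cds <- mutate_cds_stopfree(cds0, gene_divergence)
  lesion <- "none"
  if (is_pseudo) {
    lesion <- if (length(lesion_opts) == 1L) lesion_opts else
      sample(lesion_opts, 1L)
    if (lesion == "premature_stop") {
      j <- sample(2:(max(3L, floor(0.9 * n_codons)) - 1L), 1L)
      substr(cds, 3L * (j - 1L) + 1L, 3L * j) <- "TAA"
    } else {
      l <- sample(1:2, 1L)
      pos <- sample(seq(4L, nchar(cds) - 6L), 1L)
      if (runif(1) < 0.5) {
        cds <- paste0(substr(cds, 1L, pos), random_dna(l),
                      substr(cds, pos + 1L, nchar(cds)))
      } else {
        cds <- paste0(substr(cds, 1L, pos), substr(cds, pos + 1L + l, nchar(cds)))
      }
    }
  }
  n_exons <- sample(2:8, 1L)
  ## exon boundaries on a 30 nt grid: no exon shorter than 30 nt (micro-exons
  ## below anchor size would be unmappable by any aligner, ours included)
  grid <- seq(30L, nchar(cds) - 30L, by = 30L)
  cuts <- sort(sample(grid, min(n_exons - 1L, length(grid))))
  n_exons <- length(cuts) + 1L
  bounds <- c(0L, cuts, nchar(cds))
  exons <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
  ## canonical GT...AG splice ends; like real splice sites they are not
  ## subject to divergence (introns here are generated fresh, not mutated)
  introns <- vapply(seq_len(n_exons - 1L), function(i)
    paste0("GT", random_dna(sample(50:500, 1L) - 4L), "AG"), character(1))
  genomic <- paste0(paste0(exons[-n_exons], introns, collapse = ""), exons[n_exons])
  list(genomic = genomic, cds_query = cds0, lesion = lesion,
       n_codons = n_codons, n_exons = n_exons)
}

## draw TE insertion events for one arm
draw_te_events <- function(arm_len, families, rate_per_mbp, young_frac,
                           k_young, k_old) {
  n <- rpois(1L, rate_per_mbp * arm_len / 1e6)
  if (n == 0L)
    return(data.frame(pos = integer(0), family = character(0),
                      age = character(0), target_divergence = numeric(0),
                      realized_divergence = numeric(0), seq = character(0),
                      stringsAsFactors = FALSE))
  exp_len <- mean(nchar(unlist(families)))
  if (n * exp_len > 50 * arm_len)
    stop_fmt("plant_te_copies: expected insertions (%d x %.0f bp) exceed sequence capacity", n, exp_len)
  pos <- sample.int(arm_len, n, replace = TRUE) - 1L
  fam <- sample(names(families), n, replace = TRUE)
  young <- runif(n) < young_frac
  d <- ifelse(young, k_young, k_old)
  seqs <- character(n); real <- numeric(n)
  for (i in seq_len(n)) {
    mu <- mutate_string(families[[fam[i]]], d[i])
    seqs[i] <- mu$seq
    real[i] <- mu$n_sub / nchar(mu$seq)
  }
  data.frame(pos = pos, family = fam, age = ifelse(young, "young", "old"),
             target_divergence = d, realized_divergence = real, seq = seqs,
             stringsAsFactors = FALSE)
}

## assemble one arm: substitutions in place, then indel/TE/gene insertion
## events applied in a single coordinate pass over the ancestral arm
build_arm <- function(arm_seq, cfg, te_rate, young_frac, n_genes_arm,
                      pseudo_frac, gene_prefix) {
  arm_len <- nchar(arm_seq)
  mut <- mutate_string(arm_seq, cfg$base_divergence)$seq

  ev <- list()
  ## indels
  n_ind <- rpois(1L, cfg$indel_rate * arm_len)
  if (n_ind > 0L) {
    ipos <- sample.int(arm_len, n_ind, replace = TRUE) - 1L
    is_ins <- runif(n_ind) < 0.5
    ilen <- 1L + rgeom(n_ind, cfg$indel_length_geom_p)
    ev$indel <- data.frame(pos = ipos, type = ifelse(is_ins, "ins", "del"),
                           del_len = ifelse(is_ins, 0L, ilen),
                           seq = ifelse(is_ins, vapply(ilen, random_dna, ""), ""),
                           class = "indel", meta = NA_integer_,
                           stringsAsFactors = FALSE)
  }
  ## TE copies
  te <- draw_te_events(arm_len, cfg$families, te_rate, young_frac,
                       cfg$kimura_young_mean, cfg$kimura_old_mean)
  if (nrow(te) > 0L)
    ev$te <- data.frame(pos = te$pos, type = "ins", del_len = 0L, seq = te$seq,
                        class = "te", meta = seq_len(nrow(te)),
                        stringsAsFactors = FALSE)
  ## genes
  genes <- list()
  if (n_genes_arm > 0L) {
    is_pseudo <- runif(n_genes_arm) < pseudo_frac
    gpos <- sample.int(arm_len, n_genes_arm, replace = TRUE) - 1L
    for (i in seq_len(n_genes_arm))
      genes[[i]] <- c(make_gene(is_pseudo[i], cfg$gene_divergence,
                                cfg$lesion_opts %||% c("frameshift", "premature_stop")),
                      list(pos = gpos[i], is_pseudo = is_pseudo[i]))
    ev$gene <- data.frame(pos = gpos, type = "ins", del_len = 0L,
                          seq = vapply(genes, `[[`, "", "genomic"),
                          class = "gene", meta = seq_along(genes),
                          stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(pos = integer(0), type = character(0), del_len = integer(0),
               seq = character(0), class = character(0), meta = integer(0),
               stringsAsFactors = FALSE)
  events <- events[order(events$pos), , drop = FALSE]
  ## drop events at duplicate positions or inside an earlier deletion
  keep <- logical(nrow(events)); cur <- 0L
  last_pos <- -1L
  for (i in seq_len(nrow(events))) {
    p <- events$pos[i]
    if (p < cur || p == last_pos) next
    keep[i] <- TRUE
    last_pos <- p
    if (events$type[i] == "del") cur <- p + events$del_len[i]
    else cur <- max(cur, p)
  }
  events <- events[keep, , drop = FALSE]

  ## single assembly pass
  pieces_seq <- character(0)
  hom <- list(); te_iv <- list(); gene_iv <- list()
  cur <- 0L; w <- 0L
  emit_hom <- function(z0, z1) {
    if (z1 > z0) {
      pieces_seq[[length(pieces_seq) + 1L]] <<- substr(mut, z0 + 1L, z1)
      hom[[length(hom) + 1L]] <<- c(z0, z1, w)
      w <<- w + (z1 - z0)
    }
  }
  for (i in seq_len(nrow(events))) {
    p <- events$pos[i]
    emit_hom(cur, p)
    if (events$type[i] == "del") {
      cur <- p + events$del_len[i]
    } else {
      s <- events$seq[i]
      if (events$class[i] == "te")
        te_iv[[length(te_iv) + 1L]] <- c(events$meta[i], w, w + nchar(s))
      if (events$class[i] == "gene")
        gene_iv[[length(gene_iv) + 1L]] <- c(events$meta[i], w, w + nchar(s))
      pieces_seq[[length(pieces_seq) + 1L]] <- s
      w <- w + nchar(s)
      cur <- p
    }
  }
  emit_hom(cur, arm_len)

  hom_df <- if (length(hom)) {
    h <- do.call(rbind, hom)
    data.frame(z_start = h[, 1], z_end = h[, 2], w_start = h[, 3],
               w_end = h[, 3] + (h[, 2] - h[, 1]))
  } else data.frame(z_start = integer(0), z_end = integer(0),
                    w_start = integer(0), w_end = integer(0))
  te_df <- te[integer(0), , drop = FALSE]
  if (length(te_iv)) {
    tm <- do.call(rbind, te_iv)
    te_df <- te[tm[, 1], , drop = FALSE]
    te_df$w_start <- tm[, 2]; te_df$w_end <- tm[, 3]
  } else {
    te_df$w_start <- integer(0); te_df$w_end <- integer(0)
  }
  gene_df <- data.frame(gene_id = character(0), w_start = integer(0),
                        w_end = integer(0), is_pseudogene = logical(0),
                        lesion = character(0), stringsAsFactors = FALSE)
  gene_cds <- character(0)
  if (length(gene_iv)) {
    gm <- do.call(rbind, gene_iv)
    ids <- sprintf("%s%03d", gene_prefix, gm[, 1])
    gene_df <- data.frame(
      gene_id = ids, w_start = gm[, 2], w_end = gm[, 3],
      is_pseudogene = vapply(genes[gm[, 1]], `[[`, logical(1), "is_pseudo"),
      lesion = vapply(genes[gm[, 1]], `[[`, "", "lesion"),
      stringsAsFactors = FALSE)
    gene_cds <- setNames(vapply(genes[gm[, 1]], `[[`, "", "cds_query"), ids)
  }
  list(seq = paste(pieces_seq, collapse = ""), w_len = w,
       homology = hom_df, te = te_df, genes = gene_df, gene_cds = gene_cds)
}

#' Simulate a Z/W chromosome pair with full ground truth
#'
#' @param config [sim_config()]
#' @return list of class `wz_sim` with elements `z`, `w`
#'   ([genome_sequence()]) and `truth`: `homology_map` (Z/W co-linear
#'   segment pairs), `planted_te`, `planted_genes` (+ `gene_cds`, the
#'   ancestral query CDS per gene), `planted_snps`, `gap_interval`,
#'   `arms`, `config`
#' @export
simulate_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  z_seq <- random_dna(config$z_length)

  fam_names <- sprintf("TE%02d", seq_len(config$n_te_families))
  families <- setNames(lapply(seq_len(config$n_te_families), function(i)
    random_dna(sample(config$te_consensus_len_range[1]:config$te_consensus_len_range[2], 1L))),
    fam_names)
  cfg <- c(unclass(config), list(families = families))

  L1 <- round(config$w_long_frac * config$z_length)
  short_len <- round(config$w_short_scale * (config$z_length - L1))
  n_genes_long <- if (L1 + short_len > 0)
    round(config$n_genes * L1 / (L1 + short_len)) else 0L
  n_genes_short <- config$n_genes - n_genes_long

  long <- build_arm(substr(z_seq, 1L, L1), cfg,
                    config$te_burst_rate_long, config$te_age_young_frac_long,
                    n_genes_long, config$pseudo_frac_long, "gL")
  short <- build_arm(substr(z_seq, L1 + 1L, L1 + short_len), cfg,
                     config$te_rate_short, config$te_age_young_frac_short,
                     n_genes_short, config$pseudo_frac_short, "gS")

  gap_len <- round(config$gap_frac * config$z_length)
  w_seq <- paste0(long$seq, strrep("N", gap_len), short$seq)
  off_short_w <- long$w_len + gap_len

  shift <- function(df, cols, by) { for (cl in cols) df[[cl]] <- df[[cl]] + by; df }
  short_hom <- shift(short$homology, c("z_start", "z_end"), L1)
  short_hom <- shift(short_hom, c("w_start", "w_end"), off_short_w)
  hom <- rbind(long$homology, short_hom)
  te <- rbind(cbind(long$te, arm = if (nrow(long$te)) "long_arm" else character(0)),
              cbind(shift(short$te, c("w_start", "w_end"), off_short_w),
                    arm = if (nrow(short$te)) "short_arm" else character(0)))
  te$chrom <- if (nrow(te)) "W" else character(0)
  genes <- rbind(cbind(long$genes, arm = if (nrow(long$genes)) "long_arm" else character(0)),
                 cbind(shift(short$genes, c("w_start", "w_end"), off_short_w),
                       arm = if (nrow(short$genes)) "short_arm" else character(0)))
  gene_cds <- c(long$gene_cds, short$gene_cds)

  ## female-specific SNP sites on the assembled W
  w_len <- nchar(w_seq)
  draw_snps <- function(start, end, rate_per_kb) {
    n <- rpois(1L, rate_per_kb * (end - start) / 1000)
    if (n == 0L) return(integer(0))
    start + sample.int(end - start, min(n, end - start)) - 1L
  }
  snp_pos <- sort(c(draw_snps(0L, long$w_len, config$snp_rate_w_long),
                    draw_snps(off_short_w, w_len, config$snp_rate_background)))
  snp_ref <- if (length(snp_pos)) substring(w_seq, snp_pos + 1L, snp_pos + 1L)
             else character(0)
  keep <- snp_ref %in% DNA_BASES
  snp_pos <- snp_pos[keep]; snp_ref <- snp_ref[keep]
  alt_shift <- sample(1:3, length(snp_pos), replace = TRUE)
  snp_alt <- DNA_BASES[((match(snp_ref, DNA_BASES) - 1L + alt_shift) %% 4L) + 1L]
  snps <- data.frame(chrom = rep("W", length(snp_pos)), pos = snp_pos,
                     ref = snp_ref, allele = snp_alt,
                     sex = rep("female", length(snp_pos)),
                     stringsAsFactors = FALSE)

  gap_interval <- if (gap_len > 0) c(long$w_len, long$w_len + gap_len) else NULL
  arms <- if (gap_len > 0)
    partition_arms(w_len, boundaries = gap_interval) else NULL

  truth <- list(homology_map = hom, planted_te = te, planted_genes = genes,
                gene_cds = gene_cds, planted_snps = snps,
                gap_interval = gap_interval, arms = arms,
                te_families = families, config = config)
  structure(list(z = genome_sequence("Z", z_seq),
                 w = genome_sequence("W", w_seq),
                 truth = truth),
            class = "wz_sim")
}

#' @export
print.wz_sim <- function(x, ...) {
  cat(sprintf("<wz_sim> Z %d bp, W %d bp; %d TE copies, %d genes, %d SNPs planted\n",
              x$z$length, x$w$length, nrow(x$truth$planted_te),
              nrow(x$truth$planted_genes), nrow(x$truth$planted_snps)))
  invisible(x)
}

#' Plant TE copies into a sequence
#'
#' Standalone version of the generator's TE stage for one sequence:
#' copies are family consensuses mutated at the drawn age-component
#' divergence and inserted at Poisson-distributed positions. Uses the
#' current RNG stream.
#'
#' @param seq [genome_sequence()] or string
#' @param families named list of consensus sequences
#' @param rate_per_mbp insertions per Mbp
#' @param young_frac fraction of copies from the young component
#' @param kimura_young,kimura_old expected divergence per component
#' @return list with `seq` (new [genome_sequence()]) and `truth`
#'   (data.frame of planted copies with realized divergence)
#' @export
plant_te_copies <- function(seq, families, rate_per_mbp, young_frac = 0.01,
                            kimura_young = 0.005, kimura_old = 0.15) {
  s <- as_seq_string(seq)
  nm <- if (inherits(seq, "genome_sequence")) seq$name else "seq"
  te <- draw_te_events(nchar(s), families, rate_per_mbp, young_frac,
                       kimura_young, kimura_old)
  te <- te[order(te$pos), , drop = FALSE]
  te <- te[!duplicated(te$pos), , drop = FALSE]
  if (nrow(te) == 0L)
    return(list(seq = genome_sequence(nm, s),
                truth = cbind(te, w_start = integer(0), w_end = integer(0))))
  bounds <- c(0L, te$pos)
  segs <- substring(s, bounds[-length(bounds)] + 1L, te$pos)
  widths <- nchar(segs) + nchar(te$seq)
  w_end_ins <- cumsum(widths)
  te$w_start <- w_end_ins - nchar(te$seq)
  te$w_end <- w_end_ins
  out <- paste0(paste0(segs, te$seq, collapse = ""),
                substr(s, te$pos[nrow(te)] + 1L, nchar(s)))
  list(seq = genome_sequence(nm, out), truth = te)
}

#' Plant multi-exon genes and pseudogenes into a sequence
#'
#' Each gene is a 2-8 exon model with a CDS that starts with ATG, ends
#' with a stop and has length divisible by 3. A pseudogenized gene
#' carries exactly one lesion: a 1-2 bp coding indel (frameshift) or a
#' substitution creating an in-frame stop before 90% of the CDS
#' (premature stop), chosen 50/50 unless restricted. Uses the current
#' RNG stream.
#'
#' @param seq [genome_sequence()] or string
#' @param n_genes number of genes to plant
#' @param pseudo_frac probability each gene is pseudogenized
#' @param gene_divergence codon-aware substitution rate vs the query CDS
#' @param lesion_opts lesion kinds allowed
#' @return list with `seq`, `truth` (data.frame) and `cds` (named query
#'   CDS vector)
#' @export
plant_genes_and_pseudogenes <- function(seq, n_genes, pseudo_frac = 0,
                                        gene_divergence = 0,
                                        lesion_opts = c("frameshift", "premature_stop")) {
  s <- as_seq_string(seq)
  nm <- if (inherits(seq, "genome_sequence")) seq$name else "seq"
  if (n_genes == 0L)
    return(list(seq = genome_sequence(nm, s),
                truth = data.frame(gene_id = character(0), w_start = integer(0),
                                   w_end = integer(0), is_pseudogene = logical(0),
                                   lesion = character(0)),
                cds = character(0)))
  is_pseudo <- runif(n_genes) < pseudo_frac
  pos <- sample.int(nchar(s), n_genes, replace = TRUE) - 1L
  while (anyDuplicated(pos))
    pos[duplicated(pos)] <- sample.int(nchar(s), sum(duplicated(pos))) - 1L
  models <- lapply(seq_len(n_genes), function(i)
    make_gene(is_pseudo[i], gene_divergence, lesion_opts))
  o <- order(pos)
  pos <- pos[o]; models <- models[o]; is_pseudo <- is_pseudo[o]
  gseq <- vapply(models, `[[`, "", "genomic")
  bounds <- c(0L, pos)
  segs <- substring(s, bounds[-length(bounds)] + 1L, pos)
  w_end_ins <- cumsum(nchar(segs) + nchar(gseq))
  ids <- sprintf("g%03d", seq_len(n_genes))
  truth <- data.frame(gene_id = ids,
                      w_start = w_end_ins - nchar(gseq), w_end = w_end_ins,
                      is_pseudogene = is_pseudo,
                      lesion = vapply(models, `[[`, "", "lesion"),
                      stringsAsFactors = FALSE)
  out <- paste0(paste0(segs, gseq, collapse = ""),
                substr(s, pos[n_genes] + 1L, nchar(s)))
  list(seq = genome_sequence(nm, out), truth = truth,
       cds = setNames(vapply(models, `[[`, "", "cds_query"), ids))
}

#' Simulate pooled female/male allele counts
#'
#' Emits per-site A/C/G/T depths for a female and a male pool on the W.
#' At planted female-specific sites the female pool draws the alternate
#' allele at expected frequency 0.5 (a heterogametic ZW female carries
#' one W allele against one Z allele); the male pool sees it only through
#' sequencing error. Depths are Poisson.
#'
#' @param w [genome_sequence()] W chromosome
#' @param truth simulation truth (needs `planted_snps`)
#' @param depth mean per-pool depth
#' @param n_sites total sites (planted sites always included)
#' @param error_rate per-read error probability
#' @param female_alt_freq expected alternate frequency in the female pool
#' @param seed optional seed (otherwise continues the current stream)
#' @return [pooled_counts()] data.frame
#' @export
simulate_pools <- function(w, truth, depth = 40, n_sites = 20000L,
                           error_rate = 0.002, female_alt_freq = 0.5,
                           seed = NULL) {
  if (depth <= 0) stop_fmt("simulate_pools: depth must be > 0")
  if (!is.null(seed)) set.seed(seed)
  s <- as_seq_string(w)
  L <- nchar(s)
  planted <- truth$planted_snps
  n_extra <- max(0L, n_sites - nrow(planted))
  extra <- integer(0)
  if (n_extra > 0L) {
    cand <- sample.int(L, min(L, 2L * n_sites + 1000L)) - 1L
    ok <- substring(s, cand + 1L, cand + 1L) %in% DNA_BASES &
      !cand %in% planted$pos
    extra <- head(cand[ok], n_extra)
  }
  pos <- sort(unique(c(planted$pos, extra)))
  ref <- substring(s, pos + 1L, pos + 1L)
  alt <- rep(NA_character_, length(pos))
  alt[match(planted$pos, pos)] <- planted$allele
  n <- length(pos)

  fd <- rpois(n, depth); md <- rpois(n, depth)
  f_alt <- integer(n)
  pl <- !is.na(alt)
  f_alt[pl] <- rbinom(sum(pl), fd[pl], female_alt_freq)

  mk_counts <- function(dep, true_alt_reads, alt_allele) {
    cnt <- matrix(0L, n, 4L, dimnames = list(NULL, DNA_BASES))
    ref_reads <- dep - true_alt_reads
    ## sequencing errors flip reads to a uniform other base
    err_ref <- rbinom(n, ref_reads, error_rate)
    err_alt <- rbinom(n, true_alt_reads, error_rate)
    cnt[cbind(seq_len(n), match(ref, DNA_BASES))] <- ref_reads - err_ref
    has_alt <- true_alt_reads > 0L
    if (any(has_alt)) {
      i <- which(has_alt)
      cnt[cbind(i, match(alt_allele[i], DNA_BASES))] <-
        cnt[cbind(i, match(alt_allele[i], DNA_BASES))] + true_alt_reads[i] - err_alt[i]
    }
    for (i in which(err_ref + err_alt > 0L)) {
      n_err <- err_ref[i] + err_alt[i]
      tgt <- sample(setdiff(DNA_BASES, ref[i]), n_err, replace = TRUE)
      for (b in tgt) cnt[i, b] <- cnt[i, b] + 1L
    }
    cnt
  }
  fc <- mk_counts(fd, f_alt, alt)
  mc <- mk_counts(md, integer(n), alt)
  pooled_counts(data.frame(chrom = rep(if (inherits(w, "genome_sequence")) w$name else "W", n),
                           pos = pos, ref = ref,
                           fA = fc[, 1], fC = fc[, 2], fG = fc[, 3], fT = fc[, 4],
                           mA = mc[, 1], mC = mc[, 2], mG = mc[, 3], mT = mc[, 4],
                           stringsAsFactors = FALSE))
}

#' Write a simulation and its ground truth to a directory
#'
#' Emits `z.fa`, `w.fa`, `te_consensus.fa`, `te_copies.tsv` (internal
#' copy-alignment dialect), `truth_te.bed`, `genes_cds.fa`,
#' `truth_genes.tsv`, `truth_snps.tsv`, `truth.json` and, when `pools`
#' is given, `pools.tsv`.
#'
#' @param sim [simulate_pair()] result
#' @param dir output directory (created if needed)
#' @param pools optional [simulate_pools()] table
#' @return invisibly, `dir`
#' @export
write_simulation <- function(sim, dir, pools = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(sim$z, p("z.fa"))
  write_fasta(sim$w, p("w.fa"))
  write_fasta(lapply(names(sim$truth$te_families), function(f)
    genome_sequence(f, sim$truth$te_families[[f]])), p("te_consensus.fa"))
  te <- sim$truth$planted_te
  if (nrow(te)) {
    copies <- data.frame(chrom = te$chrom, start = te$w_start, end = te$w_end,
                         family = te$family, strand = "+", copy_seq = te$seq,
                         stringsAsFactors = FALSE)
    write.table(copies, p("te_copies.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_interval_table(data.frame(chrom = te$chrom, start = te$w_start,
                                    end = te$w_end, name = te$family,
                                    age = te$age), p("truth_te.bed"), "bed")
  }
  if (length(sim$truth$gene_cds))
    write_fasta(lapply(names(sim$truth$gene_cds), function(g)
      genome_sequence(g, sim$truth$gene_cds[[g]])), p("genes_cds.fa"))
  g <- sim$truth$planted_genes
  if (nrow(g))
    write.table(g, p("truth_genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$planted_snps, p("truth_snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(pools)) write_pool_counts(pools, p("pools.tsv"))
  meta <- list(config = unclass(sim$truth$config),
               gap_interval = sim$truth$gap_interval,
               z_length = sim$z$length, w_length = sim$w$length)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                              null = "null"),
             p("truth.json"))
  invisible(dir)
}
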