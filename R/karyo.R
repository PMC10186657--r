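## Karyotype arithmetic and the integrated per-arm report: N-gap
## detection, centromere candidate intervals from cytogenetic arm-length
## ratios, the long/gap/short arm partition, and the roll-up combining
## every analysis track.

#' Find assembly N-gaps
#'
#' Maximal runs of `N` of at least `min_run` bases, 0-based half-open,
#' sorted by position.
#'
#' @param seq [genome_sequence()] (or DNA string)
#' @param min_run minimum run length reported
#' @return data.frame `start,end,length`
#' @export
find_n_gaps <- function(seq, min_run = 1000L) {
  s <- as_seq_string(seq)
  m <- gregexpr("N+", s)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), end = integer(0), length = integer(0)))
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  keep <- len >= min_run
  data.frame(start = start[keep], end = start[keep] + len[keep],
             length = len[keep])
}

#' Centromere candidate intervals from an arm-length ratio
#'
#' A cytogenetically measured centromere position (`arm_fraction` of
#' total length, with uncertainty `fraction_sd`) maps onto the assembly
#' at two mirror-image candidate intervals, because the overall
#' orientation of the assembled sequence relative to the metaphase
#' chromosome is unknown. Both are always reported.
#'
#' @param total_length chromosome length in bases
#' @param arm_fraction centromere position as a fraction of total length
#'   (e.g. 0.596)
#' @param fraction_sd uncertainty on the fraction (e.g. 0.022)
#' @return list of class `centromere_estimate` with `interval_distal`
#'   (`[(f-sd)L, (f+sd)L]`), `interval_proximal` (its mirror image about
#'   the midpoint) in bases, and both in Mbp rounded half-up to one
#'   decimal (`*_mbp`)
#' @export
centromere_candidates <- function(total_length, arm_fraction, fraction_sd = 0) {
  if (!(arm_fraction > 0 && arm_fraction < 1))
    stop_fmt("centromere_candidates: arm_fraction must be in (0,1)")
  if (fraction_sd < 0 ||
      arm_fraction - fraction_sd <= 0 || arm_fraction + fraction_sd >= 1)
    stop_fmt("centromere_candidates: arm_fraction +/- fraction_sd must stay in (0,1)")
  L <- total_length
  distal <- c((arm_fraction - fraction_sd) * L, (arm_fraction + fraction_sd) * L)
  proximal <- c((1 - arm_fraction - fraction_sd) * L, (1 - arm_fraction + fraction_sd) * L)
  ## mirror-symmetry invariant: proximal = L - rev(distal)
  stopifnot(all(abs(proximal - (L - rev(distal))) < 1e-6))
  structure(list(total_length = L, arm_fraction = arm_fraction,
                 fraction_sd = fraction_sd,
                 interval_distal = distal, interval_proximal = proximal,
                 interval_distal_mbp = round_half_up(distal / 1e6, 1),
                 interval_proximal_mbp = round_half_up(proximal / 1e6, 1)),
            class = "centromere_estimate")
}

#' @export
print.centromere_estimate <- function(x, ...) {
  cat(sprintf("<centromere_estimate> %.1f%% +/- %.1f%% of %.1f Mbp\n",
              100 * x$arm_fraction, 100 * x$fraction_sd, x$total_length / 1e6))
  cat(sprintf("  candidate intervals: %.1f-%.1f Mbp or %.1f-%.1f Mbp\n",
              x$interval_proximal_mbp[1], x$interval_proximal_mbp[2],
              x$interval_distal_mbp[1], x$interval_distal_mbp[2]))
  invisible(x)
}

#' Partition a chromosome into long arm, gap and short arm
#'
#' By convention the long arm sits at the sequence start; `flip = TRUE`
#' handles assemblies oriented the other way. With several gaps the
#' largest is used (with a warning); explicit boundaries override gap
#' detection.
#'
#' @param chrom_length chromosome length
#' @param gaps data.frame from [find_n_gaps()] (or NULL)
#' @param boundaries optional `c(gap_start, gap_end)` override
#' @param flip long arm at the sequence end instead of the start
#' @return list of class `arm_partition` with `long_arm`, `gap`,
#'   `short_arm` intervals (`c(start, end)`) that exactly tile
#'   `[0, chrom_length)`
#' @export
partition_arms <- function(chrom_length, gaps = NULL, boundaries = NULL,
                           flip = FALSE) {
  if (is.null(boundaries)) {
    if (is.null(gaps) || nrow(gaps) == 0L)
      stop_fmt("partition_arms: no gap and no explicit boundaries given")
    if (nrow(gaps) > 1L) {
      warning("partition_arms: multiple gaps; using the largest", call. = FALSE)
      gaps <- gaps[which.max(gaps$end - gaps$start), , drop = FALSE]
    }
    boundaries <- c(gaps$start[1], gaps$end[1])
  }
  if (boundaries[1] < 0 || boundaries[2] > chrom_length || boundaries[1] >= boundaries[2])
    stop_fmt("partition_arms: gap [%s,%s) outside chromosome [0,%s)",
             boundaries[1], boundaries[2], chrom_length)
  first <- c(0, boundaries[1]); second <- c(boundaries[2], chrom_length)
  p <- if (flip)
    list(long_arm = second, gap = boundaries, short_arm = first)
  else
    list(long_arm = first, gap = boundaries, short_arm = second)
  stopifnot(diff(p$long_arm) + diff(p$gap) + diff(p$short_arm) == chrom_length)
  structure(c(p, list(chrom_length = chrom_length, flip = flip)),
            class = "arm_partition")
}

#' @export
print.arm_partition <- function(x, ...) {
  cat(sprintf("<arm_partition> long [%d,%d) | gap [%d,%d) | short [%d,%d)\n",
              x$long_arm[1], x$long_arm[2], x$gap[1], x$gap[2],
              x$short_arm[1], x$short_arm[2]))
  invisible(x)
}

arm_regions <- function(partition) {
  data.frame(name = c("long_arm", "short_arm"),
             start = c(partition$long_arm[1], partition$short_arm[1]),
             end = c(partition$long_arm[2], partition$short_arm[2]),
             stringsAsFactors = FALSE)
}

report_cell <- function(x) if (is.null(x)) "absent" else x

#' Build the integrated per-arm differentiation report
#'
#' Combines the per-arm outputs of the divergence, TE-age, gene-decay and
#' sex-SNP tracks over one arm partition into a single machine-readable
#' structure. Missing tracks are marked `"absent"`, never zero. The
#' report is fully deterministic: regenerating it from the same inputs is
#' byte-identical.
#'
#' @param partition [partition_arms()] result for the W chromosome
#' @param divergence optional named list of [region_summary()] results
#'   (one per arm, names `long_arm`/`short_arm`)
#' @param te optional [young_fraction_by_region()] data.frame
#' @param genes optional [pseudogene_fraction()] data.frame
#' @param snps optional call table from [call_sex_specific_sites()]
#' @param chrom_lengths optional named vector of chromosome lengths
#'   (e.g. `c(W = ..., Z = ...)`); when both W and Z are present their
#'   size difference is reported
#' @param config optional configuration list embedded verbatim
#'   (provenance)
#' @param autosome_pseudo_pct optional average autosome pseudogene
#'   percentage used for the long-arm excess arithmetic
#' @return list of class `wz_report`
#' @export
build_report <- function(partition, divergence = NULL, te = NULL, genes = NULL,
                         snps = NULL, chrom_lengths = NULL, config = NULL,
                         autosome_pseudo_pct = NULL) {
  stopifnot(inherits(partition, "arm_partition"))
  regions <- arm_regions(partition)
  check_regions <- function(df, what) {
    if (!is.null(df) && !all(regions$name %in% df$region))
      stop_fmt("build_report: %s output missing regions: %s", what,
               paste(setdiff(regions$name, df$region), collapse = ","))
  }
  check_regions(te, "te"); check_regions(genes, "genes")

  arm_summary <- lapply(regions$name, function(rn) {
    ri <- regions[regions$name == rn, ]
    len_mbp <- (ri$end - ri$start) / 1e6
    s <- list(region = rn, start = ri$start, end = ri$end)
    s$divergence <- report_cell(divergence[[rn]])
    s$young_te <- report_cell(if (!is.null(te)) as.list(te[te$region == rn, ]))
    s$pseudogenes <- report_cell(if (!is.null(genes)) as.list(genes[genes$region == rn, ]))
    if (!is.null(snps)) {
      nf <- sum(snps$sex == "female" & snps$pos >= ri$start & snps$pos < ri$end)
      nm <- sum(snps$sex == "male" & snps$pos >= ri$start & snps$pos < ri$end)
      s$snp_density_per_mbp <- list(female = nf / len_mbp, male = nm / len_mbp,
                                    n_female = nf, n_male = nm)
    } else s$snp_density_per_mbp <- "absent"
    s
  })
  names(arm_summary) <- regions$name

  folds <- list()
  if (!is.null(te)) {
    a <- te[te$region == "long_arm", ]; b <- te[te$region == "short_arm", ]
    folds$young_te_long_vs_short <-
      if (!is.na(a$pct_young) && !is.na(b$pct_young) && b$pct_young > 0)
        a$pct_young / b$pct_young else NA
  }
  if (!is.null(snps)) {
    enr <- region_snp_enrichment(snps, partition$long_arm, partition$short_arm,
                                 sex = "female")
    folds$female_snp_long_vs_short <- enr[c("fold", "ci_low", "ci_high")]
  }
  if (!is.null(genes) && !is.null(autosome_pseudo_pct)) {
    lp <- genes$pct_1dp[genes$region == "long_arm"]
    folds$pseudogene_excess_long_vs_autosome_pct <-
      round_half_up(lp - autosome_pseudo_pct, 1)
  }
  if (!is.null(chrom_lengths) && all(c("W", "Z") %in% names(chrom_lengths))) {
    folds$w_minus_z_size_mbp <-
      round_half_up((chrom_lengths[["W"]] - chrom_lengths[["Z"]]) / 1e6, 1)
  }

  structure(list(
    tool = list(name = "wzdiff", version = as.character(packageVersion("wzdiff"))),
    partition = list(long_arm = partition$long_arm, gap = partition$gap,
                     short_arm = partition$short_arm,
                     chrom_length = partition$chrom_length, flip = partition$flip),
    chrom_lengths = report_cell(if (!is.null(chrom_lengths)) as.list(chrom_lengths)),
    arms = arm_summary,
    folds = folds,
    config = report_cell(config)
  ), class = "wz_report")
}

#' Write a report as deterministic JSON
#'
#' @param report [build_report()] result
#' @param path output path
#' @return invisibly, `path`
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n")
  invisible(path)
}
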