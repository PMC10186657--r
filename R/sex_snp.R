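## Sex-specific SNP calling from female/male pooled allele counts.
##
## The caller is fully parameterized: an allele is sex-specific when it is
## well supported in one pool and (near-)absent in the other, with depth
## gates applied to BOTH pools so a site that is uncallable in either pool
## can never be declared specific.

#' Calling parameters for sex-specific SNPs
#'
#' @param min_depth_per_pool minimum read depth required in each pool
#' @param min_alt_reads minimum alternate-allele reads in the carrier pool
#' @param min_alt_freq minimum alternate-allele frequency in the carrier
#'   pool (in `(0, 1]`)
#' @param max_other_pool_alt_reads maximum alternate reads tolerated in
#'   the other pool (0 = strict absence)
#' @return list of class `snp_call_params`
#' @export
snp_call_params <- function(min_depth_per_pool = 10L, min_alt_reads = 3L,
                            min_alt_freq = 0.1, max_other_pool_alt_reads = 0L) {
  if (min_depth_per_pool < 0 || min_alt_reads < 0 || max_other_pool_alt_reads < 0)
    stop_fmt("snp_call_params: counts must be >= 0")
  if (!(min_alt_freq > 0 && min_alt_freq <= 1))
    stop_fmt("snp_call_params: min_alt_freq must be in (0, 1]")
  structure(list(min_depth_per_pool = min_depth_per_pool,
                 min_alt_reads = min_alt_reads,
                 min_alt_freq = min_alt_freq,
                 max_other_pool_alt_reads = max_other_pool_alt_reads),
            class = "snp_call_params")
}

#' Call sex-specific SNPs from pooled counts
#'
#' At most one call is made per site: among qualifying alleles the one
#' with the highest carrier-pool frequency wins, ties broken by
#' lexicographic allele order. Sites failing a depth gate yield no call.
#'
#' @param pools [pooled_counts()] data.frame
#' @param params [snp_call_params()]
#' @return data.frame `chrom,pos,ref,allele,sex,female_freq,male_freq`
#'   (0-based `pos`)
#' @export
call_sex_specific_sites <- function(pools, params = snp_call_params()) {
  stopifnot(inherits(params, "snp_call_params"))
  f <- as.matrix(pools[, c("fA", "fC", "fG", "fT")])
  m <- as.matrix(pools[, c("mA", "mC", "mG", "mT")])
  colnames(f) <- colnames(m) <- DNA_BASES
  fd <- rowSums(f); md <- rowSums(m)
  depth_ok <- fd >= params$min_depth_per_pool & md >= params$min_depth_per_pool

  out <- list()
  for (bi in 1:4) {
    allele <- DNA_BASES[bi]
    non_ref <- pools$ref != allele
    ff <- ifelse(fd > 0, f[, bi] / fd, 0)
    mf <- ifelse(md > 0, m[, bi] / md, 0)
    fem <- depth_ok & non_ref &
      f[, bi] >= params$min_alt_reads & ff >= params$min_alt_freq &
      m[, bi] <= params$max_other_pool_alt_reads
    mal <- depth_ok & non_ref &
      m[, bi] >= params$min_alt_reads & mf >= params$min_alt_freq &
      f[, bi] <= params$max_other_pool_alt_reads
    idx <- which(fem | mal)
    if (length(idx))
      out[[allele]] <- data.frame(
        row = idx, chrom = pools$chrom[idx], pos = pools$pos[idx],
        ref = pools$ref[idx], allele = allele,
        sex = ifelse(fem[idx], "female", "male"),
        female_freq = ff[idx], male_freq = mf[idx],
        carrier_freq = ifelse(fem[idx], ff[idx], mf[idx]),
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      allele = character(0), sex = character(0),
                      female_freq = numeric(0), male_freq = numeric(0),
                      stringsAsFactors = FALSE))
  calls <- do.call(rbind, out)
  ## one call per site: highest carrier frequency, then allele order
  calls <- calls[order(calls$row, -calls$carrier_freq, calls$allele), , drop = FALSE]
  calls <- calls[!duplicated(calls$row), , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  calls[, c("chrom", "pos", "ref", "allele", "sex", "female_freq", "male_freq")]
}

#' Windowed counts of sex-specific SNP calls
#'
#' @param calls output of [call_sex_specific_sites()]
#' @param chrom_length chromosome length in bases
#' @param window window size
#' @return data.frame `chrom,start,end,n_female,n_male`
#' @export
snp_window_counts <- function(calls, chrom_length, window = 100000L) {
  win_start <- seq.int(0L, max(chrom_length - 1L, 0L), by = window)
  nwin <- length(win_start)
  cnt <- function(sex) {
    pos <- calls$pos[calls$sex == sex]
    tabulate(floor(pos / window) + 1L, nbins = nwin)
  }
  data.frame(chrom = if (nrow(calls)) calls$chrom[1] else "chrom",
             start = win_start, end = pmin(win_start + window, chrom_length),
             n_female = cnt("female"), n_male = cnt("male"),
             stringsAsFactors = FALSE)
}

#' Fold enrichment of SNP density between two regions
#'
#' Densities are calls per Mbp; the fold ratio carries a Poisson-based
#' 95% interval (conditional binomial rate-ratio interval). With zero
#' calls in the denominator region the fold is infinite and the interval
#' lower bound is reported.
#'
#' @param calls call table (optionally pre-filtered by sex)
#' @param region_a,region_b `c(start, end)` intervals in bases
#' @param sex restrict to `"female"` or `"male"` calls (default: all)
#' @param conf confidence level
#' @return list with `n_a`, `n_b`, `density_a`, `density_b` (per Mbp),
#'   `fold`, `ci_low`, `ci_high`
#' @export
region_snp_enrichment <- function(calls, region_a, region_b, sex = NULL,
                                  conf = 0.95) {
  la <- (region_a[2] - region_a[1]) / 1e6
  lb <- (region_b[2] - region_b[1]) / 1e6
  if (la <= 0 || lb <= 0) stop_fmt("region_snp_enrichment: empty region")
  if (!is.null(sex)) calls <- calls[calls$sex == sex, , drop = FALSE]
  na <- sum(calls$pos >= region_a[1] & calls$pos < region_a[2])
  nb <- sum(calls$pos >= region_b[1] & calls$pos < region_b[2])
  fold <- if (nb > 0) (na / la) / (nb / lb) else Inf
  if (na + nb > 0) {
    bt <- binom.test(na, na + nb, p = la / (la + lb), conf.level = conf)
    ci_p <- bt$conf.int
    to_fold <- function(p) if (p >= 1) Inf else (p / (1 - p)) * (lb / la)
    ci <- c(to_fold(ci_p[1]), to_fold(ci_p[2]))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(n_a = na, n_b = nb, density_a = na / la, density_b = nb / lb,
       fold = fold, ci_low = ci[1], ci_high = ci[2])
}
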