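## Gene decay on the W: project coding queries onto a chromosome by
## k-mer seeding plus banded refinement, filter by coverage/identity,
## call pseudogenes by frameshift or premature stop codon, and cluster
## duplicated copies by H-score.

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(seq_chars(s)), collapse = ""))
}

translate_string <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return(character(0))
  codons <- substring(dna, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  aa
}

## Build one gene hit from refined alignment blocks (all on the forward
## target strand, query co-linear).
##
## Target-only gaps are interpreted through gap clusters: delete runs
## separated by at most `jitter` aligned columns are one physical gap
## whose boundary the aligner placed imperfectly (a few exon bases
## matching intron sequence by chance). Clusters totalling at least
## min_intron bases are introns -- excluded from the spliced projection
## together with the dubious columns inside them -- while smaller
## clusters are coding gaps and flag a frameshift when their total is
## not divisible by 3. Query-only (insert) runs flag a frameshift the
## same way unless they sit inside an intron cluster.
##
## The premature-stop scan works in query codon coordinates: a codon is
## translated only when all three of its query positions are aligned, so
## alignment noise can never shift the reading frame of the rest of the
## gene.
build_hit <- function(gene_id, blocks, qlen, target_str, strand, min_intron,
                      jitter = 12L) {
  if (length(blocks) == 0L) return(NULL)
  matches <- 0L; mismatches <- 0L; gap_runs <- 0L
  frameshift <- FALSE
  tbase <- rep(NA_character_, qlen)  # target base aligned to each query position
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    ops <- b$ops
    n_ops <- nrow(ops)
    rpos <- b$ref_start + c(0L, cumsum(ops$len * (ops$kind != "insert")))[seq_len(n_ops)]
    qpos <- b$qry_start + c(0L, cumsum(ops$len * (ops$kind != "delete")))[seq_len(n_ops)]

    ## cluster target-only gap runs
    cluster_of <- integer(n_ops)          # 0 = not in a cluster
    n_clusters <- 0L
    last_del <- -1L; sep <- 0L
    for (oi in seq_len(n_ops)) {
      if (ops$kind[oi] == "delete") {
        if (last_del > 0L && sep <= jitter) {
          cluster_of[oi] <- cluster_of[last_del]
          ## columns between the two deletes belong to the gap
          if (oi - last_del > 1L)
            cluster_of[(last_del + 1L):(oi - 1L)] <- cluster_of[last_del]
        } else {
          n_clusters <- n_clusters + 1L
          cluster_of[oi] <- n_clusters
        }
        last_del <- oi; sep <- 0L
      } else {
        sep <- sep + ops$len[oi]
      }
    }
    cl_del_sum <- vapply(seq_len(max(n_clusters, 0L)), function(ci)
      sum(ops$len[cluster_of == ci & ops$kind == "delete"]), 0L)
    intron_cluster <- cl_del_sum >= min_intron
    trim <- 3L  # aligned columns blanked on each side of an intron (boundary jitter)

    for (oi in seq_len(n_ops)) {
      kind <- ops$kind[oi]; len <- ops$len[oi]
      ci <- cluster_of[oi]
      in_intron <- ci > 0L && intron_cluster[ci]
      if (kind %in% c("match", "mismatch")) {
        if (!in_intron) {
          if (kind == "match") matches <- matches + len else mismatches <- mismatches + len
          tbase[qpos[oi] + seq_len(len)] <-
            seq_chars(substr(target_str, rpos[oi] + 1L, rpos[oi] + len))
        }
      } else if (kind == "insert") {
        if (!in_intron) {
          gap_runs <- gap_runs + 1L
          if (len %% 3L != 0L) frameshift <- TRUE
        }
      }
    }
    if (n_clusters > 0L) {
      small <- which(!intron_cluster)
      gap_runs <- gap_runs + length(small)
      if (any(cl_del_sum[small] %% 3L != 0L)) frameshift <- TRUE
      for (ci in which(intron_cluster)) {
        in_cl <- which(cluster_of == ci)
        ## blank boundary-jitter columns around the intron before the
        ## stop scan (the aligner places splice boundaries imperfectly)
        qL <- qpos[min(in_cl)]; qR <- qpos[max(in_cl)]
        lo <- max(1L, qL - trim + 1L)
        if (lo <= qL && qL >= 1L) tbase[lo:qL] <- NA_character_
        hi <- min(qlen, qR + trim)
        if (qR + 1L <= hi) tbase[(qR + 1L):hi] <- NA_character_
      }
    }
  }
  aligned_q <- matches + mismatches
  if (aligned_q == 0L) return(NULL)
  ## query-frame stop scan over fully aligned codons, excluding the last
  ## aligned codon (the gene's own terminator)
  n_codons <- qlen %/% 3L
  cod_start <- 3L * (seq_len(n_codons) - 1L) + 1L
  full <- !is.na(tbase[cod_start]) & !is.na(tbase[cod_start + 1L]) &
    !is.na(tbase[cod_start + 2L])
  premature <- FALSE
  if (any(full)) {
    idx <- which(full)
    idx_check <- idx[idx < max(idx)]
    if (length(idx_check)) {
      codons <- paste0(tbase[cod_start[idx_check]],
                       tbase[cod_start[idx_check] + 1L],
                       tbase[cod_start[idx_check] + 2L])
      premature <- any(codons %in% c("TAA", "TAG", "TGA"))
    }
  }
  proj <- paste(tbase[!is.na(tbase)], collapse = "")
  list(gene_id = gene_id,
       chrom = NA_character_,
       start = blocks[[1]]$ref_start,
       end = blocks[[length(blocks)]]$ref_end,
       strand = strand,
       coverage = aligned_q / qlen,
       identity = matches / aligned_q,
       score = 2 * matches - 3 * mismatches - 5 * gap_runs,
       qry_start = blocks[[1]]$qry_start,
       qry_end = blocks[[length(blocks)]]$qry_end,
       frameshift = frameshift,
       premature_stop = premature,
       cds_projection = proj,
       blocks = blocks)
}

#' Project coding queries onto a target chromosome
#'
#' Candidate loci are found by exact k-mer seeding (both strands), seeds
#' are clustered, and each candidate window is refined with the anchor
#' aligner under a banded affine gap model. Multiple non-overlapping hits
#' per query are allowed, which is what captures gene duplications.
#'
#' @param queries named character vector (or named list) of CDS sequences
#' @param target [genome_sequence()] target chromosome
#' @param k seed k-mer size
#' @param stride spacing of query seed k-mers
#' @param min_seeds minimum seeds per candidate locus
#' @param band maximum gap closed during refinement (must exceed the
#'   largest expected intron)
#' @param min_intron target-only gaps at least this long are introns;
#'   shorter gaps are coding-frame gaps (frameshift candidates)
#' @param pad window padding around the seed cluster
#' @param cluster_gap seed clusters split at target gaps larger than this
#' @param both_strands also search the reverse complement of each query
#' @return list of gene hits (see [gene_hits_table()] for a tabular view)
#' @export
project_genes <- function(queries, target, k = 12L, stride = 6L, min_seeds = 2L,
                          band = 600L, min_intron = 40L, pad = 300L,
                          cluster_gap = 5000L, both_strands = TRUE) {
  tstr <- as_seq_string(target)
  tname <- if (inherits(target, "genome_sequence")) target$name else "target"
  queries <- vapply(queries, as_seq_string, character(1))
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    stop_fmt("project_genes: queries must be named")
  short <- nchar(queries) < 90L
  if (any(short))
    stop_fmt("project_genes: query '%s' shorter than 90 nt", names(queries)[short][1])

  ## batch seed table over all queries (and reverse complements)
  seed_rows <- list()
  for (g in names(queries)) {
    for (str in if (both_strands) c("+", "-") else "+") {
      qs <- if (str == "+") queries[[g]] else revcomp(queries[[g]])
      starts <- seq.int(1L, nchar(qs) - k + 1L, by = stride)
      seed_rows[[paste(g, str)]] <- data.frame(
        gene = g, strand = str, qpos = starts,
        pattern = substring(qs, starts, starts + k - 1L),
        stringsAsFactors = FALSE)
    }
  }
  seeds <- do.call(rbind, seed_rows)
  seeds <- seeds[!grepl("N", seeds$pattern, fixed = TRUE), , drop = FALSE]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$pattern))
  mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(tstr))
  sl <- Biostrings::startIndex(mi)

  hits <- list()
  for (g in names(queries)) {
    for (str in if (both_strands) c("+", "-") else "+") {
      rows <- which(seeds$gene == g & seeds$strand == str)
      tpos <- unlist(sl[rows], use.names = FALSE)
      if (is.null(tpos) || length(tpos) < min_seeds) next
      qpos <- rep(seeds$qpos[rows],
                  vapply(sl[rows], function(x) if (is.null(x)) 0L else length(x), 0L))
      o <- order(tpos); tpos <- tpos[o]; qpos <- qpos[o]
      cl <- cumsum(c(TRUE, diff(tpos) > cluster_gap))
      qs <- if (str == "+") queries[[g]] else revcomp(queries[[g]])
      qlen <- nchar(qs)
      for (ci in unique(cl)) {
        sel <- cl == ci
        if (sum(sel) < min_seeds) next
        w0 <- max(0L, min(tpos[sel] - qpos[sel]) - pad)
        w1 <- min(nchar(tstr), max(tpos[sel] + (qlen - qpos[sel])) + pad)
        win <- substr(tstr, w0 + 1L, w1)
        blocks <- tryCatch(anchor_align(win, qs, k = k, band = band),
                           error = function(e) NULL)
        if (is.null(blocks)) next
        ## shift window-relative coordinates to chromosome coordinates
        blocks <- lapply(blocks, function(b) {
          b$ref_start <- b$ref_start + w0; b$ref_end <- b$ref_end + w0
          b$ref_name <- tname
          b
        })
        h <- build_hit(g, blocks, qlen, tstr, str, min_intron)
        if (!is.null(h)) {
          h$chrom <- tname
          hits[[length(hits) + 1L]] <- h
        }
      }
    }
  }
  hits
}

#' Project one gene
#'
#' Convenience wrapper around [project_genes()] for a single query.
#'
#' @param query CDS sequence
#' @param target target chromosome
#' @param gene_id identifier used in the hits
#' @param ... passed to [project_genes()]
#' @return list of hits (possibly empty; no seeds is not an error)
#' @export
project_gene <- function(query, target, gene_id = "query", ...) {
  hits <- tryCatch(
    project_genes(setNames(as_seq_string(query), gene_id), target, ...),
    error = function(e) {
      if (grepl("shorter than 90", conditionMessage(e))) stop(e)
      list()
    })
  hits
}

#' Filter gene hits by coverage and identity
#'
#' Strict `>` on both thresholds, then per-locus resolution: when two
#' hits overlap reciprocally by more than 50% of each, only the
#' best-scoring one is kept.
#'
#' @param hits list of gene hits
#' @param min_cov coverage threshold (kept iff coverage > min_cov)
#' @param min_ident identity threshold (kept iff identity > min_ident)
#' @return filtered hit list
#' @export
filter_gene_alignments <- function(hits, min_cov = 0.35, min_ident = 0.50) {
  keep <- vapply(hits, function(h) h$coverage > min_cov && h$identity > min_ident,
                 logical(1))
  hits <- hits[keep]
  if (length(hits) <= 1L) return(hits)
  o <- order(vapply(hits, `[[`, 0, "score"), decreasing = TRUE)
  hits <- hits[o]
  kept <- list()
  for (h in hits) {
    clash <- FALSE
    for (kh in kept) {
      if (kh$chrom != h$chrom) next
      ov <- min(kh$end, h$end) - max(kh$start, h$start)
      ## different queries: per-locus best on reciprocal > 50% overlap;
      ## same query: any hit mostly contained in a better-scoring hit is
      ## a redundant fragment of the same locus, not a duplication
      if (kh$gene_id == h$gene_id) {
        if (ov > 0.5 * (h$end - h$start)) { clash <- TRUE; break }
      } else if (ov > 0.5 * (h$end - h$start) && ov > 0.5 * (kh$end - kh$start)) {
        clash <- TRUE; break
      }
    }
    if (!clash) kept[[length(kept) + 1L]] <- h
  }
  kept[order(vapply(kept, function(h) as.numeric(h$start), 0))]
}

#' Classify a gene hit as intact or pseudogene
#'
#' A hit is a pseudogene iff its coding alignment contains a gap whose
#' length is not divisible by 3 (frameshift) or its spliced projection
#' contains an in-frame stop codon strictly before the final codon of the
#' aligned region (premature stop). Frameshift takes precedence when both
#' are present (a frameshift scrambles all downstream codons).
#'
#' @param hit a gene hit from [project_genes()]
#' @return one of `"intact"`, `"pseudogene(frameshift)"`,
#'   `"pseudogene(premature_stop)"`
#' @export
classify_pseudogene <- function(hit) {
  if (is.null(hit$cds_projection))
    stop_fmt("classify_pseudogene: hit has no CDS projection")
  if (isTRUE(hit$frameshift)) return("pseudogene(frameshift)")
  if (isTRUE(hit$premature_stop)) return("pseudogene(premature_stop)")
  "intact"
}

#' Per-region pseudogene fraction
#'
#' Genes are assigned to regions by interval midpoint;
#' `pct = 100 * n_pseudo / n_genes` (also given rounded half-up to one
#' decimal, the convention for human-readable output).
#'
#' @param hits classified (filtered) hit list
#' @param regions data.frame `name,start,end`
#' @return data.frame `region,n_genes,n_pseudo,pct,pct_1dp`
#' @export
pseudogene_fraction <- function(hits, regions) {
  regions <- as.data.frame(regions)
  mid <- vapply(hits, function(h) (h$start + h$end) / 2, 0)
  pseudo <- vapply(hits, function(h) classify_pseudogene(h) != "intact", logical(1))
  out <- lapply(seq_len(nrow(regions)), function(i) {
    sel <- mid >= regions$start[i] & mid < regions$end[i]
    n <- sum(sel); np <- sum(pseudo & sel)
    data.frame(region = regions$name[i], n_genes = n, n_pseudo = np,
               pct = if (n > 0) 100 * np / n else NA_real_,
               pct_1dp = if (n > 0) round_half_up(100 * np / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tabular view of gene hits
#'
#' @param hits list of gene hits
#' @return data.frame with one row per hit (class included)
#' @export
gene_hits_table <- function(hits) {
  if (length(hits) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      coverage = numeric(0), identity = numeric(0),
                      score = numeric(0), class = character(0)))
  data.frame(gene_id = vapply(hits, `[[`, "", "gene_id"),
             chrom = vapply(hits, `[[`, "", "chrom"),
             start = vapply(hits, `[[`, 0L, "start"),
             end = vapply(hits, `[[`, 0L, "end"),
             strand = vapply(hits, `[[`, "", "strand"),
             coverage = vapply(hits, `[[`, 0, "coverage"),
             identity = vapply(hits, `[[`, 0, "identity"),
             score = vapply(hits, `[[`, 0, "score"),
             class = vapply(hits, classify_pseudogene, ""),
             stringsAsFactors = FALSE)
}

#' Normalized pairwise similarity H-score
#'
#' `H = 100 * S(a,b) / min(S(a,a), S(b,b))` where `S` is the local
#' alignment score (match +2, mismatch -3, gap open 5, gap extend 2).
#' Symmetric by construction, `H(a, a) = 100`, and near 0 for unrelated
#' sequences. The threshold convention for calling duplicated gene copies
#' is `H > 90`.
#'
#' @param a,b DNA sequences
#' @return numeric score in `[0, 100]` (values slightly above 100 are
#'   clamped; they cannot arise with this scoring)
#' @export
hscore <- function(a, b) {
  A <- Biostrings::DNAString(as_seq_string(a))
  B <- Biostrings::DNAString(as_seq_string(b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  sc <- function(x, y)
    Biostrings::pairwiseAlignment(x, y, type = "local", substitutionMatrix = mat,
                                  gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
  min(100, 100 * sc(A, B) / min(sc(A, A), sc(B, B)))
}

#' Cluster duplicated gene copies on the target chromosome
#'
#' For each source (Z) gene, target (W) hits with H-score above the
#' threshold against the source CDS are cluster members; clusters with at
#' least two copies are reported with per-region copy counts.
#'
#' @param z_cds named character vector of source CDS sequences
#' @param w_hits filtered hit list on the target
#' @param target target [genome_sequence()] (for member locus sequences)
#' @param h_threshold H-score threshold (strict `>`)
#' @param regions optional data.frame `name,start,end` for per-region
#'   member counts
#' @return data.frame `source_gene_id,n_copies,members` (members as
#'   `start-end` strings) plus one count column per region
#' @export
cluster_duplicates <- function(z_cds, w_hits, target, h_threshold = 90,
                               regions = NULL) {
  tstr <- as_seq_string(target)
  gene_ids <- vapply(w_hits, `[[`, "", "gene_id")
  rows <- list()
  for (g in intersect(names(z_cds), unique(gene_ids))) {
    cand <- w_hits[gene_ids == g]
    hs <- vapply(cand, function(h) {
      hscore(z_cds[[g]], substr(tstr, h$start + 1L, h$end))
    }, 0)
    members <- cand[hs > h_threshold]
    if (length(members) < 2L) next
    row <- data.frame(source_gene_id = g, n_copies = length(members),
                      members = paste(vapply(members, function(h)
                        sprintf("%d-%d", h$start, h$end), ""), collapse = ","),
                      stringsAsFactors = FALSE)
    if (!is.null(regions)) {
      mid <- vapply(members, function(h) (h$start + h$end) / 2, 0)
      for (i in seq_len(nrow(regions)))
        row[[paste0("n_", regions$name[i])]] <-
          sum(mid >= regions$start[i] & mid < regions$end[i])
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) {
    out <- data.frame(source_gene_id = character(0), n_copies = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
    if (!is.null(regions))
      for (i in seq_len(nrow(regions))) out[[paste0("n_", regions$name[i])]] <- integer(0)
    return(out)
  }
  do.call(rbind, rows)
}
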