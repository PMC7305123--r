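#' Configuration of a synthetic ChIP-seq study
#'
#' Captures every knob of the simulated study.  The defaults are the study
#' conditions used throughout the package's validation: a 2000-gene toy
#' genome, the 4 untreated + 5 fear-conditioned pairs per genotype of the
#' reference design, 10\% of genes responsive at 2-fold in WT with total
#' attenuation in the KO, 2e5 fragments per sample, 300 bp fragments with a
#' TSS-peaked placement kernel, 5\% multimapping reads, and sporadic PCR
#' duplicate bursts.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Toy chromosomes (genes distributed round-robin).
#' @param n_untreated,n_fc Replicate pairs per treatment arm (each pair has
#'   one WT and one KO sample).
#' @param depth Expected fragments per sample.
#' @param fragment_len Fragment length in bases (sonication midpoint 300).
#' @param baseline_meanlog,baseline_sdlog Log-normal per-gene baseline
#'   expression (natural-log scale).
#' @param responsive_fraction Fraction of genes induced by FC in WT.
#' @param effect_log2 True log2 induction of responsive genes in WT.
#' @param ko_attenuation Fraction of the WT effect lost in KO (1 = no
#'   induction in KO).
#' @param noise_sdlog Per-gene, per-sample log-normal biological noise
#'   (natural-log sd).
#' @param multimapper_fraction Fraction of fragments that multimap.
#' @param multimapper_probs Distribution of the match count n among
#'   multimappers (names "2", "3", "4"; n = 4 reads are dropped by the
#'   ingest rule).
#' @param duplicate_rate Fraction of fragments amplified into a PCR burst.
#' @param duplicate_copies Extra identical copies per burst (7 extra, so
#'   bursts exceed the cap of 5).
#' @param tss_mix Probability a fragment falls in the TSS window rather
#'   than the exons (promoter-proximal enrichment stand-in).
#' @param tdrd3_rho Target gene-level correlation between TDRD3 and Pol II
#'   log baselines.
#' @param tss_up,tss_down TSS window extent for placement.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000, n_chroms = 3,
                       n_untreated = 4, n_fc = 5,
                       depth = 2e5, fragment_len = 300,
                       baseline_meanlog = 0, baseline_sdlog = 1,
                       responsive_fraction = 0.1, effect_log2 = 1,
                       ko_attenuation = 1, noise_sdlog = 0.25,
                       multimapper_fraction = 0.05,
                       multimapper_probs = c("2" = 0.5, "3" = 0.3, "4" = 0.2),
                       duplicate_rate = 0.01, duplicate_copies = 7,
                       tss_mix = 0.6, tdrd3_rho = 0.9,
                       tss_up = 700, tss_down = 700) {
  cfg <- as.list(environment())
  rates <- c(responsive_fraction, multimapper_fraction, duplicate_rate,
             tss_mix)
  stopifnot(all(rates >= 0 & rates <= 1), n_genes >= 1, depth > 0,
            abs(sum(multimapper_probs) - 1) < 1e-9)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a toy genome annotation
#'
#' Lays out non-overlapping genes (1-5 exons each, random strand) along the
#' configured chromosomes with intergenic spacing, and returns the gene
#' models plus chromosome lengths.  Uses the current RNG state; set a seed
#' (or call through \code{\link{simulate_study}}) for reproducibility.
#'
#' @param config A \code{sim_config}.
#' @return List with \code{genes} (a \code{gene_models}), \code{chrom_len}
#'   (named vector).
#' @export
simulate_annotation <- function(config) {
  n <- config$n_genes
  chrom <- paste0("chr", rep_len(seq_len(config$n_chroms), n))
  n_ex <- sample(1:5, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  spacing <- round(stats::runif(n, 3000, 8000))
  ids <- sprintf("gene%04d", seq_len(n))
  starts_l <- vector("list", n); ends_l <- vector("list", n)
  span <- numeric(n)
  for (i in seq_len(n)) {
    widths <- round(stats::runif(n_ex[i], 200, 1200))
    gaps <- if (n_ex[i] > 1) round(stats::runif(n_ex[i] - 1, 100, 2000)) else numeric(0)
    starts_l[[i]] <- cumsum(c(0, widths[-n_ex[i]] + gaps))   # offsets in gene
    ends_l[[i]] <- starts_l[[i]] + widths - 1
    span[i] <- ends_l[[i]][n_ex[i]] + 1
  }
  # lay genes out per chromosome: spacing, then the gene's span
  pos <- numeric(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- 1 + cumsum(spacing[idx]) +
      c(0, cumsum(span[idx][-length(idx)]))
  }
  ex_start <- unlist(starts_l) + rep(pos, n_ex)
  ex_end <- unlist(ends_l) + rep(pos, n_ex)
  exons <- GenomicRanges::GRanges(rep(chrom, n_ex),
                                  IRanges::IRanges(ex_start, ex_end),
                                  strand = rep(strand, n_ex))
  gm <- build_gene_models(exons, rep(ids, n_ex))
  chrom_len <- vapply(split(ex_end, rep(chrom, n_ex)), max, 0) + 10000
  list(genes = gm, chrom_len = chrom_len)
}

#' Ground truth of the synthetic study
#'
#' Draws per-gene baselines, responsiveness, effect sizes and the
#' TDRD3-binding flag consistent with a \code{sim_config}.
#'
#' @param config A \code{sim_config}.
#' @param genes A \code{gene_models} (for gene ids).
#' @return data.frame with \code{gene_id}, \code{baseline} (relative
#'   expression), \code{responsive}, \code{effect_log2} (WT FC induction),
#'   \code{ko_attenuation}, \code{tdrd3_baseline}, \code{tdrd3_bound}.
#' @export
simulate_truth <- function(config, genes) {
  ids <- genes$genes$gene_id
  n <- length(ids)
  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  responsive <- stats::runif(n) < config$responsive_fraction
  # TDRD3 log baseline = Pol II log baseline + independent noise sized so
  # the gene-level log correlation is tdrd3_rho
  tau <- config$baseline_sdlog * sqrt(1 / config$tdrd3_rho^2 - 1)
  tdrd3 <- exp(log(baseline) + stats::rnorm(n, 0, tau))
  data.frame(gene_id = ids, baseline = baseline, responsive = responsive,
             effect_log2 = ifelse(responsive, config$effect_log2, 0),
             ko_attenuation = config$ko_attenuation,
             tdrd3_baseline = tdrd3,
             tdrd3_bound = tdrd3 >= stats::quantile(tdrd3, 0.7),
             stringsAsFactors = FALSE)
}

# Vectorized fragment placement for one sample.  Returns raw alignment
# records (with n_matches evidence) ready for weight_reads().
place_fragments <- function(config, anno, truth, counts) {
  g <- anno$genes$genes
  ex <- anno$genes$exons
  flen <- config$fragment_len
  gene_idx <- rep(seq_len(nrow(g)), counts)
  ntot <- length(gene_idx)
  if (ntot == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_matches = integer(), stringsAsFactors = FALSE))
  in_tss <- stats::runif(ntot) < config$tss_mix
  mid <- numeric(ntot)
  # TSS component: midpoint uniform in the +/-700 window (strand-agnostic)
  if (any(in_tss)) {
    gi <- gene_idx[in_tss]
    mid[in_tss] <- g$tss[gi] + floor(stats::runif(sum(in_tss),
                                                  -config$tss_up,
                                                  config$tss_down))
  }
  # exon component: midpoint uniform over the gene's exon-union bases,
  # mapped through the global cumulative exon widths (exons are grouped
  # contiguously by gene)
  if (any(!in_tss)) {
    gi <- gene_idx[!in_tss]
    wd <- GenomicRanges::width(ex)
    cumw <- cumsum(as.numeric(wd))
    exoff_by_gene <- c(0, cumw)[match(g$gene_id, ex$gene_id)]  # offset before gene's first exon
    u <- pmax(stats::runif(sum(!in_tss), 0, g$exon_len[gi]), 1e-9)
    p <- exoff_by_gene[gi] + u
    row <- findInterval(p, cumw, left.open = TRUE) + 1L
    off <- p - c(0, cumw)[row]
    mid[!in_tss] <- GenomicRanges::start(ex)[row] + ceiling(off) - 1
  }
  start <- pmax(round(mid) - floor(flen / 2), 1)
  rec <- data.frame(chrom = g$chrom[gene_idx], start = start,
                    end = start + flen - 1,
                    strand = sample(c("+", "-"), ntot, replace = TRUE),
                    n_matches = 1L, stringsAsFactors = FALSE)
  # multimappers: the true placement plus n-1 decoy placements elsewhere,
  # all carrying the match count n
  mm <- which(stats::runif(ntot) < config$multimapper_fraction)
  if (length(mm) > 0) {
    nmatch <- as.integer(sample(names(config$multimapper_probs), length(mm),
                                replace = TRUE,
                                prob = config$multimapper_probs))
    rec$n_matches[mm] <- nmatch
    extra <- rep(mm, nmatch - 1L)
    if (length(extra) > 0) {
      dch <- sample(names(anno$chrom_len), length(extra), replace = TRUE)
      dst <- floor(stats::runif(length(extra), 1,
                                anno$chrom_len[dch] - flen))
      decoys <- data.frame(chrom = dch, start = dst, end = dst + flen - 1,
                           strand = sample(c("+", "-"), length(extra),
                                           replace = TRUE),
                           n_matches = rec$n_matches[extra],
                           stringsAsFactors = FALSE)
      rec <- rbind(rec, decoys)
    }
  }
  # PCR duplicate bursts: identical coordinates repeated
  burst <- which(stats::runif(nrow(rec)) < config$duplicate_rate)
  if (length(burst) > 0)
    rec <- rbind(rec, rec[rep(burst, each = config$duplicate_copies), ])
  rownames(rec) <- NULL
  rec
}

#' Simulate raw alignment records for one sample
#'
#' Per-gene expected coverage is \code{depth x relative baseline x
#' 2^(treatment x effect x genotype modifier)} with multiplicative
#' log-normal biological noise and Poisson fragment counts; fragments are
#' placed by the TSS-peaked kernel, multimappers duplicated at their decoy
#' loci, and duplicate bursts appended.
#'
#' @param config A \code{sim_config}.
#' @param anno Result of \code{\link{simulate_annotation}}.
#' @param truth Result of \code{\link{simulate_truth}}.
#' @param genotype \code{"WT"} or \code{"KO"}.
#' @param treatment \code{"untreated"} or \code{"FC"}.
#' @param antibody \code{"PolII"}, \code{"TDRD3"} or \code{"input"}
#'   (uniform genome-wide background).
#' @return Raw records data.frame for \code{\link{read_set}}.
#' @export
simulate_reads <- function(config, anno, truth, genotype = "WT",
                           treatment = "untreated", antibody = "PolII") {
  if (antibody == "input") {
    n <- stats::rpois(1, config$depth)
    ch <- sample(names(anno$chrom_len), n, replace = TRUE)
    st <- floor(stats::runif(n, 1, anno$chrom_len[ch] - config$fragment_len))
    return(data.frame(chrom = ch, start = st,
                      end = st + config$fragment_len - 1,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      n_matches = 1L, stringsAsFactors = FALSE))
  }
  base <- if (antibody == "TDRD3") truth$tdrd3_baseline else truth$baseline
  modifier <- if (genotype == "KO") 1 - config$ko_attenuation else 1
  fold <- if (treatment == "FC") 2^(truth$effect_log2 * modifier) else 1
  mu <- base * fold
  mu <- mu / sum(mu) * config$depth
  noise <- stats::rlnorm(length(mu), -config$noise_sdlog^2 / 2,
                         config$noise_sdlog)
  counts <- stats::rpois(length(mu), mu * noise)
  if (sum(counts) == 0) stop("zero-depth sample")
  place_fragments(config, anno, truth, counts)
}

#' Simulate a complete synthetic study
#'
#' Annotation, ground truth, and weighted/capped read sets for the full
#' factorial design (one WT and one KO sample per pair; 4 untreated + 5 FC
#' pairs by default), optionally with TDRD3 ChIP samples and an input
#' control.  Fully deterministic given \code{seed}.
#'
#' @param config A \code{sim_config}.
#' @param seed Integer random seed (mandatory for reproducibility).
#' @param tdrd3 Also simulate TDRD3 ChIP samples (one per condition).
#' @param input Also simulate an input-chromatin control.
#' @param cap,max_matches Ingest settings passed to \code{\link{read_set}}
#'   (duplicate cap 5, multimapper limit 3 by default; \code{cap = Inf}
#'   recovers raw weighted counts for audits).
#' @return List with \code{genes}, \code{chrom_len}, \code{truth},
#'   \code{samples} (list of \code{read_set}), optional \code{tdrd3}
#'   samples and \code{input}, and \code{config}.
#' @export
simulate_study <- function(config = sim_config(), seed,
                           tdrd3 = FALSE, input = FALSE,
                           cap = 5, max_matches = 3) {
  if (missing(seed)) stop("seed is mandatory for a reproducible study")
  set.seed(seed)
  anno <- simulate_annotation(config)
  truth <- simulate_truth(config, anno$genes)
  samples <- list()
  k <- 0
  for (treatment in c("untreated", "FC")) {
    npair <- if (treatment == "untreated") config$n_untreated else config$n_fc
    for (pair in seq_len(npair)) {
      for (genotype in c("WT", "KO")) {
        k <- k + 1
        rec <- simulate_reads(config, anno, truth, genotype, treatment)
        samples[[k]] <- read_set(
          rec, sample_id = sprintf("%s_%s_p%d", genotype, treatment, pair),
          genotype = genotype, treatment = treatment, batch = NA,
          antibody = "PolII", cap = cap, max_matches = max_matches)
      }
    }
  }
  out <- list(genes = anno$genes, chrom_len = anno$chrom_len, truth = truth,
              samples = samples, config = config)
  if (tdrd3) {
    out$tdrd3 <- list()
    k <- 0
    for (treatment in c("untreated", "FC")) for (genotype in c("WT", "KO")) {
      k <- k + 1
      rec <- simulate_reads(config, anno, truth, genotype, treatment, "TDRD3")
      out$tdrd3[[k]] <- read_set(
        rec, sample_id = sprintf("TDRD3_%s_%s", genotype, treatment),
        genotype = genotype, treatment = treatment, batch = NA,
        antibody = "TDRD3")
    }
  }
  if (input) {
    rec <- simulate_reads(config, anno, truth, antibody = "input")
    out$input <- read_set(rec, sample_id = "input", antibody = "input")
  }
  out
}

#' Simulate gene-set collections over the synthetic genes
#'
#' Random sets, optionally enriched in responsive (or any flagged) genes,
#' for exercising the PAGE module.
#'
#' @param truth Truth table of the study.
#' @param n_sets Number of sets.
#' @param set_size Members per set.
#' @param enrich_responsive Fraction of each of the first
#'   \code{n_enriched} sets drawn from responsive genes.
#' @param n_enriched How many sets are enriched (default 0: all random).
#' @return Named list of gene-id vectors (a GMT-ready collection).
#' @export
simulate_gene_sets <- function(truth, n_sets = 50, set_size = 30,
                               enrich_responsive = 0.5, n_enriched = 0) {
  ids <- truth$gene_id
  resp <- ids[truth$responsive]
  sets <- lapply(seq_len(n_sets), function(i) {
    if (i <= n_enriched && length(resp) > 0) {
      k <- min(round(set_size * enrich_responsive), length(resp))
      unique(c(sample(resp, k), sample(ids, set_size - k)))
    } else sample(ids, set_size)
  })
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  sets
}

#' Confusion summary of differential calls against ground truth
#'
#' Compares "up" calls of one comparison with the truth's responsive flag.
#'
#' @param truth Truth table of the study.
#' @param fit An \code{nadt_fit} on the same genes.
#' @param contrast Which comparison (default \code{"WT_FC_effect"}).
#' @param direction Which class counts as a positive call (default
#'   \code{"up"}).
#' @return List with \code{sensitivity}, \code{specificity},
#'   \code{realized_fdr} (0 when nothing is called), and the confusion
#'   counts \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @export
evaluate_recovery <- function(truth, fit, contrast = "WT_FC_effect",
                              direction = "up") {
  if (!all(fit$gene_id %in% truth$gene_id))
    stop("gene id mismatch between fit and truth")
  tr <- truth[match(fit$gene_id, truth$gene_id), ]
  pos <- tr$responsive & tr$effect_log2 != 0
  call <- as.character(fit$contrasts[[contrast]]$class) == direction
  call[is.na(call)] <- FALSE
  tp <- sum(call & pos); fp <- sum(call & !pos)
  fn <- sum(!call & pos); tn <- sum(!call & !pos)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA,
       realized_fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Write gene models as GTF
#'
#' Exon records with \code{gene_id}/\code{gene_name} attributes (1-based
#' closed coordinates), deterministic ordering.
#'
#' @param genes A \code{gene_models}.
#' @param path Output GTF.
#' @export
write_gtf <- function(genes, path) {
  ex <- genes$exons
  sym <- genes$genes$symbol[match(ex$gene_id, genes$genes$gene_id)]
  lines <- sprintf(
    '%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
    as.character(GenomeInfoDb::seqnames(ex)), GenomicRanges::start(ex),
    GenomicRanges::end(ex), as.character(GenomicRanges::strand(ex)),
    ex$gene_id, sym)
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output GMT.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Write the sample sheet of a simulated study as TSV
#'
#' @param study Result of \code{\link{simulate_study}}.
#' @param path Output TSV.
#' @export
write_sample_sheet <- function(study, path) {
  meta <- do.call(rbind, lapply(study$samples, function(s)
    data.frame(sample_id = s$sample$id, genotype = s$sample$genotype,
               treatment = s$sample$treatment, batch = s$sample$batch,
               antibody = s$sample$antibody, stringsAsFactors = FALSE)))
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the truth table as TSV
#'
#' @param truth Truth table data.frame.
#' @param path Output TSV.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
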