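#' Weighted read count over a region or region union
#'
#' Sums read weights for reads overlapping the region by at least one base.
#' When \code{regions} carries a \code{gene_id} column the count is returned
#' per gene, and a read spanning several intervals of the same gene (e.g.
#' two exons of a union) is counted once.
#'
#' @param rs A \code{read_set}.
#' @param regions \code{GRanges}, optionally with a \code{gene_id} column.
#' @return Single weighted count, or a named vector per gene id (zero for
#'   genes without reads).
#' @export
region_signal <- function(rs, regions) {
  gr <- rs$reads
  hits <- GenomicRanges::findOverlaps(gr, regions, ignore.strand = TRUE)
  if (is.null(regions$gene_id)) {
    return(sum(gr$weight[unique(S4Vectors::queryHits(hits))]))
  }
  gid <- regions$gene_id[S4Vectors::subjectHits(hits)]
  q <- S4Vectors::queryHits(hits)
  dup <- duplicated(paste(q, gid, sep = "\r"))   # read counted once per gene
  counts <- rowsum(gr$weight[q][!dup], gid[!dup])
  out <- stats::setNames(rep(0, length(unique(regions$gene_id))),
                         unique(regions$gene_id))
  out[rownames(counts)] <- counts[, 1]
  out
}

#' Fragments per kilobase per million (FPKM)
#'
#' @param count Weighted fragment count over the region.
#' @param region_len Region length in bases (> 0).
#' @param library_size Weighted library fragments (> 0).
#' @return FPKM value(s): \code{count / (region_len/1e3) / (library_size/1e6)}.
#' @export
fpkm <- function(count, region_len, library_size) {
  if (any(region_len <= 0)) stop("region length must be positive")
  if (any(library_size <= 0)) stop("undefined signal: library size must be positive")
  count / (region_len / 1e3) / (library_size / 1e6)
}

# Library size: summed weights of reads overlapping any gene body
# ("total reads counted in all transcripts"), or all retained reads.
library_size <- function(rs, genes, policy = c("transcripts", "all")) {
  policy <- match.arg(policy)
  if (policy == "all") return(sum(rs$reads$weight))
  bodies <- GenomicRanges::reduce(gene_body_ranges(genes), ignore.strand = TRUE)
  ov <- IRanges::overlapsAny(rs$reads, bodies, ignore.strand = TRUE)
  sum(rs$reads$weight[ov])
}

#' Genes-by-samples FPKM matrix for one region class
#'
#' Quantifies each sample's weighted reads over TSS windows, exon unions or
#' whole gene bodies, in FPKM with the library counted over annotated
#' transcripts.  Missing coverage yields 0, never NA.
#'
#' @param samples List of \code{read_set} objects.
#' @param genes A \code{gene_models} object.
#' @param region_class \code{"tss"}, \code{"exons"} or \code{"gene_body"}.
#' @param up,down TSS window extent (used for \code{region_class = "tss"}).
#' @param chrom_len Optional chromosome lengths for TSS-window clipping.
#' @param library_policy \code{"transcripts"} (default) or \code{"all"}.
#' @return Object of class \code{signal_matrix}: list with \code{values}
#'   (genes x samples numeric matrix), \code{samples} (data.frame of sample
#'   metadata incl. \code{library_size}), \code{region_class} and
#'   \code{region_len} (per-gene region lengths).
#' @export
build_signal_matrix <- function(samples, genes,
                                region_class = c("tss", "exons", "gene_body"),
                                up = 700, down = 700, chrom_len = NULL,
                                library_policy = c("transcripts", "all")) {
  region_class <- match.arg(region_class)
  library_policy <- match.arg(library_policy)
  stopifnot(length(samples) >= 1, nrow(genes$genes) >= 1)
  regions <- switch(region_class,
    tss = tss_window(genes, up, down, chrom_len),
    exons = genes$exons,
    gene_body = gene_body_ranges(genes))
  gid <- genes$genes$gene_id
  rlen <- switch(region_class,
    tss = {
      w <- rowsum(GenomicRanges::width(regions), regions$gene_id)[, 1]
      stats::setNames(w[gid], gid)
    },
    exons = exon_union_length(genes),
    gene_body = stats::setNames(genes$genes$end - genes$genes$start + 1, gid))
  anno_chroms <- unique(genes$genes$chrom)
  vals <- matrix(0, nrow = length(gid), ncol = length(samples),
                 dimnames = list(gid, vapply(samples, function(s) s$sample$id, "")))
  meta <- do.call(rbind, lapply(samples, function(s)
    data.frame(sample_id = s$sample$id, genotype = s$sample$genotype,
               treatment = s$sample$treatment, batch = s$sample$batch,
               antibody = s$sample$antibody, stringsAsFactors = FALSE)))
  meta$library_size <- NA_real_
  for (j in seq_along(samples)) {
    rs <- samples[[j]]
    rchr <- unique(as.character(GenomeInfoDb::seqnames(rs$reads)))
    bad <- setdiff(rchr, anno_chroms)
    if (length(bad) > 0 && length(bad) == length(rchr))
      stop("sample '", rs$sample$id,
           "' and annotation share no chromosome; read chromosomes: ",
           paste(bad, collapse = ", "))
    lib <- library_size(rs, genes, library_policy)
    if (lib <= 0) stop("undefined signal: zero library size in sample '",
                       rs$sample$id, "'")
    cnt <- region_signal(rs, regions)
    vals[names(cnt), j] <- fpkm(cnt, rlen[names(cnt)], lib)
    meta$library_size[j] <- lib
  }
  structure(list(values = vals, samples = meta,
                 region_class = region_class, region_len = rlen),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix [", x$region_class, "]: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Write a signal matrix as TSV with a sample-sheet sidecar
#'
#' @param sm A \code{signal_matrix}.
#' @param path Output TSV (genes x samples, first column gene_id); the
#'   sample sheet goes to \code{<path>.samples.tsv}.
#' @export
write_signal_matrix <- function(sm, path) {
  df <- data.frame(gene_id = rownames(sm$values), sm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sm$samples, paste0(path, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Metagene profile of signal around the TSS
#'
#' Bins read midpoints by distance to each gene's TSS (strand-flipped so
#' positive offsets are downstream of transcription), normalizes per sample
#' to reads per million, averages over genes, then averages replicate
#' samples within each condition.
#'
#' @param samples List of \code{read_set} objects.
#' @param genes A \code{gene_models} object.
#' @param span Half-width of the profiled region in bases (default 2000).
#' @param bin Bin width in bases (must divide \code{span}; default 50).
#' @param gene_subset Optional character vector of gene ids.
#' @param condition Factor/character grouping of samples (default
#'   genotype:treatment from the sample metadata).
#' @return Object of class \code{profile_matrix}: list with \code{offset}
#'   (bin start offsets relative to TSS), \code{values} (bins x conditions
#'   matrix of mean RPM per bin per gene), \code{n_genes}.
#' @export
tss_profile <- function(samples, genes, span = 2000, bin = 50,
                        gene_subset = NULL, condition = NULL) {
  stopifnot(span %% bin == 0)
  g <- genes$genes
  if (!is.null(gene_subset)) {
    g <- g[g$gene_id %in% gene_subset, , drop = FALSE]
    if (nrow(g) == 0) stop("empty gene subset")
  }
  nbins <- 2 * span / bin
  offsets <- seq(-span, span - bin, by = bin)
  if (is.null(condition))
    condition <- vapply(samples, function(s)
      paste(s$sample$genotype, s$sample$treatment, sep = ":"), "")
  condition <- as.character(condition)
  win <- GenomicRanges::GRanges(g$chrom,
                                IRanges::IRanges(pmax(g$tss - span, 1),
                                                 g$tss + span - 1))
  prof <- matrix(0, nbins, length(samples))
  for (j in seq_along(samples)) {
    rs <- samples[[j]]
    mids <- floor((GenomicRanges::start(rs$reads) +
                   GenomicRanges::end(rs$reads)) / 2)
    mgr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(rs$reads),
                                  IRanges::IRanges(mids, mids))
    hits <- GenomicRanges::findOverlaps(mgr, win, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    off <- mids[q] - g$tss[s]
    off[g$strand[s] == "-"] <- -off[g$strand[s] == "-"]
    b <- floor((off + span) / bin) + 1L
    ok <- b >= 1 & b <= nbins
    lib <- sum(rs$reads$weight)
    if (lib <= 0) stop("zero-weight sample '", rs$sample$id, "'")
    acc <- Matrix::sparseMatrix(i = s[ok], j = b[ok],
                                x = rs$reads$weight[q][ok] / lib * 1e6,
                                dims = c(nrow(g), nbins))
    prof[, j] <- Matrix::colMeans(acc)     # mean over genes of per-gene RPM
  }
  conds <- unique(condition)
  vals <- vapply(conds, function(cc)
    rowMeans(prof[, condition == cc, drop = FALSE]), numeric(nbins))
  structure(list(offset = offsets, values = vals, bin = bin,
                 n_genes = nrow(g)), class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", length(x$offset), "bins of", x$bin, "bp x",
      ncol(x$values), "condition(s),", x$n_genes, "genes\n")
  invisible(x)
}

#' Genome-wide feature distribution of a sample's signal
#'
#' Classifies each read's midpoint as promoter / exon / intron / intergenic
#' and returns weighted fractions (summing to 1).
#'
#' @param rs A \code{read_set}.
#' @param genes A \code{gene_models} object.
#' @param promoter_up,promoter_down Promoter extent around the TSS.
#' @return Named numeric vector of fractions over the four features.
#' @export
feature_distribution <- function(rs, genes,
                                 promoter_up = 700, promoter_down = 700) {
  if (length(rs$reads) == 0) stop("empty read set")
  mids <- floor((GenomicRanges::start(rs$reads) +
                 GenomicRanges::end(rs$reads)) / 2)
  lab <- classify_position(as.character(GenomeInfoDb::seqnames(rs$reads)),
                           mids, genes, promoter_up, promoter_down)
  w <- rs$reads$weight
  tot <- sum(w)
  vapply(levels(lab), function(l) sum(w[lab == l]) / tot, 0)
}

#' Export per-sample coverage as bedGraph
#'
#' Weighted fragment coverage binned at fixed width, for genome-browser
#' comparison of samples.
#'
#' @param rs A \code{read_set}.
#' @param path Output bedGraph file.
#' @param bin Bin width in bases (default 10).
#' @export
write_bedgraph <- function(rs, path, bin = 10) {
  gr <- rs$reads
  chroms <- unique(as.character(GenomeInfoDb::seqnames(gr)))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chroms) {
    sub <- gr[GenomeInfoDb::seqnames(gr) == ch]
    mids <- floor((GenomicRanges::start(sub) + GenomicRanges::end(sub)) / 2)
    b <- floor((mids - 1) / bin)
    cnt <- rowsum(sub$weight, b)
    idx <- as.integer(rownames(cnt))
    nz <- cnt[, 1] > 0
    writeLines(sprintf("%s\t%d\t%d\t%g", ch, idx[nz] * bin,
                       (idx[nz] + 1L) * bin, cnt[nz, 1]), con)
  }
  invisible(path)
}
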