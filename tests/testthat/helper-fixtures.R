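# in-code fixtures shared across the suite

# toy gene models built directly from exon coordinates
# exons: list of gene_id -> matrix/list of c(start, end) pairs (1-based closed)
toy_genes <- function(exons, strand = "+") {
  gid <- rep(names(exons), vapply(exons, nrow, 0L))
  if (length(strand) == 1) strand <- rep(strand, length(exons))
  str <- rep(strand, vapply(exons, nrow, 0L))
  gr <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(unlist(lapply(exons, function(m) m[, 1])),
                     unlist(lapply(exons, function(m) m[, 2]))),
    strand = str)
  nadtseq:::build_gene_models(gr, gid)
}

# raw alignment records data.frame
toy_records <- function(start, end, chrom = "chr1", n = 1, strand = "+") {
  data.frame(chrom = chrom, start = start, end = end,
             strand = strand, n_matches = n, stringsAsFactors = FALSE)
}

toy_read_set <- function(start, end, chrom = "chr1", n = 1, id = "s1", ...) {
  read_set(toy_records(start, end, chrom, n), sample_id = id, ...)
}

# a tiny GTF file (1-based closed), returns its path
write_toy_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_exon <- function(chrom, start, end, strand, gene, symbol = gene) {
  sprintf('%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
          chrom, start, end, strand, gene, symbol)
}

# balanced/unbalanced design sheets
toy_design <- function(n_unt = 4, n_fc = 5) {
  rows <- expand.grid(pair = seq_len(max(n_unt, n_fc)),
                      genotype = c("WT", "KO"),
                      treatment = c("untreated", "FC"),
                      stringsAsFactors = FALSE)
  rows <- rows[(rows$treatment == "untreated" & rows$pair <= n_unt) |
               (rows$treatment == "FC" & rows$pair <= n_fc), ]
  data.frame(sample_id = sprintf("%s_%s_%d", rows$genotype, rows$treatment,
                                 rows$pair),
             genotype = rows$genotype, treatment = rows$treatment,
             stringsAsFactors = FALSE)
}

# brute-force per-base interval membership (oracle for overlap logic)
base_set <- function(start, end) unlist(mapply(seq, start, end, SIMPLIFY = FALSE))

# explicit left-to-right scan oracle for gap-tolerant island merging:
# maximal runs of eligible windows <= g bases apart
oracle_islands <- function(mask, w, g) {
  idx <- which(mask)
  if (length(idx) == 0) return(NULL)
  runs <- list()
  cur <- prev <- idx[1]
  for (k in idx[-1]) {
    if ((k - prev - 1) * w > g) {
      runs[[length(runs) + 1]] <- c(cur, prev)
      cur <- k
    }
    prev <- k
  }
  runs[[length(runs) + 1]] <- c(cur, prev)
  do.call(rbind, runs)
}
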