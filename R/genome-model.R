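#' Gene models from a GTF or BED12 annotation
#'
#' Reads a transcript annotation and collapses it to one model per gene:
#' the union of all exons across transcripts, the gene body spanning the
#' outermost exon boundaries, and a single strand-aware transcription start
#' site (the outermost start on the gene's strand).  All coordinates are
#' held as 1-based closed intervals in \code{GRanges}; GTF is native in that
#' convention and BED (0-based half-open) is shifted on read.
#'
#' @param path Path to a GTF file (Ensembl/UCSC dialects, \code{gene_id} and
#'   optionally \code{gene_name} attributes) or a BED12 file.
#' @param id_policy Which attribute identifies a gene: \code{"gene_id"}
#'   (default) or \code{"symbol"} (uses \code{gene_name}, falling back to
#'   \code{gene_id}).
#' @param format \code{"auto"} (by extension), \code{"gtf"} or \code{"bed"}.
#' @return An object of class \code{gene_models}: a list with
#'   \describe{
#'     \item{genes}{data.frame with one row per gene: \code{gene_id},
#'       \code{symbol}, \code{chrom}, \code{strand}, \code{tss} (1-based),
#'       \code{start}, \code{end} (gene body, 1-based closed),
#'       \code{exon_len} (union-exon length in bases).}
#'     \item{exons}{\code{GRanges} of union exons with a \code{gene_id}
#'       metadata column, sorted, pairwise disjoint within gene.}
#'   }
#'   Genes are ordered by (chrom, start, gene_id).
#' @export
load_annotation <- function(path, id_policy = c("gene_id", "symbol"),
                            format = c("auto", "gtf", "bed")) {
  id_policy <- match.arg(id_policy)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed[0-9]*$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gtf") {
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e) stop("GTF parse error in '", path, "': ",
                                            conditionMessage(e)))
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0 && length(gr) > 0) ex <- gr   # exon-less dialect: take all records
    gid <- as.character(ex$gene_id)
    sym <- if (!is.null(ex$gene_name)) as.character(ex$gene_name) else gid
    sym[is.na(sym)] <- gid[is.na(sym)]
  } else {
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e) stop("BED parse error in '", path, "': ",
                                            conditionMessage(e)))
    # expand BED12 blocks (or plain BED intervals) into exon ranges
    if (!is.null(gr$blocks)) {
      nb <- S4Vectors::elementNROWS(gr$blocks)
      ex <- GenomicRanges::GRanges(
        rep(GenomeInfoDb::seqnames(gr), nb),
        IRanges::shift(unlist(gr$blocks, use.names = FALSE),
                       rep(GenomicRanges::start(gr), nb) - 1L),
        strand = rep(GenomicRanges::strand(gr), nb))
      gid <- rep(as.character(gr$name), nb)
    } else {
      ex <- GenomicRanges::granges(gr)
      gid <- as.character(gr$name)
    }
    sym <- gid
  }
  if (length(ex) == 0) stop("empty annotation: no gene records in '", path, "'")
  if (id_policy == "symbol") gid <- sym
  names(sym) <- gid
  build_gene_models(ex, gid, sym[!duplicated(gid)])
}

# Collapse exon ranges tagged by gene id into a gene_models object.
build_gene_models <- function(exons, gene_id, symbols = NULL) {
  stopifnot(length(exons) == length(gene_id))
  exl <- GenomicRanges::reduce(GenomicRanges::split(exons, gene_id))
  ex <- unlist(exl, use.names = FALSE)
  S4Vectors::mcols(ex)$gene_id <- rep(names(exl), S4Vectors::elementNROWS(exl))
  ids <- names(exl)
  chrom <- as.character(GenomeInfoDb::seqnames(ex))[match(ids, ex$gene_id)]
  strand <- as.character(GenomicRanges::strand(ex))[match(ids, ex$gene_id)]
  gstart <- vapply(split(GenomicRanges::start(ex), ex$gene_id)[ids], min, 0)
  gend <- vapply(split(GenomicRanges::end(ex), ex$gene_id)[ids], max, 0)
  elen <- vapply(split(GenomicRanges::width(ex), ex$gene_id)[ids], sum, 0)
  if (any(elen <= 0)) stop("gene with zero exon length in annotation")
  if (is.null(symbols)) symbols <- stats::setNames(ids, ids)
  genes <- data.frame(
    gene_id = ids,
    symbol = unname(symbols[ids]),
    chrom = chrom, strand = strand,
    tss = ifelse(strand == "-", gend, gstart),
    start = gstart, end = gend, exon_len = elen,
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  rownames(genes) <- genes$gene_id
  ex <- ex[order(match(ex$gene_id, genes$gene_id), GenomicRanges::start(ex))]
  structure(list(genes = genes, exons = ex), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", length(x$exons),
      "union exons on", length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Promoter window around a transcription start site
#'
#' Builds the TSS region used for promoter-level quantification: by default
#' 700 bp on each side of the TSS (a 1400 bp window), clipped to the
#' chromosome.  \code{up}/\code{down} are strand-oriented: \code{up} extends
#' against the direction of transcription.
#'
#' @param genes A \code{gene_models} object (or its \code{$genes} data.frame).
#' @param up,down Bases upstream/downstream of the TSS (defaults 700/700).
#' @param chrom_len Named vector of chromosome lengths, or a single length,
#'   or \code{NULL} for no right clipping.
#' @return \code{GRanges} of TSS windows with \code{gene_id} metadata.
#' @export
tss_window <- function(genes, up = 700, down = 700, chrom_len = NULL) {
  g <- if (inherits(genes, "gene_models")) genes$genes else genes
  minus <- g$strand == "-"
  # strand-aware: upstream is left of tss on + ('.' treated as +), right on -;
  # a symmetric up == down window is identical on both strands
  left <- ifelse(minus, g$tss - down, g$tss - up)
  right <- ifelse(minus, g$tss + up - 1L, g$tss + down - 1L)
  left <- pmax(left, 1)
  if (!is.null(chrom_len)) {
    len <- if (length(chrom_len) == 1 && is.null(names(chrom_len)))
      rep(chrom_len, nrow(g)) else unname(chrom_len[g$chrom])
    right <- pmin(right, len)
  }
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(left, right),
                               strand = g$strand)
  S4Vectors::mcols(gr)$gene_id <- g$gene_id
  gr
}

# GRanges of gene bodies
gene_body_ranges <- function(gm) {
  g <- gm$genes
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                               strand = g$strand)
  S4Vectors::mcols(gr)$gene_id <- g$gene_id
  gr
}

#' Classify genomic positions by feature
#'
#' Labels positions as promoter, exon, intron or intergenic with fixed
#' priority promoter > exon > intron > intergenic.  The promoter is the TSS
#' window (default +/-700 bp, configurable).
#'
#' @param chrom Character vector of chromosome names.
#' @param pos 1-based positions (same length as \code{chrom}, or either
#'   may be length 1).
#' @param genes A \code{gene_models} object.
#' @param promoter_up,promoter_down Promoter extent around the TSS.
#' @return Factor with levels promoter, exon, intron, intergenic.
#' @export
classify_position <- function(chrom, pos, genes,
                              promoter_up = 700, promoter_down = 700) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  known <- unique(genes$genes$chrom)
  if (any(!chrom %in% known))
    warning("positions on unannotated chromosome(s) labelled intergenic: ",
            paste(unique(chrom[!chrom %in% known]), collapse = ", "))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  prom <- tss_window(genes, promoter_up, promoter_down)
  hit <- function(subject)
    suppressWarnings(IRanges::overlapsAny(q, subject, ignore.strand = TRUE))
  lab <- rep("intergenic", n)
  lab[hit(gene_body_ranges(genes))] <- "intron"
  lab[hit(genes$exons)] <- "exon"
  lab[hit(prom)] <- "promoter"
  factor(lab, levels = c("promoter", "exon", "intron", "intergenic"))
}

#' Union-exon length of each gene
#'
#' Total bases covered by the (already-unioned) exons of a gene: the
#' denominator of exon-level FPKM.
#'
#' @param genes A \code{gene_models} object.
#' @param gene_id Optional subset of gene ids.
#' @return Named numeric vector of lengths in bases.
#' @export
exon_union_length <- function(genes, gene_id = NULL) {
  len <- stats::setNames(genes$genes$exon_len, genes$genes$gene_id)
  if (!is.null(gene_id)) len <- len[gene_id]
  len
}

#' Read a gene panel from a one-gene-per-line file
#'
#' @param path Text file, one gene id/symbol per line (blank lines and
#'   \code{#} comments ignored).
#' @param name Panel label; defaults to the file name.
#' @return List with \code{name} and \code{members} (character vector).
#' @export
load_panel <- function(path, name = NULL) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  list(name = if (is.null(name)) basename(path) else name,
       members = unique(x))
}
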