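#' Load aligned reads from SAM/BAM or BED
#'
#' Parses alignments into the raw record form consumed by
#' \code{\link{weight_reads}}.  The number of genomic matches \code{n} of
#' each read is taken from the SAM \code{NH} tag when present, else from the
#' BED score column; records without either are assumed unique (n = 1) with
#' a warning.
#'
#' @param path SAM, BAM or BED file.  SAM text is converted on the fly.
#' @param format \code{"auto"}, \code{"bam"}, \code{"sam"} or \code{"bed"}.
#' @param paired Collapse properly-paired alignments to one fragment per
#'   pair (SAM/BAM only).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (1-based closed), \code{strand}, \code{n_matches}.
#' @export
load_alignments <- function(path, format = c("auto", "bam", "sam", "bed"),
                            paired = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bam = "bam", sam = "sam", bed = "bed",
                     stop("cannot guess alignment format from '", path, "'"))
  }
  if (format == "bed") {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(bed) == 0 || ncol(bed) < 3)
      stop("malformed BED: need at least chrom/start/end in '", path, "'")
    n <- if (ncol(bed) >= 5) {
      nm <- suppressWarnings(as.integer(bed[[5]]))
      if (anyNA(nm)) stop("non-integer score (match count) in BED '", path, "'")
      nm
    } else {
      warning("BED without score column: assuming unique alignments (n = 1)")
      rep(1L, nrow(bed))
    }
    return(data.frame(chrom = as.character(bed[[1]]),
                      start = bed[[2]] + 1L,       # BED is 0-based half-open
                      end = bed[[3]],
                      strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "*",
                      n_matches = n, stringsAsFactors = FALSE))
  }
  if (format == "sam") {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
    path <- bam
  }
  param <- Rsamtools::ScanBamParam(
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  if (paired) {
    ga <- GenomicAlignments::readGAlignmentPairs(path, param = param)
    gr <- GenomicRanges::granges(ga, on.discordant.seqnames = "drop")
    nh <- S4Vectors::mcols(GenomicAlignments::first(ga))$NH
  } else {
    ga <- GenomicAlignments::readGAlignments(path, param = param)
    gr <- GenomicRanges::granges(ga)
    nh <- S4Vectors::mcols(ga)$NH
  }
  if (length(gr) == 0) {
    warning("no mapped alignments in '", path, "'")
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_matches = integer(), stringsAsFactors = FALSE))
  }
  if (is.null(nh) || all(is.na(nh))) {
    warning("no NH tag in '", path, "': assuming unique alignments (n = 1)")
    nh <- rep(1L, length(gr))
  }
  nh[is.na(nh)] <- 1L
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             n_matches = as.integer(nh), stringsAsFactors = FALSE)
}

#' Fractional weighting of multimapping reads
#'
#' Drops reads matching more than three genomic loci and weights the rest
#' \code{1/n}, so a fragment placed at n <= 3 loci contributes total weight
#' 1 and a fragment with n > 3 contributes nothing.
#'
#' @param records data.frame from \code{\link{load_alignments}} (columns
#'   \code{chrom}, \code{start}, \code{end}, \code{n_matches}, optionally
#'   \code{strand}).
#' @param max_matches Retain reads with at most this many matches
#'   (default 3).
#' @return data.frame of retained records with a \code{weight} column
#'   (\code{= 1/n_matches}).
#' @export
weight_reads <- function(records, max_matches = 3) {
  if (nrow(records) == 0) {
    records$weight <- numeric(0)
    return(records)
  }
  if (any(records$n_matches < 1))
    stop("invalid match count: n_matches must be >= 1")
  keep <- records$n_matches <= max_matches
  out <- records[keep, , drop = FALSE]
  out$weight <- 1 / out$n_matches
  rownames(out) <- NULL
  out
}

#' Cap PCR duplicates at identical coordinates
#'
#' Retains at most \code{cap} reads per identical (chrom, start, end) key
#' (strand ignored by default), guarding against PCR-amplification bias.
#' Retention is deterministic: records are stably sorted on
#' (chrom, start, end, weight) and the first \code{cap} of each group kept.
#'
#' @param reads Weighted records from \code{\link{weight_reads}}.
#' @param cap Maximum records per coordinate key (default 5).
#' @param by_strand Include strand in the duplicate key.
#' @return The capped data.frame.
#' @export
cap_duplicates <- function(reads, cap = 5, by_strand = FALSE) {
  stopifnot(cap >= 1)
  if (nrow(reads) == 0) return(reads)
  w <- if (is.null(reads$weight)) rep(1, nrow(reads)) else reads$weight
  use_strand <- by_strand && !is.null(reads$strand)
  ord <- if (use_strand)
    order(reads$chrom, reads$start, reads$end, reads$strand, w,
          method = "radix")
  else order(reads$chrom, reads$start, reads$end, w, method = "radix")
  reads <- reads[ord, , drop = FALSE]
  new_grp <- reads$chrom[-1] != reads$chrom[-nrow(reads)] |
    reads$start[-1] != reads$start[-nrow(reads)] |
    reads$end[-1] != reads$end[-nrow(reads)]
  if (use_strand)
    new_grp <- new_grp | reads$strand[-1] != reads$strand[-nrow(reads)]
  grp_len <- diff(c(0L, which(new_grp), nrow(reads)))
  within <- sequence(grp_len)
  out <- reads[within <= cap, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a weighted, duplicate-capped read set for one sample
#'
#' Runs the fixed ingest pipeline (1/n weighting, then duplicate capping)
#' and attaches sample metadata.  The library size (summed weights of reads
#' overlapping annotated transcripts) is filled in lazily by
#' \code{\link{build_signal_matrix}}.
#'
#' @param records Raw records (data.frame) or a file path accepted by
#'   \code{\link{load_alignments}}.
#' @param sample_id Sample identifier.
#' @param genotype,treatment,batch,antibody Sample metadata; genotype in
#'   \{WT, KO\}, treatment in \{untreated, FC\}.
#' @param max_matches,cap,by_strand Passed to the ingest steps.
#' @return Object of class \code{read_set}: list with \code{reads} (a
#'   \code{GRanges} with a \code{weight} column), \code{sample} metadata
#'   list, and \code{library_size} (NA until computed).
#' @export
read_set <- function(records, sample_id, genotype = NA, treatment = NA,
                     batch = NA, antibody = NA,
                     max_matches = 3, cap = 5, by_strand = FALSE) {
  if (is.character(records) && length(records) == 1)
    records <- load_alignments(records)
  w <- weight_reads(records, max_matches = max_matches)
  w <- cap_duplicates(w, cap = cap, by_strand = by_strand)
  gr <- GenomicRanges::GRanges(
    w$chrom, IRanges::IRanges(w$start, w$end),
    strand = if (is.null(w$strand)) "*" else w$strand)
  S4Vectors::mcols(gr)$weight <- w$weight
  structure(list(reads = gr,
                 sample = list(id = sample_id, genotype = genotype,
                               treatment = treatment, batch = batch,
                               antibody = antibody),
                 library_size = NA_real_),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set '", x$sample$id, "': ", length(x$reads),
      " weighted reads (total weight ", round(sum(x$reads$weight), 2),
      "), genotype=", x$sample$genotype, ", treatment=", x$sample$treatment,
      "\n", sep = "")
  invisible(x)
}

#' Write a weighted read set as BED for audit
#'
#' BED6 with the weight in the score column (0-based half-open coordinates).
#'
#' @param rs A \code{read_set}.
#' @param path Output file.
#' @export
write_weighted_bed <- function(rs, path) {
  gr <- rs$reads
  df <- data.frame(as.character(GenomeInfoDb::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   rs$sample$id, gr$weight,
                   as.character(GenomicRanges::strand(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
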