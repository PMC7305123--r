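#' Tile weighted read counts into fixed-width windows
#'
#' Assigns each fragment to the window containing its midpoint and sums
#' weights, per chromosome.
#'
#' @param rs A \code{read_set}.
#' @param w Window width in bases (default 100).
#' @param chrom_len Named vector of chromosome lengths; defaults to the
#'   largest read end per chromosome.
#' @return Object of class \code{window_grid}: list with \code{w} and
#'   \code{counts}, a named list of per-chromosome numeric vectors (window
#'   i covers bases \code{[(i-1)*w + 1, i*w]}).
#' @export
count_windows <- function(rs, w = 100, chrom_len = NULL) {
  stopifnot(w >= 1)
  gr <- rs$reads
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  mids <- floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
  if (is.null(chrom_len)) {
    chrom_len <- tapply(GenomicRanges::end(gr), chrom, max)
  }
  counts <- lapply(names(chrom_len), function(ch) {
    nwin <- max(1L, ceiling(chrom_len[[ch]] / w))
    v <- numeric(nwin)
    sel <- chrom == ch
    if (any(sel)) {
      idx <- pmin(pmax(floor((mids[sel] - 1) / w) + 1L, 1L), nwin)
      acc <- rowsum(gr$weight[sel], idx)
      v[as.integer(rownames(acc))] <- acc[, 1]
    }
    v
  })
  names(counts) <- names(chrom_len)
  structure(list(w = w, counts = counts,
                 total_weight = sum(gr$weight)), class = "window_grid")
}

#' Poisson background rate per window
#'
#' \code{lambda = total weighted reads * w / effective genome length}.
#'
#' @param grid A \code{window_grid}.
#' @param effective_length Effective genome length in bases; defaults to the
#'   total tiled length of the grid.
#' @return Expected weighted count per window.
#' @export
window_lambda <- function(grid, effective_length = NULL) {
  if (is.null(effective_length))
    effective_length <- sum(vapply(grid$counts, length, 0L)) * grid$w
  grid$total_weight * grid$w / effective_length
}

# upper-tail Poisson probability P(X >= count); weighted counts rounded up
pois_tail <- function(count, lambda)
  stats::ppois(ceiling(count) - 1, lambda, lower.tail = FALSE)

#' Windows enriched over the Poisson background
#'
#' A window is eligible when its count is improbably high under the
#' background: \code{P(X >= count | Poisson(lambda)) <= p0}.
#'
#' @param grid A \code{window_grid}.
#' @param lambda Background rate (see \code{\link{window_lambda}}).
#' @param p0 Eligibility tail probability (default 0.05).
#' @return Named list of logical masks, one per chromosome.
#' @export
eligible_windows <- function(grid, lambda, p0 = 0.05) {
  stopifnot(lambda > 0)
  lapply(grid$counts, function(v) pois_tail(v, lambda) <= p0)
}

#' Merge eligible windows into gap-tolerant islands
#'
#' Maximal runs of eligible windows in which consecutive eligible windows
#' are separated by at most \code{g} bases of ineligible ground (the SICER
#' gap rule; \code{g} is rounded down to whole windows).  The island spans
#' the first to the last member window.
#'
#' @param mask Eligibility masks from \code{\link{eligible_windows}}.
#' @param grid The \code{window_grid}.
#' @param g Maximum gap in bases (default 600).
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (1-based
#'   closed), \code{first_win}, \code{last_win} (window indices).
#' @export
build_islands <- function(mask, grid, g = 600) {
  w <- grid$w
  gap_win <- floor(g / w)
  out <- lapply(names(mask), function(ch) {
    idx <- which(mask[[ch]])
    if (length(idx) == 0) return(NULL)
    # new island when the run of ineligible windows exceeds gap_win
    brk <- c(TRUE, diff(idx) - 1 > gap_win)
    isl <- cumsum(brk)
    first <- tapply(idx, isl, min)
    last <- tapply(idx, isl, max)
    data.frame(chrom = ch, start = (first - 1) * w + 1, end = last * w,
               first_win = as.integer(first), last_win = as.integer(last),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), first_win = integer(),
                      last_win = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# aggregate score of one island: sum of -ln Poisson tails of its eligible
# member windows
island_score <- function(counts, eligible, lambda)
  sum(-log(pmax(pois_tail(counts[eligible], lambda), .Machine$double.xmin)))

#' Score islands against the Poisson background
#'
#' Aggregate island score = sum over eligible member windows of
#' \code{-ln P(X >= count | Poisson(lambda))}; island p-value approximated
#' by the product of the member tails (\code{exp(-score)}), BH-adjusted
#' across islands.
#'
#' @param islands data.frame from \code{\link{build_islands}}.
#' @param grid The \code{window_grid}.
#' @param lambda Background rate.
#' @param mask Eligibility masks (recomputed from \code{p0} if omitted).
#' @param p0 Eligibility threshold used when recomputing the mask.
#' @return The islands data.frame with \code{score}, \code{p_value},
#'   \code{q_value} columns.
#' @export
score_islands <- function(islands, grid, lambda, mask = NULL, p0 = 0.05) {
  if (is.null(mask)) mask <- eligible_windows(grid, lambda, p0)
  sc <- vapply(seq_len(nrow(islands)), function(i) {
    ch <- islands$chrom[i]
    win <- islands$first_win[i]:islands$last_win[i]
    island_score(grid$counts[[ch]][win], mask[[ch]][win], lambda)
  }, 0)
  islands$score <- sc
  islands$p_value <- exp(-sc)
  islands$q_value <- adjust_fdr(islands$p_value)
  islands
}

#' Subtract scaled input-chromatin counts from island windows
#'
#' Rescores islands after replacing every member-window count with
#' \code{max(0, count - input_count * depth_ratio)}, where the input is
#' scaled to the ChIP library by total weight.
#'
#' @param islands Scored islands.
#' @param grid ChIP \code{window_grid}.
#' @param input_grid Input-control \code{window_grid} on the same tiling
#'   (or NULL: islands pass through with a warning).
#' @param lambda Background rate of the ChIP grid.
#' @param mask Eligibility masks of the ChIP grid.
#' @param p0 Eligibility threshold used when recomputing the mask.
#' @return Islands with an \code{input_subtracted_score} column.
#' @export
subtract_input <- function(islands, grid, input_grid, lambda,
                           mask = NULL, p0 = 0.05) {
  if (is.null(input_grid)) {
    warning("no input control: input_subtracted_score = score")
    islands$input_subtracted_score <- islands$score
    return(islands)
  }
  stopifnot(input_grid$w == grid$w)
  if (is.null(mask)) mask <- eligible_windows(grid, lambda, p0)
  ratio <- grid$total_weight / input_grid$total_weight
  islands$input_subtracted_score <-
    vapply(seq_len(nrow(islands)), function(i) {
      ch <- islands$chrom[i]
      win <- islands$first_win[i]:islands$last_win[i]
      inp_full <- input_grid$counts[[ch]]
      inp <- numeric(length(win))
      valid <- win <= length(inp_full)
      inp[valid] <- inp_full[win[valid]]
      adj <- pmax(grid$counts[[ch]][win] - inp * ratio, 0)
      island_score(adj, mask[[ch]][win], lambda)
    }, 0)
  islands
}

#' Call significant binding islands
#'
#' The full SICER-style pipeline: window counts, Poisson eligibility, gap
#' merging, aggregate scoring, optional input subtraction, and the joint
#' significance filter (p-value, absolute score, FDR).
#'
#' @param rs ChIP \code{read_set}.
#' @param input_rs Optional input-control \code{read_set}.
#' @param w Window width (default 100).
#' @param g Gap (default 600).
#' @param p0 Window eligibility threshold (default 0.05).
#' @param chrom_len Named chromosome lengths (also the effective genome
#'   length for the background rate).
#' @param max_p,min_score,max_q Island filters (defaults 0.05, 200, 0.05).
#' @param filter Apply the significance filter (default TRUE; FALSE returns
#'   all scored islands).
#' @return data.frame of islands (see \code{\link{score_islands}}), filtered
#'   to significant "binding islands" when \code{filter} is TRUE.
#' @export
call_islands <- function(rs, input_rs = NULL, w = 100, g = 600, p0 = 0.05,
                         chrom_len = NULL, max_p = 0.05, min_score = 200,
                         max_q = 0.05, filter = TRUE) {
  grid <- count_windows(rs, w, chrom_len)
  lambda <- window_lambda(grid)
  mask <- eligible_windows(grid, lambda, p0)
  isl <- build_islands(mask, grid, g)
  if (nrow(isl) == 0) {
    isl$score <- isl$p_value <- isl$q_value <-
      isl$input_subtracted_score <- numeric(0)
    return(isl)
  }
  isl <- score_islands(isl, grid, lambda, mask)
  isl <- if (!is.null(input_rs)) {
    igrid <- count_windows(input_rs, w, chrom_len)
    subtract_input(isl, grid, igrid, lambda, mask)
  } else {
    isl$input_subtracted_score <- isl$score
    isl
  }
  if (filter)
    isl <- isl[isl$p_value <= max_p & isl$score >= min_score &
               isl$q_value <= max_q, , drop = FALSE]
  rownames(isl) <- NULL
  isl
}

#' Map islands to genes
#'
#' Links each island to every gene whose body it overlaps (any shared
#' base); overlap with the TSS window is recorded separately and drives
#' "bound gene" calls.
#'
#' @param islands Islands data.frame.
#' @param genes A \code{gene_models} object.
#' @param up,down TSS window extent.
#' @return data.frame with one row per island-gene link: island index,
#'   \code{gene_id}, \code{overlaps_body}, \code{overlaps_tss}.
#' @export
islands_to_genes <- function(islands, genes, up = 700, down = 700) {
  if (nrow(islands) == 0)
    return(data.frame(island = integer(), gene_id = character(),
                      overlaps_body = logical(), overlaps_tss = logical(),
                      stringsAsFactors = FALSE))
  igr <- GenomicRanges::GRanges(islands$chrom,
                                IRanges::IRanges(islands$start, islands$end))
  link <- function(regions) {
    h <- GenomicRanges::findOverlaps(igr, regions, ignore.strand = TRUE)
    paste(S4Vectors::queryHits(h), regions$gene_id[S4Vectors::subjectHits(h)],
          sep = "\r")
  }
  body_keys <- link(gene_body_ranges(genes))
  tss_keys <- link(tss_window(genes, up, down))
  keys <- union(body_keys, tss_keys)
  if (length(keys) == 0)
    return(data.frame(island = integer(), gene_id = character(),
                      overlaps_body = logical(), overlaps_tss = logical(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(island = as.integer(vapply(parts, `[`, "", 1)),
                    gene_id = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  out$overlaps_body <- keys %in% body_keys
  out$overlaps_tss <- keys %in% tss_keys
  out <- out[order(out$island, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Genes bound by a ChIP factor, from island calls
#'
#' Operational definition of e.g. "TDRD3-bound" genes: genes whose TSS
#' window or body overlaps a significant island.
#'
#' @param islands Filtered islands.
#' @param genes A \code{gene_models} object.
#' @param where \code{"tss_or_body"} (default), \code{"tss"} or \code{"body"}.
#' @return Character vector of gene ids.
#' @export
bound_genes <- function(islands, genes, where = c("tss_or_body", "tss", "body")) {
  where <- match.arg(where)
  lk <- islands_to_genes(islands, genes)
  keep <- switch(where,
                 tss_or_body = lk$overlaps_tss | lk$overlaps_body,
                 tss = lk$overlaps_tss, body = lk$overlaps_body)
  sort(unique(lk$gene_id[keep]))
}

#' Write islands as BED6+ for browser inspection
#'
#' @param islands Scored islands.
#' @param path Output file (0-based half-open BED coordinates; extra
#'   columns: p, q, input-subtracted score).
#' @export
write_islands <- function(islands, path) {
  df <- data.frame(islands$chrom, islands$start - 1L, islands$end,
                   paste0("island_", seq_len(nrow(islands))),
                   round(islands$score, 3), ".",
                   signif(islands$p_value, 4), signif(islands$q_value, 4),
                   round(islands$input_subtracted_score, 3))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
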