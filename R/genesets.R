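#' Load a gene-set collection from a GMT file
#'
#' One set per line: name, description, then member genes (tab-separated).
#' Members are deduplicated; matching elsewhere is case-insensitive.
#'
#' @param path GMT file.
#' @param min_size,max_size Size bounds applied at load (defaults 10, Inf).
#' @param source Label for the collection (GO, MeSH-disease, custom).
#' @return Object of class \code{gene_set_collection}: list with
#'   \code{sets} (named list of character vectors) and \code{source}.
#' @export
load_gene_sets <- function(path, min_size = 10, max_size = Inf,
                           source = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3)
  if (length(bad) > 0)
    stop("malformed GMT line ", bad[1], ": fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  sz <- vapply(sets, length, 0L)
  sets <- sets[sz >= min_size & sz <= max_size]
  if (length(sets) == 0)
    stop("empty collection after size filtering (", min_size, "..",
         max_size, ")")
  structure(list(sets = sets, source = source,
                 min_size = min_size, max_size = max_size),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection [", x$source, "]: ", length(x$sets),
      " sets, sizes ", min(lengths(x$sets)), "..", max(lengths(x$sets)),
      "\n", sep = "")
  invisible(x)
}

#' Parametric gene-set enrichment (PAGE) on log2 ratios
#'
#' For each set, \code{Z = (Sm - mu) * sqrt(m) / delta} where \code{Sm} is
#' the mean log2 ratio of the set's scored members, and \code{mu},
#' \code{delta} are the mean and standard deviation over all scored genes.
#' Two-sided normal p, BH q across the collection, rows ordered by Z
#' ascending (most negative first).
#'
#' @param ratios Named numeric vector of per-gene log2 ratios (names are
#'   gene ids/symbols); non-finite entries are dropped from background and
#'   sets alike.
#' @param collection A \code{gene_set_collection} (or named list of sets).
#' @param min_size Minimum members after intersection with the scored genes
#'   (default 10).
#' @return data.frame with \code{term}, \code{m}, \code{Sm}, \code{Z},
#'   \code{p}, \code{q}.
#' @export
page_enrichment <- function(ratios, collection, min_size = 10) {
  sets <- if (inherits(collection, "gene_set_collection"))
    collection$sets else collection
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < max(min_size, 10))
    stop("too few scored genes for PAGE (", length(ratios), ")")
  key <- toupper(names(ratios))
  if (anyDuplicated(key)) {
    ratios <- ratios[!duplicated(key)]
    key <- key[!duplicated(key)]
  }
  mu <- mean(ratios)
  delta <- stats::sd(ratios)
  if (!is.finite(delta) || delta == 0)
    stop("degenerate input: zero variance of the gene-level ratios")
  rows <- lapply(names(sets), function(nm) {
    idx <- match(unique(toupper(sets[[nm]])), key)
    idx <- idx[!is.na(idx)]
    m <- length(idx)
    if (m < min_size) return(NULL)
    Sm <- mean(ratios[idx])
    data.frame(term = nm, m = m, Sm = Sm,
               Z = (Sm - mu) * sqrt(m) / delta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no set passes min_size after intersection")
  out$p <- 2 * stats::pnorm(-abs(out$Z))
  out$q <- adjust_fdr(out$p)
  out <- out[order(out$Z, out$term), ]
  rownames(out) <- NULL
  attr(out, "background") <- c(mu = mu, delta = delta,
                               n_genes = length(ratios))
  out
}

#' Top enriched terms by signed Z
#'
#' @param rows Result of \code{\link{page_enrichment}}.
#' @param direction \code{"negative"} or \code{"positive"}.
#' @param k Number of terms (default 10).
#' @return Up to \code{k} rows of the requested sign, ordered by |Z|
#'   descending, ties broken by term name; fewer rows with a warning when
#'   not enough qualify.
#' @export
rank_terms <- function(rows, direction = c("negative", "positive"), k = 10) {
  direction <- match.arg(direction)
  sel <- if (direction == "negative") rows$Z < 0 else rows$Z > 0
  out <- rows[sel, , drop = FALSE]
  out <- out[order(-abs(out$Z), out$term), , drop = FALSE]
  if (nrow(out) < k)
    warning("only ", nrow(out), " ", direction, " term(s) available (k = ",
            k, ")")
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Write enrichment rows as TSV
#'
#' @param rows PAGE result.
#' @param path Output file.
#' @export
write_enrichment <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
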