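# round half away from zero at the stated precision (base round() is
# half-even, which would turn 12.5 into 12)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Pearson correlation of two per-gene signals on the log scale
#'
#' @param x,y Named (or aligned) per-gene signal vectors.
#' @param pseudocount Added before \code{log2} (default 0.1).
#' @param transform Apply the log2 transform first (default TRUE).
#' @return Pearson r on the transformed values.
#' @export
correlate_signals <- function(x, y, pseudocount = 0.1, transform = TRUE) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  if (transform) {
    x <- log2(x + pseudocount)
    y <- log2(y + pseudocount)
  }
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need >= 3 genes with finite values")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x[ok], y[ok])
}

#' Hierarchical clustering of genes on row-wise Z-scores
#'
#' Rows (genes) are Z-scored, distances are 1 - Pearson correlation,
#' linkage is average.  Constant rows are excluded with a warning.
#'
#' @param mat Genes x assays numeric matrix (e.g. log2 normalized signals).
#' @param k Number of clusters to cut (default 2).
#' @return List with \code{hclust} (the tree), \code{labels} (named cluster
#'   assignment), \code{zscores} (the Z-scored matrix used),
#'   \code{excluded} (constant genes).
#' @export
cluster_genes <- function(mat, k = 2) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  rs <- apply(mat, 1, stats::sd)
  excluded <- rownames(mat)[rs == 0]
  if (length(excluded) > 0)
    warning("excluding ", length(excluded), " constant gene(s) from clustering")
  mat <- mat[rs > 0, , drop = FALSE]
  z <- t(scale(t(mat)))
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  list(hclust = hc, labels = labels, zscores = z, excluded = excluded)
}

#' Overlap between two gene categories
#'
#' @param a,b Character vectors (or lists with \code{members}) of gene ids
#'   over the same universe.
#' @return List with \code{n_a}, \code{n_b}, \code{n_intersect},
#'   \code{n_union}, and conditional percentages \code{pct_of_a} and
#'   \code{pct_of_b} (= 100 * |a&b| / |a| resp. |b|).
#' @export
venn_overlap <- function(a, b) {
  if (is.list(a) && !is.null(a$members)) a <- a$members
  if (is.list(b) && !is.null(b$members)) b <- b$members
  a <- unique(a); b <- unique(b)
  ab <- intersect(a, b)
  list(n_a = length(a), n_b = length(b), n_intersect = length(ab),
       n_union = length(union(a, b)),
       pct_of_a = if (length(a) > 0) 100 * length(ab) / length(a) else NA,
       pct_of_b = if (length(b) > 0) 100 * length(ab) / length(b) else NA)
}

#' Summarize a gene panel's response classes
#'
#' Counts panel members classified up / no_change / down in one comparison
#' of an \code{nadt_fit} (or from a supplied classification vector), with
#' percentages rounded half-up at the stated precision.
#'
#' @param panel Character vector of gene ids, or a list with \code{name}
#'   and \code{members}.
#' @param classes Named factor/character of per-gene classes (up /
#'   no_change / down), or an \code{nadt_fit}.
#' @param contrast When \code{classes} is an \code{nadt_fit}: which
#'   comparison (default \code{"WT_FC_effect"}).
#' @param digits Percentage precision: 0 for integer percent (default),
#'   1 for one decimal.
#' @param drop_unresolved Exclude panel members absent from the scored
#'   genes from the total (default TRUE; they are always reported).
#' @return Object of class \code{panel_summary}: list with \code{panel},
#'   \code{total}, \code{counts}, \code{percentages}, \code{unresolved}.
#' @export
panel_summary <- function(panel, classes, contrast = "WT_FC_effect",
                          digits = 0, drop_unresolved = TRUE) {
  name <- "panel"
  if (is.list(panel) && !is.null(panel$members)) {
    name <- panel$name
    panel <- panel$members
  }
  if (inherits(classes, "nadt_fit")) {
    cls <- stats::setNames(as.character(classes$contrasts[[contrast]]$class),
                           classes$gene_id)
  } else cls <- stats::setNames(as.character(classes), names(classes))
  panel <- unique(panel)
  found <- panel %in% names(cls)
  unresolved <- panel[!found]
  members <- panel[found]
  total <- if (drop_unresolved) length(members) else length(panel)
  counts <- vapply(c("up", "no_change", "down"),
                   function(l) sum(cls[members] == l, na.rm = TRUE), 0)
  pct <- round_half_up(100 * counts / total, digits)
  structure(list(panel = name, total = total, counts = counts,
                 percentages = pct, unresolved = unresolved,
                 digits = digits), class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  fmt <- paste0("%.", x$digits, "f")
  cat("Panel '", x$panel, "' (n = ", x$total, "):\n", sep = "")
  for (l in names(x$counts))
    cat(sprintf("  %-10s %4d (%s%%)\n", l, x$counts[[l]],
                sprintf(fmt, x$percentages[[l]])))
  if (length(x$unresolved) > 0)
    cat("  unresolved:", length(x$unresolved), "member(s)\n")
  invisible(x)
}

#' Context-discrimination index
#'
#' \code{DI = (freeze_A - freeze_B) / (freeze_A + freeze_B)}: the
#' difference in freezing time between the shock-paired context A and the
#' neutral context B over the total freezing time.  Always in [-1, 1];
#' +/-1 exactly when one of the durations is zero.
#'
#' @param freeze_A,freeze_B Freezing times in seconds (both >= 0, total
#'   > 0).
#' @return The discrimination index.
#' @export
discrimination_index <- function(freeze_A, freeze_B) {
  if (any(freeze_A < 0) || any(freeze_B < 0))
    stop("freezing times must be non-negative")
  tot <- freeze_A + freeze_B
  if (any(tot == 0)) stop("undefined index: total freezing time is zero")
  (freeze_A - freeze_B) / tot
}

#' Average fold induction of a gene panel
#'
#' Ratio of the geometric means of the panel's genes between two condition
#' cells (e.g. FC-treated over untreated WT), on normalized signals.
#'
#' @param panel Gene ids (or list with \code{members}).
#' @param sm A \code{signal_matrix} (typically baseline-normalized).
#' @param design A \code{study_design} (defaults to the matrix's samples).
#' @param cell_a,cell_b Condition cells as \code{c(genotype, treatment)}
#'   (defaults: WT FC over WT untreated).
#' @param pseudocount Added inside the geometric means (default 0.1).
#' @return Linear fold change of the panel's geometric mean signal.
#' @export
average_panel_induction <- function(panel, sm, design = NULL,
                                    cell_a = c("WT", "FC"),
                                    cell_b = c("WT", "untreated"),
                                    pseudocount = 0.1) {
  if (is.list(panel) && !is.null(panel$members)) panel <- panel$members
  vals <- if (inherits(sm, "signal_matrix")) sm$values else sm
  if (is.null(design)) design <- study_design(sm$samples)
  rows <- intersect(panel, rownames(vals))
  if (length(rows) == 0) stop("empty panel after resolving against genes")
  pick <- function(cell) design$genotype == cell[1] & design$treatment == cell[2]
  gm <- function(cols)
    exp(mean(log(vals[rows, cols, drop = FALSE] + pseudocount)))
  gm(pick(cell_a)) / gm(pick(cell_b))
}
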