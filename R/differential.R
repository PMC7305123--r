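#' Study design for the genotype-by-treatment factorial
#'
#' Validates and normalizes the sample sheet of the 2x2 design (genotype WT
#' vs KO, treatment untreated vs FC).  The reference study uses 4 untreated
#' and 5 fear-conditioned (FC) pairs per genotype; any replicate counts with
#' at least two samples in two or more cells are accepted.
#'
#' @param samples data.frame with columns \code{sample_id}, \code{genotype},
#'   \code{treatment} and optionally \code{batch}.
#' @return data.frame of class \code{study_design} with factor columns
#'   (genotype levels WT, KO; treatment levels untreated, FC).
#' @export
study_design <- function(samples) {
  stopifnot(all(c("sample_id", "genotype", "treatment") %in% names(samples)))
  d <- samples
  d$genotype <- factor(as.character(d$genotype), levels = c("WT", "KO"))
  d$treatment <- factor(as.character(d$treatment),
                        levels = c("untreated", "FC"))
  if (anyNA(d$genotype) || anyNA(d$treatment))
    stop("genotype must be WT/KO and treatment untreated/FC")
  if (is.null(d$batch)) d$batch <- NA
  class(d) <- c("study_design", "data.frame")
  d
}

#' Normalize signals to the untreated wild-type baseline
#'
#' Per gene (and per batch when batch ids are present), every sample's value
#' is divided by the geometric mean of the untreated-WT samples of the same
#' batch, after adding a pseudocount: \code{(v + eps) / geomean(v_base + eps)}.
#' The geometric mean of the normalized baseline cells is therefore exactly
#' 1 for every gene.  Output stays on the original (linear) scale.
#'
#' @param sm A \code{signal_matrix}, or a plain genes x samples matrix
#'   (then \code{design} is required).
#' @param design A \code{study_design} (defaults to the
#'   \code{signal_matrix}'s sample metadata).
#' @param pseudocount Added before the ratio (default 0.1 FPKM).
#' @return A \code{signal_matrix} (or matrix) of normalized values, with a
#'   \code{reference_policy} attribute recording the baseline rule.
#' @export
normalize_to_baseline <- function(sm, design = NULL, pseudocount = 0.1) {
  is_sm <- inherits(sm, "signal_matrix")
  vals <- if (is_sm) sm$values else sm
  if (is.null(design)) {
    if (!is_sm) stop("design required for a plain matrix")
    design <- study_design(sm$samples)
  }
  stopifnot(ncol(vals) == nrow(design))
  batches <- as.character(design$batch)
  if (all(is.na(batches))) batches <- rep("global", length(batches))
  out <- vals
  for (b in unique(batches)) {
    cols <- which(batches == b)
    base <- cols[design$genotype[cols] == "WT" &
                 design$treatment[cols] == "untreated"]
    if (length(base) == 0)
      stop("no untreated-WT baseline sample in batch '", b, "'")
    logbase <- rowMeans(log(vals[, base, drop = FALSE] + pseudocount))
    if (pseudocount == 0 && any(!is.finite(logbase))) {
      bad <- rownames(vals)[!is.finite(logbase)]
      warning("all-zero baseline with pseudocount 0; flagged genes set NA: ",
              paste(utils::head(bad, 5), collapse = ", "),
              if (length(bad) > 5) ", ...")
    }
    gm <- exp(logbase)
    out[, cols] <- (vals[, cols, drop = FALSE] + pseudocount) / gm
  }
  policy <- list(reference = "untreated-WT geometric mean",
                 pseudocount = pseudocount,
                 batchwise = !all(batches == "global"))
  if (is_sm) {
    sm$values <- out
    attr(sm, "reference_policy") <- policy
    sm
  } else {
    attr(out, "reference_policy") <- policy
    out
  }
}

#' Log transform with pseudocount
#'
#' \code{log2(value + eps)}; the scale on which the gene-wise ANOVA is fit.
#'
#' @param x Numeric vector/matrix of non-negative values, or a
#'   \code{signal_matrix}.
#' @param pseudocount Added before the log (default 0.1).
#' @return Transformed object of the same shape.
#' @export
log_transform <- function(x, pseudocount = 0.1) {
  if (inherits(x, "signal_matrix")) {
    x$values <- log2(x$values + pseudocount)
    return(x)
  }
  log2(x + pseudocount)
}

# projection matrix of a design matrix
proj_mat <- function(X) X %*% solve(crossprod(X), t(X))

# Vectorized 2x2 two-way ANOVA across genes.
# Y: samples x genes matrix of log-scale values.
anova_engine <- function(Y, genotype, treatment) {
  cell <- droplevels(interaction(genotype, treatment))
  lev <- levels(cell)
  ncell <- table(cell)
  n <- nrow(Y)
  df_res <- n - length(lev)
  rss <- function(X) {
    P <- proj_mat(X)
    pmax(colSums(Y^2) - colSums((P %*% Y) * Y), 0)
  }
  rss_full <- rss(stats::model.matrix(~ 0 + cell))
  two_levels <- nlevels(droplevels(genotype)) == 2 &&
                nlevels(droplevels(treatment)) == 2
  if (two_levels) {
    g <- droplevels(genotype); tr <- droplevels(treatment)
    rss_add <- rss(stats::model.matrix(~ g + tr))
    rss_g <- rss(stats::model.matrix(~ g))
    rss_t <- rss(stats::model.matrix(~ tr))
    # Type II sums of squares: each main effect adjusted for the other
    ss_geno <- pmax(rss_t - rss_add, 0)
    ss_treat <- pmax(rss_g - rss_add, 0)
    ss_int <- pmax(rss_add - rss_full, 0)
  } else {
    ss_geno <- ss_treat <- ss_int <- rep(NA_real_, ncol(Y))
  }
  mse <- rss_full / df_res
  Fp <- function(ss) {
    f <- ss / mse
    list(F = f, p = stats::pf(f, 1, df_res, lower.tail = FALSE))
  }
  means <- t(rowsum(Y, cell)[lev, , drop = FALSE] / as.numeric(ncell)[match(lev, names(ncell))])
  colnames(means) <- lev
  list(cell_means = means, cell_n = stats::setNames(as.numeric(ncell), names(ncell)),
       ss = cbind(genotype = ss_geno, treatment = ss_treat, interaction = ss_int),
       F = cbind(genotype = Fp(ss_geno)$F, treatment = Fp(ss_treat)$F,
                 interaction = Fp(ss_int)$F),
       p = cbind(genotype = Fp(ss_geno)$p, treatment = Fp(ss_treat)$p,
                 interaction = Fp(ss_int)$p),
       mse = mse, df_res = df_res)
}

#' Gene-wise two-way ANOVA on log-transformed signals
#'
#' Fits the genotype x treatment factorial to one gene (vector) or to every
#' gene of a matrix at once, with Type II sums of squares (appropriate for
#' the unbalanced 4 + 5 pair design), F tests against the pooled residual
#' mean square, and the residual MSE/df needed for pairwise contrasts.
#'
#' @param values Numeric vector of one gene's log-scale replicate values, or
#'   a genes x samples matrix.
#' @param design A \code{study_design} matching the samples.
#' @return List with \code{cell_means} (genes x cells, columns named
#'   \code{WT.untreated}, \code{KO.untreated}, \code{WT.FC}, \code{KO.FC}),
#'   \code{ss}, \code{F}, \code{p} (genes x \{genotype, treatment,
#'   interaction\}), \code{mse}, \code{df_res}, \code{cell_n}.
#' @export
fit_two_way_anova <- function(values, design) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1,
                                             dimnames = list("gene", NULL))
  stopifnot(ncol(values) == nrow(design))
  cellcnt <- table(interaction(design$genotype, design$treatment, drop = TRUE))
  if (sum(cellcnt >= 2) < 2)
    stop("need at least two cells with >= 2 replicates for ANOVA")
  if (nrow(design) - length(cellcnt) < 1)
    stop("zero residual degrees of freedom: p-values undefined")
  out <- anova_engine(t(values), design$genotype, design$treatment)
  rn <- rownames(values)
  rownames(out$cell_means) <- rn
  rownames(out$ss) <- rownames(out$F) <- rownames(out$p) <- rn
  names(out$mse) <- rn
  out
}

#' Pairwise comparison of cell means with the pooled MSE
#'
#' Fisher-LSD style contrast: \code{t = (mean_a - mean_b) /
#' sqrt(MSE * (1/n_a + 1/n_b))} on the ANOVA's residual degrees of freedom,
#' two-sided p.
#'
#' @param fit Result of \code{\link{fit_two_way_anova}}.
#' @param cell_a,cell_b Cell labels, e.g. \code{"WT.FC"}, \code{"WT.untreated"}.
#' @return List with \code{estimate} (mean_a - mean_b, i.e. the log2 ratio
#'   when the fit is on log2 scale), \code{t}, \code{df}, \code{p} (vectors
#'   over genes).
#' @export
pairwise_contrast <- function(fit, cell_a, cell_b) {
  stopifnot(cell_a %in% colnames(fit$cell_means),
            cell_b %in% colnames(fit$cell_means))
  na <- fit$cell_n[cell_a]; nb <- fit$cell_n[cell_b]
  if (na == 0 || nb == 0) stop("empty cell in contrast")
  est <- fit$cell_means[, cell_a] - fit$cell_means[, cell_b]
  se <- sqrt(fit$mse * (1 / na + 1 / nb))
  t <- est / se
  t[se == 0 & est == 0] <- 0
  p <- 2 * stats::pt(abs(t), fit$df_res, lower.tail = FALSE)
  list(estimate = est, t = t, df = fit$df_res, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment within one contrast family.
#'
#' @param p Vector of p-values in \code{[0, 1]} (NA allowed).
#' @return q-values, monotone in p.
#' @export
adjust_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Log2 ratio of two linear-scale means
#'
#' @param mean_a,mean_b Means on the linear scale.
#' @param pseudocount Added to both before the ratio (default 0).
#' @return \code{log2((mean_a + eps) / (mean_b + eps))}.
#' @export
log2_ratio <- function(mean_a, mean_b, pseudocount = 0)
  log2((mean_a + pseudocount) / (mean_b + pseudocount))

#' Classify a gene's response from fold change and significance
#'
#' \code{up} when the log2 ratio reaches \code{log2(fold_threshold)} with
#' \code{p < alpha}; \code{down} symmetric; otherwise \code{no_change}.
#'
#' @param log2_ratio Log2 fold change(s).
#' @param p Contrast p-value(s).
#' @param fold_threshold Linear fold threshold (default 1.5).
#' @param alpha Significance level (default 0.05).
#' @return Factor with levels up, no_change, down.
#' @export
classify_response <- function(log2_ratio, p, fold_threshold = 1.5,
                              alpha = 0.05) {
  lt <- log2(fold_threshold)
  cls <- rep("no_change", length(log2_ratio))
  sig <- !is.na(p) & p < alpha
  cls[sig & log2_ratio >= lt] <- "up"
  cls[sig & log2_ratio <= -lt] <- "down"
  cls[is.na(log2_ratio)] <- NA
  factor(cls, levels = c("up", "no_change", "down"))
}

# the four reported comparisons and their cells (a vs b)
.nadt_contrasts <- list(
  WT_FC_effect = c("WT.FC", "WT.untreated"),
  KO_FC_effect = c("KO.FC", "KO.untreated"),
  KO_vs_WT_untreated = c("KO.untreated", "WT.untreated"),
  KO_vs_WT_FC = c("KO.FC", "WT.FC"))

#' Fit the activity-dependent transcription differential model
#'
#' The package's central model: per gene, signals are normalized to the
#' untreated-WT baseline, log2-transformed, and fit with a genotype x
#' treatment two-way ANOVA (Type II SS).  The four pairwise comparisons of
#' cell means (FC effect within each genotype; KO vs WT within each
#' treatment) are tested Fisher-LSD style against the pooled residual MSE,
#' BH-adjusted across genes separately per comparison, and classified
#' up / no_change / down at a fold-change and significance threshold.
#'
#' @param x A \code{signal_matrix} (from \code{\link{build_signal_matrix}})
#'   or a genes x samples matrix of non-negative signals.
#' @param design A \code{study_design}; defaults to the signal matrix's
#'   sample metadata.
#' @param pseudocount Pseudocount for normalization/log (default 0.1).
#' @param fold_threshold,alpha Classification thresholds (1.5-fold, 0.05).
#' @param normalize Normalize to the untreated-WT baseline first (default
#'   TRUE; the fitted statistics are invariant to the global baseline, but
#'   reported means are on the normalized scale).
#' @return Object of class \code{nadt_fit}; see
#'   \code{\link{as.data.frame.nadt_fit}} for the per-gene table, and the
#'   \code{print}, \code{summary}, \code{coef} and \code{plot} methods.
#' @examples
#' sim <- simulate_study(sim_config(n_genes = 60, depth = 3e4), seed = 1)
#' sm <- build_signal_matrix(sim$samples, sim$genes, "tss")
#' fit <- nadt_fit(sm)
#' summary(fit)
#' head(coef(fit))
#' @export
nadt_fit <- function(x, design = NULL, pseudocount = 0.1,
                     fold_threshold = 1.5, alpha = 0.05, normalize = TRUE) {
  vals <- if (inherits(x, "signal_matrix")) x$values else as.matrix(x)
  if (is.null(design)) {
    if (!inherits(x, "signal_matrix"))
      stop("design required for a plain matrix")
    design <- study_design(x$samples)
  } else if (!inherits(design, "study_design")) design <- study_design(design)
  if (normalize)
    vals <- normalize_to_baseline(vals, design, pseudocount)
  logv <- log2(vals + if (normalize) 0 else pseudocount)
  # normalized values already carry the pseudocount inside the ratio
  av <- fit_two_way_anova(logv, design)
  contrasts <- lapply(.nadt_contrasts, function(cc)
    pairwise_contrast(av, cc[1], cc[2]))
  tabs <- lapply(names(contrasts), function(nm) {
    co <- contrasts[[nm]]
    q <- adjust_fdr(co$p)
    cls <- classify_response(co$estimate, co$p, fold_threshold, alpha)
    data.frame(log2_ratio = co$estimate, t = co$t, p = co$p, q = q,
               class = cls)
  })
  names(tabs) <- names(contrasts)
  structure(list(anova = av, contrasts = tabs, design = design,
                 params = list(pseudocount = pseudocount,
                               fold_threshold = fold_threshold,
                               alpha = alpha, normalized = normalize,
                               contrast_cells = .nadt_contrasts),
                 gene_id = rownames(logv)),
            class = "nadt_fit")
}

#' @export
print.nadt_fit <- function(x, ...) {
  cat("Gene-wise genotype x treatment ANOVA fit (nadt_fit)\n")
  cat("  genes: ", length(x$gene_id), ";  samples: ", nrow(x$design),
      " (residual df ", x$anova$df_res, ")\n", sep = "")
  cat("  thresholds: ", x$params$fold_threshold, "-fold, alpha ",
      x$params$alpha, "\n", sep = "")
  for (nm in names(x$contrasts)) {
    tb <- table(x$contrasts[[nm]]$class)
    cat(sprintf("  %-20s up %5d | no_change %5d | down %5d\n",
                nm, tb["up"], tb["no_change"], tb["down"]))
  }
  invisible(x)
}

#' @export
summary.nadt_fit <- function(object, ...) {
  cls <- vapply(object$contrasts,
                function(tb) table(tb$class)[c("up", "no_change", "down")],
                numeric(3))
  rownames(cls) <- c("up", "no_change", "down")
  out <- list(n_genes = length(object$gene_id),
              design = table(object$design$genotype,
                             object$design$treatment),
              class_counts = t(cls),
              params = object$params)
  class(out) <- "summary.nadt_fit"
  out
}

#' @export
print.summary.nadt_fit <- function(x, ...) {
  cat("nadt_fit summary:", x$n_genes, "genes\n\nDesign (samples per cell):\n")
  print(x$design)
  cat("\nResponse classes per comparison (", x$params$fold_threshold,
      "-fold, p < ", x$params$alpha, "):\n", sep = "")
  print(x$class_counts)
  invisible(x)
}

#' Log2 ratio estimates of the fitted comparisons
#'
#' @param object An \code{nadt_fit}.
#' @param ... Unused.
#' @return Genes x comparisons matrix of log2 ratios.
#' @export
coef.nadt_fit <- function(object, ...) {
  vapply(object$contrasts, function(tb) tb$log2_ratio,
         numeric(length(object$gene_id)))
}

#' Per-gene results table of an nadt_fit
#'
#' @param x An \code{nadt_fit}.
#' @param ... Unused.
#' @param row.names,optional Standard \code{as.data.frame} arguments (unused).
#' @return One row per gene: cell means (log2 scale), factor F and p, and
#'   per comparison the log2 ratio, p, q and class.
#' @export
as.data.frame.nadt_fit <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- data.frame(gene_id = x$gene_id, x$anova$cell_means,
                    F_genotype = x$anova$F[, "genotype"],
                    F_treatment = x$anova$F[, "treatment"],
                    F_interaction = x$anova$F[, "interaction"],
                    p_genotype = x$anova$p[, "genotype"],
                    p_treatment = x$anova$p[, "treatment"],
                    p_interaction = x$anova$p[, "interaction"],
                    mse = x$anova$mse, stringsAsFactors = FALSE)
  for (nm in names(x$contrasts)) {
    tb <- x$contrasts[[nm]]
    out[[paste0("log2_", nm)]] <- tb$log2_ratio
    out[[paste0("p_", nm)]] <- tb$p
    out[[paste0("q_", nm)]] <- tb$q
    out[[paste0("class_", nm)]] <- tb$class
  }
  rownames(out) <- NULL
  out
}

#' Write the per-gene differential table as TSV
#'
#' @param fit An \code{nadt_fit}.
#' @param path Output file.
#' @export
write_differential <- function(fit, path) {
  utils::write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Volcano plot of one comparison of an nadt_fit
#'
#' @param x An \code{nadt_fit}.
#' @param contrast Which comparison (default \code{"WT_FC_effect"}).
#' @param ... Passed to \code{plot}.
#' @export
plot.nadt_fit <- function(x, contrast = "WT_FC_effect", ...) {
  tb <- x$contrasts[[contrast]]
  if (is.null(tb)) stop("unknown contrast '", contrast, "'")
  col <- c(up = "firebrick", no_change = "grey60", down = "steelblue")
  graphics::plot(tb$log2_ratio, -log10(tb$p),
                 col = col[as.character(tb$class)], pch = 20,
                 xlab = "log2 ratio", ylab = "-log10 p",
                 main = paste("nadt_fit:", contrast), ...)
  graphics::abline(v = c(-1, 1) * log2(x$params$fold_threshold),
                   h = -log10(x$params$alpha), lty = 2, col = "grey40")
  invisible(x)
}
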