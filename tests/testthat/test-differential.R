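# baseline normalization, gene-wise two-way ANOVA, contrasts, FDR, classes

test_that("baseline normalization divides by the untreated-WT geometric mean", {
  d <- study_design(data.frame(
    sample_id = c("w1", "w2", "wf", "k1"),
    genotype = c("WT", "WT", "WT", "KO"),
    treatment = c("untreated", "untreated", "FC", "untreated")))
  m <- matrix(c(2, 8, 8, 4), 1, 4,
              dimnames = list("g", d$sample_id))
  nm <- normalize_to_baseline(m, d, pseudocount = 0)
  expect_equal(unname(nm[1, "wf"]), 2.0)          # 8 / geomean(2, 8) = 8/4
  expect_equal(unname(nm[1, "k1"]), 1.0)
  expect_equal(exp(mean(log(nm[1, c("w1", "w2")]))), 1)  # baseline geomean = 1
  # all-ones matrix is unchanged; single baseline sample divides by itself
  m1 <- matrix(1, 2, 4, dimnames = list(c("a", "b"), d$sample_id))
  expect_equal(unname(normalize_to_baseline(m1, d, 0)), unname(m1),
               ignore_attr = TRUE)
  d2 <- study_design(data.frame(sample_id = c("w1", "kf"),
                                genotype = c("WT", "KO"),
                                treatment = c("untreated", "FC")))
  m2 <- matrix(c(5, 10), 1, 2, dimnames = list("g", d2$sample_id))
  expect_equal(unname(normalize_to_baseline(m2, d2, 0)[1, ]), c(1, 2))
})

test_that("batch-wise normalization uses each batch's own baseline", {
  d <- study_design(data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    genotype = "WT", treatment = "untreated",
    batch = c("A", "A", "B", "B")))
  m <- matrix(c(2, 4, 10, 20), 1, 4, dimnames = list("g", d$sample_id))
  nm <- normalize_to_baseline(m, d, pseudocount = 0)
  expect_equal(unname(nm[1, ]), c(2, 4, 10, 20) /
                 rep(c(exp(mean(log(c(2, 4)))), exp(mean(log(c(10, 20))))), each = 2))
  d$batch <- c("A", "A", "C", "C"); d$genotype <- c("WT", "WT", "KO", "KO")
  expect_error(normalize_to_baseline(m, d, 0), "baseline")
})

test_that("log transform applies the pseudocount and preserves order", {
  expect_equal(log_transform(1, 0), 0)
  expect_equal(log_transform(3, 1), 2)
  set.seed(3)
  x <- rexp(50)
  expect_equal(order(log_transform(x)), order(x))
})

test_that("ANOVA F/p and LSD contrasts match the lm + car Type II oracle", {
  skip_if_not_installed("car")
  d <- toy_design(4, 5)   # unbalanced 4 + 5 pairs
  design <- study_design(d)
  set.seed(202)
  for (rep in 1:100) {
    y <- rnorm(nrow(d), mean = rnorm(1), sd = runif(1, 0.2, 2)) +
      2 * (d$genotype == "KO") * runif(1, -1, 1) +
      (d$treatment == "FC") * runif(1, -1, 1)
    fit <- fit_two_way_anova(y, design)
    ref <- stats::lm(y ~ genotype * treatment, data = design)
    tab <- car::Anova(ref, type = 2)
    expect_equal(unname(fit$F[1, ]), tab$`F value`[1:3], tolerance = 1e-8)
    expect_equal(unname(fit$p[1, ]), tab$`Pr(>F)`[1:3], tolerance = 1e-8)
    expect_equal(unname(fit$mse), tab$`Sum Sq`[4] / tab$Df[4],
                 tolerance = 1e-8)
    # LSD contrast vs direct arithmetic on the oracle's MSE
    co <- pairwise_contrast(fit, "WT.FC", "WT.untreated")
    ma <- mean(y[d$genotype == "WT" & d$treatment == "FC"])
    mb <- mean(y[d$genotype == "WT" & d$treatment == "untreated"])
    mse <- tab$`Sum Sq`[4] / tab$Df[4]
    t_ref <- (ma - mb) / sqrt(mse * (1 / 5 + 1 / 4))
    expect_equal(unname(co$t), t_ref, tolerance = 1e-8)
    expect_equal(unname(co$p), 2 * pt(abs(t_ref), tab$Df[4], lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("null and additive corner cases behave analytically", {
  design <- study_design(toy_design(3, 3))
  # equal cell means, pure noise: F small, p spread to 1
  set.seed(9)
  y0 <- rnorm(12, mean = 5, sd = 1)
  y0 <- y0 - ave(y0, interaction(design$genotype, design$treatment)) + 5
  fit0 <- fit_two_way_anova(y0, design)
  expect_true(all(fit0$F[1, ] < 1e-20))
  expect_true(all(fit0$p[1, ] > 1 - 1e-10))
  # additive effects without noise: interaction SS exactly 0
  ya <- 1 + 2 * (design$genotype == "KO") + 3 * (design$treatment == "FC")
  fita <- fit_two_way_anova(ya, design)
  expect_equal(unname(fita$ss[1, "interaction"]), 0, tolerance = 1e-20)
  # identical means in a contrast: t = 0, p = 1
  co <- pairwise_contrast(fit0, "KO.untreated", "WT.untreated")
  expect_equal(unname(co$t), 0, tolerance = 1e-10)
  expect_equal(unname(co$p), 1, tolerance = 1e-9)
})

test_that("hand-computed contrast: means 2 vs 0, MSE 1, n 4 and 5", {
  fit <- list(cell_means = matrix(c(2, 0), 1, 2,
                                  dimnames = list("g", c("WT.FC", "WT.untreated"))),
              cell_n = c(WT.FC = 4, WT.untreated = 5),
              mse = c(g = 1), df_res = 14)
  co <- pairwise_contrast(fit, "WT.FC", "WT.untreated")
  expect_equal(unname(co$t), 2 / sqrt(1 * (1 / 4 + 1 / 5)))
  expect_equal(unname(round(co$t, 3)), 2.981)
  expect_equal(unname(co$p), 2 * pt(2.981424, 14, lower.tail = FALSE),
               tolerance = 1e-5)
})

test_that("with only two cells the contrast reduces to the pooled t-test", {
  d <- study_design(data.frame(
    sample_id = paste0("s", 1:9),
    genotype = "WT",
    treatment = rep(c("untreated", "FC"), c(4, 5))))
  set.seed(33)
  y <- rnorm(9) + (d$treatment == "FC")
  fit <- fit_two_way_anova(y, d)
  co <- pairwise_contrast(fit, "WT.FC", "WT.untreated")
  ref <- t.test(y[d$treatment == "FC"], y[d$treatment == "untreated"],
                var.equal = TRUE)
  expect_equal(unname(co$p), ref$p.value, tolerance = 1e-10)
  expect_equal(unname(co$t), unname(ref$statistic), tolerance = 1e-10)
})

test_that("BH q-values follow the step-up rule and stay monotone", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(4)
  p <- sort(runif(100))
  q <- adjust_fdr(p)
  expect_true(all(diff(q) >= -1e-15))
  expect_true(all(q >= p))
})

test_that("response classes respect the 1.5-fold AND p < 0.05 boundary", {
  expect_equal(as.character(classify_response(log2(1.6), 0.01)), "up")
  expect_equal(as.character(classify_response(log2(1.4), 0.001)), "no_change")
  expect_equal(as.character(classify_response(-1.0, 0.20)), "no_change")
  expect_equal(as.character(classify_response(-log2(1.6), 0.01)), "down")
  # boundary: fold exactly 1.5 counts; p exactly alpha does not
  expect_equal(as.character(classify_response(log2(1.5), 0.049)), "up")
  expect_equal(as.character(classify_response(log2(1.5), 0.05)), "no_change")
})

test_that("log2 ratios are antisymmetric and honour the pseudocount", {
  expect_equal(log2_ratio(5, 5), 0)
  expect_equal(log2_ratio(3, 1), log2(3))
  expect_equal(log2_ratio(3, 1), -log2_ratio(1, 3))
  expect_equal(log2_ratio(0, 1, pseudocount = 1), -1)
})

test_that("classifications barely move under a perturbed pseudocount", {
  sim <- simulate_study(sim_config(n_genes = 150, depth = 4e4), seed = 8)
  sm <- build_signal_matrix(sim$samples, sim$genes, "tss",
                            chrom_len = sim$chrom_len)
  f1 <- nadt_fit(sm, pseudocount = 0.1)
  f2 <- nadt_fit(sm, pseudocount = 0.3)
  agree <- mean(as.character(f1$contrasts$WT_FC_effect$class) ==
                as.character(f2$contrasts$WT_FC_effect$class))
  expect_gte(agree, 0.95)
})

test_that("nadt_fit assembles contrasts, q-values and classes coherently", {
  sim <- simulate_study(sim_config(n_genes = 80, depth = 2e4), seed = 5)
  sm <- build_signal_matrix(sim$samples, sim$genes, "tss",
                            chrom_len = sim$chrom_len)
  fit <- nadt_fit(sm)
  expect_s3_class(fit, "nadt_fit")
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 80)
  expect_true(all(df$q_WT_FC_effect >= df$p_WT_FC_effect - 1e-12))
  cc <- coef(fit)
  expect_equal(dim(cc), c(80, 4))
  # classes recompute from the stored ratios/ps at the stored thresholds
  re <- classify_response(df$log2_WT_FC_effect, df$p_WT_FC_effect)
  expect_equal(as.character(re), as.character(df$class_WT_FC_effect))
  expect_output(print(fit), "WT_FC_effect")
  expect_output(print(summary(fit)), "Response classes")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  # statistics are invariant to the baseline normalization switch
  fit_raw <- nadt_fit(sm, normalize = FALSE)
  expect_equal(fit$contrasts$WT_FC_effect$p, fit_raw$contrasts$WT_FC_effect$p,
               tolerance = 1e-9)
})
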