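# correlations, clustering, overlaps, panel summaries, discrimination index

test_that("signal correlation works on the log scale with edge handling", {
  x <- stats::setNames(2^(1:10), paste0("g", 1:10))
  expect_equal(correlate_signals(x, x, pseudocount = 0), 1)
  y <- stats::setNames(2^(10:1), paste0("g", 1:10))
  expect_equal(correlate_signals(x, y, pseudocount = 0), -1)
  # 5-point hand check against the textbook formula
  a <- c(1, 2, 4, 8, 10); b <- c(2, 1, 5, 9, 8)
  names(a) <- names(b) <- paste0("g", 1:5)
  la <- log2(a + 0.1); lb <- log2(b + 0.1)
  manual <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  expect_equal(correlate_signals(a, b), manual, tolerance = 1e-12)
  # invariant to positive affine transforms after the log
  expect_equal(correlate_signals(3 * la + 2, lb, transform = FALSE),
               correlate_signals(la, lb, transform = FALSE), tolerance = 1e-12)
  expect_error(correlate_signals(a[1:2], b[1:2]), ">= 3")
  expect_error(correlate_signals(rep(1, 5), b, transform = FALSE),
               "zero variance")
})

test_that("clustering recovers duplicated blocks and planted structure", {
  set.seed(61)
  blockA <- matrix(rep(c(5, 5, 0, 0), each = 10), 10, 4) + rnorm(40, 0, 0.1)
  blockB <- matrix(rep(c(0, 0, 5, 5), each = 10), 10, 4) + rnorm(40, 0, 0.1)
  m <- rbind(blockA, blockB)
  rownames(m) <- paste0("g", 1:20)
  cl <- cluster_genes(m, k = 2)
  expect_equal(length(unique(cl$labels[1:10])), 1)
  expect_equal(length(unique(cl$labels[11:20])), 1)
  expect_true(cl$labels[1] != cl$labels[11])
  # constant rows excluded with a warning
  m2 <- rbind(m, gflat = rep(1, 4))
  expect_warning(cl2 <- cluster_genes(m2, k = 2), "constant")
  expect_equal(cl2$excluded, "gflat")
  # planted 3-cluster structure recovered at ARI >= 0.95
  skip_if_not_installed("mclust")
  centers <- matrix(rnorm(3 * 6, sd = 4), 3, 6)
  truth <- rep(1:3, each = 40)
  m3 <- centers[truth, ] + matrix(rnorm(120 * 6, sd = 0.5), 120, 6)
  rownames(m3) <- paste0("g", 1:120)
  cl3 <- cluster_genes(m3, k = 3)
  expect_gte(mclust::adjustedRandIndex(cl3$labels, truth), 0.95)
})

test_that("cluster labels permute consistently with the input genes", {
  set.seed(62)
  m <- matrix(rnorm(60), 15, 4, dimnames = list(paste0("g", 1:15), NULL))
  cl <- cluster_genes(m, k = 3)
  perm <- sample(15)
  clp <- cluster_genes(m[perm, ], k = 3)
  # same partition: co-membership matrices agree
  co <- function(l) outer(l, l, "==")
  expect_equal(unname(co(clp$labels)[order(perm), order(perm)]),
               unname(co(cl$labels)))
})

test_that("venn overlaps obey inclusion-exclusion and subset limits", {
  a <- paste0("g", 1:30); b <- paste0("g", 21:70)
  v <- venn_overlap(a, b)
  expect_equal(v$n_intersect, 10)
  expect_equal(v$n_union, v$n_a + v$n_b - v$n_intersect)
  expect_equal(venn_overlap(a, paste0("x", 1:5))$n_intersect, 0)
  sub <- venn_overlap(paste0("g", 1:10), a)
  expect_equal(sub$pct_of_a, 100)                  # a subset of b
  set.seed(63)
  for (i in 1:20) {
    aa <- sample(paste0("g", 1:100), sample(5:50, 1))
    bb <- sample(paste0("g", 1:100), sample(5:50, 1))
    vv <- venn_overlap(aa, bb)
    expect_equal(vv$n_intersect, sum(aa %in% bb))   # brute-force scan
    expect_equal(vv$n_union, vv$n_a + vv$n_b - vv$n_intersect)
  }
})

test_that("panel summaries reproduce printed-count percentages", {
  mk_classes <- function(total, up = 0, down = 0) {
    stats::setNames(rep(c("up", "down", "no_change"),
                        c(up, down, total - up - down)),
                    paste0("g", seq_len(total)))
  }
  # 28 of 45 up -> 62%; 21 of 45 -> 47% (integer, half-up)
  ner_tss <- panel_summary(paste0("g", 1:45), mk_classes(45, up = 28))
  expect_equal(unname(ner_tss$percentages["up"]), 62)
  ner_ex <- panel_summary(paste0("g", 1:45), mk_classes(45, up = 21))
  expect_equal(unname(ner_ex$percentages["up"]), 47)
  # SZDB: 60/279 -> 21.5%, 5/279 -> 1.8% (one decimal), 34/279 -> 12%
  szdb <- paste0("g", 1:279)
  expect_equal(unname(panel_summary(szdb, mk_classes(279, down = 60),
                                    digits = 1)$percentages["down"]), 21.5)
  expect_equal(unname(panel_summary(szdb, mk_classes(279, down = 5),
                                    digits = 1)$percentages["down"]), 1.8)
  expect_equal(unname(panel_summary(szdb, mk_classes(279, up = 34),
                                    digits = 0)$percentages["up"]), 12)
  # learning/memory: 31/169 -> 18.3%
  expect_equal(unname(panel_summary(paste0("g", 1:169),
                                    mk_classes(169, down = 31),
                                    digits = 1)$percentages["down"]), 18.3)
  # counts always sum to the resolved total; 0 up -> 0%
  s <- panel_summary(paste0("g", 1:45), mk_classes(45))
  expect_equal(sum(s$counts), s$total)
  expect_equal(unname(s$percentages["up"]), 0)
  # unresolved members are reported and excluded from the total
  s2 <- panel_summary(c(paste0("g", 1:10), "missing1"), mk_classes(10, up = 5))
  expect_equal(s2$total, 10)
  expect_equal(s2$unresolved, "missing1")
  expect_output(print(s2), "50%")
})

test_that("percentages recompute from counts at the stated precision", {
  expect_equal(nadtseq:::round_half_up(12.5), 13)  # half-up, not half-even
  expect_equal(nadtseq:::round_half_up(21.505376, 1), 21.5)
  expect_equal(nadtseq:::round_half_up(1.792, 1), 1.8)
  expect_equal(round(12.5), 12)                    # why base round won't do
})

test_that("discrimination index follows its defining ratio", {
  expect_equal(discrimination_index(30, 10), 0.5)
  expect_equal(discrimination_index(10, 10), 0)
  expect_equal(discrimination_index(10, 30), -0.5) # antisymmetry
  expect_equal(discrimination_index(20, 0), 1)
  set.seed(64)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  di <- discrimination_index(a, b)
  expect_true(all(di >= -1 & di <= 1))
  expect_equal(di, -discrimination_index(b, a))
  expect_error(discrimination_index(0, 0), "undefined")
  expect_error(discrimination_index(-1, 5), "non-negative")
})

test_that("panel induction is the ratio of condition geometric means", {
  d <- study_design(data.frame(
    sample_id = c("w1", "w2", "wf1", "wf2"),
    genotype = "WT", treatment = c("untreated", "untreated", "FC", "FC")))
  m <- matrix(c(1, 1, 2, 2,   4, 4, 8, 8,   1, 1, 1, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), d$sample_id))
  # uniformly 2-fold induced panel -> 2.0 (pseudocount 0)
  expect_equal(average_panel_induction(c("g1", "g2"), m, d, pseudocount = 0), 2)
  expect_equal(average_panel_induction("g3", m, d, pseudocount = 0), 1)
  # mixed panel: geometric mean of per-gene folds
  expect_equal(average_panel_induction(c("g1", "g3"), m, d, pseudocount = 0),
               sqrt(2), tolerance = 1e-12)
  expect_error(average_panel_induction("absent", m, d), "empty")
})
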