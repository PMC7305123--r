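# SICER-style island calling: windows, eligibility, merging, scoring

# grid with prescribed per-window counts on one toy chromosome
grid_from_counts <- function(counts, w = 100)
  structure(list(w = w, counts = list(chr1 = counts),
                 total_weight = sum(counts)), class = "window_grid")

test_that("reads land in the window holding their midpoint, weights conserved", {
  rs <- toy_read_set(c(1, 101, 120), c(300, 200, 181), n = c(1, 2, 2))
  # midpoints 150 (window 2), 150, 150
  grid <- count_windows(rs, w = 100, chrom_len = c(chr1 = 1000))
  expect_equal(length(grid$counts$chr1), 10)
  expect_equal(grid$counts$chr1[2], 1 + 0.5 + 0.5)
  expect_equal(sum(unlist(grid$counts)), sum(rs$reads$weight))
  # conservation on random reads
  set.seed(11)
  st <- sample(1:9000, 500, replace = TRUE)
  rs2 <- toy_read_set(st, st + 299, n = sample(1:3, 500, TRUE))
  g2 <- count_windows(rs2, 100, c(chr1 = 11000))
  expect_equal(sum(unlist(g2$counts)), sum(rs2$reads$weight))
})

test_that("window eligibility follows the Poisson tail threshold", {
  grid <- grid_from_counts(c(0, 1, 4, 10))
  # P(X >= 4 | lambda = 1) = 0.01899 <= 0.05 -> eligible
  expect_equal(1 - ppois(3, 1), 0.0190, tolerance = 1e-3)
  m <- eligible_windows(grid, lambda = 1, p0 = 0.05)$chr1
  expect_equal(m, c(FALSE, FALSE, TRUE, TRUE))
  # count 0 ineligible for any lambda > 0, p0 < 1
  expect_false(eligible_windows(grid_from_counts(0), 0.01, 0.5)$chr1)
  # raising p0 never removes eligible windows
  m2 <- eligible_windows(grid, lambda = 1, p0 = 0.2)$chr1
  expect_true(all(m2[m]))
})

test_that("the 600 bp gap rule merges and splits as stated", {
  w <- 100
  # eligible windows 1 and 7: gap 5 windows = 500 <= 600 -> one island
  mask <- list(chr1 = c(TRUE, rep(FALSE, 5), TRUE))
  grid <- grid_from_counts(c(10, rep(0, 5), 10))
  isl <- build_islands(mask, grid, g = 600)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 1); expect_equal(isl$end, 700)
  # gap 700 -> two islands
  mask2 <- list(chr1 = c(TRUE, rep(FALSE, 7), TRUE))
  isl2 <- build_islands(mask2, grid_from_counts(c(10, rep(0, 7), 10)), 600)
  expect_equal(nrow(isl2), 2)
  # single eligible window -> island of one window width
  isl3 <- build_islands(list(chr1 = c(FALSE, TRUE, FALSE)),
                        grid_from_counts(c(0, 9, 0)), 600)
  expect_equal(isl3$end - isl3$start + 1, 100)
})

test_that("island calls equal the exhaustive oracle on random masks", {
  set.seed(21)
  for (g in c(0, 200, 600)) {
    for (rep in 1:20) {
      mask <- runif(60) < 0.25
      grid <- grid_from_counts(ifelse(mask, 8, 0))
      isl <- build_islands(list(chr1 = mask), grid, g)
      orc <- oracle_islands(mask, 100, g)
      expect_equal(nrow(isl), nrow(orc))
      expect_equal(isl$first_win, orc[, 1])
      expect_equal(isl$last_win, orc[, 2])
    }
  }
})

test_that("island scores are additive tails and grow with enrichment", {
  lambda <- 1
  grid <- grid_from_counts(c(5, 0, 0, 0, 0, 0, 7))
  mask <- eligible_windows(grid, lambda)
  isl <- score_islands(build_islands(mask, grid, 600), grid, lambda, mask)
  expect_equal(nrow(isl), 1)
  manual <- -log(1 - ppois(4, 1)) - log(1 - ppois(6, 1))
  expect_equal(isl$score, manual, tolerance = 1e-12)
  expect_equal(isl$p_value, exp(-manual), tolerance = 1e-12)
  # doubling member counts strictly increases the score
  grid2 <- grid_from_counts(c(10, 0, 0, 0, 0, 0, 14))
  isl2 <- score_islands(build_islands(mask, grid2, 600), grid2, lambda, mask)
  expect_gt(isl2$score, isl$score)
  # a single window at expectation scores low
  g0 <- grid_from_counts(2)
  s0 <- score_islands(data.frame(chrom = "chr1", start = 1, end = 100,
                                 first_win = 1L, last_win = 1L),
                      g0, 2, list(chr1 = TRUE))
  expect_lt(s0$score, 1.2)
})

test_that("input subtraction scales by depth ratio and zeroes equal tracks", {
  lambda <- 1
  grid <- grid_from_counts(c(8, 8))
  mask <- list(chr1 = c(TRUE, TRUE))
  isl <- score_islands(build_islands(mask, grid, 600), grid, lambda, mask)
  # input identical to the ChIP -> everything subtracts to zero
  same <- subtract_input(isl, grid, grid, lambda, mask)
  expect_equal(same$input_subtracted_score, 0)
  # input library at half the ChIP depth (total 8 vs 16) is scaled x2:
  # island windows hold input 2 each -> counts 8 - 2*2 = 4 per window
  half <- grid_from_counts(c(2, 2, 4))
  sub <- subtract_input(isl, grid, half, lambda, mask)
  manual <- 2 * -log(1 - ppois(3, 1))
  expect_equal(sub$input_subtracted_score, manual, tolerance = 1e-12)
  # input with no signal in the island leaves the score unchanged
  zero <- grid_from_counts(c(0, 0, 16))
  expect_equal(subtract_input(isl, grid, zero, lambda, mask)$input_subtracted_score,
               isl$score)
  expect_warning(out <- subtract_input(isl, grid, NULL, lambda, mask),
                 "input")
  expect_equal(out$input_subtracted_score, isl$score)
})

test_that("islands map to overlapping gene bodies and TSS windows", {
  gm <- toy_genes(list(gA = cbind(2001, 4000), gB = cbind(4201, 6000)))
  isl <- data.frame(chrom = "chr1",
                    start = c(3901, 9001, 1500),
                    end = c(4400, 9400, 1600),
                    first_win = 1L, last_win = 1L)
  lk <- islands_to_genes(isl, gm)
  # island 1 spans the gA/gB junction -> linked to both bodies
  expect_setequal(lk$gene_id[lk$island == 1 & lk$overlaps_body],
                  c("gA", "gB"))
  # island 2 is in a gene desert -> unlinked
  expect_false(2 %in% lk$island)
  # island 3 only touches gA's promoter window (1301..2700)
  expect_true(all(lk$gene_id[lk$island == 3] == "gA"))
  expect_true(all(lk$overlaps_tss[lk$island == 3]))
  expect_false(any(lk$overlaps_body[lk$island == 3]))
  expect_setequal(bound_genes(isl, gm), c("gA", "gB"))
  expect_equal(bound_genes(isl[0, ], gm), character(0))
})

test_that("a planted enrichment block is called; homogeneous null is not", {
  set.seed(31)
  glen <- 2e6
  n <- 2e4                           # lambda = n*w/glen = 1
  st <- floor(runif(n, 1, glen - 300))
  rec <- toy_records(st, st + 299)
  null_isl <- call_islands(read_set(rec, "null"), chrom_len = c(chr1 = glen))
  expect_equal(nrow(null_isl), 0)
  plant <- c(8e5, 8e5 + 4999)
  stp <- floor(runif(400, plant[1], plant[2] - 299))   # ~8x over background
  rs <- read_set(rbind(rec, toy_records(stp, stp + 299)), "plant")
  isl <- call_islands(rs, chrom_len = c(chr1 = glen))
  expect_equal(nrow(isl), 1)
  cover <- (min(isl$end, plant[2]) - max(isl$start, plant[1]) + 1) / 5000
  expect_gte(cover, 0.9)
  expect_true(isl$score >= 200 && isl$q_value <= 0.05)
  out <- tempfile(fileext = ".bed")
  write_islands(isl, out)
  expect_equal(nrow(read.table(out, sep = "\t")), 1)
})
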