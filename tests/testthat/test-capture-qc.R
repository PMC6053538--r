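test_that("on-target fraction hits its closed-form extremes", {
  targets <- data.frame(target_id = "t1", scaffold = "s1",
                        start = 1000L, end = 1150L, stringsAsFactors = FALSE)
  inside <- data.frame(read_id = c("r1", "r2"), scaffold = "s1",
                       start = c(1000L, 1020L), end = c(1150L, 1100L),
                       read_length = c(150L, 80L), stringsAsFactors = FALSE)
  expect_equal(on_target_fraction(inside, targets)$reads_on_target, 1)
  expect_equal(on_target_fraction(inside, targets)$targets_captured, 1)
  outside <- transform(inside, start = c(5000L, 6000L), end = c(5150L, 6080L))
  expect_equal(on_target_fraction(outside, targets)$reads_on_target, 0)
  expect_error(on_target_fraction(inside, targets[0, ]), "empty")
})

test_that("containment mode is stricter than any-overlap", {
  targets <- data.frame(target_id = "t1", scaffold = "s1",
                        start = 1000L, end = 1150L, stringsAsFactors = FALSE)
  straddle <- data.frame(read_id = "r1", scaffold = "s1", start = 950L,
                         end = 1100L, read_length = 150L,
                         stringsAsFactors = FALSE)
  expect_equal(on_target_fraction(straddle, targets, "any")$reads_on_target, 1)
  expect_equal(on_target_fraction(straddle, targets, "contained")$reads_on_target, 0)
})

test_that("uniform reads land on target proportionally to coverage", {
  set.seed(71)
  # 10 targets of 1 kb on a 100 kb scaffold: 10% target coverage
  targets <- data.frame(target_id = sprintf("t%02d", 1:10), scaffold = "s1",
                        start = seq(0L, 90000L, by = 10000L),
                        stringsAsFactors = FALSE)
  targets$end <- targets$start + 1000L
  starts <- sample(0:99000, 5000, replace = TRUE)
  reads <- data.frame(read_id = sprintf("r%04d", 1:5000), scaffold = "s1",
                      start = starts, end = starts + 1L, read_length = 1L,
                      stringsAsFactors = FALSE)
  frac <- on_target_fraction(reads, targets)$reads_on_target
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 5000))
})

test_that("breadth and depth match closed forms and the pileup oracle", {
  targets <- data.frame(target_id = "t1", scaffold = "s1",
                        start = 100L, end = 200L, stringsAsFactors = FALSE)
  exact <- data.frame(read_id = "r1", scaffold = "s1", start = 100L,
                      end = 200L, read_length = 100L, stringsAsFactors = FALSE)
  bd <- breadth_and_depth(exact, targets)
  expect_equal(bd$per_target$breadth, 1)
  expect_equal(bd$per_target$mean_depth, 1)
  half <- transform(exact, start = 150L, end = 250L)
  expect_equal(breadth_and_depth(half, targets)$per_target$breadth, 0.5)

  set.seed(72)
  starts <- sample(0:900, 200, replace = TRUE)
  lens <- sample(20:80, 200, replace = TRUE)
  reads <- data.frame(read_id = sprintf("r%03d", 1:200), scaffold = "s1",
                      start = starts, end = starts + lens,
                      read_length = lens, stringsAsFactors = FALSE)
  tg <- data.frame(target_id = c("a", "b"), scaffold = "s1",
                   start = c(100L, 600L), end = c(300L, 950L),
                   stringsAsFactors = FALSE)
  bd2 <- breadth_and_depth(reads, tg)
  depth <- oracle_pileup(reads$start, reads$end, 1000L)
  for (k in 1:2) {
    span <- (tg$start[k] + 1):tg$end[k]
    expect_equal(bd2$per_target$breadth[k], mean(depth[span] > 0))
    expect_equal(bd2$per_target$mean_depth[k], mean(depth[span]))
  }
})

test_that("identical replicate call sets are fully concordant", {
  set.seed(73)
  g <- sample(c(-1L, 0L, 1L), 500, replace = TRUE)
  d <- rep(30L, 500)
  rep_same <- replicate_concordance(g, g, d, d)
  expect_equal(rep_same$common, sum(g == 0L))
  expect_equal(rep_same$different, 0L)
  expect_equal(rep_same$identical_fraction, 1)
  expect_equal(rep_same$all_site_similarity, 1)
})

test_that("concordance is symmetric and responds to depth loss", {
  set.seed(74)
  ped <- build_pedigree(1, 0, list())
  fr <- simulate_species_freqs(4000, 0, seed = 75)
  g <- drop_genotypes(ped, fr, seed = 76)
  full1 <- simulate_read_counts(g, 60, 5, 0.005, seed = 77)
  full2 <- simulate_read_counts(g, 60, 5, 0.005, seed = 78)
  half2 <- simulate_read_counts(g, 15, 5, 0.005, seed = 79)
  call1 <- call_genotypes(full1)[1, ]
  call2 <- call_genotypes(full2)[1, ]
  callh <- call_genotypes(half2)[1, ]
  cc_full <- replicate_concordance(call1, call2, full1$depth[1, ], full2$depth[1, ])
  cc_swap <- replicate_concordance(call2, call1, full2$depth[1, ], full1$depth[1, ])
  expect_equal(cc_full$common, cc_swap$common)
  expect_equal(cc_full$all_site_similarity, cc_swap$all_site_similarity)
  cc_half <- replicate_concordance(call1, callh, full1$depth[1, ], half2$depth[1, ])
  expect_lt(cc_half$common, cc_full$common)
  expect_gt(cc_half$identical_fraction, 0.99)
  expect_error(replicate_concordance(call1, call2[-1], full1$depth[1, ],
                                     full2$depth[1, ][-1]), "site universe")
})

test_that("cross-platform comparisons count sites times individuals", {
  set.seed(80)
  a <- matrix(sample(c(-1L, 0L, 1L), 250 * 25, replace = TRUE), 250, 25,
              dimnames = list(sprintf("i%03d", 1:250), sprintf("s%02d", 1:25)))
  b <- a
  res <- cross_platform_concordance(a, b)
  expect_equal(res$comparisons, 6250L)
  expect_equal(res$concordance, 1)
  # plant exactly 2% discordance
  flip <- sample(length(b), 125)
  b[flip] <- -a[flip]  # hom <-> hom, het stays het: force change where hom
  hom <- a[flip] != 0L
  b[flip][!hom] <- 1L
  expect_equal(cross_platform_concordance(a, b)$concordance, 0.98)
})

test_that("read-length regression matches closed-form least squares", {
  x <- c(140, 160, 175, 190)
  y <- c(0.18, 0.22, 0.27, 0.33)
  fit <- readlen_ontarget_regression(x, y)
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-12)
  # collinear points: perfect fit ("essentially perfect fit" note expected)
  col <- suppressWarnings(readlen_ontarget_regression(x, 0.001 * x + 0.02))
  expect_equal(col$adj_r_squared, 1)
  # independence: adjusted R^2 near zero
  set.seed(81)
  xr <- rnorm(1000, 170, 10)
  yr <- rnorm(1000, 0.25, 0.03)
  expect_lt(abs(readlen_ontarget_regression(xr, yr)$adj_r_squared), 0.02)
  expect_error(readlen_ontarget_regression(rep(170, 5), rnorm(5)), "variance")
})
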