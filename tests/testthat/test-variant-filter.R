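sct <- function(depth, alt) {
  structure(list(depth = depth, alt_reads = alt), class = "site_call_table")
}

test_that("genotype calling applies depth and allele-fraction rules", {
  depth <- matrix(c(9L, 20L, 20L, 20L, 10L, 10L), 1)
  alt <- matrix(c(5L, 10L, 5L, 6L, 3L, 2L), 1)
  g <- call_genotypes(sct(depth, alt))
  expect_identical(as.vector(g), c(
    NA_integer_,  # depth 9 < 10: missing
    0L,           # 10/20 = 50%: het
    -1L,          # 5/20 = 25% < 30%: ref hom
    0L,           # 6/20 = 30% exactly: inclusive het boundary
    0L,           # 3/10 = 30%
    -1L           # 2/10 = 20%
  ))
  expect_error(call_genotypes(sct(matrix(5L), matrix(6L))), "exceeds")
})

test_that("heterozygote detection rate at depth 10 equals the binomial mass", {
  # two-sided intra-individual 30% rule at depth exactly 10, no error:
  # P(3 <= Bin(10, 0.5) <= 7)
  set.seed(91)
  m <- 40000
  depth <- matrix(10L, 1, m)
  alt <- matrix(rbinom(m, 10, 0.5), 1, m)
  g <- call_genotypes(sct(depth, alt))
  expected <- sum(dbinom(3:7, 10, 0.5))
  expect_lt(abs(mean(g == 0L) - expected), 3 * sqrt(expected * (1 - expected) / m))
})

test_that("polymorphism requires an observed heterozygote", {
  g <- rbind(c(-1L, -1L, 0L, -1L),
             c(-1L, 1L, -1L, NA),
             c(-1L, 1L, -1L, -1L))
  expect_identical(unname(polymorphic_sites(g)), c(FALSE, FALSE, TRUE, FALSE))
})

test_that("sample and site filters match brute-force recounts", {
  set.seed(92)
  g <- matrix(sample(c(-1L, 0L, 1L), 100 * 1000, replace = TRUE), 100, 1000,
              dimnames = list(sprintf("i%03d", 1:100), sprintf("s%04d", 1:1000)))
  g[runif(length(g)) < 0.12] <- NA
  cfg <- filter_config()
  fs <- filter_samples(g, cfg)
  keep_oracle <- apply(g, 1, function(r) sum(is.na(r)) / length(r) <= 0.20)
  expect_identical(rownames(fs), names(keep_oracle)[keep_oracle])
  anchored <- rep(c(TRUE, FALSE), length.out = ncol(g))
  ft <- filter_sites(g, anchored, cfg)
  site_oracle <- apply(g, 2, function(cc) mean(!is.na(cc)) >= 0.95) & anchored
  expect_identical(colnames(ft), names(site_oracle)[site_oracle])
  # a fully scored site on an unanchored scaffold is still removed
  g2 <- matrix(c(-1L, 0L, 1L, 0L), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(colnames(filter_sites(g2, c(TRUE, FALSE), cfg)), "a")
})

test_that("FDR adjustment follows the step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.123), 0.123)
  p <- c(0.2, 0.001, 0.04, 0.9, 0.015)
  shuffled <- sample(seq_along(p))
  expect_equal(fdr_adjust(p)[shuffled], fdr_adjust(p[shuffled]))
})

test_that("maf tiers use a strict threshold on the minor allele", {
  # 98 ref hom + 2 het of 100: maf exactly 0.01 fails the 0.01 tier
  g <- matrix(rep(c(-1L, 0L), c(98, 2)), ncol = 1)
  expect_false(maf_tier(g, 0.01))
  expect_true(maf_tier(g, 0.009))
  mono <- matrix(rep(1L, 50), ncol = 1)
  expect_false(any(vapply(c(0.01, 0.05, 0.4), function(t)
    maf_tier(mono, t), TRUE)))
  # recount oracle on a random fixture
  set.seed(93)
  gr <- matrix(sample(c(-1L, 0L, 1L, NA), 5000, replace = TRUE,
                      prob = c(0.6, 0.2, 0.1, 0.1)), 50, 100)
  oracle <- apply(gr, 2, function(cc) {
    cc <- cc[!is.na(cc)]
    p <- mean((cc + 1) / 2)
    min(p, 1 - p) > 0.05
  })
  expect_identical(unname(maf_tier(gr, 0.05)), unname(oracle))
})

test_that("LD pruning drops duplicated and correlated later markers", {
  set.seed(94)
  base <- sample(c(-1L, 0L, 1L), 80, replace = TRUE)
  g <- cbind(base, base, sample(c(-1L, 0L, 1L), 80, replace = TRUE))
  keep <- ld_prune(g, positions = c(100, 200, 300))
  expect_identical(unname(keep), c(TRUE, FALSE, TRUE))
})

test_that("independent markers survive r2 pruning almost entirely", {
  set.seed(95)
  g <- matrix(sample(c(-1L, 0L, 1L), 500 * 200, replace = TRUE), 500, 200)
  keep <- ld_prune(g, positions = seq_len(200) * 10)
  expect_gte(mean(keep), 0.95)
})

test_that("spacing pruning is greedy left to right", {
  g <- matrix(0L, 2, 4)
  keep <- ld_prune(g, positions = c(0, 500, 1000, 2600), mode = "spacing")
  expect_identical(unname(keep), c(TRUE, FALSE, TRUE, TRUE))
  expect_error(ld_prune(g, positions = c(5, 1, 9, 2)), "unsorted")
})

test_that("the cascade only removes and never edits calls", {
  set.seed(96)
  ped <- build_pedigree(30, 0, list())
  fr <- simulate_species_freqs(400, 0, seed = 97)
  geno <- drop_genotypes(ped, fr, seed = 98)
  rc <- simulate_read_counts(geno, 40, 5, 0.005, seed = 99)
  casc <- filter_cascade(rc, anchored = rep(TRUE, 400),
                         positions = seq_len(400) * 500,
                         scaffold = rep("s1", 400))
  called <- call_genotypes(rc)
  kept_sites <- colnames(casc$genotypes)
  kept_ids <- rownames(casc$genotypes)
  expect_identical(casc$genotypes, called[kept_ids, kept_sites])
  expect_length(casc$hwe_mask, ncol(casc$genotypes))
  expect_length(casc$maf_mask, ncol(casc$genotypes))
})
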