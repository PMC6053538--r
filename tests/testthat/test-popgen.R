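test_that("undifferentiated groups give near-zero Fst", {
  # both groups carry identical genotype counts (6 / 8 / 6 per locus)
  col <- rep(c(-1L, 0L, 1L), c(6, 8, 6))
  g <- rbind(cbind(col, col, col), cbind(col, col, col))
  fst <- per_locus_fst(g, rep(c("A", "B"), each = 20))
  expect_true(all(abs(fst$per_locus$fst) < 0.06))
})

test_that("a fixed difference gives Fst of exactly one", {
  g <- rbind(matrix(-1L, 20, 5), matrix(1L, 20, 5))
  fst <- per_locus_fst(g, rep(c("A", "B"), each = 20))
  expect_equal(fst$per_locus$fst, rep(1, 5))
  expect_equal(fst$pooled, 1)
})

test_that("variance components match a step-by-step scalar computation", {
  # group A: 6 ref hom, 8 het, 6 alt hom; group B: 12 ref hom, 5 het, 3 alt
  gA <- rep(c(-1L, 0L, 1L), c(6, 8, 6))
  gB <- rep(c(-1L, 0L, 1L), c(12, 5, 3))
  g <- matrix(c(gA, gB), ncol = 1)
  res <- per_locus_fst(g, rep(c("A", "B"), each = 20))
  # scalar oracle following the variance-component definitions directly
  n1 <- 20; n2 <- 20
  p1 <- (2 * 6 + 8) / 40; p2 <- (2 * 3 + 5) / 40
  h1 <- 8 / 20; h2 <- 5 / 20
  nbar <- 20; r <- 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  expect_equal(res$per_locus$fst, a / (a + b + cc), tolerance = 1e-12)
})

test_that("Fst is invariant to allele-label swap and bounded by one", {
  set.seed(131)
  fr <- simulate_species_freqs(500, 0.15, seed = 132)
  gA <- matrix(rbinom(30 * 500, 2, rep(fr$p_A, each = 30)) - 1L, 30)
  gB <- matrix(rbinom(30 * 500, 2, rep(fr$p_B, each = 30)) - 1L, 30)
  g <- rbind(gA, gB)
  lab <- rep(c("A", "B"), each = 30)
  f1 <- per_locus_fst(g, lab)
  f2 <- per_locus_fst(-g, lab)
  expect_equal(f1$per_locus$fst, f2$per_locus$fst)
  expect_true(all(f1$per_locus$fst <= 1 + 1e-12, na.rm = TRUE))
  expect_error(per_locus_fst(rbind(gA, matrix(NA, 30, 500)), lab),
               "no non-missing")
})

test_that("admixture EM separates two populations at moderate divergence", {
  set.seed(133)
  fr <- simulate_species_freqs(2000, 0.10, seed = 134)
  n <- 100
  gA <- matrix(rbinom(n * fr$m, 2, rep(fr$p_A, each = n)) - 1L, n)
  gB <- matrix(rbinom(n * fr$m, 2, rep(fr$p_B, each = n)) - 1L, n)
  g <- rbind(gA, gB)
  em <- admixture_em(g, seed = 135)
  expect_true(all(diff(em$loglik_trace) > -1e-6 * abs(em$loglik_trace[1])))
  sp <- assign_species(em$q)
  truth <- rep(c("A", "B"), each = n)
  correct <- max(mean(sp == truth), mean(chartr("AB", "BA", sp) == truth))
  expect_gte(correct, 0.95)
})

test_that("perfectly diagnostic loci drive q to the boundaries", {
  g <- rbind(matrix(-1L, 15, 80), matrix(1L, 15, 80))
  em <- admixture_em(g, seed = 136)
  expect_true(all(em$q > 0.99 | em$q < 0.01))
  expect_false(em$flat_likelihood)
})

test_that("identical cluster frequencies are flagged as unidentifiable", {
  set.seed(137)
  g <- matrix(sample(c(-1L, 0L, 1L), 40 * 100, replace = TRUE), 40, 100)
  em <- suppressWarnings(admixture_em(g, seed = 138, init = "random",
                                      max_iter = 50))
  # no real structure: likelihood gain from start is comparatively tiny
  gain <- diff(range(em$loglik_trace))
  expect_lt(gain / abs(em$loglik_trace[1]), 0.05)
})

test_that("species assignment is a pure threshold function", {
  q <- seq(0, 1, by = 0.01)
  lab <- assign_species(q)
  expect_true(all(lab[q >= 0.9] == "A"))
  expect_true(all(lab[q <= 0.1] == "B"))
  expect_true(all(lab[q > 0.1 & q < 0.9] == "admixed"))
  expect_identical(assign_species(c(0.95, 0.5, 0.1)),
                   c("A", "admixed", "B"))
  expect_error(assign_species(1.2))
})
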