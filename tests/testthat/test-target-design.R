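make_gene <- function(scaffold, gene_id, start, end, exon_bounds) {
  list(
    gene = data.frame(gene_id = gene_id, scaffold = scaffold,
                      start = start, end = end, strand = "+",
                      stringsAsFactors = FALSE),
    exons = data.frame(gene_id = gene_id, scaffold = scaffold,
                       start = vapply(exon_bounds, `[`, 0, 1),
                       end = vapply(exon_bounds, `[`, 0, 2),
                       stringsAsFactors = FALSE)
  )
}

test_that("short genes yield a single exonic target", {
  set.seed(51)
  g <- make_gene("s1", "g1", 1000L, 2200L,
                 list(c(1000L, 1400L), c(1800L, 2200L)))
  gn <- manual_genome(c(s1 = random_dna(5000)), g$gene, g$exons)
  tg <- select_genic_targets(gn)
  expect_equal(nrow(tg), 1L)
  expect_equal(tg$category, "exon")
  expect_equal(tg$end - tg$start, 150L)
  # fully inside one exon
  expect_true(tg$start >= 1000 && tg$end <= 1400 ||
              tg$start >= 1800 && tg$end <= 2200)
})

test_that("long genes yield exon and junction targets in extreme thirds", {
  set.seed(52)
  g <- make_gene("s1", "g1", 1000L, 7000L,
                 list(c(1000L, 1600L), c(3500L, 4200L), c(6400L, 7000L)))
  gn <- manual_genome(c(s1 = random_dna(8000)), g$gene, g$exons)
  tg <- select_genic_targets(gn)
  expect_equal(nrow(tg), 2L)
  expect_setequal(tg$category, c("exon", "intron_exon"))
  ex <- tg[tg$category == "exon", ]
  jn <- tg[tg$category == "intron_exon", ]
  # extreme thirds of the 6 kb gene: [1000, 3000) and [5000, 7000)
  expect_true(ex$start >= 1000 && ex$end <= 3000)
  expect_true(jn$start >= 5000 && jn$end <= 7000)
  # the junction target spans the 6400 intron-exon boundary
  expect_true(jn$start < 6400 && jn$end > 6400)
})

test_that("single-exon long genes fall back to two exonic targets", {
  set.seed(53)
  g <- make_gene("s1", "g1", 500L, 2500L, list(c(500L, 2500L)))
  gn <- manual_genome(c(s1 = random_dna(4000)), g$gene, g$exons)
  tg <- select_genic_targets(gn)
  expect_equal(nrow(tg), 2L)
  expect_equal(tg$category, c("exon", "exon"))
  expect_equal(attr(tg, "fallback"), "g1")
  # one per extreme third
  expect_true(any(tg$end <= 500 + 667 + 150))
  expect_true(any(tg$start >= 2500 - 667 - 1))
})

test_that("an empty gene set yields an empty target set", {
  gn <- manual_genome(c(s1 = random_dna(1000)))
  tg <- select_genic_targets(gn)
  expect_equal(nrow(tg), 0L)
})

test_that("intergenic windows each contribute at most one target", {
  set.seed(54)
  gn <- manual_genome(c(s1 = random_dna(300000)))
  tg <- select_intergenic_targets(gn, select_genic_targets(gn))
  expect_equal(nrow(tg), 3L)
  expect_equal(tg$start, c(0L, 100000L, 200000L))
  expect_equal(tg$category, rep("intergenic", 3))
})

test_that("windows with a prior target are skipped", {
  set.seed(55)
  gn <- manual_genome(c(s1 = random_dna(200000)))
  existing <- data.frame(target_id = "tg00001", scaffold = "s1",
                         start = 50000L, end = 50150L, category = "exon",
                         gene_id = "g1", stringsAsFactors = FALSE)
  tg <- select_intergenic_targets(gn, existing)
  expect_equal(tg$start, 100000L)
})

test_that("TE-colliding candidates shift downstream in 150 bp steps", {
  set.seed(56)
  te <- data.frame(scaffold = "s1", start = 0L, end = 200L)
  gn <- manual_genome(c(s1 = random_dna(100000)), te = te)
  tg <- select_intergenic_targets(gn, select_genic_targets(gn))
  expect_equal(tg$start, 300L)  # 0 and 150 both collide with the TE
  expect_equal(tg$start %% 150L, 0L)
  expect_false(any(tg$start < 200 & tg$end > 0))  # clear of the TE
})

test_that("a TE-saturated window yields no target and is logged", {
  te <- data.frame(scaffold = "s1", start = 0L, end = 5000L)
  gn <- manual_genome(c(s1 = random_dna(5000)), te = te)
  tg <- select_intergenic_targets(gn, select_genic_targets(gn),
                                  window = 5000L)
  expect_equal(nrow(tg), 0L)
  expect_equal(attr(tg, "saturated")$window_start, 0L)
})

test_that("GC filtering keeps inclusive bounds and matches a recount", {
  at_seq <- paste(rep("AT", 75), collapse = "")
  gc45 <- paste(c(rep("G", 67), rep("A", 83)), collapse = "")
  gn <- manual_genome(c(s1 = paste0(at_seq, gc45)))
  tg <- data.frame(target_id = c("a", "b"), scaffold = "s1",
                   start = c(0L, 150L), end = c(150L, 300L),
                   category = "exon", gene_id = NA, stringsAsFactors = FALSE)
  kept <- filter_gc(tg, gn)
  expect_equal(kept$target_id, "b")
  expect_equal(kept$gc, 67 / 150)
  expect_equal(attr(kept, "removed")$gc, 0)

  # random targets against a string-counting oracle
  set.seed(57)
  gn2 <- manual_genome(c(s1 = random_dna(20000)))
  tg2 <- data.frame(target_id = sprintf("t%03d", 1:100), scaffold = "s1",
                    start = sample(0:19850, 100), category = "exon",
                    gene_id = NA, stringsAsFactors = FALSE)
  tg2$end <- tg2$start + 150L
  kept2 <- filter_gc(tg2, gn2)
  gc_oracle <- vapply(seq_len(nrow(tg2)), function(i) {
    s <- substr(as.character(gn2$sequences[[1]]), tg2$start[i] + 1, tg2$end[i])
    mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, 0)
  expect_setequal(kept2$target_id,
                  tg2$target_id[gc_oracle >= 0.30 & gc_oracle <= 0.60])
})

test_that("unique sequences survive the repeat filter with one hit", {
  set.seed(58)
  gn <- manual_genome(c(s1 = random_dna(100000)))
  tg <- data.frame(target_id = "t1", scaffold = "s1", start = 4000L,
                   end = 4150L, category = "exon", gene_id = NA,
                   stringsAsFactors = FALSE)
  out <- filter_repetitive(tg, gn)
  expect_equal(out$repeat_hits, 1L)
  expect_equal(nrow(out), 1L)
})

test_that("high-copy sequences are removed by the repeat filter", {
  set.seed(59)
  unit <- random_dna(150)
  spacers <- replicate(12, random_dna(300))
  gn <- manual_genome(c(s1 = paste0(paste0(spacers, unit, collapse = ""),
                                    random_dna(2000))))
  tg <- data.frame(target_id = "t1", scaffold = "s1", start = 300L,
                   end = 450L, category = "exon", gene_id = NA,
                   stringsAsFactors = FALSE)
  expect_equal(unname(as.character(target_seqs(tg, gn))), unit)
  out <- filter_repetitive(tg, gn)
  expect_equal(nrow(out), 0L)
  expect_gte(attr(out, "removed")$repeat_hits, 10L)
})

test_that("seeded match counting equals the exhaustive-scan oracle", {
  set.seed(60)
  unit <- random_dna(150)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(150, k)
    ch[at] <- vapply(ch[at], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(ch, collapse = "")
  }
  genome_seq <- paste0(
    random_dna(2000), unit,             # exact copy
    random_dna(500), mutate(unit, 8),   # 94.7% identity: counts
    random_dna(500), mutate(unit, 15),  # 90% identity: counts (boundary)
    random_dna(500), mutate(unit, 25),  # 83% identity: does not count
    random_dna(2000)
  )
  gn <- manual_genome(c(s1 = genome_seq))
  tg <- data.frame(target_id = "t1", scaffold = "s1", start = 2000L,
                   end = 2150L, category = "exon", gene_id = NA,
                   stringsAsFactors = FALSE)
  hits <- filter_repetitive(tg, gn, max_hits = 100)$repeat_hits
  expect_equal(hits, oracle_hits(unit, gn))
  expect_equal(hits, 3L)
})

test_that("probe tiling follows the length arithmetic", {
  tg <- data.frame(target_id = c("a", "b", "c"), scaffold = "s1",
                   start = c(0L, 1000L, 5000L),
                   end = c(150L, 1240L, 5100L),
                   category = c("exon", "intergenic", "exon"),
                   gene_id = NA, stringsAsFactors = FALSE)
  pr <- design_probes(tg)
  expect_equal(sum(pr$target_id == "a"), 1L)   # 150 bp: one probe
  expect_equal(sum(pr$target_id == "b"), 2L)   # 240 bp: two probes
  expect_equal(attr(pr, "unprobed"), "c")      # 100 bp: none
  expect_true(all(pr$end - pr$start == 120L))
  b <- pr[pr$target_id == "b", ]
  expect_lte(b$start[2] - b$end[1] + 120L, 120L)  # non-overlapping
  expect_true(all(b$start >= 1000L & b$end <= 1240L))
  expect_equal(nrow(design_probes(tg[0, ])), 0L)
})

test_that("probe accounting conserves totals and flags orphans", {
  tg <- data.frame(target_id = c("a", "b"), scaffold = "s1",
                   start = c(0L, 200L), end = c(150L, 350L),
                   category = c("exon", "intergenic"), gene_id = NA,
                   stringsAsFactors = FALSE)
  pr <- design_probes(tg)
  acc <- probe_accounting(pr, tg)
  expect_equal(acc$probes[acc$category == "total"],
               sum(acc$probes[acc$category %in%
                              c("intergenic", "exon", "intron", "intron_exon")]))
  orphan <- pr
  orphan$target_id[1] <- "ghost"
  expect_error(probe_accounting(orphan, tg), "orphan|absent")
  empty <- probe_accounting(pr[0, ], tg[0, ])
  expect_true(all(empty$probes == 0))
})

test_that("full design on a simulated genome obeys every rule", {
  gn <- simulate_genome(5e5, 30, 0.3, 2, seed = 61)
  d <- design_targets(gn, window = 50000L)
  tg <- d$targets
  # no TE overlap for intergenic targets, by interval intersection
  inter <- tg[tg$category == "intergenic", ]
  expect_false(any(standkin:::interval_overlaps_any(inter, gn$te)))
  # GC and repeat bounds hold on the kept set
  expect_true(all(tg$gc >= 0.30 & tg$gc <= 0.60))
  expect_true(all(tg$repeat_hits < 10))
  # probes contained in their parent target; categories partition probes
  pr <- d$probes
  pidx <- match(pr$target_id, tg$target_id)
  expect_false(anyNA(pidx))
  expect_true(all(pr$start >= tg$start[pidx] & pr$end <= tg$end[pidx]))
  expect_identical(pr$category, tg$category[pidx])
})
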