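#' Filtering configuration for SNP calling and marker selection
#'
#' Bundles the thresholds of the calling/filtering cascade: genotype calls
#' need depth >= `min_depth` and an intra-individual allele-read fraction
#' of at least `intra_maf` to score a heterozygote; individuals missing
#' more than `sample_missing_max` of sites are dropped; sites need a call
#' rate of at least `site_callrate_min` and an anchored scaffold; analysis
#' branches then apply a Hardy-Weinberg exact test at FDR-adjusted
#' `hwe_alpha`, LD pruning (`ld_r2_max` within `ld_window` markers, or
#' `min_spacing` bp), and a population minor-allele-frequency tier from
#' `maf_tiers`.
#'
#' @param min_depth Minimum read depth for a genotype call.
#' @param intra_maf Minimum within-individual allele-read fraction for a
#'   heterozygote call (inclusive boundary).
#' @param sample_missing_max Maximum tolerated per-individual missingness.
#' @param site_callrate_min Minimum per-site call rate.
#' @param maf_tiers Population maf thresholds available to analyses.
#' @param hwe_alpha Retention threshold on FDR-adjusted HWE p-values
#'   (markers with adjusted p > `hwe_alpha` are kept).
#' @param ld_r2_max Squared-correlation cutoff for LD pruning.
#' @param ld_window LD-pruning window size in markers.
#' @param min_spacing Minimum spacing (bp) for the spacing-pruned set.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10L, intra_maf = 0.30,
                          sample_missing_max = 0.20,
                          site_callrate_min = 0.95,
                          maf_tiers = c(0.01, 0.05, 0.10, 0.15, 0.30, 0.40),
                          hwe_alpha = 0.05, ld_r2_max = 0.40,
                          ld_window = 50L, min_spacing = 1000L) {
  stopifnot(min_depth >= 0, intra_maf >= 0, intra_maf <= 0.5,
            sample_missing_max >= 0, sample_missing_max <= 1,
            site_callrate_min >= 0, site_callrate_min <= 1,
            all(maf_tiers >= 0 & maf_tiers < 0.5),
            hwe_alpha > 0, hwe_alpha < 1,
            ld_r2_max > 0, ld_r2_max <= 1, ld_window >= 2, min_spacing >= 0)
  structure(list(
    min_depth = as.integer(min_depth), intra_maf = intra_maf,
    sample_missing_max = sample_missing_max,
    site_callrate_min = site_callrate_min, maf_tiers = maf_tiers,
    hwe_alpha = hwe_alpha, ld_r2_max = ld_r2_max,
    ld_window = as.integer(ld_window), min_spacing = as.integer(min_spacing)
  ), class = "filter_config")
}

#' Call genotypes from per-site read counts
#'
#' Applies the depth and intra-individual allele-fraction rules: sites with
#' depth below `min_depth` are missing; otherwise the alternate-allele read
#' fraction calls the genotype — below `intra_maf` a reference homozygote
#' (-1), above `1 - intra_maf` an alternate homozygote (+1), anything in
#' between (boundaries inclusive) a heterozygote (0).
#'
#' @param site_calls A `site_call_table` (matrices `depth`, `alt_reads`).
#' @param cfg A [filter_config()].
#' @return Genotype matrix coded `{-1, 0, 1, NA}`.
#' @export
call_genotypes <- function(site_calls, cfg = filter_config()) {
  depth <- site_calls$depth
  alt <- site_calls$alt_reads
  if (any(alt > depth)) stop("alt_reads exceeds depth")
  g <- matrix(NA_integer_, nrow(depth), ncol(depth),
              dimnames = dimnames(depth))
  ok <- depth >= cfg$min_depth
  frac <- alt / depth
  g[ok & frac < cfg$intra_maf] <- -1L
  g[ok & frac > 1 - cfg$intra_maf] <- 1L
  g[ok & frac >= cfg$intra_maf & frac <= 1 - cfg$intra_maf] <- 0L
  g
}

#' Mask of polymorphic sites
#'
#' A site is a SNP when at least one individual carries a heterozygous
#' call; sites segregating only the two homozygote classes do not qualify
#' under this within-individual definition.
#'
#' @param genotypes Genotype matrix `{-1, 0, 1, NA}`.
#' @return Logical site mask.
#' @export
polymorphic_sites <- function(genotypes) {
  colSums(genotypes == 0L, na.rm = TRUE) > 0L
}

#' Remove individuals with excessive missingness
#'
#' @param genotypes Genotype matrix.
#' @param cfg A [filter_config()]; individuals with missingness strictly
#'   above `sample_missing_max` are removed.
#' @return Filtered genotype matrix (attribute `"removed"`: dropped ids).
#' @export
filter_samples <- function(genotypes, cfg = filter_config()) {
  miss <- rowMeans(is.na(genotypes))
  keep <- miss <= cfg$sample_missing_max
  out <- genotypes[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(genotypes)[!keep]
  out
}

#' Remove low-call-rate and unanchored-scaffold sites
#'
#' @param genotypes Genotype matrix.
#' @param anchored Logical vector per site: `TRUE` when the site lies on an
#'   anchored scaffold.
#' @param cfg A [filter_config()]; sites called in fewer than
#'   `site_callrate_min` of individuals are removed.
#' @return Filtered genotype matrix (attribute `"removed"`: dropped site
#'   names).
#' @export
filter_sites <- function(genotypes, anchored = NULL, cfg = filter_config()) {
  callrate <- colMeans(!is.na(genotypes))
  keep <- callrate >= cfg$site_callrate_min
  if (!is.null(anchored)) {
    stopifnot(length(anchored) == ncol(genotypes))
    keep <- keep & anchored
  }
  out <- genotypes[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(genotypes)[!keep]
  out
}

#' Hardy-Weinberg exact test
#'
#' Exact test conditional on the observed allele counts: enumerates every
#' feasible heterozygote count, computes its probability
#' `P(n_het) = n! / (n11! n_het! n22!) * 2^n_het * nA! na! / (2n)!`,
#' and sums the probabilities of configurations no more probable than the
#' observed one (two-sided). Vectorized over sites.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (vectors of equal
#'   length).
#' @return Vector of exact p-values in `(0, 1]`.
#' @export
hwe_exact <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(length(n_het) == length(n_hom_ref),
            length(n_het) == length(n_hom_alt))
  if (any(n_hom_ref < 0 | n_het < 0 | n_hom_alt < 0))
    stop("negative genotype counts")
  mapply(function(n11, nh, n22) {
    n <- n11 + nh + n22
    if (n == 0) stop("no data: all genotype counts zero")
    nA <- 2L * n11 + nh
    na <- 2L * n22 + nh
    rare <- min(nA, na)
    ks <- seq(rare %% 2L, rare, by = 2L)
    lp <- ks * log(2) + lfactorial(n) -
      lfactorial((nA - ks) / 2) - lfactorial(ks) - lfactorial((na - ks) / 2) +
      lfactorial(nA) + lfactorial(na) - lfactorial(2L * n)
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    obs <- p[match(nh, ks)]
    sum(p[p <= obs * (1 + 1e-9)])
  }, n_hom_ref, n_het, n_hom_alt)
}

#' Genotype counts per site
#'
#' @param genotypes Genotype matrix `{-1, 0, 1, NA}`.
#' @return `data.frame` with `n_hom_ref`, `n_het`, `n_hom_alt` per site.
#' @export
genotype_counts <- function(genotypes) {
  data.frame(
    n_hom_ref = colSums(genotypes == -1L, na.rm = TRUE),
    n_het = colSums(genotypes == 0L, na.rm = TRUE),
    n_hom_alt = colSums(genotypes == 1L, na.rm = TRUE)
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param pvalues Raw p-values.
#' @return Adjusted p-values, monotone and bounded by 1.
#' @export
fdr_adjust <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' HWE retention mask
#'
#' Markers are retained when their FDR-adjusted exact-test p-value exceeds
#' `cfg$hwe_alpha` (low-p, HWE-violating markers are discarded).
#'
#' @param genotypes Genotype matrix.
#' @param cfg A [filter_config()].
#' @return Logical site mask.
#' @export
hwe_retain <- function(genotypes, cfg = filter_config()) {
  cnt <- genotype_counts(genotypes)
  p <- hwe_exact(cnt$n_hom_ref, cnt$n_het, cnt$n_hom_alt)
  fdr_adjust(p) > cfg$hwe_alpha
}

#' Greedy LD pruning
#'
#' `mode = "r2"`: scans markers left to right within each scaffold; a
#' marker is dropped when its squared genotypic correlation (computed on
#' the `{-1, 0, 1}` codes, pairwise-complete) with any retained marker
#' among the previous `ld_window - 1` positions exceeds `ld_r2_max` — the
#' earlier marker of an offending pair always survives.
#' `mode = "spacing"`: greedy left-to-right retention keeping markers at
#' least `min_spacing` bp apart.
#'
#' @param genotypes Genotype matrix (individuals x sites).
#' @param positions Per-site base-pair positions, sorted increasing within
#'   scaffold.
#' @param scaffold Optional per-site scaffold labels (single scaffold if
#'   omitted).
#' @param cfg A [filter_config()].
#' @param mode `"r2"` or `"spacing"`.
#' @return Logical site mask of retained markers.
#' @export
ld_prune <- function(genotypes, positions, scaffold = NULL,
                     cfg = filter_config(), mode = c("r2", "spacing")) {
  mode <- match.arg(mode)
  m <- ncol(genotypes)
  stopifnot(length(positions) == m)
  if (is.null(scaffold)) scaffold <- rep("scf", m)
  keep <- logical(m)
  for (s in unique(scaffold)) {
    idx <- which(scaffold == s)
    pos <- positions[idx]
    if (is.unsorted(pos)) stop("positions unsorted within scaffold ", s)
    if (mode == "spacing") {
      last <- -Inf
      for (j in seq_along(idx)) {
        if (pos[j] >= last + cfg$min_spacing) {
          keep[idx[j]] <- TRUE
          last <- pos[j]
        }
      }
    } else {
      kept_local <- integer()
      for (j in seq_along(idx)) {
        win <- kept_local[kept_local > j - cfg$ld_window]
        drop <- FALSE
        if (length(win)) {
          r <- suppressWarnings(
            cor(genotypes[, idx[j]], genotypes[, idx[win], drop = FALSE],
                use = "pairwise.complete.obs")
          )
          r[is.na(r)] <- 0
          drop <- any(r^2 > cfg$ld_r2_max)
        }
        if (!drop) {
          keep[idx[j]] <- TRUE
          kept_local <- c(kept_local, j)
        }
      }
    }
  }
  keep
}

#' Population minor-allele-frequency tier mask
#'
#' Computes the minor-allele frequency from non-missing calls and retains
#' sites with maf strictly exceeding the tier threshold.
#'
#' @param genotypes Genotype matrix.
#' @param threshold Tier threshold (strict `>`).
#' @return Logical site mask.
#' @export
maf_tier <- function(genotypes, threshold) {
  p <- allele_freqs(genotypes)
  maf <- pmin(p, 1 - p)
  maf > threshold
}

#' Run the full filtering cascade
#'
#' Calling, polymorphism screen, sample filter and site filters in the
#' fixed cascade order (each stage removes rows/columns, never edits
#' calls); the analysis-branch masks (HWE, LD, maf tier) are returned
#' separately so each analysis can pick its own branch.
#'
#' @param site_calls A `site_call_table`.
#' @param anchored Logical per-site anchored-scaffold flags.
#' @param positions Per-site bp positions (for LD pruning).
#' @param scaffold Per-site scaffold labels.
#' @param cfg A [filter_config()].
#' @param maf Population maf tier applied in the returned `maf_mask`.
#' @return List: `genotypes` (post sample/site filters), `hwe_mask`,
#'   `ld_mask`, `spacing_mask`, `maf_mask` (masks over the surviving
#'   sites), `positions`, `scaffold`, and `log` (per-stage dimensions).
#' @export
filter_cascade <- function(site_calls, anchored = NULL, positions = NULL,
                           scaffold = NULL, cfg = filter_config(),
                           maf = 0.01) {
  g <- call_genotypes(site_calls, cfg)
  log <- list(called = dim(g))
  site_keep <- polymorphic_sites(g)
  sel <- function(mask) {
    if (!is.null(positions)) positions <<- positions[mask]
    if (!is.null(scaffold)) scaffold <<- scaffold[mask]
    if (!is.null(anchored)) anchored <<- anchored[mask]
  }
  g <- g[, site_keep, drop = FALSE]
  sel(site_keep)
  log$polymorphic <- dim(g)
  g <- filter_samples(g, cfg)
  log$samples_kept <- dim(g)
  cr <- colMeans(!is.na(g)) >= cfg$site_callrate_min
  keep2 <- cr & (anchored %||% rep(TRUE, ncol(g)))
  g <- g[, keep2, drop = FALSE]
  sel(keep2)
  log$sites_kept <- dim(g)
  list(
    genotypes = g,
    hwe_mask = hwe_retain(g, cfg),
    ld_mask = if (!is.null(positions))
      ld_prune(g, positions, scaffold, cfg, mode = "r2") else NULL,
    spacing_mask = if (!is.null(positions))
      ld_prune(g, positions, scaffold, cfg, mode = "spacing") else NULL,
    maf_mask = maf_tier(g, maf),
    positions = positions, scaffold = scaffold, log = log
  )
}
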