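#' On-target read fraction and target capture rate
#'
#' Computes the two headline enrichment metrics of a capture experiment:
#' the fraction of reads aligned to a target ("on-target"), and the
#' fraction of targets hit by at least one read ("captured"). The default
#' overlap rule counts any overlap of at least 1 bp; `mode = "contained"`
#' requires the read to lie fully inside a target.
#'
#' @param alignments Alignment `data.frame` (`scaffold`, `start`, `end`,
#'   0-based half-open).
#' @param targets Target `data.frame` (same convention). Must be
#'   non-empty.
#' @param mode `"any"` (>= 1 bp overlap) or `"contained"`.
#' @return List: `reads_on_target`, `targets_captured` (both fractions),
#'   `n_reads`, `n_targets`.
#' @export
on_target_fraction <- function(alignments, targets, mode = c("any", "contained")) {
  mode <- match.arg(mode)
  if (!nrow(targets)) stop("empty target set")
  n_reads <- nrow(alignments)
  read_on <- logical(n_reads)
  tgt_hit <- logical(nrow(targets))
  for (s in unique(c(alignments$scaffold, targets$scaffold))) {
    ai <- which(alignments$scaffold == s)
    ti <- which(targets$scaffold == s)
    if (!length(ai) || !length(ti)) next
    ar <- IRanges::IRanges(alignments$start[ai] + 1L, alignments$end[ai])
    tr <- IRanges::IRanges(targets$start[ti] + 1L, targets$end[ti])
    if (mode == "any") {
      read_on[ai] <- IRanges::overlapsAny(ar, tr)
    } else {
      read_on[ai] <- IRanges::overlapsAny(ar, tr, type = "within")
    }
    tgt_hit[ti] <- IRanges::overlapsAny(tr, ar)
  }
  list(
    reads_on_target = if (n_reads) mean(read_on) else NA_real_,
    targets_captured = mean(tgt_hit),
    n_reads = n_reads, n_targets = nrow(targets)
  )
}

#' Per-target coverage breadth and depth
#'
#' Pileup-based capture metrics: for each target, the fraction of its
#' length covered by at least one read (breadth) and its mean per-base
#' depth; pooled values average breadth over targets and depth over all
#' target bases.
#'
#' @param alignments Alignment `data.frame`.
#' @param targets Target `data.frame`.
#' @return List: `per_target` (`target_id`, `breadth`, `mean_depth`),
#'   `mean_breadth`, `mean_depth`.
#' @export
breadth_and_depth <- function(alignments, targets) {
  ids <- targets$target_id %||% sprintf("t%05d", seq_len(nrow(targets)))
  breadth <- numeric(nrow(targets))
  mdepth <- numeric(nrow(targets))
  depth_sum <- 0
  base_sum <- 0
  for (s in unique(targets$scaffold)) {
    ti <- which(targets$scaffold == s)
    ai <- which(alignments$scaffold == s)
    cov <- if (length(ai)) {
      IRanges::coverage(IRanges::IRanges(alignments$start[ai] + 1L,
                                         alignments$end[ai]),
                        width = max(c(targets$end[ti], alignments$end[ai])))
    } else {
      S4Vectors::Rle(0L, max(targets$end[ti]))
    }
    for (k in ti) {
      slice <- as.integer(
        S4Vectors::window(cov, start = targets$start[k] + 1L,
                          end = targets$end[k])
      )
      breadth[k] <- mean(slice > 0L)
      mdepth[k] <- mean(slice)
      depth_sum <- depth_sum + sum(slice)
      base_sum <- base_sum + length(slice)
    }
  }
  list(
    per_target = data.frame(target_id = ids, breadth = breadth,
                            mean_depth = mdepth, stringsAsFactors = FALSE),
    mean_breadth = mean(breadth),
    mean_depth = depth_sum / base_sum
  )
}

#' Replicate concordance report
#'
#' Compares two independent call sets of the same individual over an
#' identical site universe. A site counts as a SNP within a replicate when
#' it is called heterozygous (within-individual polymorphism); the report
#' gives the SNP count per replicate, the SNPs common to both, and how many
#' of the common ones carry identical alleles (for strictly diallelic calls
#' the alleles of two heterozygotes always agree, so `different` is only
#' non-zero for multi-allelic inputs). Over all sites — polymorphic or not —
#' genotype similarity is computed restricted to sites covered at
#' `min_depth_all` or more in both replicates.
#'
#' @param geno1,geno2 Genotype vectors coded `{-1, 0, 1, NA}` over the same
#'   sites.
#' @param depth1,depth2 Matching depth vectors.
#' @param min_depth_all Depth floor (both replicates) for the all-site
#'   similarity (default 20).
#' @return List of class `concordance_report`: `snps_1`, `snps_2`,
#'   `common`, `identical`, `different`, `identical_fraction`,
#'   `all_site_similarity`, `n_sites_compared`.
#' @export
replicate_concordance <- function(geno1, geno2, depth1, depth2,
                                  min_depth_all = 20L) {
  if (length(geno1) != length(geno2))
    stop("replicates must share one site universe")
  het1 <- !is.na(geno1) & geno1 == 0L
  het2 <- !is.na(geno2) & geno2 == 0L
  common <- het1 & het2
  identical_n <- sum(common & geno1 == geno2)
  deep <- !is.na(geno1) & !is.na(geno2) &
    depth1 >= min_depth_all & depth2 >= min_depth_all
  structure(list(
    snps_1 = sum(het1), snps_2 = sum(het2),
    common = sum(common), identical = identical_n,
    different = sum(common) - identical_n,
    identical_fraction = if (sum(common)) identical_n / sum(common) else NA_real_,
    all_site_similarity = if (sum(deep)) mean(geno1[deep] == geno2[deep]) else NA_real_,
    n_sites_compared = sum(deep)
  ), class = "concordance_report")
}

#' Pooled replicate concordance from printed counts
#'
#' Aggregates per-individual common/identical SNP counts (e.g., a published
#' replicate table) into per-pair and pooled identical-allele fractions.
#'
#' @param common Integer vector: SNPs detected in both replicates, per
#'   individual.
#' @param identical Integer vector: of those, SNPs with identical alleles.
#' @return List: `per_pair` fractions, `pooled` identical fraction,
#'   `total_common`, `total_identical`.
#' @export
concordance_from_counts <- function(common, identical) {
  stopifnot(length(common) == length(identical), all(identical <= common))
  list(
    per_pair = identical / common,
    pooled = sum(identical) / sum(common),
    total_common = sum(common), total_identical = sum(identical)
  )
}

#' Cross-platform genotype concordance
#'
#' Compares genotype tables for the same individuals and sites produced by
#' two assays; reports the comparison count (`sites x individuals` per call
#' set) and the concordant fraction over pairs non-missing in both.
#'
#' @param calls_a,calls_b Genotype matrices (individuals x sites) with
#'   matching dimnames or identical layout.
#' @return List: `n_sites`, `n_individuals`, `comparisons`, `concordance`.
#' @export
cross_platform_concordance <- function(calls_a, calls_b) {
  if (!is.null(rownames(calls_a)) && !is.null(rownames(calls_b))) {
    ids <- intersect(rownames(calls_a), rownames(calls_b))
    sts <- intersect(colnames(calls_a), colnames(calls_b))
    if (!length(ids) || !length(sts)) stop("empty individual or site intersection")
    calls_a <- calls_a[ids, sts, drop = FALSE]
    calls_b <- calls_b[ids, sts, drop = FALSE]
  } else if (!all(dim(calls_a) == dim(calls_b))) {
    stop("call sets must match in dimension or share dimnames")
  }
  ok <- !is.na(calls_a) & !is.na(calls_b)
  if (!any(ok)) stop("no jointly scored genotypes")
  list(
    n_sites = ncol(calls_a), n_individuals = nrow(calls_a),
    comparisons = nrow(calls_a) * ncol(calls_a),
    concordance = mean(calls_a[ok] == calls_b[ok])
  )
}

#' Regress on-target fraction on read length
#'
#' Ordinary least squares of per-sample on-target fraction on mean read
#' length, reporting the slope and adjusted R-squared — the standard check
#' that longer reads align to their targets more reliably.
#'
#' @param read_length Per-sample mean read lengths (>= 3 samples).
#' @param on_target Per-sample on-target fractions.
#' @return List: `slope`, `intercept`, `adj_r_squared`, `p_value`.
#' @export
readlen_ontarget_regression <- function(read_length, on_target) {
  stopifnot(length(read_length) == length(on_target), length(read_length) >= 3)
  if (sd(read_length) == 0) stop("zero variance in read length")
  fit <- lm(on_target ~ read_length)
  s <- summary(fit)
  list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    adj_r_squared = s$adj.r.squared,
    p_value = unname(s$coefficients[2, 4])
  )
}
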