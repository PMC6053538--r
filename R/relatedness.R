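#' Alternate-allele frequencies from genotypes
#'
#' Frequency of the allele coded +1, computed from non-missing calls. This
#' orientation-consistent frequency (not folded to the minor allele) is
#' what centers the genotype matrix in [grm()].
#'
#' @param genotypes Genotype matrix `{-1, 0, 1, NA}` (individuals x sites).
#' @return Numeric vector of frequencies per site.
#' @export
allele_freqs <- function(genotypes) {
  if (any(colSums(!is.na(genotypes)) == 0))
    stop("site(s) with no non-missing calls")
  colMeans((genotypes + 1L) / 2, na.rm = TRUE)
}

#' Genomic relationship matrix (VanRaden form)
#'
#' Computes `G = (M - P)(M - P)' / (2 * sum(p_i * (1 - p_i)))`, where `M`
#' holds genotypes coded -1/0/+1 and column `i` of `P` is the constant
#' `2 * (p_i - 0.5)` — the centering that gives `M - P` mean zero under
#' Hardy-Weinberg. The denominator scales the diagonal to an expectation of
#' 1 for a non-inbred individual, so `diag(G) - 1` is genomic inbreeding.
#' Missing genotypes are imputed to the locus mean `2 p_i - 1` before
#' centering (contributing zero), or handled pairwise-complete with
#' `impute = "pairwise"`.
#'
#' By default frequencies are estimated in-sample, which induces the
#' well-known slight downward bias of realized relatedness in samples of
#' related individuals; pass known truth via `freqs` for simulation
#' studies.
#'
#' @param genotypes Genotype matrix `{-1, 0, 1, NA}`.
#' @param freqs Optional per-site +1-allele frequencies; defaults to
#'   [allele_freqs()] of the sample.
#' @param impute `"mean"` (default) or `"pairwise"`.
#' @return Symmetric n x n matrix with attributes `m` (marker count) and
#'   `freq_source`.
#' @examples
#' g <- matrix(c(0L, 0L, 1L, -1L), 2, 2)
#' grm(g, freqs = c(0.5, 0.5))
#' @export
grm <- function(genotypes, freqs = NULL, impute = c("mean", "pairwise")) {
  impute <- match.arg(impute)
  p <- freqs %||% allele_freqs(genotypes)
  stopifnot(length(p) == ncol(genotypes))
  if (all(p <= 0 | p >= 1))
    stop("all sites monomorphic: zero denominator")
  poly <- p > 0 & p < 1
  g <- genotypes[, poly, drop = FALSE]
  p <- p[poly]
  denom <- 2 * sum(p * (1 - p))
  W <- sweep(g, 2, 2 * (p - 0.5))
  if (impute == "mean") {
    W[is.na(W)] <- 0
    G <- tcrossprod(W) / denom
  } else {
    W0 <- W
    W0[is.na(W0)] <- 0
    num <- tcrossprod(W0)
    ind <- (!is.na(g)) * 1
    den <- ind %*% t(sweep(ind, 2, 2 * p * (1 - p), "*"))
    G <- num / den
  }
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  attr(G, "m") <- sum(poly)
  attr(G, "freq_source") <- if (is.null(freqs)) "in-sample" else "supplied"
  G
}

#' Genomic inbreeding coefficients
#'
#' `G[i,i] - 1`: the excess (positive) or deficit (negative) of an
#' individual's homozygosity relative to expectation under the population
#' allele frequencies used to build `G`.
#'
#' @param G A genomic relationship matrix from [grm()].
#' @return Named numeric vector.
#' @export
genomic_inbreeding <- function(G) {
  diag(G) - 1
}

#' Compare realized genomic relatedness with pedigree expectation
#'
#' Groups the known-relationship pairs by their expected additive
#' relationship and summarizes the realized (genomic) values per category:
#' mean, variance, and mean deviation from expectation.
#'
#' @param G Realized relationship matrix ([grm()]).
#' @param A Expected relationship matrix ([pedigree_A()]), or a pair table
#'   from [pedigree_pairs()] via the `pairs` argument.
#' @param pairs Optional `data.frame` (`id1`, `id2`, `expected`); defaults
#'   to all off-diagonal pairs with `A > 0` grouped by (rounded) expected
#'   value.
#' @return `data.frame`: `expected`, `n_pairs`, `mean_realized`,
#'   `var_realized`, `mean_deviation`.
#' @export
compare_realized_expected <- function(G, A = NULL, pairs = NULL) {
  if (is.null(pairs)) {
    stopifnot(!is.null(A))
    ids <- rownames(A)
    ut <- which(upper.tri(A) & round(A, 6) > 0, arr.ind = TRUE)
    pairs <- data.frame(
      id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
      expected = round(A[ut], 6), stringsAsFactors = FALSE
    )
  }
  realized <- mapply(function(a, b) G[a, b], pairs$id1, pairs$id2)
  by_cat <- split(realized, pairs$expected)
  out <- data.frame(
    expected = as.numeric(names(by_cat)),
    n_pairs = vapply(by_cat, length, 0L),
    mean_realized = vapply(by_cat, mean, 0),
    var_realized = vapply(by_cat, function(x)
      if (length(x) > 1) var(x) else NA_real_, 0),
    row.names = NULL
  )
  out$mean_deviation <- out$mean_realized - out$expected
  out
}
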