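#' Simulate diverged species allele frequencies
#'
#' Draws per-site alternate-allele frequencies for two partially diverged
#' species under the Balding-Nichols model: an ancestral frequency is drawn
#' per site, and each species' frequency is a Beta draw around it with
#' variance `fst * p * (1 - p)`. For weak divergence this yields the
#' characteristic L-shaped per-locus Fst distribution seen between sister
#' species that still exchange genes: most loci barely differentiated, a thin
#' tail of strongly differentiated ones.
#'
#' @param m Number of sites.
#' @param fst Divergence parameter in `[0, 1)`. `fst = 0` returns identical
#'   frequencies in both species.
#' @param seed Optional integer seed for reproducibility.
#' @param anc_range Range of the uniform ancestral-frequency draw. Kept away
#'   from 0/1 so loci are informative; species frequencies may still drift to
#'   the boundary by chance and are never clipped.
#' @return An object of class `species_freqs`: a list with `m`, `p_anc`,
#'   `p_A`, `p_B`, `fst_nominal`.
#' @examples
#' fr <- simulate_species_freqs(1000, fst = 0.07, seed = 1)
#' mean((fr$p_A - fr$p_B)^2 / (2 * fr$p_anc * (1 - fr$p_anc)))
#' @export
simulate_species_freqs <- function(m, fst, seed = NULL, anc_range = c(0.05, 0.95)) {
  stopifnot(length(m) == 1L, m >= 0, is.finite(m))
  if (!is.numeric(fst) || length(fst) != 1L || fst < 0 || fst >= 1)
    stop("`fst` must be a single value in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(m)
  p_anc <- runif(m, anc_range[1], anc_range[2])
  if (fst == 0) {
    p_A <- p_anc
    p_B <- p_anc
  } else {
    shape <- (1 - fst) / fst
    p_A <- rbeta(m, p_anc * shape, (1 - p_anc) * shape)
    p_B <- rbeta(m, p_anc * shape, (1 - p_anc) * shape)
  }
  structure(
    list(m = m, p_anc = p_anc, p_A = p_A, p_B = p_B, fst_nominal = fst),
    class = "species_freqs"
  )
}

#' Pooled Fst computed directly from species frequency arrays
#'
#' Ratio-of-sums estimator over loci: numerator the per-locus sample variance
#' of the two species frequencies, denominator `pbar(1-pbar) + s2/2`. Used to
#' check that realized divergence of a simulated frequency set matches its
#' nominal `fst`.
#'
#' @param p_a,p_b Per-site allele frequencies of the two species.
#' @return Single pooled Fst value.
#' @export
fst_from_freqs <- function(p_a, p_b) {
  stopifnot(length(p_a) == length(p_b))
  pbar <- (p_a + p_b) / 2
  s2 <- (p_a - p_b)^2 / 2
  sum(s2) / sum(pbar * (1 - pbar) + s2 / 2)
}
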