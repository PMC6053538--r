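#' Gene-drop genotypes through a pedigree
#'
#' Founder alleles are drawn Hardy-Weinberg from their species' allele
#' frequencies (`admixed` founders use the mean of the two species'
#' frequencies); each offspring receives, per locus, one allele copied at
#' random from each parent (Mendelian gene dropping). Genotypes are coded
#' -1 (reference homozygote), 0 (heterozygote), +1 (alternate homozygote);
#' the +1 allele is the alternate allele throughout the package.
#'
#' @param pedigree A pedigree `data.frame` (see [build_pedigree()]).
#' @param freqs A `species_freqs` object from [simulate_species_freqs()].
#' @param seed Optional integer seed.
#' @param keep_alleles If `TRUE`, attach the two 0/1 allele matrices as
#'   attributes `"allele1"`/`"allele2"` (useful for transmission checks).
#' @return Integer matrix (individuals x sites, dimnames set) with values
#'   in `{-1, 0, 1}`.
#' @export
drop_genotypes <- function(pedigree, freqs, seed = NULL, keep_alleles = FALSE) {
  validate_pedigree(pedigree)
  stopifnot(inherits(freqs, "species_freqs"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pedigree)
  m <- freqs$m
  a1 <- matrix(0L, n, m)
  a2 <- matrix(0L, n, m)
  pos <- setNames(seq_len(n), pedigree$id)
  for (k in order(pedigree$generation)) {
    s <- pedigree$sire[k]
    d <- pedigree$dam[k]
    if (is.na(s) != is.na(d))
      stop("individual ", pedigree$id[k], " has exactly one known parent")
    if (is.na(s)) {
      p <- switch(pedigree$species[k],
        A = freqs$p_A,
        B = freqs$p_B,
        admixed = (freqs$p_A + freqs$p_B) / 2,
        stop("unknown species label for founder ", pedigree$id[k], ": ",
             pedigree$species[k])
      )
      a1[k, ] <- rbinom(m, 1L, p)
      a2[k, ] <- rbinom(m, 1L, p)
    } else {
      si <- pos[[s]]
      di <- pos[[d]]
      from1 <- runif(m) < 0.5
      a1[k, ] <- ifelse(from1, a1[si, ], a2[si, ])
      from1 <- runif(m) < 0.5
      a2[k, ] <- ifelse(from1, a1[di, ], a2[di, ])
    }
  }
  g <- a1 + a2 - 1L
  dimnames(g) <- list(pedigree$id, sprintf("S%05d", seq_len(m)))
  if (keep_alleles) {
    attr(g, "allele1") <- a1
    attr(g, "allele2") <- a2
  }
  g
}

#' Simulate per-site read counts for called genotypes
#'
#' Sequencing depth per individual x site is drawn from a negative binomial
#' (mean `mean_depth`, size `depth_dispersion`), reflecting the large
#' run-to-run depth variation of capture experiments; `depth_dispersion =
#' Inf` gives Poisson depths. Given the true genotype, alternate-allele
#' reads are binomial with success probability `error_rate` (ref hom),
#' `0.5` (het), or `1 - error_rate` (alt hom).
#'
#' @param genotypes Matrix coded `{-1, 0, 1}` (no missing values).
#' @param mean_depth Mean sequencing depth (default 97, a typical capture
#'   depth for this design scale).
#' @param depth_dispersion Negative-binomial size parameter (default 5).
#' @param error_rate Per-read error probability in `[0, 0.5)`.
#' @param seed Optional integer seed.
#' @return List of class `site_call_table` with matrices `depth` and
#'   `alt_reads` shaped like `genotypes`.
#' @export
simulate_read_counts <- function(genotypes, mean_depth = 97,
                                 depth_dispersion = 5, error_rate = 0.01,
                                 seed = NULL) {
  stopifnot(mean_depth >= 0, error_rate >= 0, error_rate < 0.5,
            depth_dispersion > 0)
  if (any(is.na(genotypes)) || !all(genotypes %in% c(-1L, 0L, 1L)))
    stop("genotypes must be complete and coded -1/0/1")
  if (!is.null(seed)) set.seed(seed)
  nm <- length(genotypes)
  depth <- if (mean_depth == 0) {
    rep(0L, nm)
  } else if (is.infinite(depth_dispersion)) {
    rpois(nm, mean_depth)
  } else {
    rnbinom(nm, mu = mean_depth, size = depth_dispersion)
  }
  p_alt <- c(`-1` = error_rate, `0` = 0.5, `1` = 1 - error_rate)
  pr <- p_alt[as.character(as.vector(genotypes))]
  alt <- rbinom(nm, depth, pr)
  depth <- matrix(as.integer(depth), nrow(genotypes), ncol(genotypes),
                  dimnames = dimnames(genotypes))
  alt <- matrix(as.integer(alt), nrow(genotypes), ncol(genotypes),
                dimnames = dimnames(genotypes))
  structure(list(depth = depth, alt_reads = alt), class = "site_call_table")
}
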