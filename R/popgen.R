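#' Per-locus Weir-Cockerham Fst between two groups
#'
#' Variance-components estimator (Weir & Cockerham 1984) computed per
#' locus from genotype counts in two labeled groups, with the standard
#' heterozygosity correction. Returns per-locus components and the
#' conventional summaries: mean and median of per-locus ratios, and the
#' pooled ratio-of-sums estimate.
#'
#' @param genotypes Genotype matrix `{-1, 0, 1, NA}` (individuals x
#'   sites).
#' @param labels Group label per individual (exactly two distinct values).
#' @return List of class `fst_result`: `per_locus` (`fst`, `a`, `b`, `c`),
#'   `mean`, `median`, `pooled`.
#' @export
per_locus_fst <- function(genotypes, labels) {
  stopifnot(length(labels) == nrow(genotypes))
  grp <- unique(labels)
  if (length(grp) != 2) stop("exactly two groups required")
  g1 <- genotypes[labels == grp[1], , drop = FALSE]
  g2 <- genotypes[labels == grp[2], , drop = FALSE]
  n1 <- colSums(!is.na(g1))
  n2 <- colSums(!is.na(g2))
  if (any(n1 == 0 | n2 == 0))
    stop("locus/loci with no non-missing calls in one group: ",
         paste(utils::head(which(n1 == 0 | n2 == 0), 10), collapse = ", "))
  p1 <- colMeans((g1 + 1) / 2, na.rm = TRUE)
  p2 <- colMeans((g2 + 1) / 2, na.rm = TRUE)
  h1 <- colMeans(g1 == 0, na.rm = TRUE)
  h2 <- colMeans(g2 == 0, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- ifelse(denom > 0, a / denom, NA_real_)
  ok <- !is.na(fst)
  structure(list(
    per_locus = data.frame(fst = fst, a = a, b = b, c = cc),
    mean = mean(fst[ok]), median = median(fst[ok]),
    pooled = sum(a[ok]) / sum(denom[ok])
  ), class = "fst_result")
}

#' Two-cluster admixture estimation by EM
#'
#' Maximum-likelihood admixture model for two source clusters: each of an
#' individual's two allele copies at a locus originates from cluster A
#' with probability `q_i`, so the alternate-allele dosage is
#' `Binomial(2, q_i f_Al + (1 - q_i) f_Bl)`. The EM alternates expected
#' cluster-of-origin counts with ancestry (`q`) and cluster-frequency
#' (`f`) updates; the log-likelihood is non-decreasing by construction and
#' is returned as a trace. Label switching is resolved by anchoring
#' cluster A to the individual with the highest initial `q`. Identical
#' cluster frequencies leave `q` unidentifiable; this surfaces as a flat
#' likelihood trace and is flagged.
#'
#' Plain EM crawls toward the `q` boundaries from a random start, so two
#' standard remedies are built in: the default initialization splits
#' individuals on the leading principal component of the (mean-imputed)
#' dosage matrix and seeds `q` and the cluster frequencies from that split
#' (`init = "random"` gives the uninformed start), and iterations use
#' squared extrapolation (SQUAREM-type) acceleration with fallback to the
#' plain EM step whenever extrapolation would lower the likelihood.
#'
#' @param genotypes Genotype matrix `{-1, 0, 1, NA}`.
#' @param K Number of clusters; only 2 is supported.
#' @param tol Relative convergence tolerance: iteration stops when the
#'   log-likelihood increase falls below `tol * (1 + |loglik|)`.
#' @param max_iter Maximum accelerated EM cycles (each cycle applies two
#'   EM steps plus an extrapolated step).
#' @param seed Optional seed for the random jitter/initialization.
#' @param init `"pca"` (default) or `"random"`.
#' @return List of class `admixture_result`: `q` (cluster-A ancestry per
#'   individual), `freq_A`, `freq_B`, `loglik_trace`, `converged`,
#'   `iterations`, `flat_likelihood`.
#' @export
admixture_em <- function(genotypes, K = 2, tol = 1e-8, max_iter = 1000,
                         seed = NULL, init = c("pca", "random")) {
  if (K != 2) stop("only K = 2 is supported")
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  x <- genotypes + 1  # dosage 0..2
  n <- nrow(x); m <- ncol(x)
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  p0 <- colMeans(x, na.rm = TRUE) / 2
  eps <- 1e-6
  clamp <- function(v) pmin(pmax(v, eps), 1 - eps)
  if (init == "pca" && n >= 4) {
    xi <- x
    for (j in seq_len(m)) xi[is.na(xi[, j]), j] <- 2 * p0[j]
    sdv <- apply(xi, 2, sd)
    pc1 <- prcomp(xi[, sdv > 0, drop = FALSE], center = TRUE)$x[, 1]
    grpA <- pc1 >= median(pc1)
    q <- ifelse(grpA, 0.9, 0.1)
    fA <- clamp(colMeans(x[grpA, , drop = FALSE], na.rm = TRUE) / 2)
    fB <- clamp(colMeans(x[!grpA, , drop = FALSE], na.rm = TRUE) / 2)
    fA[is.na(fA)] <- p0[is.na(fA)]
    fB[is.na(fB)] <- p0[is.na(fB)]
  } else {
    q <- runif(n, 0.2, 0.8)
    fA <- clamp(p0 + runif(m, -0.1, 0.1))
    fB <- clamp(p0 + runif(m, -0.1, 0.1))
  }
  anchor <- which.max(q)
  loglik <- function(q, fA, fB) {
    pi <- q %o% fA + (1 - q) %o% fB
    ll <- x * log(pi) + (2 - x) * log(1 - pi)
    sum(ll[obs])
  }
  trace <- loglik(q, fA, fB)
  converged <- FALSE
  it <- 0L
  em_step <- function(th) {
    q <- th$q; fA <- th$fA; fB <- th$fB
    piA <- q %o% fA
    piB <- (1 - q) %o% fB
    zA <- piA / (piA + piB)                       # alt copy from A
    nuA <- q %o% (1 - fA)
    nuB <- (1 - q) %o% (1 - fB)
    wA <- nuA / (nuA + nuB)                       # ref copy from A
    EA_alt <- x0 * zA
    EA_ref <- (2 - x0) * wA
    EA_alt[!obs] <- 0; EA_ref[!obs] <- 0
    EA <- EA_alt + EA_ref
    EB_alt <- x0 * (1 - zA); EB_alt[!obs] <- 0
    EB <- 2 * obs - EA
    list(q = clamp(rowSums(EA) / (2 * rowSums(obs))),
         fA = clamp(colSums(EA_alt) / pmax(colSums(EA), eps)),
         fB = clamp(colSums(EB_alt) / pmax(colSums(EB), eps)))
  }
  # SQUAREM-type acceleration: extrapolate through two EM steps, fall back
  # to the plain double step whenever extrapolation would lower the
  # likelihood, so the trace stays monotone
  th <- list(q = q, fA = fA, fB = fB)
  while (it < max_iter) {
    it <- it + 1L
    t1 <- em_step(th)
    t2 <- em_step(t1)
    r <- unlist(t1) - unlist(th)
    v <- (unlist(t2) - unlist(t1)) - r
    alpha <- -sqrt(sum(r^2)) / max(sqrt(sum(v^2)), 1e-12)
    alpha <- min(alpha, -1)
    prop <- unlist(th) - 2 * alpha * r + alpha^2 * v
    prop <- clamp(prop)
    nq <- length(th$q); nf <- length(th$fA)
    cand <- list(q = prop[seq_len(nq)],
                 fA = prop[nq + seq_len(nf)],
                 fB = prop[nq + nf + seq_len(nf)])
    # one EM step from the extrapolated point keeps it in the stable manifold
    cand <- em_step(cand)
    ll_cand <- loglik(cand$q, cand$fA, cand$fB)
    ll_t2 <- loglik(t2$q, t2$fA, t2$fB)
    th <- if (is.finite(ll_cand) && ll_cand >= ll_t2) cand else t2
    ll_new <- max(ll_cand, ll_t2, na.rm = TRUE)
    delta <- ll_new - trace[length(trace)]
    trace <- c(trace, ll_new)
    if (abs(delta) < tol * (1 + abs(ll_new))) { converged <- TRUE; break }
  }
  q <- th$q; fA <- th$fA; fB <- th$fB
  if (q[anchor] < 0.5) {
    q <- 1 - q
    tmp <- fA; fA <- fB; fB <- tmp
  }
  flat <- diff(range(trace)) < max(1e-8, tol) * max(1, abs(trace[1]))
  if (!converged)
    warning("admixture EM did not converge in ", max_iter, " iterations")
  structure(list(
    q = setNames(q, rownames(genotypes)), freq_A = fA, freq_B = fB,
    loglik_trace = trace, converged = converged, iterations = it,
    flat_likelihood = flat
  ), class = "admixture_result")
}

#' Assign individuals to species by admixture threshold
#'
#' Pure threshold rule on the ancestry coefficient: `q >= hi` assigns
#' species A, `q <= lo` species B (both boundaries inclusive), anything in
#' between is admixed.
#'
#' @param q Ancestry coefficients in `[0, 1]`.
#' @param hi,lo Purebred thresholds (defaults 0.9 / 0.1).
#' @return Character vector in `{"A", "B", "admixed"}`.
#' @export
assign_species <- function(q, hi = 0.9, lo = 0.1) {
  stopifnot(all(q >= 0 & q <= 1), lo < hi)
  ifelse(q >= hi, "A", ifelse(q <= lo, "B", "admixed"))
}
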