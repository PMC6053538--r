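# Independent oracle implementations used to cross-check the package.
# These deliberately use different algorithms from the package code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kinship by recursion (Wright-style path counting via coancestry):
# f(i, j) with i processed after j; A = 2 * f off-diagonal, diag = 1 + F.
oracle_A <- function(ped) {
  ids <- ped$id
  sire <- setNames(ped$sire, ids)
  dam <- setNames(ped$dam, ids)
  gen <- setNames(ped$generation, ids)
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (identical(i, j)) {
      return(0.5 * (1 + f(sire[[i]], dam[[i]])))
    }
    # recurse on the later-generation individual
    if (gen[[i]] < gen[[j]]) { tmp <- i; i <- j; j <- tmp }
    if (is.na(sire[[i]]) && is.na(dam[[i]])) return(0)
    0.5 * (f(sire[[i]], j) + f(dam[[i]], j))
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    A[a, b] <- 2 * f(ids[a], ids[b])  # diag: 2 * (1 + F)/2 = 1 + F
  }
  A
}

# Naive double-loop VanRaden GRM (mean-imputed missing).
oracle_grm <- function(g, p) {
  n <- nrow(g)
  m <- ncol(g)
  W <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    gij <- g[i, j]
    if (is.na(gij)) gij <- 2 * p[j] - 1
    W[i, j] <- gij - 2 * (p[j] - 0.5)
  }
  denom <- 0
  for (j in seq_len(m)) denom <- denom + 2 * p[j] * (1 - p[j])
  G <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    s <- 0
    for (j in seq_len(m)) s <- s + W[a, j] * W[b, j]
    G[a, b] <- s / denom
  }
  G
}

# Exact HWE p-value via the ratio recurrence (Wigginton-style), built from
# the distribution mode outward -- an algorithm distinct from the direct
# log-factorial evaluation in the package.
oracle_hwe <- function(n11, n12, n22) {
  nA <- 2 * n11 + n12
  na <- 2 * n22 + n12
  n <- n11 + n12 + n22
  rare <- min(nA, na)
  ks <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(ks))
  mid <- which.min(abs(ks - rare * (nA + na - rare) / (nA + na)))
  probs[mid] <- 1
  if (mid < length(ks)) {
    for (idx in mid:(length(ks) - 1)) {
      k <- ks[idx]
      hr <- (nA - k) / 2   # hom for the rarer allele side
      hc <- (na - k) / 2
      probs[idx + 1] <- probs[idx] * 4 * hr * hc / ((k + 2) * (k + 1))
    }
  }
  if (mid > 1) {
    for (idx in mid:2) {
      k <- ks[idx]
      probs[idx - 1] <- probs[idx] * k * (k - 1) /
        (4 * ((nA - k) / 2 + 1) * ((na - k) / 2 + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n12, ks)]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# Brute-force per-base pileup over [0, width) from 0-based half-open reads.
oracle_pileup <- function(starts, ends, width) {
  depth <- integer(width)
  for (k in seq_along(starts)) {
    span <- (starts[k] + 1):ends[k]
    span <- span[span >= 1 & span <= width]
    depth[span] <- depth[span] + 1L
  }
  depth
}

# Brute-force approximate-match count: slide the pattern over every offset
# of every scaffold (both strands), counting Hamming distance directly on
# character vectors.
oracle_hits <- function(pattern, genome, min_identity = 0.9) {
  pat <- strsplit(as.character(pattern), "")[[1]]
  L <- length(pat)
  max_mm <- L - as.integer(ceiling(min_identity * L - 1e-9))
  rc <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(pattern))), "")[[1]]
  total <- 0L
  for (s in seq_along(genome$sequences)) {
    chars <- strsplit(as.character(genome$sequences[[s]]), "")[[1]]
    slen <- length(chars)
    if (slen < L) next
    for (off in 0:(slen - L)) {
      win <- chars[(off + 1):(off + L)]
      if (sum(win != pat) <= max_mm) total <- total + 1L
      else if (sum(win != rc) <= max_mm) total <- total + 1L
    }
  }
  total
}

# A hand-assembled toy genome from explicit components (0-based half-open).
manual_genome <- function(seqs, genes = NULL, exons = NULL, te = NULL,
                          anchored = NULL) {
  sequences <- Biostrings::DNAStringSet(seqs)
  empty_iv <- data.frame(scaffold = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  empty_gene <- cbind(data.frame(gene_id = character()), empty_iv,
                      data.frame(strand = character()))
  structure(list(
    sequences = sequences,
    scaffolds = data.frame(
      name = names(sequences), length = Biostrings::width(sequences),
      anchored = anchored %||% rep(TRUE, length(sequences)),
      stringsAsFactors = FALSE
    ),
    genes = genes %||% empty_gene,
    exons = exons %||% cbind(data.frame(gene_id = character()), empty_iv),
    te = te %||% empty_iv
  ), class = "toy_genome")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
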