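#' Simulate a toy annotated genome
#'
#' Builds a small multi-scaffold genome with gene models (exons/introns),
#' a transposable-element (TE) track, and anchored/unanchored scaffold
#' flags — everything the capture-target design stage consumes. Base
#' composition varies along the sequence (per-block GC drawn from a Beta
#' law) so that GC-content filtering has something to act on. Genes are
#' packed left-to-right with random intergenic gaps; each gene has 1-5
#' exons separated by introns. TE intervals are placed uniformly at random
#' until they cover approximately `te_fraction` of the genome.
#'
#' All coordinates are 0-based half-open, the package's internal convention
#' (BED-style).
#'
#' @param length Total genome length in bp (split across scaffolds).
#' @param n_genes Number of genes to place.
#' @param te_fraction Approximate fraction of the genome covered by TEs.
#' @param n_scaffolds Number of scaffolds.
#' @param unanchored_fraction Fraction of scaffolds flagged unanchored
#'   (at least one scaffold stays anchored).
#' @param gc_block Block size (bp) for the varying GC level.
#' @param exons_per_gene Fixed exon count per gene; `NULL` (default) draws
#'   1-5 exons per gene at random.
#' @param seed Optional integer seed.
#' @return List of class `toy_genome`: `sequences` (a
#'   [Biostrings::DNAStringSet]), `scaffolds` (`name`, `length`,
#'   `anchored`), `genes` (`gene_id`, `scaffold`, `start`, `end`,
#'   `strand`), `exons` (`gene_id`, `scaffold`, `start`, `end`), `te`
#'   (`scaffold`, `start`, `end`).
#' @export
simulate_genome <- function(length = 2e6, n_genes = 100, te_fraction = 0.3,
                            n_scaffolds = 4, unanchored_fraction = 0.25,
                            gc_block = 500, exons_per_gene = NULL,
                            seed = NULL) {
  stopifnot(length > 0, n_genes >= 0, te_fraction >= 0, te_fraction < 1,
            n_scaffolds >= 1)
  if (!is.null(seed)) set.seed(seed)
  total <- as.integer(length)
  base_len <- total %/% n_scaffolds
  scaf_len <- rep(base_len, n_scaffolds)
  scaf_len[n_scaffolds] <- total - base_len * (n_scaffolds - 1L)
  scaf <- sprintf("scf%02d", seq_len(n_scaffolds))
  n_unanch <- min(n_scaffolds - 1L, round(unanchored_fraction * n_scaffolds))
  anchored <- rep(TRUE, n_scaffolds)
  if (n_unanch > 0) anchored[sample(n_scaffolds, n_unanch)] <- FALSE

  seqs <- vapply(scaf_len, function(L) {
    nb <- ceiling(L / gc_block)
    gc <- rbeta(nb, 8, 11)  # mean ~0.42, sd ~0.11
    gc <- rep(gc, each = gc_block)[seq_len(L)]
    at_split <- runif(L) < 0.5
    gc_split <- runif(L) < 0.5
    is_gc <- runif(L) < gc
    paste(ifelse(is_gc, ifelse(gc_split, "G", "C"),
                 ifelse(at_split, "A", "T")), collapse = "")
  }, character(1))
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- scaf

  # genes: sequential packing, proportional allocation across scaffolds
  genes <- list(); exons <- list()
  alloc <- diff(round(c(0, cumsum(scaf_len / total * n_genes))))
  gid <- 0L
  for (s in seq_len(n_scaffolds)) {
    cursor <- 0L
    slot <- if (alloc[s] > 0) scaf_len[s] / alloc[s] else 0
    for (g in seq_len(alloc[s])) {
      gid <- gid + 1L
      n_ex <- if (is.null(exons_per_gene)) sample(1:5, 1L)
              else as.integer(exons_per_gene)
      ex_len <- sample(160:450, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(100:1500, n_ex - 1L, replace = TRUE) else integer()
      glen <- sum(ex_len) + sum(in_len)
      # spread genes over evenly sized slots with random jitter, keeping a
      # minimal intergenic gap
      gstart <- max(cursor + 200L,
                    as.integer(round((g - 1) * slot + runif(1) * 0.3 * slot)))
      if (gstart + glen > scaf_len[s])
        stop("infeasible packing: gene ", gid, " does not fit on ", scaf[s])
      id <- sprintf("gene%04d", gid)
      genes[[gid]] <- data.frame(
        gene_id = id, scaffold = scaf[s], start = gstart,
        end = gstart + glen, strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE
      )
      offs <- gstart + cumsum(c(0L, as.vector(rbind(ex_len, c(in_len, 0L)))[
        seq_len(2L * n_ex - 1L)]))
      ex_start <- offs[seq(1L, by = 2L, length.out = n_ex)]
      exons[[gid]] <- data.frame(
        gene_id = id, scaffold = scaf[s], start = ex_start,
        end = ex_start + ex_len, stringsAsFactors = FALSE
      )
      cursor <- gstart + glen
    }
  }
  genes <- if (gid > 0) do.call(rbind, genes) else
    data.frame(gene_id = character(), scaffold = character(),
               start = integer(), end = integer(), strand = character())
  exons <- if (gid > 0) do.call(rbind, exons) else
    data.frame(gene_id = character(), scaffold = character(),
               start = integer(), end = integer())
  rownames(genes) <- rownames(exons) <- NULL

  # TE track: uniform placement until the union covers ~ te_fraction
  te <- data.frame(scaffold = character(), start = integer(), end = integer())
  if (te_fraction > 0) {
    target_cov <- te_fraction * total
    per_scaf <- lapply(seq_len(n_scaffolds), function(s) IRanges::IRanges())
    covered <- 0
    while (covered < target_cov) {
      s <- sample(n_scaffolds, 1L, prob = scaf_len)
      L <- min(sample(200:2000, 1L), scaf_len[s] - 1L)
      st <- sample(scaf_len[s] - L, 1L)
      per_scaf[[s]] <- IRanges::reduce(c(per_scaf[[s]],
                                         IRanges::IRanges(st + 1L, st + L)))
      covered <- sum(vapply(per_scaf, function(x) sum(IRanges::width(x)), 0))
    }
    te <- do.call(rbind, lapply(seq_len(n_scaffolds), function(s) {
      r <- per_scaf[[s]]
      data.frame(scaffold = scaf[s], start = IRanges::start(r) - 1L,
                 end = IRanges::end(r), stringsAsFactors = FALSE)
    }))
    rownames(te) <- NULL
  }
  structure(list(
    sequences = sequences,
    scaffolds = data.frame(name = scaf, length = scaf_len,
                           anchored = anchored, stringsAsFactors = FALSE),
    genes = genes, exons = exons, te = te
  ), class = "toy_genome")
}

#' Simulate read-alignment intervals over a genome
#'
#' Places single-end read alignments on a genome: a fraction
#' `on_target_rate` of reads start within (or just upstream of) a random
#' target so that they overlap it, the rest are uniform background. Read
#' lengths are uniform on `read_length_range` (capture reads of ~140-190
#' bp).
#'
#' @param genome A `toy_genome`.
#' @param targets Target `data.frame` (`scaffold`, `start`, `end`),
#'   0-based half-open.
#' @param n_reads Number of reads.
#' @param on_target_rate Fraction of reads anchored on targets.
#' @param read_length_range Integer range of read lengths.
#' @param seed Optional integer seed.
#' @return `data.frame` with `read_id`, `scaffold`, `start`, `end`
#'   (0-based half-open), `read_length`.
#' @export
simulate_alignments <- function(genome, targets, n_reads = 10000,
                                on_target_rate = 0.25,
                                read_length_range = c(140L, 190L),
                                seed = NULL) {
  stopifnot(inherits(genome, "toy_genome"), n_reads >= 0,
            on_target_rate >= 0, on_target_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  slen <- setNames(genome$scaffolds$length, genome$scaffolds$name)
  rl <- sample(seq(read_length_range[1], read_length_range[2]),
               n_reads, replace = TRUE)
  on <- runif(n_reads) < on_target_rate & nrow(targets) > 0
  scaffold <- character(n_reads)
  start <- integer(n_reads)
  if (any(on)) {
    ti <- sample(nrow(targets), sum(on), replace = TRUE)
    scaffold[on] <- targets$scaffold[ti]
    # start anywhere that guarantees >= 1 bp overlap with the target
    lo <- pmax(0L, targets$start[ti] - rl[on] + 1L)
    hi <- pmin(targets$end[ti] - 1L, slen[scaffold[on]] - rl[on])
    start[on] <- lo + floor(runif(sum(on)) * (pmax(hi, lo) - lo + 1L))
  }
  if (any(!on)) {
    si <- sample(nrow(genome$scaffolds), sum(!on), replace = TRUE,
                 prob = genome$scaffolds$length)
    scaffold[!on] <- genome$scaffolds$name[si]
    start[!on] <- floor(runif(sum(!on)) * (slen[scaffold[!on]] - rl[!on]))
  }
  data.frame(
    read_id = sprintf("read%06d", seq_len(n_reads)),
    scaffold = scaffold, start = as.integer(start),
    end = as.integer(start + rl), read_length = as.integer(rl),
    stringsAsFactors = FALSE
  )
}
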