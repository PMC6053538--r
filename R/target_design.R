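# Interval helpers -----------------------------------------------------------
# All data.frame intervals in this package are 0-based half-open.

interval_overlaps_any <- function(query, subject) {
  # for each query row, does it overlap >=1 subject row on the same scaffold?
  out <- logical(nrow(query))
  if (!nrow(query) || !nrow(subject)) return(out)
  for (s in unique(query$scaffold)) {
    qi <- which(query$scaffold == s)
    si <- which(subject$scaffold == s)
    if (!length(si)) next
    qr <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    sr <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    out[qi] <- IRanges::overlapsAny(qr, sr)
  }
  out
}

#' Extract target sequences from a genome
#'
#' @param targets Interval `data.frame` (`scaffold`, `start`, `end`).
#' @param genome A `toy_genome` (or any list with a named `sequences`
#'   [Biostrings::DNAStringSet]).
#' @return [Biostrings::DNAStringSet] of target sequences (forward strand).
#' @export
target_seqs <- function(targets, genome) {
  if (!nrow(targets)) return(Biostrings::DNAStringSet())
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(targets)), function(i) {
    as.character(Biostrings::subseq(
      genome$sequences[[targets$scaffold[i]]],
      start = targets$start[i] + 1L, end = targets$end[i]
    ))
  }, character(1)))
  names(out) <- targets$target_id %||% sprintf("t%05d", seq_len(nrow(targets)))
  out
}

# Target selection ------------------------------------------------------------

#' Select genic capture targets
#'
#' Applies the gene-length rule used for capture design in repeat-rich tree
#' genomes: genes shorter than `long_gene` (1.5 kb) contribute a single
#' 150 bp target inside an exon; longer genes are split into thirds and
#' contribute two targets in the two extreme thirds — one fully exonic, the
#' other spanning an intron-exon junction. Single-exon long genes have no
#' junction; they fall back to a second exonic target in the opposite
#' extreme third (recorded in the `"skipped"`/`"fallback"` attributes).
#' Genes with no exon segment long enough for a target are skipped and
#' reported.
#'
#' @param genome A `toy_genome` (uses `genes` and `exons`).
#' @param target_len Target length in bp (150).
#' @param long_gene Gene-length threshold for the two-target rule (1500).
#' @return Target `data.frame` (`target_id`, `scaffold`, `start`, `end`,
#'   `category` in `exon`/`intron_exon`, `gene_id`), 0-based half-open,
#'   with attributes `"skipped"` (gene ids with no feasible target) and
#'   `"fallback"` (single-exon long genes given two exonic targets).
#' @export
select_genic_targets <- function(genome, target_len = 150L, long_gene = 1500L) {
  genes <- genome$genes
  exons <- genome$exons
  skipped <- character()
  fallback <- character()
  rows <- list()
  seg_in <- function(ex, lo, hi) {
    # exon sub-segments clipped to [lo, hi)
    s <- pmax(ex$start, lo); e <- pmin(ex$end, hi)
    ok <- e - s >= 1L
    data.frame(start = s[ok], end = e[ok])
  }
  place_exonic <- function(ex, lo, hi) {
    seg <- seg_in(ex, lo, hi)
    seg <- seg[seg$end - seg$start >= target_len, , drop = FALSE]
    if (!nrow(seg)) return(NULL)
    c(seg$start[1], seg$start[1] + target_len)
  }
  place_junction <- function(ex, g, lo, hi) {
    # internal exon boundaries = intron-exon transitions
    b <- sort(c(ex$start, ex$end))
    b <- b[b > g$start & b < g$end & b >= lo & b < hi]
    for (bp in b) {
      st <- bp - target_len %/% 2L
      st <- max(g$start, min(st, g$end - target_len))
      if (st < bp && st + target_len > bp) return(c(st, st + target_len))
    }
    NULL
  }
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    glen <- g$end - g$start
    if (glen < long_gene) {
      t1 <- place_exonic(ex, g$start, g$end)
      if (is.null(t1)) { skipped <- c(skipped, g$gene_id); next }
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = g$scaffold, start = t1[1], end = t1[2],
        category = "exon", gene_id = g$gene_id, stringsAsFactors = FALSE
      )
    } else {
      third <- glen %/% 3L
      first <- c(g$start, g$start + third)
      last <- c(g$end - third, g$end)
      t_ex <- place_exonic(ex, first[1], first[2])
      t_jn <- place_junction(ex, g, last[1], last[2])
      if (is.null(t_ex) || is.null(t_jn)) {
        # try the swapped arrangement before falling back
        t_ex2 <- place_exonic(ex, last[1], last[2])
        t_jn2 <- place_junction(ex, g, first[1], first[2])
        if (!is.null(t_ex2) && !is.null(t_jn2)) {
          t_ex <- t_ex2; t_jn <- t_jn2
        }
      }
      if (is.null(t_jn)) {
        # no junction available (e.g., single-exon gene): second exonic target
        t2 <- if (!is.null(t_ex) && t_ex[1] < first[2])
          place_exonic(ex, last[1], last[2]) else place_exonic(ex, first[1], first[2])
        if (is.null(t_ex) || is.null(t2)) { skipped <- c(skipped, g$gene_id); next }
        fallback <- c(fallback, g$gene_id)
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = g$scaffold, start = c(t_ex[1], t2[1]),
          end = c(t_ex[2], t2[2]), category = "exon",
          gene_id = g$gene_id, stringsAsFactors = FALSE
        )
      } else if (is.null(t_ex)) {
        skipped <- c(skipped, g$gene_id)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = g$scaffold, start = c(t_ex[1], t_jn[1]),
          end = c(t_ex[2], t_jn[2]),
          category = c("exon", "intron_exon"),
          gene_id = g$gene_id, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               category = character(), gene_id = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (nrow(out)) out <- cbind(target_id = sprintf("tg%05d", seq_len(nrow(out))), out,
                              stringsAsFactors = FALSE)
  else out <- cbind(data.frame(target_id = character()), out)
  attr(out, "skipped") <- skipped
  attr(out, "fallback") <- fallback
  out
}

#' Select intergenic capture targets by sliding window
#'
#' Walks non-overlapping windows (default 100 kb) along each scaffold and
#' places one 150 bp target at the window start in every window containing
#' no previously identified target. A candidate colocalizing with a TE (or
#' a gene, so the target stays intergenic) is shifted downstream in 150 bp
#' steps until clear; a window exhausted before a clear position yields no
#' target (logged in the `"saturated"` attribute).
#'
#' @param genome A `toy_genome`.
#' @param existing_targets Target `data.frame` already selected (genic
#'   targets); windows containing any of these are skipped.
#' @param window Window size in bp.
#' @param target_len Target length in bp.
#' @return Target `data.frame` with `category = "intergenic"`, plus
#'   attribute `"saturated"`: windows (scaffold, window start) where no
#'   TE-free position was found.
#' @export
select_intergenic_targets <- function(genome, existing_targets,
                                      window = 100000L, target_len = 150L) {
  avoid <- rbind(
    genome$te[, c("scaffold", "start", "end")],
    genome$genes[, c("scaffold", "start", "end")]
  )
  rows <- list()
  saturated <- list()
  for (s in seq_len(nrow(genome$scaffolds))) {
    scaf <- genome$scaffolds$name[s]
    slen <- genome$scaffolds$length[s]
    starts <- seq(0L, slen - 1L, by = window)
    for (ws in starts) {
      we <- min(ws + window, slen)
      if (we - ws < target_len) next
      win <- data.frame(scaffold = scaf, start = ws, end = we)
      if (nrow(existing_targets) &&
          any(interval_overlaps_any(existing_targets, win))) next
      if (length(rows)) {
        placed <- do.call(rbind, rows)
        if (any(interval_overlaps_any(placed, win))) next
      }
      pos <- ws
      repeat {
        if (pos + target_len > we) { saturated[[length(saturated) + 1L]] <-
          data.frame(scaffold = scaf, window_start = ws); pos <- NA; break }
        cand <- data.frame(scaffold = scaf, start = pos, end = pos + target_len)
        if (!interval_overlaps_any(cand, avoid)) break
        pos <- pos + target_len
      }
      if (!is.na(pos))
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = scaf, start = pos, end = pos + target_len,
          category = "intergenic", gene_id = NA_character_,
          stringsAsFactors = FALSE
        )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               category = character(), gene_id = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- cbind(data.frame(target_id = sprintf("ti%05d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  attr(out, "saturated") <- if (length(saturated)) do.call(rbind, saturated)
    else data.frame(scaffold = character(), window_start = integer())
  out
}

# Filters ---------------------------------------------------------------------

#' GC content of target sequences
#'
#' @param targets Target `data.frame`.
#' @param genome A `toy_genome`.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
target_gc <- function(targets, genome) {
  if (!nrow(targets)) return(numeric())
  seqs <- target_seqs(targets, genome)
  as.numeric(Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE))
}

#' Filter targets by GC content
#'
#' Retains targets with GC content between `low` and `high`, bounds
#' inclusive. Annotates the surviving table with a `gc` column.
#'
#' @param targets Target `data.frame`.
#' @param genome A `toy_genome`.
#' @param low,high Inclusive GC bounds (defaults 0.30/0.60).
#' @return Filtered target `data.frame` with `gc` column and a `"removed"`
#'   attribute holding the discarded rows.
#' @export
filter_gc <- function(targets, genome, low = 0.30, high = 0.60) {
  gc <- target_gc(targets, genome)
  targets$gc <- gc
  keep <- gc >= low & gc <= high
  out <- targets[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- targets[!keep, , drop = FALSE]
  out
}

#' Count approximate genomic matches of a sequence
#'
#' Counts positions (both strands) where the query matches the genome over
#' its full length at `min_identity` or better (mismatches only, no
#' indels). Matching is k-mer seeded: the query is cut into
#' `max_mismatch + 1` non-overlapping seeds, so any qualifying match must
#' contain at least one exact seed (pigeonhole); candidate positions from
#' exact seed hits are then verified by Hamming distance.
#'
#' @param seq A character string or `DNAString` query.
#' @param genome A `toy_genome`.
#' @param min_identity Minimum full-length identity (default 0.9).
#' @return Integer hit count (a unique sequence present once scores 1 — its
#'   own locus).
#' @export
count_genome_hits <- function(seq, genome, min_identity = 0.9) {
  pat <- Biostrings::DNAString(as.character(seq))
  L <- length(pat)
  # identity >= min_identity over L bases, robust to floating-point edges
  max_mm <- L - as.integer(ceiling(min_identity * L - 1e-9))
  n_seeds <- max_mm + 1L
  seed_len <- L %/% n_seeds
  if (seed_len < 4L) stop("query too short for seeded matching")
  offs <- (seq_len(n_seeds) - 1L) * seed_len  # 0-based seed offsets
  total <- 0L
  for (strand_pat in list(pat, Biostrings::reverseComplement(pat))) {
    for (si in seq_along(genome$sequences)) {
      subj <- genome$sequences[[si]]
      slen <- length(subj)
      cand <- integer()
      for (o in offs) {
        seed <- Biostrings::subseq(strand_pat, o + 1L, o + seed_len)
        hits <- Biostrings::start(Biostrings::matchPattern(seed, subj))
        cand <- c(cand, hits - o)
      }
      cand <- unique(cand)
      cand <- cand[cand >= 1L & cand + L - 1L <= slen]
      if (!length(cand)) next
      mm <- Biostrings::neditStartingAt(strand_pat, subj, starting.at = cand,
                                        with.indels = FALSE)
      total <- total + sum(mm <= max_mm)
    }
  }
  total
}

#' Filter targets by genomic repetitiveness
#'
#' Counts approximate full-length matches of each target in the genome
#' (see [count_genome_hits()]) and retains targets with fewer than
#' `max_hits` matches — the repeat-avoidance rule for capture design in a
#' TE-rich genome.
#'
#' @param targets Target `data.frame`.
#' @param genome A `toy_genome`.
#' @param max_hits Targets with `repeat_hits >= max_hits` are removed
#'   (default 10, i.e., "fewer than 10 alignments" retained).
#' @param min_identity Identity threshold for a match (default 0.9).
#' @return Filtered targets annotated with a `repeat_hits` column;
#'   discarded rows in the `"removed"` attribute.
#' @export
filter_repetitive <- function(targets, genome, max_hits = 10L,
                              min_identity = 0.9) {
  if (!nrow(targets)) {
    targets$repeat_hits <- integer()
    attr(targets, "removed") <- targets
    return(targets)
  }
  seqs <- target_seqs(targets, genome)
  hits <- vapply(seq_along(seqs),
                 function(i) count_genome_hits(seqs[[i]], genome, min_identity),
                 integer(1))
  targets$repeat_hits <- hits
  keep <- hits < max_hits
  out <- targets[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- targets[!keep, , drop = FALSE]
  out
}

# Probes ----------------------------------------------------------------------

#' Tile capture probes over targets
#'
#' Designs 120 bp probes per target: one or two non-overlapping probes,
#' resolved by length arithmetic — a target shorter than two probe lengths
#' (e.g., the nominal 150 bp) receives a single probe at its start; targets
#' of at least `2 * probe_len` receive two, one at each end. Targets
#' shorter than one probe length receive none and are logged.
#'
#' @param targets Target `data.frame`.
#' @param probe_len Probe length in bp (120).
#' @return Probe `data.frame` (`probe_id`, `target_id`, `scaffold`,
#'   `start`, `end`, `category`) with attribute `"unprobed"`: target ids
#'   too short for any probe.
#' @export
design_probes <- function(targets, probe_len = 120L) {
  rows <- list()
  unprobed <- character()
  for (k in seq_len(nrow(targets))) {
    t <- targets[k, ]
    len <- t$end - t$start
    if (len < probe_len) { unprobed <- c(unprobed, t$target_id); next }
    starts <- if (len >= 2L * probe_len) c(t$start, t$end - probe_len)
              else t$start
    rows[[length(rows) + 1L]] <- data.frame(
      target_id = t$target_id, scaffold = t$scaffold,
      start = starts, end = starts + probe_len,
      category = t$category, stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(), scaffold = character(),
               start = integer(), end = integer(), category = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- cbind(data.frame(probe_id = sprintf("p%05d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  attr(out, "unprobed") <- unprobed
  out
}

#' Probe and target accounting by category
#'
#' Summarizes probe/target counts per sequence category (intergenic, exon,
#' intron, intron-exon junction), with genic and overall totals and each
#' genic category's share of genic probes — the standard design-summary
#' table of a capture experiment.
#'
#' @param probes Probe `data.frame` from [design_probes()].
#' @param targets Target `data.frame`; every probe's `target_id` must be
#'   present.
#' @return See [probe_accounting_counts()].
#' @export
probe_accounting <- function(probes, targets) {
  if (nrow(probes) && !all(probes$target_id %in% targets$target_id))
    stop("probe(s) reference targets absent from the target set")
  cats <- c("intergenic", "exon", "intron", "intron_exon")
  pc <- setNames(vapply(cats, function(cc) sum(probes$category == cc), 0L), cats)
  tc <- setNames(vapply(cats, function(cc) sum(targets$category == cc), 0L), cats)
  probe_accounting_counts(pc, tc)
}

#' Probe accounting from printed category counts
#'
#' Builds the accounting table directly from per-category probe (and
#' optionally target) counts, e.g. to recompute the totals and
#' within-genic percentages of a published design summary.
#'
#' @param probe_counts Named vector with any of `intergenic`, `exon`,
#'   `intron`, `intron_exon`.
#' @param target_counts Optional named vector of target counts (same
#'   names).
#' @return `data.frame` with rows per category plus `genic` and `total`,
#'   columns `probes`, `targets`, `pct_genic_probes` (share of genic
#'   probes, in percent, for the three genic categories).
#' @export
probe_accounting_counts <- function(probe_counts, target_counts = NULL) {
  cats <- c("intergenic", "exon", "intron", "intron_exon")
  p <- setNames(numeric(4), cats)
  p[names(probe_counts)] <- probe_counts
  t <- setNames(rep(NA_real_, 4), cats)
  if (!is.null(target_counts)) {
    t[] <- 0
    t[names(target_counts)] <- target_counts
  }
  genic <- c("exon", "intron", "intron_exon")
  genic_p <- sum(p[genic])
  pct <- setNames(rep(NA_real_, 6), c(cats, "genic", "total"))
  if (genic_p > 0)
    pct[genic] <- round(100 * p[genic] / genic_p, 2)
  data.frame(
    category = c(cats, "genic", "total"),
    probes = c(p, genic_p, sum(p)),
    targets = c(t, sum(t[genic]), sum(t)),
    pct_genic_probes = pct,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run the full target-design procedure
#'
#' Genic selection, intergenic sliding-window selection, GC filter, repeat
#' filter, and probe tiling, in that order.
#'
#' @param genome A `toy_genome`.
#' @param window Intergenic window size (bp).
#' @param gc_min,gc_max Inclusive GC bounds.
#' @param max_hits Repeat-filter bound.
#' @return List with `targets`, `probes`, `accounting`.
#' @export
design_targets <- function(genome, window = 100000L, gc_min = 0.30,
                           gc_max = 0.60, max_hits = 10L) {
  genic <- select_genic_targets(genome)
  intergenic <- select_intergenic_targets(genome, genic, window = window)
  targets <- rbind(genic, intergenic)
  targets <- filter_gc(targets, genome, gc_min, gc_max)
  targets <- filter_repetitive(targets, genome, max_hits)
  probes <- design_probes(targets)
  list(targets = targets, probes = probes,
       accounting = probe_accounting(probes, targets))
}
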