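#' Default pipeline configuration
#'
#' A complete run configuration for the simulate-design-qc-filter-relate-
#' structure-fitness pipeline at desk scale: a mixed stand of two species
#' (divergence 0.07), founders plus offspring families in all four known
#' relationship categories, capture-scale read depths, and fitness traits
#' with an inbreeding effect on reproductive success.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory for stage artifacts.
#' @return Nested list of class `run_config` (serializable to YAML).
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("standkin_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, design = TRUE, qc = TRUE, filter = TRUE,
                  relate = TRUE, structure = TRUE, fitness = TRUE),
    sim = list(
      m = 5000L, fst = 0.07,
      n_founders_A = 60L, n_founders_B = 60L,
      offspring = list(
        A = c(parent_offspring = 1L, full_sib = 2L, half_sib = 2L, selfed = 1L),
        B = c(parent_offspring = 1L, full_sib = 2L, half_sib = 1L, selfed = 1L)
      ),
      mean_depth = 97, depth_dispersion = 5, error_rate = 0.005,
      fitness = list(gamma = -3.6, beta1 = 0.2, alpha = log(9), noise = 20),
      genome = list(length = 1e6, n_genes = 60L, te_fraction = 0.3,
                    n_scaffolds = 4L, unanchored_fraction = 0.25)
    ),
    design = list(window = 100000L, gc_min = 0.30, gc_max = 0.60,
                  max_hits = 10L),
    qc = list(n_reads = 20000L, on_target_rate = 0.25),
    filter = filter_config(),
    maf = 0.01
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  usr <- yaml::yaml.load_file(path)
  cfg <- default_config(seed = usr$seed %||% 1L)
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge_in(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  out <- merge_in(unclass(cfg), usr)
  if (!inherits(out$filter, "filter_config"))
    out$filter <- do.call(filter_config, out$filter)
  class(out) <- "run_config"
  out
}

stage_seed <- function(config, k) config$seed * 100L + k

read_matrix_tsv <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t", check.names = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages against one seeded configuration: simulate the
#' stand (frequencies, pedigree, genotypes, reads, fitness, toy genome),
#' design capture targets and probes, compute capture QC metrics, call and
#' filter genotypes, assign species by admixture and measure interspecific
#' differentiation, estimate the genomic relationship matrix and
#' inbreeding, and fit the inbreeding-fitness regressions. Each stage
#' writes plain-text artifacts (VCF, BED, FASTA, GFF3, TSV, JSON) under
#' `config$out_dir`; a manifest with the seed and per-file MD5 checksums
#' makes runs byte-comparable. A stage toggled off reloads its artifacts
#' from a previous run in the same directory; a stage failure aborts with
#' a stage-tagged error.
#'
#' @param config A `run_config` from [default_config()] or
#'   [read_run_config()].
#' @return List of class `run_report` with per-stage summaries and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)
  tag <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  report <- list(seed = config$seed)
  state <- list()
  sim <- config$sim

  if (config$stages$simulate) tag("simulate", {
    freqs <- simulate_species_freqs(sim$m, sim$fst, seed = stage_seed(config, 1L))
    ped <- build_pedigree(sim$n_founders_A, sim$n_founders_B, sim$offspring)
    geno_true <- drop_genotypes(ped, freqs, seed = stage_seed(config, 2L))
    reads <- simulate_read_counts(geno_true, sim$mean_depth,
                                  sim$depth_dispersion, sim$error_rate,
                                  seed = stage_seed(config, 3L))
    genome <- simulate_genome(sim$genome$length, sim$genome$n_genes,
                              sim$genome$te_fraction, sim$genome$n_scaffolds,
                              sim$genome$unanchored_fraction,
                              seed = stage_seed(config, 4L))
    A <- pedigree_A(ped)
    fit_tab <- simulate_fitness(ped, inbreeding_true = diag(A) - 1,
                                gamma = sim$fitness$gamma,
                                beta1 = sim$fitness$beta1,
                                alpha = sim$fitness$alpha,
                                noise = sim$fitness$noise,
                                seed = stage_seed(config, 5L))
    # markers interleaved across scaffolds; inter-marker spacing ~0.4-2.4 kb
    # so the 1 kb spacing-pruned set keeps a usable marker panel
    scafs <- genome$scaffolds$name
    chrom <- scafs[1 + (seq_len(sim$m) - 1L) %% length(scafs)]
    pos <- integer(sim$m)
    for (sc in scafs) {
      i <- which(chrom == sc)
      pos[i] <- cumsum(sample(400:2400, length(i), replace = TRUE))
    }
    sites <- data.frame(chrom = chrom, pos = pos, id = colnames(geno_true),
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
    o <- order(sites$chrom, sites$pos)
    sites <- sites[o, ]
    geno_true <- geno_true[, o]
    reads$depth <- reads$depth[, o]
    reads$alt_reads <- reads$alt_reads[, o]
    write_variants(geno_true, sites, art("genotypes_true.vcf"))
    write.table(ped, art("pedigree.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(fit_tab, art("fitness.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(reads$depth, art("read_depth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(reads$alt_reads, art("read_alt.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_fasta(genome$sequences, art("genome.fasta"))
    write_gff3(genome, art("genes.gff3"))
    write_bed(genome$te, art("te.bed"))
    write.table(genome$scaffolds, art("scaffolds.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state <- list(ped = ped, geno_true = geno_true, reads = reads,
                  genome = genome, A = A, fitness = fit_tab, sites = sites)
    report$simulate <- list(n = nrow(ped), m = sim$m)
  }) else tag("simulate-reload", {
    geno_true <- read_variants(art("genotypes_true.vcf"))
    ped <- read.table(art("pedigree.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    depth <- read_matrix_tsv(art("read_depth.tsv"))
    alt <- read_matrix_tsv(art("read_alt.tsv"))
    rownames(depth) <- rownames(alt) <- ped$id
    state <- list(
      ped = ped, geno_true = geno_true, sites = attr(geno_true, "sites"),
      reads = structure(list(depth = depth, alt_reads = alt),
                        class = "site_call_table"),
      A = pedigree_A(ped),
      fitness = read.table(art("fitness.tsv"), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    )
    sc <- art("scaffolds.tsv")
    if (file.exists(sc))
      state$scaffolds <- read.table(sc, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  })
  scaffold_flags <- if (!is.null(state$genome))
    setNames(state$genome$scaffolds$anchored, state$genome$scaffolds$name)
  else if (!is.null(state$scaffolds))
    setNames(state$scaffolds$anchored, state$scaffolds$name)
  else NULL

  if (config$stages$design && !is.null(state$genome)) tag("design", {
    d <- design_targets(state$genome, window = config$design$window,
                        gc_min = config$design$gc_min,
                        gc_max = config$design$gc_max,
                        max_hits = config$design$max_hits)
    write_bed(d$targets, art("targets.bed"))
    write_bed(d$probes, art("probes.bed"))
    write_fasta(target_seqs(d$targets, state$genome), art("targets.fasta"))
    write.table(d$accounting, art("probe_accounting.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state$targets <- d$targets
    report$design <- list(n_targets = nrow(d$targets),
                          n_probes = nrow(d$probes))
  }) else if (file.exists(art("targets.bed"))) {
    tb <- read_bed(art("targets.bed"))
    names(tb)[names(tb) == "name"] <- "target_id"
    state$targets <- tb
  }

  if (config$stages$qc && !is.null(state$genome) &&
      !is.null(state$targets)) tag("qc", {
    aln <- simulate_alignments(state$genome, state$targets,
                               n_reads = config$qc$n_reads,
                               on_target_rate = config$qc$on_target_rate,
                               seed = stage_seed(config, 6L))
    write.table(aln, art("alignments.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ot <- on_target_fraction(aln, state$targets)
    bd <- breadth_and_depth(aln, state$targets)
    qc <- list(reads_on_target = ot$reads_on_target,
               targets_captured = ot$targets_captured,
               mean_breadth = bd$mean_breadth, mean_depth = bd$mean_depth)
    jsonlite::write_json(qc, art("qc_report.json"), auto_unbox = TRUE,
                         digits = NA)
    report$qc <- qc
  })

  if (config$stages$filter) tag("filter", {
    anchored <- if (!is.null(scaffold_flags))
      unname(scaffold_flags[state$sites$chrom]) else NULL
    casc <- filter_cascade(state$reads, anchored = anchored,
                           positions = state$sites$pos,
                           scaffold = state$sites$chrom,
                           cfg = config$filter, maf = config$maf)
    state$filtered <- casc
    keep_sites <- state$sites[match(colnames(casc$genotypes), state$sites$id), ]
    write_variants(casc$genotypes, keep_sites, art("genotypes_filtered.vcf"))
    report$filter <- casc$log
  }) else tag("filter-reload", {
    gf <- read_variants(art("genotypes_filtered.vcf"))
    st <- attr(gf, "sites")
    state$filtered <- list(
      genotypes = gf, positions = st$pos, scaffold = st$chrom,
      maf_mask = maf_tier(gf, config$maf),
      hwe_mask = hwe_retain(gf, config$filter),
      spacing_mask = ld_prune(gf, st$pos, st$chrom, config$filter,
                              mode = "spacing")
    )
  })

  if (config$stages$structure) tag("structure", {
    fl <- state$filtered
    mask <- fl$hwe_mask & fl$spacing_mask
    gs <- fl$genotypes[, mask, drop = FALSE]
    em <- admixture_em(gs, seed = stage_seed(config, 7L))
    species_hat <- assign_species(em$q)
    truth <- state$ped$species[match(rownames(gs), state$ped$id)]
    # cluster labels are arbitrary: align A/B to the truth by majority vote
    flipped <- chartr("AB", "BA", species_hat)
    if (mean(flipped == truth) > mean(species_hat == truth))
      species_hat <- flipped
    pure <- species_hat != "admixed"
    fst <- if (length(unique(species_hat[pure])) == 2)
      per_locus_fst(fl$genotypes[pure, fl$maf_mask, drop = FALSE],
                    species_hat[pure])
    else list(mean = NA_real_, median = NA_real_)
    write.table(data.frame(id = rownames(gs), q = unname(em$q),
                           species = species_hat, stringsAsFactors = FALSE),
                art("species_assignment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    state$species_hat <- setNames(species_hat, rownames(gs))
    report$structure <- list(n_markers = ncol(gs),
                             concordance = mean(species_hat == truth),
                             fst_mean = fst$mean, fst_median = fst$median)
  }) else if (file.exists(art("species_assignment.tsv"))) {
    sa <- read.table(art("species_assignment.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    state$species_hat <- setNames(sa$species, sa$id)
  }

  if (config$stages$relate) tag("relate", {
    fl <- state$filtered
    g <- fl$genotypes[, fl$maf_mask, drop = FALSE]
    G <- grm(g)
    inb <- genomic_inbreeding(G)
    A <- state$A[rownames(G), rownames(G)]
    cmp <- compare_realized_expected(G, A)
    write.table(round(G, 6), art("grm.tsv"), sep = "\t", quote = FALSE)
    write.table(data.frame(id = names(inb), inbreeding = unname(inb)),
                art("inbreeding.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(cmp, art("relatedness_vs_pedigree.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state$inbreeding <- inb
    report$relate <- list(m = attr(G, "m"), comparison = cmp)
  }) else if (file.exists(art("inbreeding.tsv"))) {
    it <- read.table(art("inbreeding.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    state$inbreeding <- setNames(it$inbreeding, it$id)
  }

  if (config$stages$fitness) tag("fitness", {
    ft <- state$fitness
    inb <- state$inbreeding[ft$id]
    keep <- !is.na(inb) & inb <= 0.5  # discard extreme-inbreeding outliers
    ft <- ft[keep, ]
    inb <- inb[keep]
    x1 <- env_pca(ft[, paste0("env", 1:5)])$scores
    pois <- fit_offspring_glm(ft$offspring_count, x1, inb)
    grow <- fit_growth_lm(ft$circumference, x1, inb, ft$age_at_cut)
    write.table(rbind(cbind(model = "poisson_offspring", pois$coefficients),
                      cbind(model = "linear_growth", grow$coefficients)),
                art("fitness_fits.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$fitness <- list(
      gamma_offspring = pois$coefficients$estimate[
        pois$coefficients$term == "inbreeding"],
      gamma_growth = grow$coefficients$estimate[
        grow$coefficients$term == "inbreeding"],
      n = nrow(ft)
    )
  })

  files <- setdiff(sort(list.files(config$out_dir)), "manifest.json")
  sums <- md5sum(file.path(config$out_dir, files))
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("standkin")),
    files = setNames(as.list(unname(sums)), files)
  )
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE)
  report$manifest <- manifest
  class(report) <- "run_report"
  report
}
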