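#' Write a genotype matrix to a VCF file
#'
#' Serializes a `{-1, 0, 1, NA}`-coded genotype matrix (individuals x
#' sites) as a minimal VCF 4.2 file with unphased `GT` fields: `-1` becomes
#' `0/0`, `0` becomes `0/1`, `+1` becomes `1/1`, and `NA` becomes `./.`.
#' An empty matrix yields a valid header-only file.
#'
#' @param genotypes Genotype matrix, individuals in rows.
#' @param sites Optional `data.frame` with columns `chrom`, `pos` (1-based),
#'   `id`, `ref`, `alt`, one row per site. Defaults to synthetic
#'   single-scaffold positions with A/G alleles.
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @seealso [read_variants()]
#' @export
write_variants <- function(genotypes, sites = NULL, path) {
  m <- ncol(genotypes)
  n <- nrow(genotypes)
  if (is.null(sites)) {
    sites <- data.frame(
      chrom = rep("scf01", m), pos = seq_len(m) * 100L,
      id = colnames(genotypes) %||% sprintf("S%05d", seq_len(m)),
      ref = rep("A", m), alt = rep("G", m), stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(sites) == m,
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(sites)))
  samples <- rownames(genotypes) %||% sprintf("ind%03d", seq_len(n))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=standkin",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  lines <- header
  if (m > 0 && n > 0) {
    gt <- matrix("./.", n, m)
    gt[which(genotypes == -1L)] <- "0/0"
    gt[which(genotypes == 0L)] <- "0/1"
    gt[which(genotypes == 1L)] <- "1/1"
    body <- vapply(seq_len(m), function(j) {
      paste(c(sites$chrom[j], sites$pos[j], sites$id[j], sites$ref[j],
              sites$alt[j], ".", "PASS", ".", "GT", gt[, j]),
            collapse = "\t")
    }, character(1))
    lines <- c(header, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genotype matrix from a VCF file
#'
#' Parses a VCF through \pkg{vcfR} and returns the package's
#' `{-1, 0, 1, NA}` coding (individuals x sites). Only diallelic records
#' are accepted. Genotypes other than `0/0`, `0/1`, `1/0`, `1/1` or missing
#' are reported with their record number.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return Genotype matrix with a `"sites"` attribute carrying `chrom`,
#'   `pos`, `id`, `ref`, `alt`.
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 2000L)
  hdr <- grep("^#CHROM", first, value = TRUE)
  if (length(hdr) == 0) stop("not a VCF file (no #CHROM header): ", path)
  n_records <- length(readLines(path)) - max(grep("^#", readLines(path)))
  cols <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  if (n_records == 0) {
    g <- matrix(NA_integer_, length(samples), 0,
                dimnames = list(samples, character()))
    attr(g, "sites") <- data.frame(chrom = character(), pos = integer(),
                                   id = character(), ref = character(),
                                   alt = character())
    return(g)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  # strip phase, normalize
  gt <- gsub("|", "/", gt_raw, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt %in% "0/0"] <- -1L
  code[gt %in% c("0/1", "1/0")] <- 0L
  code[gt %in% "1/1"] <- 1L
  bad <- !is.na(gt) & gt != "./." & is.na(code)
  if (any(bad)) {
    recs <- unique(row(gt)[bad])
    stop("malformed genotype(s) at record(s): ",
         paste(utils::head(recs, 10), collapse = ", "))
  }
  g <- t(code)
  rownames(g) <- colnames(gt_raw)
  colnames(g) <- fix$ID
  g <- g[samples, , drop = FALSE]
  attr(g, "sites") <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  g
}

#' Write genomic intervals as BED
#'
#' Intervals are kept in the package's native 0-based half-open convention,
#' which is BED's own; columns beyond the first three are written as BED
#' name/score/strand when present.
#'
#' @param x `data.frame` with `scaffold`, `start`, `end` and optionally
#'   `name` (or `gene_id`/`target_id`), `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- x$name %||% x$target_id %||% x$gene_id %||% x$probe_id %||%
    rep(".", nrow(x))
  df <- data.frame(x$scaffold, x$start, x$end, name,
                   x$score %||% rep(0, nrow(x)),
                   x$strand %||% rep(".", nrow(x)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into the package interval convention
#'
#' @param path BED path.
#' @return `data.frame` with `scaffold`, `start`, `end`, `name`
#'   (0-based half-open, as on disk).
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  out <- data.frame(scaffold = df[[1]], start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- df[[4]]
  out
}

#' Write gene models as GFF3
#'
#' Converts the internal 0-based half-open gene/exon tables to 1-based
#' closed GFF3 records.
#'
#' @param genome A `toy_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes
  e <- genome$exons
  lines <- "##gff-version 3"
  if (nrow(g)) {
    strand <- setNames(g$strand, g$gene_id)
    gl <- sprintf("%s\tstandkin\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  g$scaffold, g$start + 1L, g$end, g$strand, g$gene_id)
    el <- sprintf("%s\tstandkin\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                  e$scaffold, e$start + 1L, e$end,
                  strand[e$gene_id], e$gene_id)
    lines <- c(lines, gl, el)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read GFF3 gene models into the internal convention
#'
#' Parses `gene` and `exon` records of a GFF3 file and converts them to the
#' package's 0-based half-open tables.
#'
#' @param path GFF3 path.
#' @return List with `genes` and `exons` data frames.
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (!length(raw))
    return(list(genes = data.frame(), exons = data.frame()))
  f <- do.call(rbind, strsplit(raw, "\t", fixed = TRUE))
  attr_id <- function(a, key) sub(sprintf(".*%s=([^;]+).*", key), "\\1", a)
  is_gene <- f[, 3] == "gene"
  is_exon <- f[, 3] == "exon"
  genes <- data.frame(
    gene_id = attr_id(f[is_gene, 9], "ID"), scaffold = f[is_gene, 1],
    start = as.integer(f[is_gene, 4]) - 1L, end = as.integer(f[is_gene, 5]),
    strand = f[is_gene, 7], stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = attr_id(f[is_exon, 9], "Parent"), scaffold = f[is_exon, 1],
    start = as.integer(f[is_exon, 4]) - 1L, end = as.integer(f[is_exon, 5]),
    stringsAsFactors = FALSE
  )
  list(genes = genes, exons = exons)
}

#' Read an alignment-summary TSV
#'
#' Expected columns: `read_id`, `scaffold`, `start`, `end`, `read_length`
#' (intervals 0-based half-open). This is the desk-scale alignment input;
#' see [read_alignments_sam()] for SAM ingestion.
#'
#' @param path TSV path with header.
#' @return Alignment `data.frame`.
#' @export
read_alignments <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("read_id", "scaffold", "start", "end", "read_length")
  if (!all(need %in% names(df)))
    stop("alignment TSV must have columns: ", paste(need, collapse = ", "))
  if (any(df$end <= df$start)) stop("alignment intervals must satisfy end > start")
  df
}

#' Read alignments from a SAM file (optional reader)
#'
#' Converts a SAM text file to the alignment-summary table via
#' \pkg{Rsamtools} (suggested dependency).
#'
#' @param path SAM file path.
#' @return Alignment `data.frame` as from [read_alignments()].
#' @export
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required for SAM input")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  a <- Rsamtools::scanBam(bam)[[1]]
  keep <- !is.na(a$pos)
  data.frame(
    read_id = a$qname[keep], scaffold = as.character(a$rname[keep]),
    start = a$pos[keep] - 1L, end = a$pos[keep] - 1L + a$qwidth[keep],
    read_length = a$qwidth[keep], stringsAsFactors = FALSE
  )
}

#' Write sequences as FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet] (named).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
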