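# Plain-text I/O: tab-separated tables for genotypes, depths, phenotypes,
# linkage maps and alignments, plus a minimal GT-only VCF bridge.

#' Read and write the pipeline's tab-separated tables
#'
#' Genotype tables are wide (rows = individuals, columns = loci, dosages
#' 0/1/2/NA) with the identifier columns `individual`, `line`, `generation`,
#' `population`, `sex` in front. Depth tables are long
#' (`individual`, `locus`, `depth_a1`, `depth_a2`); maps carry `locus`,
#' `chromosome`, `cM`, `mapped`; alignments are BED-like
#' (`locus`, `genome`, `contig`, `start`, `end`, `mapq`; 0-based half-open).
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return `read_hatch_tsv()` returns a tibble; writers return `x`
#'   invisibly.
#' @export
read_hatch_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_hatch_tsv
#' @export
write_hatch_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' @rdname read_hatch_tsv
#' @export
read_genotypes_tsv <- function(path) {
  g <- read_hatch_tsv(path)
  for (l in geno_loci(g)) g[[l]] <- as.integer(g[[l]])
  g
}

#' Read a GT-only VCF into a wide genotype table
#'
#' Uses vcfR to parse the file; the dosage counts ALT alleles. Phasing is
#' ignored.
#'
#' @param path VCF path (plain or gzipped).
#' @param design Optional tibble mapping `individual` to `line`,
#'   `generation`, `population`, `sex`.
#' @return Wide genotype tibble.
#' @export
read_genotypes_vcf <- function(path, design = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_input("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  wide <- tibble::as_tibble(t(dos))
  wide <- dplyr::bind_cols(tibble::tibble(individual = colnames(dos)), wide)
  if (!is.null(design)) {
    keep <- intersect(names(design), GENO_ID_COLS)
    wide <- dplyr::left_join(wide, dplyr::distinct(design[keep]),
                             by = "individual")
    wide <- dplyr::relocate(wide, dplyr::any_of(GENO_ID_COLS))
  }
  wide
}

#' Write a wide genotype table as a minimal GT-only VCF
#'
#' Emits placeholder contigs/positions (locus order) and `GT` genotypes
#' (`0/0`, `0/1`, `1/1`, `./.`); intended for interchange with tools that
#' want VCF, not as a faithful variant record.
#'
#' @param gm Wide genotype tibble.
#' @param path Output path.
#' @param map Optional linkage map supplying `chromosome` (as contig) and
#'   `cM` (scaled to an integer position).
#' @return `gm`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path, map = NULL) {
  loci <- geno_loci(gm)
  X <- geno_matrix(gm)
  chrom <- rep("1", length(loci))
  pos <- seq_along(loci)
  if (!is.null(map)) {
    hit <- match(loci, map$locus)
    ok <- !is.na(hit)
    chrom[ok] <- as.character(map$chromosome[hit[ok]])
    pos[ok] <- round(map$cM[hit[ok]] * 1e4) + 1
  }
  gt_code <- c("0/0", "0/1", "1/1")
  lines_out <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individual), collapse = "\t"))
  body <- vapply(seq_along(loci), function(j) {
    g <- X[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(chrom[j], pos[j], loci[j], "A", "C", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines_out, body), path)
  invisible(gm)
}

#' Write every output of a simulated study to a directory
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hatch_tsv(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_hatch_tsv(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_hatch_tsv(sim$map, file.path(dir, "linkage_map.tsv"))
  if (!is.null(sim$depths)) {
    write_hatch_tsv(sim$depths, file.path(dir, "depths.tsv"))
  }
  if (!is.null(sim$alignments)) {
    write_hatch_tsv(sim$alignments, file.path(dir, "alignments.tsv"))
    write_hatch_tsv(sim$truth$alignment,
                    file.path(dir, "alignment_truth.tsv"))
  }
  invisible(dir)
}
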