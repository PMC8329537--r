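#' Write simulated genotypes to VCF
#'
#' Emits a biallelic-SNP VCF (GT field only, contigs = autosome names)
#' through vcfR. Internal 0-based marker coordinates become 1-based VCF
#' POS.
#'
#' @param genotypes Dosage matrix (markers x animals), `NA` = missing.
#' @param map Marker map tibble (`marker_id`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param path Output path; vcfR writes gzipped VCF, so use a
#'   `.vcf.gz` extension.
#' @return Invisibly `path`.
#' @export
write_genotypes_vcf <- function(genotypes, map, path) {
  stopifnot(nrow(genotypes) == nrow(map))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(genotypes), ncol(genotypes))
  ok <- !is.na(genotypes)
  gt[ok] <- gt_code[as.character(genotypes[ok])]
  gt <- cbind(FORMAT = "GT", gt)
  colnames(gt) <- c("FORMAT", colnames(genotypes))
  fix <- cbind(
    CHROM = map$chrom, POS = as.character(map$pos + 1L), ID = map$marker_id,
    REF = map$ref, ALT = map$alt, QUAL = ".", FILTER = "PASS", INFO = "."
  )
  meta <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(map$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses a biallelic-SNP VCF with vcfR into the package's internal
#' representation: a marker map (0-based positions) and an integer dosage
#' matrix.
#'
#' @param path VCF path (plain or gzipped).
#' @return List `map` (tibble `marker_id`, `chrom`, `pos`, `ref`, `alt`)
#'   and `genotypes` (dosage matrix markers x animals).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  map <- tibble::tibble(
    marker_id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"], alt = fix[, "ALT"]
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = list(map$marker_id, colnames(gt)))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  list(map = map, genotypes = dos)
}

#' Read a BED mask of excluded regions
#'
#' Three-column BED (`chrom`, `start`, `end`), 0-based half-open, as
#' consumed by [apply_region_mask()].
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_region_mask <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  col_types = "cii", comment = "#", progress = FALSE)
}

#' Write a synthetic bundle to the pipeline's standard input formats
#'
#' Writes `pedigree.csv`, `temperature.csv`, `genotypes.vcf.gz`,
#' `truth_meioses.csv`, and `truth_positions.csv` under `dir`.
#'
#' @param bundle A `recomb_bundle` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "recomb_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    pedigree = file.path(dir, "pedigree.csv"),
    temperature = file.path(dir, "temperature.csv"),
    genotypes = file.path(dir, "genotypes.vcf.gz"),
    meioses = file.path(dir, "truth_meioses.csv"),
    positions = file.path(dir, "truth_positions.csv")
  )
  readr::write_csv(bundle$pedigree, paths["pedigree"])
  readr::write_csv(bundle$temperature, paths["temperature"])
  write_genotypes_vcf(bundle$genotypes, bundle$map, paths["genotypes"])
  readr::write_csv(bundle$meioses, paths["meioses"])
  readr::write_csv(bundle$positions, paths["positions"])
  invisible(paths)
}

#' Read a pedigree CSV
#'
#' @param path CSV with columns `animal_id`, `sire_id`, `dam_id`, `sex`,
#'   `birth_date`, `farm_id`, `chip_class` (and optionally `generation`).
#' @return A tibble with `birth_date` parsed as Date.
#' @export
read_pedigree_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$birth_date <- as.Date(out$birth_date)
  out
}

#' Read a monthly temperature CSV
#'
#' @param path CSV with columns `farm_id`, `year`, `month`, `tavg_c`.
#' @return A tibble.
#' @export
read_temperature_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
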