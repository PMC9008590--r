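#' Write a synthetic population to plain-text files
#'
#' Emits `pedigree.csv` (unknown parents coded `UNKNOWN`), `genotypes.csv`
#' (dosages), `genotypes.vcf` (minimal biallelic VCF with GT fields),
#' `spectra.csv` (wide, `id, wl_0400, ...`), `trait.csv` and
#' `trueparams.json`.
#'
#' @param pop Population list from [simulate_population()].
#' @param dir Output directory (created if missing).
#' @param components Which files to write.
#' @return Invisibly, the paths written.
#' @export
write_population <- function(pop, dir,
                             components = c("pedigree", "genotypes", "vcf",
                                            "spectra", "trait", "true")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if ("pedigree" %in% components) {
    ped <- pop$pedigree
    ped$sire[is.na(ped$sire)] <- "UNKNOWN"
    ped$dam[is.na(ped$dam)] <- "UNKNOWN"
    p <- file.path(dir, "pedigree.csv")
    utils::write.csv(ped, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if ("genotypes" %in% components && !is.null(pop$genotypes)) {
    p <- file.path(dir, "genotypes.csv")
    utils::write.csv(as.data.frame(as_tibble(pop$genotypes)), p,
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if ("vcf" %in% components && !is.null(pop$genotypes)) {
    p <- file.path(dir, "genotypes.vcf")
    write_minimal_vcf(pop$genotypes, p)
    paths <- c(paths, p)
  }
  if ("spectra" %in% components && !is.null(pop$spectra)) {
    p <- file.path(dir, "spectra.csv")
    utils::write.csv(as.data.frame(as_tibble(pop$spectra)), p,
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if ("trait" %in% components && !is.null(pop$trait)) {
    p <- file.path(dir, "trait.csv")
    utils::write.csv(pop$trait, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if ("true" %in% components && !is.null(pop$true)) {
    p <- file.path(dir, "trueparams.json")
    tp <- pop$true
    tp$components <- NULL  # per-individual vectors stay in memory only
    jsonlite::write_json(unclass(tp), p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# minimal biallelic VCF with phased GT entries; read back with vcfR
write_minimal_vcf <- function(genotypes, path) {
  map <- genotypes$map
  ids <- rownames(genotypes$dosage)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%d>", sort(unique(map$chrom))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  gt <- matrix(paste(t(genotypes$h1), t(genotypes$h2), sep = "|"),
               nrow = ncol(genotypes$dosage))
  body <- cbind(map$chrom, as.integer(map$pos), map$marker, "A", "G", ".",
                "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a pedigree CSV (UNKNOWN parents become NA)
#' @param path CSV path with columns id, sire, dam, family, provenance,
#'   block (and optionally generation).
#' @return A pedigree tibble.
#' @export
read_pedigree <- function(path) {
  ped <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  for (col in c("sire", "dam")) {
    ped[[col]][ped[[col]] %in% c("UNKNOWN", "", "0")] <- NA_character_
  }
  if (!"generation" %in% names(ped)) {
    ped$generation <- ifelse(is.na(ped$sire) & is.na(ped$dam), 0L, 1L)
  }
  ped
}

#' Read wide spectra CSV into a cyp_spectra object
#' @param path CSV with `id` then `wl_<nm>` columns.
#' @return A `cyp_spectra` (without generator ground truth).
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[setdiff(names(df), "id")])
  rownames(X) <- df$id
  wl <- as.numeric(sub("wl_", "", colnames(X)))
  structure(list(reflectance = X, wavelength = wl),
            class = "cyp_spectra")
}

#' Read a dosage matrix from VCF
#'
#' Thin wrapper over vcfR; returns a `cyp_geno` without phase if the file
#' has unphased genotypes, with phase if all entries use `|`.
#'
#' @param path VCF path.
#' @return A `cyp_geno` list.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    rlang::abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- apply(gt, 2, function(col) {
    a <- substr(col, 1, 1); b <- substr(col, 3, 3)
    as.integer(a) + as.integer(b)
  })
  dos <- t(dos)
  phased <- all(grepl("\\|", gt))
  h1 <- if (phased) t(apply(gt, 2, function(col) as.integer(substr(col, 1, 1)))) else NULL
  h2 <- if (phased) t(apply(gt, 2, function(col) as.integer(substr(col, 3, 3)))) else NULL
  map <- tibble::tibble(
    marker = rownames(gt),
    chrom = as.integer(v@fix[, "CHROM"]),
    pos = as.numeric(v@fix[, "POS"]),
    freq = colMeans(dos) / 2
  )
  structure(list(dosage = dos, map = map, h1 = h1, h2 = h2),
            class = "cyp_geno")
}
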