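#' Read / write the plain-text interchange formats
#'
#' Pedigree CSV: `clone,sire,dam,cytoplasm` with `0` or empty for unknown
#' parents. Phenotype CSV: `clone,trait,value,year,block,replicate` with empty
#' fields for missing values. Dosage TSV: first column `clone`, remaining
#' columns marker dosages on the 0-4 scale, `NA` for missing. Relationship
#' matrices: TSV with a header row and first column of clone ids.
#'
#' @param path File path.
#' @name io
NULL

#' @rdname io
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  stopifnot(all(c("clone", "sire", "dam") %in% names(d)))
  if ("male_sterile" %in% names(d))
    d$male_sterile <- as.logical(d$male_sterile)
  sort_pedigree(d)
}

#' @rdname io
#' @param ped Pedigree data frame.
#' @export
write_pedigree <- function(ped, path) {
  d <- ped
  d$sire[is.na(d$sire)] <- "0"
  d$dam[is.na(d$dam)] <- "0"
  d$generation <- NULL
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("clone", "trait", "value") %in% names(d)))
  d$clone <- as.character(d$clone)
  d$value <- as.numeric(d$value)
  d
}

#' @rdname io
#' @param pheno Long-format phenotype table.
#' @export
write_phenotypes <- function(pheno, path) {
  d <- pheno
  d$value <- sprintf("%.17g", d$value)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_dosage <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  M <- as.matrix(d[, -1, drop = FALSE])
  rownames(M) <- as.character(d[[1]])
  storage.mode(M) <- "double"
  M
}

#' @rdname io
#' @param dosage Clones x markers dosage matrix.
#' @export
write_dosage <- function(dosage, path) {
  d <- data.frame(clone = rownames(dosage), dosage, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @param K Relationship matrix with clone dimnames.
#' @export
write_relationship_matrix <- function(K, path) {
  d <- data.frame(clone = rownames(K),
                  apply(unclass(K), 2, function(x) sprintf("%.17g", x)),
                  check.names = FALSE, stringsAsFactors = FALSE)
  colnames(d) <- c("clone", colnames(K))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_relationship_matrix <- function(path) {
  M <- read_dosage(path)
  stopifnot(identical(rownames(M), colnames(M)))
  M
}

#' Export a simulated diallel to plain-text files
#'
#' Writes `pedigree.csv`, `phenotypes.csv`, `dosages.tsv` and `truth.json`
#' into a directory. The truth file documents the generator's latent values
#' and is never read by the analysis code; the other three round-trip through
#' [read_pedigree()], [read_phenotypes()] and [read_dosage()] such that a
#' re-export is byte-identical.
#'
#' @param sim Result of [sim_diallel()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
sim_export <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  write_phenotypes(sim$pheno, file.path(dir, "phenotypes.csv"))
  write_dosage(sim$dosage, file.path(dir, "dosages.tsv"))
  tr <- sim$truth
  truth <- list(
    clones = rownames(tr$bv),
    bv = as.data.frame(tr$bv),
    line = as.data.frame(tr$line),
    family = as.data.frame(tr$family),
    seed = tr$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}
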