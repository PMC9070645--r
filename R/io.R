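# Plain-text readers/writers for the package's tabular interfaces:
# dosage CSV (individuals x markers), marker map CSV, pedigree CSV,
# phenotype CSV and a minimal VCFv4.2 emitter (GT only, phased for
# parents).  VCF reading goes through vcfR when available.

#' Write / read a dosage matrix as CSV
#'
#' The dosage CSV has one row per individual (first column \code{id}) and
#' one column per marker; the marker map is stored alongside as its own
#' CSV (columns marker, chrom, pos_bp, pos_cM).
#'
#' @param d a \code{\linkS4class{DosageMatrix}}.
#' @param path output CSV path; the map goes to \code{mapPath}.
#' @param mapPath map CSV path (default: path with "_map" suffix).
#' @return \code{readDosageCSV} returns a \code{DosageMatrix}.
#' @export
writeDosageCSV <- function(d, path, mapPath = defaultMapPath(path)) {
  x <- dosages(d)
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(markerMap(d), mapPath, row.names = FALSE, quote = FALSE)
  invisible(path)
}

defaultMapPath <- function(path) sub("(\\.[^.]*)?$", "_map.csv",
                                     sub("\\.csv$", "", path))

#' @rdname writeDosageCSV
#' @export
readDosageCSV <- function(path, mapPath = defaultMapPath(path)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  map <- utils::read.csv(mapPath, stringsAsFactors = FALSE)
  new("DosageMatrix", dosages = x, map = map)
}

#' Write a pedigree CSV (offspring, cross, parent1, parent2)
#'
#' @param population population table with offspring rows.
#' @param path output path.
#' @export
writePedigreeCSV <- function(population, path) {
  off <- population[population$role == "offspring",
                    c("individual", "cross", "parent1", "parent2")]
  names(off)[1] <- "offspring"
  utils::write.csv(off, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read long-format phenotype records
#'
#' Columns: genotype, cross, block, year, x, y, trait, value.
#'
#' @param records phenotype data.frame; @param path CSV path.
#' @export
writePhenotypesCSV <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePhenotypesCSV
#' @export
readPhenotypesCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write genotypes as a VCF (v4.2, GT field)
#'
#' Dosages are encoded as unphased GT (0 -> 0/0, 1 -> 0/1, 2 -> 1/1);
#' individuals present in \code{phased} are written with phased genotypes
#' (hapA|hapB).  REF/ALT are placeholder alleles A/B; the dosage counts
#' the ALT allele.
#'
#' @param d a \code{\linkS4class{DosageMatrix}} with integer dosages.
#' @param path output path (plain text).
#' @param phased optional \code{\linkS4class{PhasedGenotypes}} for a
#'   subset of individuals.
#' @export
writeDosageVCF <- function(d, path, phased = NULL) {
  x <- dosages(d)
  if (any(!(x %in% c(0, 1, 2))))
    stop("VCF output requires integer dosages")
  map <- markerMap(d)
  ids <- rownames(x)
  gt <- matrix("", nrow(map), length(ids))
  code <- c("0/0", "0/1", "1/1")
  for (i in seq_along(ids)) gt[, i] <- code[x[i, ] + 1]
  if (!is.null(phased)) {
    pids <- intersect(ids, individualIds(phased))
    for (id in pids) {
      ia <- phased@hapA[id, ]; ib <- phased@hapB[id, ]
      gt[, match(id, ids)] <- paste0(ia, "|", ib)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  body <- cbind(map$chrom, map$pos_bp, map$marker, "A", "B", ".", ".",
                ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a biallelic-SNP VCF into a DosageMatrix
#'
#' Uses vcfR to parse the file and counts ALT alleles in the GT field;
#' positions in cM default to 1 cM per Mb when no genetic map is given.
#'
#' @param path VCF path.
#' @param cmPerMb genetic-to-physical scaling for the cM positions.
#' @return a \code{\linkS4class{DosageMatrix}}.
#' @export
readDosageVCF <- function(path, cmPerMb = 1) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- function(g) {
    g <- gsub("\\|", "/", g)
    ifelse(is.na(g) | g == "./.", NA_real_,
           vapply(strsplit(g, "/", fixed = TRUE),
                  function(p) sum(p == "1"), numeric(1)))
  }
  d <- apply(gt, 1, alt)            # samples x variants
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(colnames(gt)))
  fix <- vcfR::getFIX(v)
  map <- data.frame(marker = fix[, "ID"], chrom = fix[, "CHROM"],
                    pos_bp = as.integer(fix[, "POS"]),
                    pos_cM = as.numeric(fix[, "POS"]) / 1e6 * cmPerMb,
                    stringsAsFactors = FALSE)
  colnames(d) <- map$marker
  new("DosageMatrix", dosages = d, map = map)
}
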