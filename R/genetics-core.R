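#' @useDynLib rfmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Single-character genotype codes used throughout:
#   A = homozygous for the CMS (female-parent) allele
#   B = homozygous for the restorer (male-parent) allele
#   H = heterozygous
#   - = missing call
GENOTYPE_CODES <- c("A", "B", "H", "-")

PHENOTYPES <- c("FERTILE", "STERILE")

LINE_ROLES <- c("CMS", "RESTORER", "MAINTAINER")

#' Construct a marker panel
#'
#' A marker panel describes the genotyped loci: name, chromosome, 1-based
#' physical position, and marker class (SSR or InDel length polymorphism).
#'
#' @param marker character vector of unique marker names.
#' @param chromosome character vector (recycled if length 1).
#' @param pos_bp integer-like vector of 1-based positions, all >= 1.
#' @param marker_class "SSR" or "InDel" (recycled if length 1).
#' @return A `data.frame` of class `marker_panel`.
#' @export
marker_panel <- function(marker, chromosome, pos_bp, marker_class = "SSR") {
  marker <- as.character(marker)
  if (anyDuplicated(marker))
    stop("duplicate marker names in panel: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  pos_bp <- as.numeric(pos_bp)
  if (any(is.na(pos_bp)) || any(pos_bp < 1))
    stop("marker positions must be 1-based (>= 1)")
  if (!all(marker_class %in% c("SSR", "InDel")))
    stop("marker_class must be 'SSR' or 'InDel'")
  out <- data.frame(marker = marker,
                    chromosome = rep_len(as.character(chromosome), length(marker)),
                    pos_bp = pos_bp,
                    marker_class = rep_len(marker_class, length(marker)),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Construct an F2 population table
#'
#' @param plant_id character vector of unique plant identifiers.
#' @param phenotype character vector of "FERTILE"/"STERILE".
#' @param calls data.frame or matrix of genotype calls (one column per
#'   marker) using the codes A/B/H/-.
#' @return A `data.frame` of class `f2_population` with columns `plant_id`,
#'   `phenotype`, then one column per marker.
#' @export
f2_population <- function(plant_id, phenotype, calls) {
  plant_id <- as.character(plant_id)
  if (anyDuplicated(plant_id))
    stop("duplicate plant id: ",
         paste(unique(plant_id[duplicated(plant_id)]), collapse = ", "))
  phenotype <- as.character(phenotype)
  if (!all(phenotype %in% PHENOTYPES))
    stop("phenotype must be one of: ", paste(PHENOTYPES, collapse = ", "))
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  for (j in seq_along(calls)) {
    cj <- as.character(calls[[j]])
    bad <- !(cj %in% GENOTYPE_CODES)
    if (any(bad))
      stop("invalid genotype symbol '", cj[which(bad)[1]], "' at marker ",
           names(calls)[j], " (allowed: A, B, H, -)")
    calls[[j]] <- cj
  }
  out <- cbind(data.frame(plant_id = plant_id, phenotype = phenotype,
                          stringsAsFactors = FALSE), calls)
  class(out) <- c("f2_population", "data.frame")
  out
}

marker_names <- function(pop) setdiff(names(pop), c("plant_id", "phenotype"))

read_tsv_lines <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  list(lines = raw[keep], lineno = which(keep))
}

#' Read a genotype/phenotype table
#'
#' Tab-separated, '#' comment lines ignored. The header row names the
#' columns: `plant_id`, `phenotype`, then one column per marker. Genotype
#' calls use the single characters A (homozygous CMS-parent allele), B
#' (homozygous restorer-parent allele), H (heterozygous), '-' (missing).
#'
#' @param path path to a tab-separated text file.
#' @return An `f2_population` data.frame.
#' @export
read_genotype_table <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) < 2L) stop("genotype table needs a header and >= 1 row: ", path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (!all(c("plant_id", "phenotype") %in% header))
    stop("genotype table header must contain 'plant_id' and 'phenotype'")
  ncol <- length(header)
  rows <- fields[-1L]
  linenos <- tl$lineno[-1L]
  bad <- which(vapply(rows, length, 0L) != ncol)
  if (length(bad))
    stop("malformed row at line ", linenos[bad[1L]], ": expected ",
         ncol, " tab-separated fields")
  mat <- do.call(rbind, rows)
  colnames(mat) <- header
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  markers <- setdiff(header, c("plant_id", "phenotype"))
  for (m in markers) {
    bad <- !(df[[m]] %in% GENOTYPE_CODES)
    if (any(bad))
      stop("invalid genotype symbol '", df[[m]][which(bad)[1]],
           "' at line ", linenos[which(bad)[1]], ", marker ", m)
  }
  f2_population(df$plant_id, df$phenotype, df[, markers, drop = FALSE])
}

#' Write a genotype/phenotype table
#'
#' Inverse of [read_genotype_table()]; tab-separated with a header line.
#'
#' @param pop an `f2_population`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(pop, path) {
  utils::write.table(as.data.frame(pop), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a marker definition table
#'
#' Tab-separated with header `marker`, `chromosome`, `pos_bp`, and
#' optionally `marker_class`.
#'
#' @param path path to a tab-separated text file.
#' @return A `marker_panel`.
#' @export
read_marker_panel <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "pos_bp")
  if (!all(need %in% names(df)))
    stop("marker panel must have columns: ", paste(need, collapse = ", "))
  cls <- if ("marker_class" %in% names(df)) df$marker_class else "SSR"
  marker_panel(df$marker, df$chromosome, df$pos_bp, cls)
}

#' Read sequences from FASTA
#'
#' Sequences are upper-cased; names are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
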