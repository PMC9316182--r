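#' Classify the coding consequence of a single-nucleotide substitution
#'
#' Translates the affected codon before and after the substitution under
#' the standard nuclear genetic code. For a stop-loss, the supplied
#' sequence may extend past the annotated stop; the read-through extension
#' is measured as the number of codons translated after the mutated codon
#' before the next in-frame stop.
#'
#' @param cds coding (plus optional downstream) nucleotide sequence,
#'   in-frame from position 1.
#' @param offset 1-based position of the substituted base within `cds`.
#' @param ref,alt reference and alternate nucleotides; `cds` must carry
#'   `ref` at `offset`.
#' @return List of class `variant_effect`: `consequence` (one of MISSENSE,
#'   SYNONYMOUS, STOP_LOSS, STOP_GAIN), `ref_aa`, `alt_aa`, and for a
#'   stop-loss `extension_aa` (`NA` with an `unbounded_extension` flag when
#'   no downstream in-frame stop exists in the supplied sequence).
#' @export
classify_variant <- function(cds, offset, ref, alt) {
  cds <- toupper(cds)
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) stop("ref and alt alleles must differ")
  n <- nchar(cds)
  if (offset < 1 || offset > n) stop("offset outside supplied sequence")
  have <- substr(cds, offset, offset)
  if (have != ref)
    stop("reference allele mismatch at offset ", offset, ": sequence has '",
         have, "', expected '", ref, "'")
  codon_i <- (offset - 1) %/% 3
  cstart <- codon_i * 3 + 1
  if (cstart + 2 > n) stop("affected codon truncated by end of sequence")
  codon_ref <- substr(cds, cstart, cstart + 2)
  pos_in <- offset - cstart + 1
  codon_alt <- codon_ref
  substr(codon_alt, pos_in, pos_in) <- alt
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon_ref])
  aa_alt <- unname(code[codon_alt])
  if (is.na(aa_ref) || is.na(aa_alt))
    stop("ambiguous or non-nucleotide codon: ", codon_ref, "/", codon_alt)
  out <- list(ref_aa = aa_ref, alt_aa = aa_alt)
  if (aa_ref == aa_alt) {
    out$consequence <- "SYNONYMOUS"
  } else if (aa_ref == "*" && aa_alt != "*") {
    out$consequence <- "STOP_LOSS"
    ext <- 0L
    i <- cstart + 3
    found <- FALSE
    while (i + 2 <= n) {
      if (code[substr(cds, i, i + 2)] == "*") { found <- TRUE; break }
      ext <- ext + 1L
      i <- i + 3
    }
    if (found) {
      out$extension_aa <- ext
      out$unbounded_extension <- FALSE
    } else {
      out$extension_aa <- NA_integer_
      out$unbounded_extension <- TRUE
      warning("no in-frame stop downstream of the lost stop codon within ",
              "the supplied sequence; extension is unbounded")
    }
  } else if (aa_alt == "*") {
    out$consequence <- "STOP_GAIN"
  } else {
    out$consequence <- "MISSENSE"
  }
  class(out) <- "variant_effect"
  out
}

#' Construct a line-by-site variant allele matrix
#'
#' Holds homozygous allele calls for a panel of inbred lines at candidate
#' variant sites, together with the two reference haplotypes: the CMS line
#' and the restorer line whose cross defined the mapping population.
#'
#' @param lines data.frame with columns `line`, `role` (CMS, RESTORER, or
#'   MAINTAINER).
#' @param sites data.frame with columns `gene`, `cds_offset`, `cms_allele`,
#'   `restorer_allele`, `consequence`; site ids are `gene_offset`.
#' @param alleles character matrix, rows = lines, columns = site ids.
#' @param ref_cms,ref_restorer names of the two reference lines.
#' @return List of class `variant_matrix`.
#' @export
variant_matrix <- function(lines, sites, alleles, ref_cms, ref_restorer) {
  if (!all(lines$role %in% LINE_ROLES))
    stop("line roles must be one of: ", paste(LINE_ROLES, collapse = ", "))
  site_id <- paste(sites$gene, sites$cds_offset, sep = "_")
  if (!identical(sort(colnames(alleles)), sort(site_id)))
    stop("allele matrix columns must match site ids (gene_offset)")
  alleles <- alleles[lines$line, site_id, drop = FALSE]
  if (anyNA(alleles)) stop("every line needs a call at every site")
  if (!all(c(ref_cms, ref_restorer) %in% lines$line))
    stop("reference lines must appear in the line table")
  same <- sites$cms_allele == sites$restorer_allele
  if (any(same))
    stop("CMS and restorer reference alleles identical at site ",
         site_id[which(same)[1]])
  out <- list(lines = lines, sites = cbind(sites, site_id = site_id),
              alleles = alleles, ref_cms = ref_cms,
              ref_restorer = ref_restorer)
  class(out) <- "variant_matrix"
  out
}

select_sites <- function(vm, gene, sites = NULL,
                         consequences = c("MISSENSE", "STOP_LOSS", "STOP_GAIN")) {
  st <- vm$sites[vm$sites$gene == gene, , drop = FALSE]
  if (nrow(st) == 0L) stop("no sites for gene ", gene)
  if (!is.null(sites)) {
    miss <- setdiff(sites, st$cds_offset)
    if (length(miss))
      stop("site(s) not present for ", gene, ": ", paste(miss, collapse = ", "))
    st <- st[st$cds_offset %in% sites, , drop = FALSE]
  }
  if (!is.null(consequences))
    st <- st[st$consequence %in% consequences, , drop = FALSE]
  if (nrow(st) == 0L)
    stop("no sites left for ", gene, " after consequence filtering")
  st
}

score_lines <- function(vm, st) {
  scored <- vm$lines[!(vm$lines$line %in% c(vm$ref_cms, vm$ref_restorer)), ,
                     drop = FALSE]
  ids <- st$site_id
  expected <- function(role)
    if (role == "MAINTAINER") st$cms_allele else st$restorer_allele
  verdicts <- vapply(seq_len(nrow(scored)), function(i) {
    obs <- vm$alleles[scored$line[i], ids]
    exp <- expected(scored$role[i])
    alien <- obs != st$cms_allele & obs != st$restorer_allele
    if (any(alien))
      warning("line ", scored$line[i],
              " carries an allele matching neither reference at site(s) ",
              paste(ids[alien], collapse = ", "))
    all(obs == exp)
  }, TRUE)
  data.frame(line = scored$line, role = scored$role, concordant = verdicts,
             stringsAsFactors = FALSE)
}

#' Variant-trait concordance across maintainer and restorer lines
#'
#' A maintainer line is concordant when its allele equals the CMS-line
#' reference at every scored site of the gene; a restorer line when it
#' equals the restorer-line reference at every scored site. The two
#' reference lines themselves are excluded from the denominator. By
#' default only non-synonymous (sense) sites are scored.
#'
#' @param vm a `variant_matrix`.
#' @param gene gene name.
#' @param sites optional subset of that gene's `cds_offset` values.
#' @param consequences consequence classes eligible for scoring; default
#'   all non-synonymous classes.
#' @return List of class `concordance_result`: `gene`, `sites`
#'   (data.frame), `per_line` (line, role, concordant), `n_concordant`,
#'   `n_lines`, `fraction`, `percent`.
#' @export
concordance_score <- function(vm, gene, sites = NULL,
                              consequences = c("MISSENSE", "STOP_LOSS",
                                               "STOP_GAIN")) {
  st <- select_sites(vm, gene, sites, consequences)
  per_line <- score_lines(vm, st)
  n <- nrow(per_line)
  k <- sum(per_line$concordant)
  out <- list(gene = gene, sites = st, per_line = per_line,
              n_concordant = k, n_lines = n, fraction = k / n,
              percent = round(100 * k / n, 2))
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("%s: %d/%d lines concordant (%.2f%%) at site(s) %s\n",
              x$gene, x$n_concordant, x$n_lines, 100 * x$fraction,
              paste(x$sites$cds_offset, collapse = ", ")))
  invisible(x)
}

#' Single-site detection accuracy of a CAPS-style assay
#'
#' Scores concordance restricted to one polymorphic site, modelling a CAPS
#' marker that reads a single nucleotide difference as restriction-site
#' presence/absence.
#'
#' @param vm a `variant_matrix`.
#' @param gene gene name.
#' @param site a single `cds_offset`.
#' @return A `concordance_result` for that site.
#' @export
caps_accuracy <- function(vm, gene, site) {
  if (length(site) != 1L) stop("caps_accuracy scores exactly one site")
  concordance_score(vm, gene, sites = site, consequences = NULL)
}

#' Genes whose annotated span intersects a mapped interval
#'
#' @param annotation data.frame with columns `gene`, `start`, `end`
#'   (1-based, inclusive).
#' @param interval a `mapped_interval` (or list with `left_pos`,
#'   `right_pos`).
#' @return The intersecting rows of `annotation`.
#' @export
genes_in_interval <- function(annotation, interval) {
  if (nrow(annotation) == 0L) return(annotation)
  hit <- annotation$end >= interval$left_pos &
    annotation$start <= interval$right_pos
  annotation[hit, , drop = FALSE]
}
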