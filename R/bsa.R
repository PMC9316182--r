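#' Compose fertile and sterile DNA bulks
#'
#' Randomly selects `n_per_bulk` plants from each phenotype class and
#' records, per marker, the set of parental alleles present in the bulk: an
#' 'A' call contributes the CMS-parent allele, 'B' the restorer-parent
#' allele, 'H' both, '-' neither. This models the band presence/absence
#' readout of a pooled PCR on a silver-stained gel, not allele dosage.
#'
#' @param pop an `f2_population`.
#' @param n_per_bulk plants per bulk (default 10).
#' @param seed integer seed; selection is reproducible under it.
#' @return List of class `bsa_bulks` with elements `fertile` and `sterile`,
#'   each a list with `members` (plant ids) and `pattern` (data.frame
#'   `marker`, `has_A`, `has_B`).
#' @export
compose_bulks <- function(pop, n_per_bulk = 10L, seed) {
  if (missing(seed)) stop("a seed must be supplied; bulk selection is random")
  for (ph in PHENOTYPES) {
    n <- sum(pop$phenotype == ph)
    if (n < n_per_bulk)
      stop("phenotype class ", ph, " has only ", n,
           " plants; need ", n_per_bulk, " per bulk")
  }
  set.seed(seed)
  one <- function(ph) {
    ids <- pop$plant_id[pop$phenotype == ph]
    members <- sort(sample(ids, n_per_bulk))
    sub <- pop[pop$plant_id %in% members, , drop = FALSE]
    mk <- marker_names(pop)
    has_A <- vapply(mk, function(m) any(sub[[m]] %in% c("A", "H")), TRUE)
    has_B <- vapply(mk, function(m) any(sub[[m]] %in% c("B", "H")), TRUE)
    list(members = members,
         pattern = data.frame(marker = mk, has_A = unname(has_A),
                              has_B = unname(has_B), stringsAsFactors = FALSE))
  }
  out <- list(fertile = one("FERTILE"), sterile = one("STERILE"))
  class(out) <- "bsa_bulks"
  out
}

#' Screen markers for polymorphism between the two inbred parents
#'
#' @param parent_a,parent_b named character vectors of homozygous genotype
#'   calls ('A' or 'B') for the CMS and restorer parent; names are marker
#'   names and must agree.
#' @return Character vector of markers whose parental calls differ.
#' @export
screen_parent_polymorphic <- function(parent_a, parent_b) {
  if (!setequal(names(parent_a), names(parent_b)))
    stop("parent call vectors must cover the same markers")
  parent_b <- parent_b[names(parent_a)]
  het <- parent_a == "H" | parent_b == "H"
  if (any(het))
    stop("heterozygous parent call at marker ",
         names(parent_a)[which(het)[1]], "; parents must be inbred")
  names(parent_a)[parent_a != parent_b]
}

#' Screen markers whose bulk allele patterns differ
#'
#' A marker is a linkage candidate when the allele sets of the fertile and
#' sterile bulks are unequal; near the trait locus the sterile bulk carries
#' only the CMS-parent allele while the fertile bulk shows both.
#'
#' @param bulks result of [compose_bulks()].
#' @param markers markers to screen (already parent-polymorphic); default
#'   all markers in the bulks.
#' @return Character vector of flagged markers.
#' @export
screen_bulk_polymorphic <- function(bulks, markers = NULL) {
  pf <- bulks$fertile$pattern
  ps <- bulks$sterile$pattern
  if (is.null(markers)) markers <- pf$marker
  pf <- pf[match(markers, pf$marker), ]
  ps <- ps[match(markers, ps$marker), ]
  if (anyNA(pf$marker) || anyNA(ps$marker))
    stop("marker not present in bulks")
  differ <- pf$has_A != ps$has_A | pf$has_B != ps$has_B
  markers[differ]
}
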