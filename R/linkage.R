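#' Tally recombinant genotypes among sterile (homozygous-recessive) plants
#'
#' In a recessive-class mapping design every sterile F2 plant is homozygous
#' for the CMS allele at the trait locus, so any restorer-parent allele it
#' carries at a marker marks a recombinant chromosome: a 'B' call means two
#' recombinant chromosomes (HO), an 'H' call one (HE). 'A' calls are
#' non-recombinant; missing calls are excluded from the denominator.
#'
#' @param pop an `f2_population` of sterile plants only.
#' @param marker marker (column) name.
#' @return List of class `recomb_tally`: `marker`, `n_ho`, `n_he`,
#'   `n_total`.
#' @export
tally_recombinants <- function(pop, marker) {
  if (any(pop$phenotype != "STERILE"))
    stop("recessive-class tally requires sterile plants only; found ",
         sum(pop$phenotype != "STERILE"), " fertile plant(s)")
  calls <- pop[[marker]]
  if (is.null(calls)) stop("marker not in population table: ", marker)
  out <- list(marker = marker,
              n_ho = sum(calls == "B"),
              n_he = sum(calls == "H"),
              n_total = sum(calls != "-"))
  class(out) <- "recomb_tally"
  out
}

#' Recessive-class recombination fraction
#'
#' \eqn{c = (N_1 + N_2/2)/N} where \eqn{N_1} is the number of sterile
#' plants homozygous for the restorer-parent marker allele, \eqn{N_2} the
#' number heterozygous, and \eqn{N} the sterile plants scored.
#'
#' @param n_ho,n_he,n_total counts, or pass a `recomb_tally` as `n_ho`.
#' @return Recombination fraction in `[0, 1]`. Values `>= 0.5` indicate an
#'   unlinked marker and are rejected by [kosambi_cm()].
#' @export
recombination_fraction <- function(n_ho, n_he = NULL, n_total = NULL) {
  if (inherits(n_ho, "recomb_tally")) {
    t <- n_ho
    n_ho <- t$n_ho; n_he <- t$n_he; n_total <- t$n_total
  }
  if (n_total <= 0) stop("n_total must be positive")
  if (n_ho + n_he > n_total) stop("recombinant counts exceed n_total")
  (n_ho + n_he / 2) / n_total
}

#' Kosambi map function
#'
#' Converts a recombination fraction to genetic distance,
#' \eqn{d = \frac{1}{4}\ln\frac{1+2c}{1-2c}} Morgans, returned in
#' centimorgans (x100). The natural logarithm is used.
#'
#' @param c recombination fraction(s) in `[0, 0.5)`.
#' @return Distance in cM.
#' @export
kosambi_cm <- function(c) {
  if (any(c < 0) || any(c >= 0.5))
    stop("Kosambi distance requires 0 <= c < 0.5 (c >= 0.5 is unlinked)")
  100 * 0.25 * log((1 + 2 * c) / (1 - 2 * c))
}

#' Inverse Kosambi map function
#'
#' @param d_cm distance(s) in cM.
#' @return Recombination fraction.
#' @export
kosambi_inv <- function(d_cm) {
  d <- d_cm / 100
  0.5 * (exp(4 * d) - 1) / (exp(4 * d) + 1)
}

map_from_counts <- function(marker, pos_bp, n_ho, n_he, n_total) {
  c_hat <- (n_ho + n_he / 2) / n_total
  ord <- order(pos_bp)
  df <- data.frame(marker = marker, pos_bp = pos_bp,
                   n_ho = n_ho, n_he = n_he, n_total = n_total,
                   c = c_hat, stringsAsFactors = FALSE)[ord, ]
  df$d_cm <- ifelse(df$c < 0.5, kosambi_cm(pmin(df$c, 0.5 - 1e-15)), NA_real_)
  df$d_cm[df$c >= 0.5] <- NA_real_
  cmin <- min(df$c)
  if (cmin > 0)
    warning("no co-segregating marker (min c = ", signif(cmin, 3),
            "); sides assigned relative to the minimum-c marker(s)")
  block <- df$pos_bp[df$c == cmin]
  lo <- min(block); hi <- max(block)
  mid <- (lo + hi) / 2
  df$side <- ifelse(df$c == cmin, "COSEGREGATING",
                    ifelse(df$pos_bp < lo, "LEFT",
                           ifelse(df$pos_bp > hi, "RIGHT",
                                  ifelse(df$pos_bp <= mid, "LEFT", "RIGHT"))))
  rownames(df) <- NULL
  class(df) <- c("linkage_map", "data.frame")
  df
}

#' Build a marker linkage map from sterile-class genotypes
#'
#' Tallies recombinants per marker, estimates the recombination fraction,
#' converts to Kosambi cM, and assigns each marker a side relative to the
#' zero-recombinant (co-segregating) block by physical position. Markers
#' with an estimated fraction at the minimum are labelled COSEGREGATING;
#' markers with c >= 0.5 get `NA` distance (unlinked).
#'
#' @param pop an `f2_population` of sterile plants.
#' @param panel a `marker_panel` restricted to the markers to map.
#' @return A `linkage_map` data.frame ordered by physical position:
#'   `marker`, `pos_bp`, `n_ho`, `n_he`, `n_total`, `c`, `d_cm`, `side`.
#' @export
build_map <- function(pop, panel) {
  if (nrow(panel) < 1L) stop("empty marker panel")
  keep <- panel$marker %in% marker_names(pop)
  if (!any(keep)) stop("no panel marker present in the population table")
  panel <- panel[keep, ]
  tl <- lapply(panel$marker, function(m) tally_recombinants(pop, m))
  map_from_counts(panel$marker, panel$pos_bp,
                  vapply(tl, `[[`, 0, "n_ho"),
                  vapply(tl, `[[`, 0, "n_he"),
                  vapply(tl, `[[`, 0, "n_total"))
}

#' Build a linkage map directly from recombinant tallies
#'
#' For published-table inputs where per-plant genotypes are not available:
#' takes marker names, physical positions, and HO/HE recombinant counts.
#'
#' @param tallies data.frame with columns `marker`, `pos_bp`, `n_ho`,
#'   `n_he`, `n_total`.
#' @return A `linkage_map`, as [build_map()].
#' @export
map_from_tallies <- function(tallies) {
  need <- c("marker", "pos_bp", "n_ho", "n_he", "n_total")
  if (!all(need %in% names(tallies)))
    stop("tallies must have columns: ", paste(need, collapse = ", "))
  map_from_counts(tallies$marker, tallies$pos_bp, tallies$n_ho,
                  tallies$n_he, tallies$n_total)
}

#' Localize the trait locus between flanking markers
#'
#' The locus is placed inside the block of co-segregating markers; the
#' reported interval runs from the nearest recombinant marker physically
#' left of the leftmost zero-c marker to the nearest recombinant marker
#' right of the rightmost zero-c marker. A recombinant marker lying
#' physically inside the co-segregating block (a genotyping inconsistency)
#' is tolerated with a warning and does not shrink the interval.
#'
#' @param map a `linkage_map`.
#' @return List of class `mapped_interval`: `left_marker`, `right_marker`,
#'   `left_pos`, `right_pos`, `span_bp`, `span_kb` (rounded to 2 dp).
#' @export
locate_interval <- function(map) {
  cmin <- min(map$c)
  if (cmin > 0)
    warning("no marker fully co-segregates; interval anchored on the ",
            "minimum-c block (c = ", signif(cmin, 3), ")")
  block <- map[map$c == cmin, ]
  lo <- min(block$pos_bp); hi <- max(block$pos_bp)
  inside <- map$c > cmin & map$pos_bp > lo & map$pos_bp < hi
  if (any(inside))
    warning("recombinant marker(s) inside the co-segregating block: ",
            paste(map$marker[inside], collapse = ", "))
  left <- map[map$c > cmin & map$pos_bp < lo, ]
  right <- map[map$c > cmin & map$pos_bp > hi, ]
  if (nrow(left) == 0L)
    stop("open interval: co-segregating block touches the LEFT edge of the panel")
  if (nrow(right) == 0L)
    stop("open interval: co-segregating block touches the RIGHT edge of the panel")
  lm <- left[which.max(left$pos_bp), ]
  rm <- right[which.min(right$pos_bp), ]
  span <- rm$pos_bp - lm$pos_bp
  out <- list(left_marker = lm$marker, right_marker = rm$marker,
              left_pos = lm$pos_bp, right_pos = rm$pos_bp,
              span_bp = span, span_kb = round(span / 1000, 2))
  class(out) <- "mapped_interval"
  out
}

#' @export
print.mapped_interval <- function(x, ...) {
  cat(sprintf("locus mapped between %s and %s (%s..%s), span %.2f kb\n",
              x$left_marker, x$right_marker,
              format(x$left_pos, big.mark = ","),
              format(x$right_pos, big.mark = ","), x$span_kb))
  invisible(x)
}
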