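#' Specify a crossover model for F2 simulation
#'
#' Markers are placed on a genetic map (cM) alongside the trait locus;
#' gametes are generated without crossover interference (Haldane/Poisson
#' model): the crossover count on the map is Poisson with mean map-length
#' in Morgans, and crossover points fall uniformly on the genetic map.
#'
#' @param panel a `marker_panel` (physical positions).
#' @param marker_cm genetic positions of the panel markers in cM,
#'   non-decreasing with physical position.
#' @param locus_cm,locus_bp genetic and physical position of the trait
#'   locus; must lie within the map range.
#' @return List of class `crossover_model`.
#' @export
crossover_model <- function(panel, marker_cm, locus_cm, locus_bp) {
  if (nrow(panel) == 0L) stop("empty marker map")
  if (length(marker_cm) != nrow(panel))
    stop("marker_cm must have one entry per panel marker")
  ord <- order(panel$pos_bp)
  if (is.unsorted(marker_cm[ord]))
    stop("genetic positions must be non-decreasing with physical position")
  rng <- range(c(marker_cm, locus_cm))
  if (locus_cm < min(marker_cm) || locus_cm > max(marker_cm))
    stop("rf_locus genetic position must lie inside the marker map range")
  out <- list(panel = panel, marker_cm = marker_cm,
              locus_cm = locus_cm, locus_bp = locus_bp,
              length_cm = diff(rng), origin_cm = rng[1])
  class(out) <- "crossover_model"
  out
}

# one gamete allele vector (0 = CMS allele, 1 = restorer allele) at the
# given genetic positions; vectorized over gametes via the k = 0 fast path
sim_gametes <- function(n, positions, length_cm) {
  L <- length_cm / 100  # Morgans
  k <- stats::rpois(n, L)
  start <- stats::rbinom(n, 1L, 0.5)
  al <- matrix(rep(start, each = length(positions)),
               nrow = n, ncol = length(positions), byrow = TRUE)
  for (g in which(k > 0L)) {
    xo <- sort(stats::runif(k[g], 0, length_cm))
    al[g, ] <- (start[g] + findInterval(positions, xo)) %% 2L
  }
  al
}

#' Simulate an F2 population segregating for a single dominant locus
#'
#' Each plant receives two independent F1 gametes; the phenotype is
#' STERILE iff the plant is homozygous for the CMS allele at the trait
#' locus (single dominant restorer gene). Fully reproducible under `seed`.
#'
#' @param model a `crossover_model`.
#' @param n number of plants.
#' @param seed integer seed.
#' @return List of class `sim_f2`: `plants` (an `f2_population`), `truth`
#'   (data.frame `plant_id`, `locus_genotype` in A/H/B codes).
#' @export
simulate_f2 <- function(model, n, seed) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  pos <- c(model$marker_cm, model$locus_cm) - model$origin_cm
  g1 <- sim_gametes(n, pos, model$length_cm)
  g2 <- sim_gametes(n, pos, model$length_cm)
  geno <- g1 + g2  # 0, 1, 2 restorer-allele dosage
  codes <- c("A", "H", "B")
  p <- length(model$marker_cm)
  calls <- matrix(codes[geno[, seq_len(p), drop = FALSE] + 1L], nrow = n)
  colnames(calls) <- model$panel$marker
  locus <- codes[geno[, p + 1L] + 1L]
  phen <- ifelse(locus == "A", "STERILE", "FERTILE")
  ids <- sprintf("plant_%04d", seq_len(n))
  out <- list(plants = f2_population(ids, phen, as.data.frame(calls)),
              truth = data.frame(plant_id = ids, locus_genotype = locus,
                                 stringsAsFactors = FALSE))
  class(out) <- "sim_f2"
  out
}

#' Simulate an inbred-line variant allele matrix
#'
#' Lines are drawn from their class reference haplotype (maintainers from
#' the CMS line, restorers from the restorer line); each site is flipped
#' to the other reference allele independently with probability
#' `discordance`.
#'
#' @param n_maintainer,n_restorer numbers of scored lines per class.
#' @param n_sites number of variant sites (all coded MISSENSE).
#' @param discordance per-site flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A `variant_matrix` whose reference lines are `REF_CMS` and
#'   `REF_RESTORER`.
#' @export
simulate_variant_matrix <- function(n_maintainer, n_restorer, n_sites,
                                    discordance, seed) {
  if (discordance < 0 || discordance > 1)
    stop("discordance rate must be in [0, 1]")
  set.seed(seed)
  sites <- data.frame(gene = "geneX",
                      cds_offset = seq_len(n_sites) * 3L,
                      cms_allele = "A", restorer_allele = "G",
                      consequence = "MISSENSE", stringsAsFactors = FALSE)
  lines <- data.frame(
    line = c("REF_CMS", "REF_RESTORER",
             sprintf("M%02d", seq_len(n_maintainer)),
             sprintf("R%02d", seq_len(n_restorer))),
    role = c("CMS", "RESTORER",
             rep("MAINTAINER", n_maintainer), rep("RESTORER", n_restorer)),
    stringsAsFactors = FALSE)
  site_id <- paste(sites$gene, sites$cds_offset, sep = "_")
  al <- matrix(NA_character_, nrow = nrow(lines), ncol = n_sites,
               dimnames = list(lines$line, site_id))
  al["REF_CMS", ] <- sites$cms_allele
  al["REF_RESTORER", ] <- sites$restorer_allele
  for (i in 3:nrow(lines)) {
    own <- if (lines$role[i] == "MAINTAINER") sites$cms_allele else sites$restorer_allele
    oth <- if (lines$role[i] == "MAINTAINER") sites$restorer_allele else sites$cms_allele
    flip <- stats::runif(n_sites) < discordance
    al[i, ] <- ifelse(flip, oth, own)
  }
  variant_matrix(lines, sites, al, "REF_CMS", "REF_RESTORER")
}

#' Simulate a qRT-PCR Ct table
#'
#' Reference-gene Ct values are Gaussian around a fixed baseline; the
#' target gene's Ct is baseline + dCt where dCt carries the planted ddCt
#' group effects relative to the first (calibrator) block.
#'
#' @param groups,stages character vectors defining the blocks.
#' @param ddct numeric matrix (groups x stages) of planted ddCt shifts
#'   relative to `groups[1]`, `stages[1]`; 0 = calibrator level.
#' @param noise_sd Gaussian measurement noise on every Ct (>= 0).
#' @param n_rep biological replicates per block (default 3).
#' @param seed integer seed.
#' @param target,reference gene names written into the table.
#' @param base_ct reference-gene baseline Ct.
#' @param base_dct calibrator dCt (target minus reference).
#' @return A Ct data.frame usable with [relative_expression()].
#' @export
simulate_ct_table <- function(groups, stages, ddct, noise_sd = 0.1,
                              n_rep = 3L, seed = 1L, target = "target",
                              reference = "actin", base_ct = 18,
                              base_dct = 3) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ddct <- matrix(ddct, nrow = length(groups), ncol = length(stages),
                 dimnames = list(groups, stages))
  set.seed(seed)
  rows <- list()
  for (g in groups) for (s in stages) {
    for (r in seq_len(n_rep)) {
      ct_ref <- base_ct + stats::rnorm(1, 0, noise_sd)
      ct_tgt <- base_ct + base_dct + ddct[g, s] + stats::rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, stage = s, gene = c(target, reference),
        rep = r, ct = c(ct_tgt, ct_ref), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a sequence pair with planted InDel events
#'
#' Builds a random reference sequence and an alternate copy with `n_events`
#' insertions/deletions of the given length range applied at spaced
#' positions, returning both sequences and a truth table in the caller's
#' coordinate convention (1-based position of the base preceding the
#' event, left-aligned).
#'
#' @param length_bp reference length in bp.
#' @param n_events number of events.
#' @param len_range length range (inclusive) to draw event sizes from.
#' @param min_spacing minimum distance between event anchors in bp.
#' @param seed integer seed.
#' @return List: `ref`, `alt` (sequences), `truth` (data.frame `ref_pos`,
#'   `length`, `kind`, `seq`).
#' @export
plant_indels <- function(length_bp, n_events, len_range = c(5L, 30L),
                         min_spacing = 1000L, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- paste(sample(bases, length_bp, replace = TRUE), collapse = "")
  if (n_events == 0L)
    return(list(ref = ref, alt = ref,
                truth = data.frame(ref_pos = integer(), length = integer(),
                                   kind = character(), seq = character(),
                                   stringsAsFactors = FALSE)))
  margin <- max(min_spacing, max(len_range) + 1L)
  lo <- margin; hi <- length_bp - margin
  if (hi - lo < (n_events - 1L) * min_spacing)
    stop("sequence too short for ", n_events, " events at spacing ",
         min_spacing)
  # draw anchors on a jittered grid to guarantee spacing
  slots <- seq(lo, hi, length.out = n_events)
  jit <- floor(stats::runif(n_events, 0, max(1, min_spacing / 4)))
  anchors <- as.integer(slots + jit)
  lens <- sample(seq(len_range[1], len_range[2]), n_events, replace = TRUE)
  kinds <- sample(c("DELETION", "INSERTION"), n_events, replace = TRUE)
  truth <- data.frame(ref_pos = anchors, length = lens, kind = kinds,
                      seq = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n_events)) {
    if (truth$kind[i] == "DELETION") {
      truth$seq[i] <- substr(ref, truth$ref_pos[i] + 1L,
                             truth$ref_pos[i] + truth$length[i])
    } else {
      truth$seq[i] <- paste(sample(bases, truth$length[i], replace = TRUE),
                            collapse = "")
    }
    la <- left_align_call(ref, truth$ref_pos[i], truth$seq[i])
    truth$ref_pos[i] <- la$pos
    truth$seq[i] <- la$seq
  }
  # apply right-to-left so earlier coordinates stay valid
  alt <- ref
  for (i in order(truth$ref_pos, decreasing = TRUE)) {
    p <- truth$ref_pos[i]
    if (truth$kind[i] == "DELETION") {
      alt <- paste0(substr(alt, 1L, p),
                    substr(alt, p + truth$length[i] + 1L, nchar(alt)))
    } else {
      alt <- paste0(substr(alt, 1L, p), truth$seq[i],
                    substr(alt, p + 1L, nchar(alt)))
    }
  }
  list(ref = ref, alt = alt, truth = truth[order(truth$ref_pos), ])
}

FIXTURES <- c("table2_families", "table3_primary", "table3_fine",
              "table4_genes", "table5_matrix")

#' Load a packaged fixture table
#'
#' Transcriptions of the published segregation counts, recombinant
#' tallies, interval gene annotations, and line-by-site allele matrix ship
#' with the package as plain tab-separated files.
#'
#' @param name one of `"table2_families"` (family fertile/sterile counts),
#'   `"table3_primary"` / `"table3_fine"` (marker tallies; usable with
#'   [map_from_tallies()]), `"table4_genes"` (interval gene annotation),
#'   `"table5_matrix"` (a `variant_matrix`).
#' @return A typed object matching the fixture.
#' @export
load_fixture <- function(name) {
  if (!name %in% FIXTURES)
    stop("unknown fixture '", name, "'; available: ",
         paste(FIXTURES, collapse = ", "))
  path <- function(f) system.file("extdata", f, package = "rfmap",
                                  mustWork = TRUE)
  if (name == "table2_families") {
    utils::read.delim(path("table2_families.tsv"), comment.char = "#",
                      stringsAsFactors = FALSE)
  } else if (name %in% c("table3_primary", "table3_fine")) {
    utils::read.delim(path(paste0(name, ".tsv")), comment.char = "#",
                      stringsAsFactors = FALSE)
  } else if (name == "table4_genes") {
    utils::read.delim(path("table4_genes.tsv"), comment.char = "#",
                      stringsAsFactors = FALSE)
  } else {
    lines <- utils::read.delim(path("table5_lines.tsv"), comment.char = "#",
                               stringsAsFactors = FALSE)
    sites <- utils::read.delim(path("table5_sites.tsv"), comment.char = "#",
                               stringsAsFactors = FALSE)
    al <- as.matrix(lines[, -(1:2)])
    rownames(al) <- lines$line
    colnames(al) <- paste(sites$gene, sites$cds_offset, sep = "_")
    variant_matrix(lines[, 1:2], sites, al, ref_cms = "HZ1A",
                   ref_restorer = "HZ1C")
  }
}
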