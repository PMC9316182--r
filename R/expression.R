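#' Relative expression by the 2^-ddCt method
#'
#' For each (group, stage) block, dCt is the replicate-mean Ct of the
#' target gene minus the replicate-mean Ct of the reference gene; ddCt
#' subtracts the calibrator block's dCt, and fold change is 2^-ddCt. The
#' calibrator's fold change is exactly 1. Blocks where the target gene has
#' no Ct value (expression not detected) are reported as ND (`NA` fold
#' change), never as zero.
#'
#' @param ct data.frame with columns `group`, `stage`, `gene`, `rep`,
#'   `ct` (numeric; `NA` = not detected).
#' @param target,reference target and reference (internal-control) gene
#'   names.
#' @param calibrator_group,calibrator_stage the calibrator block.
#' @return data.frame with one row per (group, stage): `group`, `stage`,
#'   `dct`, `ddct`, `fold_change`, `nd`, plus attribute
#'   `"replicate_dct"`, a data.frame of per-replicate dCt values (target
#'   and reference paired by replicate id) for group comparison.
#' @export
relative_expression <- function(ct, target, reference,
                                calibrator_group, calibrator_stage) {
  need <- c("group", "stage", "gene", "rep", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table must have columns: ", paste(need, collapse = ", "))
  blocks <- unique(ct[, c("group", "stage")])
  rownames(blocks) <- NULL
  block_dct <- function(g, s) {
    tgt <- ct$ct[ct$group == g & ct$stage == s & ct$gene == target]
    ref <- ct$ct[ct$group == g & ct$stage == s & ct$gene == reference]
    if (length(ref) == 0L || all(is.na(ref)))
      stop("no reference-gene Ct rows for (", g, ", ", s, ")")
    if (length(tgt) == 0L || all(is.na(tgt))) return(NA_real_)
    mean(tgt, na.rm = TRUE) - mean(ref, na.rm = TRUE)
  }
  dct <- mapply(block_dct, blocks$group, blocks$stage)
  cal <- which(blocks$group == calibrator_group &
                 blocks$stage == calibrator_stage)
  if (length(cal) != 1L)
    stop("calibrator block (", calibrator_group, ", ", calibrator_stage,
         ") not present in the table")
  if (is.na(dct[cal])) stop("calibrator block has no detected target Ct")
  ddct <- dct - dct[cal]
  out <- data.frame(blocks, dct = dct, ddct = ddct,
                    fold_change = 2^(-ddct), nd = is.na(dct),
                    stringsAsFactors = FALSE)
  out$fold_change[cal] <- 1  # exact by construction
  # per-replicate dCt, pairing target and reference by replicate id
  reps <- ct[ct$gene == target, c("group", "stage", "rep", "ct")]
  refs <- ct[ct$gene == reference, c("group", "stage", "rep", "ct")]
  m <- merge(reps, refs, by = c("group", "stage", "rep"),
             suffixes = c("_target", "_reference"))
  m$dct <- m$ct_target - m$ct_reference
  attr(out, "replicate_dct") <- m[order(m$group, m$stage, m$rep), ]
  out
}

#' Compare expression between two groups at a stage
#'
#' Welch's (unequal-variance) two-sided t-test on per-replicate dCt
#' values, with the Fig.-2-style significance tiers: `ns`, `*` (p < 0.05),
#' `**` (p < 0.01).
#'
#' @param rep_dct per-replicate dCt table, e.g. the `"replicate_dct"`
#'   attribute of [relative_expression()].
#' @param group_a,group_b the two groups to compare.
#' @param stage stage shared by both groups.
#' @return List of class `group_comparison`: `p_value`, `tier`,
#'   `mean_dct`.
#' @export
compare_groups <- function(rep_dct, group_a, group_b, stage) {
  xa <- rep_dct$dct[rep_dct$group == group_a & rep_dct$stage == stage]
  xb <- rep_dct$dct[rep_dct$group == group_b & rep_dct$stage == stage]
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (length(xa) < 2L || length(xb) < 2L)
    stop("need >= 2 replicates per group (have ", length(xa), " and ",
         length(xb), ")")
  if (stats::var(xa) == 0 && stats::var(xb) == 0) {
    # degenerate: constant groups; identical means -> no evidence at all
    p <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
  } else {
    p <- stats::t.test(xa, xb, var.equal = FALSE)$p.value
  }
  tier <- if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  out <- list(p_value = p, tier = tier,
              mean_dct = c(mean(xa), mean(xb)))
  class(out) <- "group_comparison"
  out
}
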