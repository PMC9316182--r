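#' Chi-square goodness-of-fit test for a fertile:sterile segregation ratio
#'
#' Tests observed fertile/sterile counts against an expected Mendelian
#' ratio (3:1 for a single dominant gene). The statistic is
#' \eqn{\chi^2 = \sum (O-E)^2/E} with one degree of freedom; with the
#' continuity correction (the default) each term is
#' \eqn{(|O-E| - 0.5)^2/E}, with no clamping of the corrected deviation at
#' zero. Expected counts are always derived from the component sum
#' `n_fertile + n_sterile`.
#'
#' @param n_fertile,n_sterile observed counts (non-negative; sum >= 1).
#' @param ratio expected fertile:sterile ratio as a pair of positive
#'   numbers; default `c(3, 1)`.
#' @param correct apply the Yates continuity correction (default `TRUE`).
#' @return A list of class `chisq_gof` with elements `statistic`, `df`,
#'   `p_value`, `observed`, `expected`, `corrected`.
#' @examples
#' chi_square_gof(1277, 381)    # pooled F2 counts; statistic ~ 3.50
#' @export
chi_square_gof <- function(n_fertile, n_sterile, ratio = c(3, 1),
                           correct = TRUE) {
  if (n_fertile < 0 || n_sterile < 0) stop("counts must be non-negative")
  n <- n_fertile + n_sterile
  if (n < 1) stop("total count is zero")
  if (length(ratio) != 2L || any(ratio <= 0))
    stop("ratio must be a pair of positive numbers")
  expected <- n * ratio / sum(ratio)
  observed <- c(fertile = n_fertile, sterile = n_sterile)
  dev <- abs(observed - expected)
  if (correct) dev <- dev - 0.5
  statistic <- sum(dev^2 / expected)
  out <- list(statistic = statistic, df = 1L,
              p_value = chi_square_p(statistic, 1L),
              observed = observed,
              expected = stats::setNames(expected, names(observed)),
              corrected = correct)
  class(out) <- "chisq_gof"
  out
}

#' @export
print.chisq_gof <- function(x, ...) {
  cat(sprintf("chi-square GOF: X2 = %.2f, df = %d, p = %.2f%s\n",
              x$statistic, x$df, x$p_value,
              if (x$corrected) " (continuity-corrected)" else ""))
  invisible(x)
}

#' Upper-tail chi-square probability
#'
#' @param statistic non-negative chi-square statistic.
#' @param df degrees of freedom (>= 1).
#' @return Upper-tail probability.
#' @export
chi_square_p <- function(statistic, df) {
  if (any(statistic < 0)) stop("chi-square statistic must be non-negative")
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Per-family and pooled segregation report
#'
#' Runs [chi_square_gof()] on every family and on the pooled counts, and
#' flags each row as consistent with the expected ratio at `p > alpha`.
#'
#' @param records data.frame with columns `family`, `n_fertile`,
#'   `n_sterile`.
#' @param ratio expected ratio pair, default 3:1.
#' @param correct continuity correction flag, default `TRUE`.
#' @param alpha significance threshold, default 0.05.
#' @return data.frame with one row per family plus a pooled `Total` row;
#'   columns `family`, `n_total`, `n_fertile`, `n_sterile`, `chisq`,
#'   `p_value`, `fits_ratio`.
#' @export
segregation_report <- function(records, ratio = c(3, 1), correct = TRUE,
                               alpha = 0.05) {
  need <- c("family", "n_fertile", "n_sterile")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (nrow(records) < 1L) stop("at least one family record required")
  rows <- rbind(records[, need],
                data.frame(family = "Total",
                           n_fertile = sum(records$n_fertile),
                           n_sterile = sum(records$n_sterile)))
  res <- lapply(seq_len(nrow(rows)), function(i)
    chi_square_gof(rows$n_fertile[i], rows$n_sterile[i], ratio, correct))
  data.frame(family = rows$family,
             n_total = rows$n_fertile + rows$n_sterile,
             n_fertile = rows$n_fertile,
             n_sterile = rows$n_sterile,
             chisq = vapply(res, `[[`, 0, "statistic"),
             p_value = vapply(res, `[[`, 0, "p_value"),
             fits_ratio = vapply(res, `[[`, 0, "p_value") > alpha,
             stringsAsFactors = FALSE)
}
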