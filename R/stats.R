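#' Positional variability summary
#'
#' Full range (max - min) and sample standard deviation (n - 1 denominator)
#' of a set of positions, the two dispersion measures used for positional
#' variance tables.
#'
#' @param positions Numeric positions (%EL), `n >= 2`.
#' @return List with `n`, `full_range`, `sd`.
#' @export
#' @examples
#' positional_summary(c(45, 47, 49))  # full_range 4, sd 2
positional_summary <- function(positions) {
  positions <- positions[!is.na(positions)]
  if (length(positions) < 2L) {
    .err("need at least 2 positions for a dispersion summary",
         "gapcanal_undefined_sd")
  }
  list(n = length(positions),
       full_range = max(positions) - min(positions),
       sd = stats::sd(positions))
}

#' Positional variance filtration rate
#'
#' The fraction of input positional variability removed by the network,
#' `1 - output_sd / input_sd`. E.g. an Hb output sd of 1.3 %EL arising from
#' a Bcd input sd of 4.5 %EL gives a filtration rate above 70%.
#'
#' @param output_sd Output positional sd (%EL).
#' @param input_sd Input positional sd (%EL), > 0.
#' @return Fraction in (-Inf, 1].
#' @export
#' @examples
#' filtration_rate(1.3, 4.5)  # > 0.70
filtration_rate <- function(output_sd, input_sd) {
  if (input_sd <= 0) .err("input_sd must be > 0", "gapcanal_invalid_input")
  1 - output_sd / input_sd
}

#' Family-stratified positional variance table
#'
#' Builds the three-by-three positional variance layout: rows are
#' intersection positions, hb border positions and Bcd threshold positions;
#' columns are Family I, Family II and the full profile set. Strata with
#' fewer than two members are marked absent (NA dispersion).
#'
#' @param records Data frame with per-profile columns `intersection`,
#'   `border`, `threshold` (positions in %EL, NA allowed) and `family`
#'   (`"I"`, `"II"` or other/unclassified).
#' @return Data frame with columns `row_label`, `family`, `n`,
#'   `full_range`, `sd`.
#' @export
family_stratified_summary <- function(records) {
  stopifnot(all(c("intersection", "border", "threshold", "family") %in%
                  names(records)))
  rows <- c(intersection = "Intersection positions",
            border = "hb border positions",
            threshold = "Bcd threshold positions")
  strata <- list(I = records$family == "I", II = records$family == "II",
                 full = rep(TRUE, nrow(records)))
  out <- list()
  for (rn in names(rows)) {
    for (sn in names(strata)) {
      v <- records[[rn]][strata[[sn]]]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        row_label = rows[[rn]], family = sn, n = length(v),
        full_range = if (length(v) >= 2L) max(v) - min(v) else NA_real_,
        sd = if (length(v) >= 2L) stats::sd(v) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Pearson correlation between two sets of positions
#'
#' E.g. the correlation between basin-boundary intersection positions and
#' model hb border positions across an ensemble.
#'
#' @param xs,ys Numeric vectors of equal length, `n >= 3`, each with
#'   nonzero variance (pairs with NA in either are dropped).
#' @return Pearson correlation coefficient.
#' @export
correlate_positions <- function(xs, ys) {
  keep <- !is.na(xs) & !is.na(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 3L) .err("need at least 3 complete pairs",
                            "gapcanal_invalid_input")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    .err("zero variance in one of the position sets",
         "gapcanal_invalid_input")
  }
  stats::cor(xs, ys)
}
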