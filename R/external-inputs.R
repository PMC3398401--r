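#' External-input concentration table
#'
#' Spatio-temporal concentrations of an external transcription factor (Cad
#' or Tll) sampled on a grid of spatial positions (%EL) and cycle-14A time
#' classes T1..T8. Evaluation interpolates linearly in space and linearly in
#' time between time-class midpoints, with constant extrapolation before the
#' first midpoint; queries are clamped at the T6 midpoint, so evaluation for
#' any time after T6 equals the T6 value (the mid-blastula freeze).
#'
#' @param factor `"cad"` or `"tll"`.
#' @param x Numeric vector of positions (%EL), strictly increasing.
#' @param values Numeric matrix, `length(x)` rows x 8 columns (time classes
#'   T1..T8), all >= 0. A vector is taken as time-constant.
#' @return Object of class `external_input_table`.
#' @export
external_input_table <- function(factor = c("cad", "tll"), x, values) {
  factor <- match.arg(factor)
  if (is.null(dim(values))) values <- matrix(values, nrow = length(x),
                                             ncol = 8L)
  values <- as.matrix(values)
  if (nrow(values) != length(x)) {
    stop("values must have one row per position", call. = FALSE)
  }
  if (ncol(values) != 8L) stop("values must have 8 time-class columns",
                               call. = FALSE)
  if (any(diff(x) <= 0)) stop("positions must be strictly increasing",
                              call. = FALSE)
  if (any(values < 0)) stop("external-input concentrations must be >= 0",
                            call. = FALSE)
  structure(list(factor = factor, x = as.numeric(x), values = values),
            class = "external_input_table")
}

#' Evaluate an external-input table
#'
#' @param table An [external_input_table()].
#' @param x Position(s) in %EL (clamped to the table's spatial range).
#' @param t Time(s) in minutes.
#' @param schedule A [mitosis_schedule()] giving the time-class midpoints.
#' @return Concentration(s); if both `x` and `t` have length > 1 they must
#'   have equal length and are paired.
#' @export
eval_external_input <- function(table, x, t, schedule) {
  tmid <- schedule$class_mid
  # clamp time to [T1 midpoint, T6 midpoint]: constant before the first
  # sample, frozen from the T6 sample onwards
  tq <- pmin(pmax(t, tmid[1L]), tmid[6L])
  xq <- pmin(pmax(x, table$x[1L]), table$x[length(table$x)])
  n <- max(length(xq), length(tq))
  xq <- rep_len(xq, n); tq <- rep_len(tq, n)
  # bilinear interpolation on the (x, class-midpoint) grid
  xi <- findInterval(xq, table$x, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ti <- findInterval(tq, tmid, rightmost.closed = TRUE, all.inside = TRUE)
  wx <- (xq - table$x[xi]) / (table$x[xi + 1L] - table$x[xi])
  wt <- (tq - tmid[ti]) / (tmid[ti + 1L] - tmid[ti])
  v00 <- table$values[cbind(xi, ti)]
  v10 <- table$values[cbind(xi + 1L, ti)]
  v01 <- table$values[cbind(xi, ti + 1L)]
  v11 <- table$values[cbind(xi + 1L, ti + 1L)]
  (1 - wx) * (1 - wt) * v00 + wx * (1 - wt) * v10 +
    (1 - wx) * wt * v01 + wx * wt * v11
}

#' Time-course function of an external input at fixed positions
#'
#' Precomputes, for a set of nucleus positions, a single function
#' `f(t) -> matrix/vector` of concentrations, as needed by the integrators.
#'
#' @param table An [external_input_table()] or a single number (taken as a
#'   constant input) or `NULL` (zero input).
#' @param x Positions in %EL.
#' @param schedule A [mitosis_schedule()].
#' @return Function of `t` returning a numeric vector of length `length(x)`.
#' @export
external_input_fun <- function(table, x, schedule) {
  nx <- length(x)
  if (is.null(table)) return(function(t) numeric(nx))
  if (is.numeric(table) && length(table) == 1L) {
    const <- rep(table, nx)
    return(function(t) const)
  }
  stopifnot(inherits(table, "external_input_table"))
  tmid <- schedule$class_mid
  # spatial interpolation once; time interpolation per call
  prof <- vapply(seq_len(8L), function(k) {
    stats::approx(table$x, table$values[, k], xout = pmin(pmax(
      x, table$x[1L]), table$x[length(table$x)]))$y
  }, numeric(nx))
  prof <- matrix(prof, nrow = nx)
  function(t) {
    tq <- min(max(t, tmid[1L]), tmid[6L])
    ti <- findInterval(tq, tmid, all.inside = TRUE)
    wt <- (tq - tmid[ti]) / (tmid[ti + 1L] - tmid[ti])
    (1 - wt) * prof[, ti] + wt * prof[, ti + 1L]
  }
}
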