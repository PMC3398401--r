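#' Mitosis and cleavage-cycle schedule
#'
#' Describes the time axis of the simulation: cleavage cycle 13 (interphase
#' followed by mitosis), the nuclear division into cycle 14A, and the eight
#' equal time classes T1..T8 subdividing cycle 14A. The synthesis-gating
#' function \eqn{\chi(t)} is one during interphase and zero during mitosis;
#' after the end of time class T6 the system is treated as autonomous
#' (\eqn{\chi \equiv 1}, external inputs frozen), reflecting the onset of the
#' mid-blastula transition.
#'
#' All times are in minutes with `t0` the start of cycle 13.
#'
#' @param t0 Start of cleavage cycle 13 (default 0).
#' @param interphase13_end End of cycle-13 interphase / start of mitosis 13.
#' @param mitosis13_end End of mitosis 13 = start of cycle 14A (division time).
#' @param cycle14A_end End of cycle 14A, \eqn{\tau} (gastrulation time).
#' @param n_classes Number of equal time classes in cycle 14A (default 8).
#'
#' @return An object of class `mitosis_schedule` with fields `t0`,
#'   `interphase13_end`, `mitosis13_end`, `tau`, `class_edges` (length
#'   `n_classes + 1`), `class_mid` (class midpoints), and `t_T6` (end of time
#'   class 6).
#' @export
#' @examples
#' sch <- mitosis_schedule()
#' sch$t_T6   # 58.6 with the default timing convention
mitosis_schedule <- function(t0 = 0, interphase13_end = 16.0,
                             mitosis13_end = 21.1, cycle14A_end = 71.1,
                             n_classes = 8L) {
  stopifnot(t0 < interphase13_end, interphase13_end < mitosis13_end,
            mitosis13_end < cycle14A_end, n_classes >= 6L)
  edges <- seq(mitosis13_end, cycle14A_end, length.out = n_classes + 1L)
  structure(list(
    t0 = t0,
    interphase13_end = interphase13_end,
    mitosis13_end = mitosis13_end,
    tau = cycle14A_end,
    n_classes = as.integer(n_classes),
    class_edges = edges,
    class_mid = (edges[-1L] + edges[-length(edges)]) / 2,
    t_T6 = edges[7L]
  ), class = "mitosis_schedule")
}

#' Mitotic gating function
#'
#' \eqn{\chi(t)} equals 0 exactly on the mitosis-13 window
#' `[interphase13_end, mitosis13_end)` and 1 elsewhere (including all of
#' cycle 14A and all times after T6).
#'
#' @param t Time(s) in minutes.
#' @param schedule A [mitosis_schedule()].
#' @return Numeric vector of 0/1 values, same length as `t`.
#' @export
chi_gate <- function(t, schedule) {
  ifelse(t >= schedule$interphase13_end & t < schedule$mitosis13_end, 0, 1)
}

#' End time of a cycle-14A time class
#'
#' @param class_idx Time class 1..8.
#' @param schedule A [mitosis_schedule()].
#' @return Time in minutes at which the class ends.
#' @export
time_class_end <- function(class_idx, schedule) {
  stopifnot(all(class_idx >= 1), all(class_idx <= schedule$n_classes))
  schedule$class_edges[class_idx + 1L]
}

#' @export
print.mitosis_schedule <- function(x, ...) {
  cat("Cleavage-cycle schedule (min):\n")
  cat(sprintf("  interphase 13: [%g, %g)\n", x$t0, x$interphase13_end))
  cat(sprintf("  mitosis 13:    [%g, %g)  (chi = 0)\n",
              x$interphase13_end, x$mitosis13_end))
  cat(sprintf("  cycle 14A:     [%g, %g], %d classes, T6 ends at %g\n",
              x$mitosis13_end, x$tau, x$n_classes, x$t_T6))
  invisible(x)
}
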