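#' Nuclear lattice along the anterior-posterior axis
#'
#' Positions of blastoderm nuclei in percent egg length (%EL). The package
#' uses the convention that cycle-13 nuclei sit at odd-integer %EL positions
#' and cycle-14A nuclei at integer positions: each cycle-13 parent at odd
#' position p divides into daughters at p and p + 1, and daughters falling
#' posterior to the full-domain upper bound (92 %EL) are dropped. This is the
#' unique simple convention reproducing the modelled nucleus counts: 30
#' (cycle 13) and 58 (cycle 14A) over 35-92 %EL, and 11 / 22 over the
#' restricted 37-57 %EL analysis region.
#'
#' @param domain Length-2 numeric, `[a, b]` in %EL with `a < b`.
#' @param cycle `"13"` or `"14A"`.
#' @param full_upper Posterior bound of the full modelled domain used for
#'   clipping cycle-14A daughters (default 92 %EL).
#'
#' @return An object of class `nuclear_lattice`: list with `positions`
#'   (strictly increasing numeric), `cycle`, `domain`, `full_upper`.
#' @export
#' @examples
#' length(build_lattice(c(35, 92), "13")$positions)   # 30
#' length(build_lattice(c(35, 92), "14A")$positions)  # 58
#' length(build_lattice(c(37, 57), "13")$positions)   # 11
build_lattice <- function(domain, cycle = c("13", "14A"), full_upper = 92) {
  cycle <- match.arg(as.character(cycle), c("13", "14A"))
  if (length(domain) != 2L || !is.numeric(domain) || domain[1] >= domain[2]) {
    stop("domain must be numeric [a, b] with a < b", call. = FALSE)
  }
  a <- domain[1]; b <- domain[2]
  first_odd <- ceiling(a)
  if (first_odd %% 2 == 0) first_odd <- first_odd + 1
  parents <- seq(first_odd, floor(b + 1), by = 2)
  if (length(parents) == 0L) stop("domain contains no nuclei", call. = FALSE)
  pos <- if (cycle == "13") {
    parents
  } else {
    d <- sort(c(parents, parents + 1))
    d[d <= full_upper]
  }
  structure(list(positions = as.numeric(pos), cycle = cycle,
                 domain = as.numeric(domain), full_upper = full_upper),
            class = "nuclear_lattice")
}

#' Nuclear division from cycle 13 to cycle 14A
#'
#' Each parent nucleus at odd position p yields daughters at p and p + 1,
#' both inheriting the parent's full protein state (concentrations are
#' copied, not halved: levels are relative units). Daughters posterior to
#' the full-domain upper bound are dropped.
#'
#' @param state13 Numeric matrix, genes x nuclei, columns matching
#'   `lattice13$positions`.
#' @param lattice13 A cycle-13 [build_lattice()] object.
#' @return List with `state` (genes x daughters matrix) and `lattice`
#'   (the cycle-14A lattice).
#' @export
apply_nuclear_division <- function(state13, lattice13) {
  if (!inherits(lattice13, "nuclear_lattice") || lattice13$cycle != "13") {
    stop("lattice13 must be a cycle-13 nuclear_lattice", call. = FALSE)
  }
  state13 <- as.matrix(state13)
  if (ncol(state13) != length(lattice13$positions)) {
    stop("state13 has ", ncol(state13), " columns but lattice has ",
         length(lattice13$positions), " nuclei", call. = FALSE)
  }
  parents <- lattice13$positions
  pos <- as.vector(rbind(parents, parents + 1))
  keep <- pos <= lattice13$full_upper
  idx <- rep(seq_along(parents), each = 2L)[keep]
  lattice14 <- structure(list(positions = pos[keep], cycle = "14A",
                              domain = lattice13$domain,
                              full_upper = lattice13$full_upper),
                         class = "nuclear_lattice")
  list(state = state13[, idx, drop = FALSE], lattice = lattice14)
}

#' @export
print.nuclear_lattice <- function(x, ...) {
  cat(sprintf("Nuclear lattice, cycle %s: %d nuclei on [%g, %g] %%EL\n",
              x$cycle, length(x$positions), x$domain[1], x$domain[2]))
  invisible(x)
}
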