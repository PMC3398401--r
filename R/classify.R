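#' Classify the hb border-formation mechanism
#'
#' Labels, for one Bcd profile, which attracting set governs the solution
#' at gastrulation time in each of the two border nuclei: `A` when the
#' endpoint lies within `delta_A` of a point attractor, otherwise `M` when
#' it lies within `delta_M` of a traced 1-D unstable-manifold branch. The
#' pair (anterior, posterior) gives the mechanism: `AA` (attractor-attractor
#' switch), `AM`, `MA` or `MM`. A nucleus matching neither criterion makes
#' the profile `unclassified`.
#'
#' @param end_anterior,end_posterior Length-4 states of the hb-expressing
#'   (anterior) and hb-nonexpressing (posterior) border nuclei at time
#'   \eqn{\tau}.
#' @param attractors_anterior,attractors_posterior Labelled attractor lists
#'   for the two nuclei (equilibrium objects).
#' @param manifolds_anterior,manifolds_posterior Lists of
#'   [trace_unstable_manifold()] results for the two nuclei (may be empty).
#' @param delta_A,delta_M Closeness radii (concentration units).
#' @return List with `mechanism` (`"AA"`, `"AM"`, `"MA"`, `"MM"` or
#'   `"unclassified"`), `anterior`, `posterior` (per-nucleus `"A"`, `"M"`
#'   or `NA`), and per-nucleus distances.
#' @export
classify_border_mechanism <- function(end_anterior, end_posterior,
                                      attractors_anterior,
                                      attractors_posterior,
                                      manifolds_anterior = list(),
                                      manifolds_posterior = list(),
                                      delta_A = 5, delta_M = 5) {
  near <- function(endpoint, attractors, manifolds) {
    dA <- if (length(attractors)) min(vapply(attractors, function(e) {
      sqrt(sum((e$state - endpoint)^2))
    }, numeric(1))) else Inf
    if (dA <= delta_A) return(list(type = "A", dist = dA))
    dM <- Inf
    for (mt in manifolds) {
      for (b in mt$branches) {
        dM <- min(dM, sqrt(min(colSums((t(b) - endpoint)^2))))
      }
    }
    if (dM <= delta_M) return(list(type = "M", dist = dM))
    list(type = NA_character_, dist = min(dA, dM))
  }
  a <- near(end_anterior, attractors_anterior, manifolds_anterior)
  p <- near(end_posterior, attractors_posterior, manifolds_posterior)
  mech <- if (is.na(a$type) || is.na(p$type)) "unclassified"
          else paste0(a$type, p$type)
  list(mechanism = mech, anterior = a$type, posterior = p$type,
       dist_anterior = a$dist, dist_posterior = p$dist)
}

#' Family label from a basin transition
#'
#' The ensemble splits into families by the hb component of the attractors
#' flanking the border: a switch from an hb-ON attractor to an hb-OFF
#' attractor (e.g. code `1000` to `0100`, or `1100` to `0100`) is Family I;
#' a transition between two distinct hb-ON attractors (e.g. `1100` to
#' `1000`), where the hb-OFF state at the border is provided by an
#' attracting manifold, is Family II. Anything else (including no
#' transition) is unclassified.
#'
#' @param from,to Attractor code strings (or labels beginning with the
#'   4-character code) of the basins owning the maternal Hb value in the
#'   anterior and posterior border nuclei.
#' @return `"I"`, `"II"` or `"unclassified"`.
#' @export
family_label <- function(from, to) {
  if (is.na(from) || is.na(to) || from == to) return("unclassified")
  hb_of <- function(code) substr(code, 1L, 1L)
  f <- hb_of(from); t <- hb_of(to)
  if (f == "1" && t == "0") return("I")
  if (f == "1" && t == "1") return("II")
  "unclassified"
}

#' Classify the basin transition across the hb border
#'
#' Determines which attractor's basin owns the maternal Hb value in each
#' border nucleus and labels the transition (e.g. `1000->0100`) and its
#' family. Equal owning attractors on both sides mean the border does not
#' form by a basin-to-basin transition (the rare manifold-only case) and
#' yield transition `"none"`.
#'
#' @param partition_anterior,partition_posterior
#'   [sample_basin_partition()] results at the two border nuclei.
#' @param hb0_anterior,hb0_posterior Maternal Hb values at the two nuclei.
#' @return List with `from`, `to` (attractor labels), `transition`
#'   (`"from->to"` or `"none"`) and `family`.
#' @export
classify_basin_transition <- function(partition_anterior,
                                      partition_posterior,
                                      hb0_anterior, hb0_posterior) {
  owner <- function(partition, value) {
    iv <- partition$intervals
    hit <- which(value >= iv$c1 & value <= iv$c2)
    if (length(hit) == 0L) {
      .err(sprintf("initial Hb value %.3g lies in an unresolved gap",
                   value), "gapcanal_unresolved")
    }
    iv$label[hit[1L]]
  }
  from <- owner(partition_anterior, hb0_anterior)
  to <- owner(partition_posterior, hb0_posterior)
  if (from == to) {
    return(list(from = from, to = to, transition = "none",
                family = "unclassified"))
  }
  list(from = from, to = to, transition = paste0(from, "->", to),
       family = family_label(from, to))
}

#' Classify a solution into expression classes I/II/III
#'
#' Rule-based classification of a gastrulation-time solution by the
#' anterior Kr and gt patterns: class I has an anterior gt domain and a
#' proper anterior Kr border (an upward half-max crossing), class III lacks
#' both the gt domain and any anterior Kr expression, class II covers the
#' intermediate defects (typically ectopic anterior Kr in place of gt).
#'
#' @param x Nucleus positions (%EL).
#' @param kr,gt Kr and gt concentrations at those positions.
#' @param anterior_window Window defining "anterior" (%EL).
#' @param half Half-max threshold (default 128, half of the 0-255 scale).
#' @return List with `class` (`"I"`, `"II"`, `"III"`), and the underlying
#'   predicates `gt_domain`, `kr_border`, `kr_anterior`.
#' @export
classify_solution_class <- function(x, kr, gt,
                                    anterior_window = c(35, 50),
                                    half = 128) {
  ant <- x >= anterior_window[1] & x <= anterior_window[2]
  gt_domain <- any(gt[ant] >= half)
  kr_anterior <- any(kr[ant] >= half)
  kr_border <- FALSE
  scan <- which(x <= anterior_window[2] + 2)
  for (i in scan[-length(scan)]) {
    if (kr[i] < half && kr[i + 1L] >= half) { kr_border <- TRUE; break }
  }
  cls <- if (gt_domain && kr_border) "I"
         else if (!gt_domain && !kr_anterior) "III"
         else "II"
  list(class = cls, gt_domain = gt_domain, kr_border = kr_border,
       kr_anterior = kr_anterior)
}
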