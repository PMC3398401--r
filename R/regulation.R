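#' Sigmoid regulation function
#'
#' The regulation-expression function of the gene-circuit model family,
#' \deqn{g(u) = \frac{1}{2}\left(\frac{u}{\sqrt{u^2 + 1}} + 1\right),}
#' a strictly increasing sigmoid with range (0, 1), \eqn{g(0) = 1/2} and the
#' symmetry \eqn{g(u) + g(-u) = 1}. It scales the maximal synthesis rate of
#' each gene by the total regulatory input `u`.
#'
#' @param u Dimensionless total regulatory input (finite numeric).
#' @return Synthesis fraction in (0, 1), same shape as `u`.
#' @export
#' @examples
#' regulation_g(0)        # 0.5
#' regulation_g(1)        # (1/sqrt(2) + 1)/2
regulation_g <- function(u) {
  if (!all(is.finite(u))) stop("non-finite regulatory input u", call. = FALSE)
  0.5 * (u / sqrt(u * u + 1) + 1)
}

#' Derivative of the regulation function
#'
#' \eqn{g'(u) = \frac{1}{2}(u^2 + 1)^{-3/2}}, used in analytic Jacobians.
#'
#' @param u Dimensionless input.
#' @return \eqn{g'(u)}.
#' @export
regulation_g_prime <- function(u) {
  if (!all(is.finite(u))) stop("non-finite regulatory input u", call. = FALSE)
  0.5 * (u * u + 1)^(-1.5)
}

#' Total regulatory input of one gene
#'
#' The argument `u` of the regulation function for gene `a`:
#' \deqn{u^a = \sum_b T^{ab} v^b + m^a v^{Bcd} + \sum_e E^{ae} v^e + h^a,}
#' combining gap-gap interactions `T`, the Bcd weight, external-factor
#' (Cad, Tll) weights, and the threshold offset `h`.
#'
#' @param gene Gene name or index.
#' @param state Length-4 concentration vector (gene order of [gap_genes()]).
#' @param bcd Bcd concentration at the nucleus.
#' @param ext Named external-factor concentrations, e.g. `c(cad = 30, tll = 0)`.
#' @param params A [circuit_parameters()] object.
#' @return The scalar dimensionless input u.
#' @export
total_input <- function(gene, state, bcd, ext, params) {
  a <- gene_index(gene)
  if (length(state) != n_genes()) {
    stop("state must have length 4", call. = FALSE)
  }
  e <- c(cad = 0, tll = 0)
  if (length(ext)) {
    if (is.null(names(ext)) || !all(names(ext) %in% names(e))) {
      stop("ext must be named with 'cad' and/or 'tll'", call. = FALSE)
    }
    e[names(ext)] <- ext
  }
  unname(sum(params$T[a, ] * state) + params$bcd_weight[a] * bcd +
           params$ext_weight[a, "cad"] * e[["cad"]] +
           params$ext_weight[a, "tll"] * e[["tll"]] + params$h[a])
}

# Vectorized inputs for a genes x columns state matrix. bcd, cad, tll are
# per-column vectors (recycled scalars allowed). Returns a 4 x K matrix.
.total_input_matrix <- function(V, bcd, cad, tll, params) {
  K <- ncol(V)
  U <- params$T %*% V + params$h
  U <- U + outer(params$bcd_weight, rep_len(bcd, K) * 1)
  U <- U + outer(params$ext_weight[, "cad"], rep_len(cad, K) * 1)
  if (any(tll != 0)) {
    U <- U + outer(params$ext_weight[, "tll"], rep_len(tll, K) * 1)
  }
  U
}
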