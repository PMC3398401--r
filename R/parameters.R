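#' Circuit parameters of the gap gene model
#'
#' Bundles all regulatory constants of the circuit equations: per-gene
#' maximal synthesis rates `R` (concentration/min), the 4x4 interaction
#' matrix `T` with `T[a, b]` the action of gene b on gene a (dimensionless
#' weight per concentration unit), the per-gene Bcd weight, per-gene weights
#' on the external factors Cad and Tll, threshold offsets `h`, decay rates
#' `lambda` (1/min) and per-cycle diffusion rates `D` (1/min, acting on
#' nearest-neighbour concentration differences).
#'
#' @param R Numeric length-4, synthesis rates, >= 0.
#' @param T_matrix Numeric 4x4 interaction matrix (rows = target gene).
#' @param bcd_weight Numeric length-4 weight on the Bcd input.
#' @param ext_weight Numeric 4x2 matrix, columns `cad` and `tll` (or a
#'   length-4 vector taken as the Cad column with zero Tll weights).
#' @param h Numeric length-4 threshold offsets.
#' @param lambda Numeric length-4 decay rates, all > 0.
#' @param D Numeric length-4 diffusion rates (used for both cycles), or a
#'   4x2 matrix with columns for cycles 13 and 14A; all >= 0.
#'
#' @return Object of class `circuit_parameters` with named, gene-indexed
#'   components.
#' @export
#' @examples
#' p <- gen_parameter_fixture("decoupled")
#' p$R
circuit_parameters <- function(R, T_matrix, bcd_weight, ext_weight, h,
                               lambda, D) {
  g <- gap_genes()
  as4 <- function(x, what) {
    if (length(x) != 4L || !is.numeric(x)) {
      stop(what, " must be numeric length 4", call. = FALSE)
    }
    x <- as.numeric(x); names(x) <- g; x
  }
  R <- as4(R, "R"); bcd_weight <- as4(bcd_weight, "bcd_weight")
  h <- as4(h, "h"); lambda <- as4(lambda, "lambda")
  if (any(lambda <= 0)) stop("all decay rates lambda must be > 0",
                             call. = FALSE)
  if (any(R < 0)) stop("synthesis rates R must be >= 0", call. = FALSE)
  T_matrix <- as.matrix(T_matrix)
  if (!all(dim(T_matrix) == c(4L, 4L))) {
    stop("T_matrix must be 4x4", call. = FALSE)
  }
  dimnames(T_matrix) <- list(g, g)
  if (is.null(dim(ext_weight))) {
    ext_weight <- cbind(cad = as4(ext_weight, "ext_weight"), tll = rep(0, 4))
  } else {
    ext_weight <- as.matrix(ext_weight)
    if (!all(dim(ext_weight) == c(4L, 2L))) {
      stop("ext_weight must be 4x2 (cad, tll)", call. = FALSE)
    }
    colnames(ext_weight) <- c("cad", "tll")
  }
  rownames(ext_weight) <- g
  if (is.null(dim(D))) {
    D <- cbind("13" = as4(D, "D"), "14A" = as4(D, "D"))
  } else {
    D <- as.matrix(D)
    if (!all(dim(D) == c(4L, 2L))) stop("D must be length 4 or 4x2",
                                        call. = FALSE)
    colnames(D) <- c("13", "14A")
  }
  rownames(D) <- g
  if (any(D < 0)) stop("diffusion rates D must be >= 0", call. = FALSE)
  structure(list(R = R, T = T_matrix, bcd_weight = bcd_weight,
                 ext_weight = ext_weight, h = h, lambda = lambda, D = D),
            class = "circuit_parameters")
}

#' Diffusion rates for one cleavage cycle
#' @param params A [circuit_parameters()] object.
#' @param cycle `"13"` or `"14A"`.
#' @return Named length-4 vector of diffusion rates.
#' @export
diffusion_rates <- function(params, cycle) {
  cycle <- match.arg(as.character(cycle), c("13", "14A"))
  params$D[, cycle]
}

#' Turn off gap gene cross regulation of hb
#'
#' Returns a copy of the parameters with the hb row of the interaction
#' matrix set to zero (`T[hb, a] = 0` for every gap gene a), so that hb
#' responds only to Bcd, the external inputs and its threshold. All other
#' entries, including the Bcd/Cad/Tll weights on hb, are untouched. The
#' operation is idempotent.
#'
#' @param params A [circuit_parameters()] object.
#' @return Modified `circuit_parameters`.
#' @export
knockout_hb_inputs <- function(params) {
  params$T[gene_index("hb"), ] <- 0
  params
}

#' @export
print.circuit_parameters <- function(x, ...) {
  cat("Gap gene circuit parameters (genes: ",
      paste(gap_genes(), collapse = ", "), ")\n", sep = "")
  cat("R:      ", paste(signif(x$R, 4), collapse = " "), "\n")
  cat("lambda: ", paste(signif(x$lambda, 4), collapse = " "), "\n")
  cat("h:      ", paste(signif(x$h, 4), collapse = " "), "\n")
  cat("bcd_w:  ", paste(signif(x$bcd_weight, 4), collapse = " "), "\n")
  cat("T:\n"); print(signif(x$T, 4))
  invisible(x)
}
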