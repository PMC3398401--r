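#' The modelled gap gene set
#'
#' The circuit models exactly four zygotic gap genes of the Drosophila
#' blastoderm, in a fixed order that is used consistently for state vectors,
#' parameter rows/columns and symbolic attractor codes.
#'
#' @return Character vector `c("hb", "Kr", "gt", "kni")`.
#' @export
#' @examples
#' gap_genes()
gap_genes <- function() c("hb", "Kr", "gt", "kni")

#' Number of modelled genes
#' @return The integer 4.
#' @export
n_genes <- function() 4L

#' Gene index lookup
#'
#' @param gene Gene name (one of `gap_genes()`) or an integer index 1..4.
#' @return Integer index into the fixed gene order.
#' @export
#' @examples
#' gene_index("Kr")
gene_index <- function(gene) {
  if (is.numeric(gene)) {
    gene <- as.integer(gene)
    if (any(gene < 1L | gene > n_genes())) {
      stop("gene index out of range 1..4", call. = FALSE)
    }
    return(gene)
  }
  idx <- match(gene, gap_genes())
  if (anyNA(idx)) {
    stop("unknown gene name(s): ", paste(gene[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}
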