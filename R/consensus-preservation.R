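## Consensus modules across two tissues and differential eigengene-network
## analysis (preservation network, density D).

#' Consensus dissimilarity of two topological overlap networks
#'
#' `d_ij = 1 - min(w1_ij, w2_ij)`, after (by default) aligning the two TOM
#' scales: both matrices are multiplied down so their 95th off-diagonal
#' percentiles match the smaller of the two. Scaling only downward keeps
#' the minimum conservative — a tissue with no coexpression structure can
#' never be inflated into spurious consensus, while for two comparable
#' tissues the alignment only removes a global scale offset. Identical
#' TOMs are left untouched.
#'
#' @param tom1,tom2 TOM `adiponet_network`s over the same genes, same order.
#' @param align logical: apply 95th-percentile scaling (default TRUE).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
consensus_dissimilarity <- function(tom1, tom2, align = TRUE) {
  stopifnot(inherits(tom1, "adiponet_network"), inherits(tom2, "adiponet_network"))
  stop_if(!identical(tom1$gene_ids, tom2$gene_ids),
          "TOMs must cover the same genes in the same order")
  w1 <- tom1$weights
  w2 <- tom2$weights
  if (align) {
    off <- upper.tri(w1)
    q1 <- stats::quantile(w1[off], 0.95, names = FALSE)
    q2 <- stats::quantile(w2[off], 0.95, names = FALSE)
    qt <- min(q1, q2)
    if (q1 > 0) w1 <- w1 * qt / q1
    if (q2 > 0) w2 <- w2 * qt / q2
  }
  d <- 1 - pmin(w1, w2)
  diag(d) <- 0
  d
}

#' Detect consensus modules from a consensus dissimilarity
#'
#' Same clustering/cutting/labelling rules as [detect_modules()], applied to
#' the consensus dissimilarity.
#'
#' @param d consensus dissimilarity matrix.
#' @inheritParams detect_modules
#' @return named character vector gene -> module color.
#' @export
detect_consensus_modules <- function(d, min_module_size = 30L,
                                     cut_height = 0.99,
                                     height_type = c("absolute", "quantile")) {
  cut_dissimilarity(d, min_module_size, cut_height, height_type)
}

#' Eigengene network
#'
#' Adjacency between module eigengenes: `A_IJ = (1 + cor(E_I, E_J)) / 2`.
#'
#' @param eigengenes sample x module matrix.
#' @return object of class `eigengene_network` with fields `module_ids` and
#'   `A`.
#' @export
eigengene_network <- function(eigengenes) {
  stop_if(ncol(eigengenes) < 2L, "need at least 2 modules")
  A <- (1 + stats::cor(eigengenes)) / 2
  diag(A) <- 1
  structure(list(module_ids = colnames(eigengenes), A = A),
            class = "eigengene_network")
}

#' Preservation of two eigengene networks and density D
#'
#' `preserv_IJ = 1 - |A1_IJ - A2_IJ|`; the density `D` is the mean of the
#' off-diagonal preservation entries, `per_module_density` the off-diagonal
#' row means. D = 1 means the between-module relationships are identical in
#' the two tissues.
#'
#' @param net1,net2 `eigengene_network`s over the same modules.
#' @return list with `preserv`, `density_D`, `per_module_density`.
#' @export
preservation <- function(net1, net2) {
  stopifnot(inherits(net1, "eigengene_network"), inherits(net2, "eigengene_network"))
  stop_if(!identical(net1$module_ids, net2$module_ids),
          "eigengene networks must cover the same modules")
  m <- length(net1$module_ids)
  stop_if(m < 2L, "density undefined for a single module")
  pres <- 1 - abs(net1$A - net2$A)
  off <- row(pres) != col(pres)
  list(preserv = pres,
       density_D = mean(pres[off]),
       per_module_density = rowSums(pres * off) / (m - 1))
}
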