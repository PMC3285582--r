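## Weighted gene coexpression network construction: correlation, soft power
## by scale-free fit, adjacency, topological overlap, module detection,
## eigengenes, membership, connectivities.

# fixed module palette; largest module gets the first color, "grey" is
# reserved for unassigned genes
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue",
                   "darkred", "darkgreen", "darkturquoise", "darkgrey",
                   "orange", "darkorange", "white", "skyblue", "saddlebrown",
                   "steelblue", "paleturquoise", "violet", "darkolivegreen",
                   "darkmagenta")

new_network <- function(weights, power_beta, kind) {
  structure(list(gene_ids = rownames(weights), weights = weights,
                 power_beta = power_beta, kind = kind),
            class = "adiponet_network")
}

#' Gene-gene Pearson correlation matrix
#'
#' @param expr probeset x sample matrix with at least 3 samples.
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   genes get correlation 0 to all others (with a warning).
#' @export
correlation_matrix <- function(expr) {
  stop_if(ncol(expr) < 3L, "need at least 3 samples")
  check_finite(expr, "expression")
  sds <- apply(expr, 1L, stats::sd)
  cc <- suppressWarnings(stats::cor(t(expr)))
  if (any(sds == 0)) {
    warning("zero-variance gene(s): correlations set to 0", call. = FALSE)
    bad <- which(sds == 0)
    cc[bad, ] <- 0
    cc[, bad] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Soft-power adjacency
#'
#' Unsigned weighted network: `a_ij = |cor_ij|^beta`, diagonal 1.
#'
#' @param corr correlation matrix.
#' @param beta positive integer soft-thresholding power.
#' @return an adjacency `adiponet_network`.
#' @export
adjacency <- function(corr, beta) {
  stop_if(beta < 1 || beta != round(beta), "beta must be a positive integer")
  a <- abs(corr)^beta
  diag(a) <- 1
  new_network(a, as.integer(beta), "adjacency")
}

whole_network_connectivity <- function(net) {
  w <- if (inherits(net, "adiponet_network")) net$weights else net
  rowSums(w) - diag(w)
}

#' Scale-free topology fit of a weighted network
#'
#' Bins whole-network connectivities into `n_bins` equal-width bins, then
#' regresses `log10(frequency)` on `log10(mean k)` over non-empty bins.
#' Reported as the signed fit index `-sign(slope) * R^2` (truncated below at
#' 0 when the slope is positive), so only decaying degree distributions can
#' pass; a perfect scale-free network scores 1.
#'
#' @param net an adjacency `adiponet_network`, or a connectivity vector.
#' @param n_bins number of connectivity bins (default 10).
#' @return list with `power_beta`, `r2`, `slope`, `n_bins`.
#' @export
scale_free_fit <- function(net, n_bins = 10L) {
  k <- if (is.numeric(net) && is.null(dim(net))) net
       else whole_network_connectivity(net)
  stop_if(diff(range(k)) == 0, "all connectivities identical: fit undefined")
  cuts <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, cuts, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  kmean <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(kmean) & kmean > 0
  stop_if(sum(ok) < 2L, "too few populated bins for a fit")
  x <- log10(kmean[ok])
  y <- log10(freq[ok])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  signed <- -sign(slope) * r2
  if (slope > 0) signed <- max(signed, 0)  # positive slope never passes
  list(power_beta = if (inherits(net, "adiponet_network")) net$power_beta else NA_integer_,
       r2 = unname(signed), slope = unname(slope), n_bins = as.integer(n_bins))
}

#' Choose the soft-thresholding power by the scale-free criterion
#'
#' Returns the smallest candidate power whose signed scale-free fit index
#' reaches `target_r2`; if none qualifies, the power maximizing the index,
#' with a warning.
#'
#' @param corr correlation matrix.
#' @param candidates integer powers to scan.
#' @param target_r2 fit-index threshold (default 0.8).
#' @param n_bins bins for [scale_free_fit()].
#' @return chosen power (integer), with the per-power fit table in
#'   `attr(, "fit_table")`.
#' @export
pick_soft_power <- function(corr, candidates = 1:20, target_r2 = 0.8,
                            n_bins = 10L) {
  stop_if(length(candidates) == 0L, "no candidate powers")
  ac <- abs(corr)
  tab <- data.frame(power_beta = as.integer(candidates), r2 = NA_real_,
                    slope = NA_real_)
  for (i in seq_along(candidates)) {
    k <- rowSums(ac^candidates[i]) - 1
    f <- tryCatch(scale_free_fit(k, n_bins), error = function(e) NULL)
    if (!is.null(f)) {
      tab$r2[i] <- f$r2
      tab$slope[i] <- f$slope
    }
  }
  hit <- which(!is.na(tab$r2) & tab$r2 >= target_r2)
  if (length(hit)) {
    beta <- tab$power_beta[hit[1]]
  } else {
    warning("no candidate reaches target fit index; returning the maximizer",
            call. = FALSE)
    beta <- tab$power_beta[which.max(tab$r2)]
  }
  structure(beta, fit_table = tab)
}

#' Topological overlap matrix
#'
#' Unsigned TOM: for i != j,
#' `w_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k_i = sum_{u != i} a_iu`; diagonal 1.
#'
#' @param adj an adjacency `adiponet_network` (values in \[0,1\], unit
#'   diagonal).
#' @return a TOM `adiponet_network`.
#' @export
topological_overlap <- function(adj) {
  stopifnot(inherits(adj, "adiponet_network"))
  stop_if(adj$kind != "adjacency", "input must be an adjacency network")
  a <- adj$weights
  k <- rowSums(a) - 1
  shared <- a %*% a - 2 * a            # sum_{u != i,j} a_iu a_uj (diag = 1)
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  diag(den) <- 1  # diagonal overwritten below
  stop_if(any(den <= 0), "nonpositive TOM denominator: adjacency outside [0,1]?")
  w <- num / den
  diag(w) <- 1
  w[w < 0] <- 0   # guard tiny negative round-off
  dimnames(w) <- dimnames(a)
  new_network(w, adj$power_beta, "TOM")
}

# shared machinery: average-linkage clustering of a dissimilarity matrix,
# fixed-height cut (absolute on the [0,1] dissimilarity scale by default,
# or at a quantile of merge heights), minimum module size, size-ranked
# color labels; ties in size broken by lexicographic smallest gene id for
# determinism
cut_dissimilarity <- function(d, min_module_size, cut_height,
                              height_type = c("absolute", "quantile")) {
  height_type <- match.arg(height_type)
  ids <- rownames(d)
  if (nrow(d) < min_module_size)
    return(stats::setNames(rep("grey", nrow(d)), ids))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  h <- if (height_type == "quantile")
    stats::quantile(hc$height, cut_height, names = FALSE) else cut_height
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  first_id <- vapply(big, function(g) min(ids[cl == g]), character(1))
  ord <- order(-sizes[big], first_id)
  big <- big[ord]
  labels <- rep("grey", length(cl))
  pal <- c(MODULE_COLORS, sprintf("module%d", seq_len(max(0, length(big) -
                                                            length(MODULE_COLORS)))))
  labels[cl %in% big] <- pal[match(cl[cl %in% big], big)]
  stats::setNames(labels, ids)
}

#' Detect modules from a topological overlap network
#'
#' Average-linkage hierarchical clustering on `1 - TOM`; the dendrogram is
#' cut at a fixed height (default: absolute height 0.99 on the \[0,1\] TOM
#' dissimilarity scale — the static-cut convention of the coexpression
#' framework; `height_type = "quantile"` instead cuts at that quantile of
#' merge heights). Clusters of at least `min_module_size` genes become
#' modules labelled by decreasing size from a fixed color palette
#' (largest = "turquoise"); everything else is "grey".
#'
#' @param tom a TOM `adiponet_network`.
#' @param min_module_size minimum module size (default 30).
#' @param cut_height cut height (absolute dissimilarity or quantile).
#' @param height_type `"absolute"` (default) or `"quantile"`.
#' @return named character vector gene -> module color.
#' @export
detect_modules <- function(tom, min_module_size = 30L, cut_height = 0.99,
                           height_type = c("absolute", "quantile")) {
  stopifnot(inherits(tom, "adiponet_network"))
  d <- 1 - tom$weights
  cut_dissimilarity(d, min_module_size, cut_height, height_type)
}

#' Module eigengenes by singular value decomposition
#'
#' Per module: genes are standardized across samples, the first principal
#' component of samples is extracted via SVD, its sign fixed so the
#' eigengene correlates positively with the module's mean standardized
#' expression, and the profile scaled to unit variance.
#'
#' @param expr probeset x sample matrix.
#' @param labels named gene -> module vector ("grey" skipped).
#' @return sample x module matrix, columns named `ME<module>`.
#' @export
module_eigengene <- function(expr, labels) {
  mods <- setdiff(unique(labels), "grey")
  stop_if(length(mods) == 0L, "no modules to summarize")
  samples <- colnames(expr)
  out <- matrix(NA_real_, ncol(expr), length(mods),
                dimnames = list(samples, paste0("ME", mods)))
  for (j in seq_along(mods)) {
    genes <- names(labels)[labels == mods[j]]
    stop_if(length(genes) < 2L, "module '", mods[j], "' has fewer than 2 genes")
    z <- standardize_rows(expr[genes, , drop = FALSE])
    sv <- svd(t(z), nu = 1L, nv = 0L)
    e <- sv$u[, 1L]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    out[, j] <- e / stats::sd(e)
  }
  out
}

#' Module membership and intramodular connectivity
#'
#' `MM_gm = cor(x_g, E_m)` with a two-sided p-value from the t-distribution
#' on n - 2 df; intramodular connectivity is `|MM|` for the gene's own
#' module, whole-network connectivity the row sum of adjacency.
#'
#' @param expr probeset x sample matrix.
#' @param eigengenes sample x module matrix from [module_eigengene()].
#' @param labels optional gene -> module vector (enables `k_intramodular`).
#' @param adj optional adjacency network (enables `k_whole`).
#' @return list with matrices `mm`, `p`, and per-gene data.frame `table`.
#' @export
module_membership <- function(expr, eigengenes, labels = NULL, adj = NULL) {
  n <- ncol(expr)
  mm <- stats::cor(t(expr), eigengenes)
  tt <- mm * sqrt((n - 2) / pmax(1 - mm^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  colnames(mm) <- colnames(p) <- sub("^ME", "", colnames(eigengenes))
  tab <- data.frame(probeset_id = rownames(expr), stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    tab$module <- unname(labels[tab$probeset_id])
    own <- match(tab$module, colnames(mm))
    tab$mm_own <- mm[cbind(seq_len(nrow(mm)), own)]
    tab$mm_p <- p[cbind(seq_len(nrow(p)), own)]
    tab$k_intramodular <- abs(tab$mm_own)
  }
  if (!is.null(adj)) tab$k_whole <- whole_network_connectivity(adj)
  list(mm = mm, p = p, table = tab)
}

#' Gene significance
#'
#' `GS = -log10(p)` of a gene-trait association; `p = 0` is capped.
#'
#' @param p numeric p-values in \[0, 1\] (a `DeResult` data.frame with a `p`
#'   column is also accepted).
#' @param cap value substituted for `-log10(0)` (default 300, with warning).
#' @return numeric vector of gene significances.
#' @export
gene_significance <- function(p, cap = 300) {
  if (is.data.frame(p)) p <- p$p
  stop_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  gs <- -log10(p)
  if (any(p == 0, na.rm = TRUE)) {
    warning("p = 0 capped at ", cap, call. = FALSE)
    gs[p == 0] <- cap
  }
  gs
}
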