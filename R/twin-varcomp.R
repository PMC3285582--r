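## Maximum-likelihood variance decomposition of expression traits in a twin
## repeated-measures design. The likelihood is evaluated pair-by-pair from
## the block covariance implied by six variance components:
##   sigma2_pair  (shared by co-twins of either zygosity; genetics A/2 + C)
##   sigma2_zyg   (shared only within MZ pairs; genetics A/2)
##   sigma2_ind   (individual environment, constant across visits)
##   sigma2_cv    (common visit: shared by co-twins sampled at one visit)
##   sigma2_iv    (individual visit)
##   sigma2_res   (residual, per aliquot)
## Fixed effects (intercept + batch) are profiled out by GLS; the profiled
## log-likelihood is maximized by L-BFGS-B with analytic gradients under
## nonnegativity constraints, from a moment start plus random restarts.

VC_NAMES <- c("sigma2_pair", "sigma2_zyg", "sigma2_ind", "sigma2_cv",
              "sigma2_iv", "sigma2_res")

#' Precompute the twin-likelihood structure for a design
#'
#' Builds the per-pair indicator matrices and fixed-effect design once, so
#' repeated fits over many probesets (or SNPs) reuse them.
#'
#' @param design data.frame with `pair_id`, `zygosity` ("MZ"/"DZ"),
#'   `twin_index`, `visit`, `aliquot`, and any covariate columns; one row
#'   per observation, aligned with the data vectors to be fitted.
#' @param covariates fixed-effect covariate columns (constant columns are
#'   dropped); an intercept is always included.
#' @param extra_fixed optional matrix of additional fixed-effect columns
#'   (e.g. SNP dosage), same row order as `design`.
#' @return object of class `twin_structure`.
#' @export
twin_structure <- function(design, covariates = "plate", extra_fixed = NULL) {
  req <- c("pair_id", "zygosity", "twin_index", "visit", "aliquot")
  stop_if(!all(req %in% names(design)), "design lacks required columns")
  n_pairs <- length(unique(design$pair_id))
  stop_if(n_pairs < 10L, "need at least 10 twin pairs")

  ord <- order(design$pair_id, design$twin_index, design$visit, design$aliquot)
  d <- design[ord, , drop = FALSE]

  X <- matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  for (cn in covariates) {
    v <- d[[cn]]
    if (is.null(v) || length(unique(v)) < 2L) next
    mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
    colnames(mm) <- paste0(cn, seq_len(ncol(mm)))
    X <- cbind(X, mm)
  }
  if (!is.null(extra_fixed))
    X <- cbind(X, as.matrix(extra_fixed)[ord, , drop = FALSE])

  pair_f <- factor(d$pair_id, levels = unique(d$pair_id))
  idx_by_pair <- split(seq_len(nrow(d)), pair_f)

  make_block <- function(ix) {
    tw <- d$twin_index[ix]; vi <- d$visit[ix]
    mz <- d$zygosity[ix][1] == "MZ"
    same_tw <- outer(tw, tw, "==") * 1
    list(M = list(pair = matrix(1, length(ix), length(ix)),
                  zyg = if (mz) matrix(1, length(ix), length(ix)) else same_tw,
                  ind = same_tw,
                  cv = outer(vi, vi, "==") * 1,
                  iv = (outer(vi, vi, "==") & outer(tw, tw, "==")) * 1,
                  res = diag(length(ix))),
         d = length(ix))
  }
  sig <- vapply(idx_by_pair, function(ix)
    paste(d$zygosity[ix][1], paste(d$twin_index[ix], d$visit[ix],
                                   d$aliquot[ix], collapse = ";"),
          sep = "|"), character(1))
  pat_of_pair <- match(sig, unique(sig))
  blocks <- lapply(idx_by_pair[match(unique(sig), sig)], make_block)
  # pattern-stacked observation indices (pairs x block-size) so the
  # likelihood vectorizes over all pairs sharing a block shape; the
  # theta-independent fixed-effect cross-products are precomputed here
  for (p in seq_along(blocks)) {
    members <- idx_by_pair[pat_of_pair == p]
    idx <- do.call(rbind, members)
    blocks[[p]]$idx <- idx
    d_p <- ncol(idx)
    XtX <- vector("list", d_p * d_p)
    for (a in seq_len(d_p)) for (b in seq_len(d_p))
      XtX[[(a - 1L) * d_p + b]] <-
        crossprod(X[idx[, a], , drop = FALSE], X[idx[, b], , drop = FALSE])
    blocks[[p]]$XtX <- XtX
  }

  structure(list(order = ord, X = X, blocks = blocks,
                 n = nrow(d), n_pairs = n_pairs),
            class = "twin_structure")
}

# theta-independent X' y slices per pattern, computed once per trait
twin_xty <- function(st, y) {
  lapply(st$blocks, function(blk) {
    idx <- blk$idx
    d <- ncol(idx)
    out <- vector("list", d * d)
    for (a in seq_len(d)) for (b in seq_len(d))
      out[[(a - 1L) * d + b]] <-
        crossprod(st$X[idx[, a], , drop = FALSE], y[idx[, b]])
    out
  })
}

# profiled negative log-likelihood and analytic gradient at theta (6 vars);
# all pairs sharing a block shape are processed as one stacked matrix
twin_negloglik <- function(theta, st, y, want_grad = FALSE, xty = NULL) {
  ridge <- 1e-9 * max(sum(theta), 1)
  pats <- lapply(st$blocks, function(b) {
    S <- theta[1] * b$M$pair + theta[2] * b$M$zyg + theta[3] * b$M$ind +
      theta[4] * b$M$cv + theta[5] * b$M$iv + (theta[6] + ridge) * b$M$res
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(Sinv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
  })
  if (any(vapply(pats, is.null, logical(1)))) return(list(value = 1e10))

  if (is.null(xty)) xty <- twin_xty(st, y)
  q <- ncol(st$X)
  A <- matrix(0, q, q)
  bvec <- numeric(q)
  for (p in seq_along(st$blocks)) {
    blk <- st$blocks[[p]]
    Si <- pats[[p]]$Sinv
    d <- ncol(blk$idx)
    for (a in seq_len(d)) for (b in seq_len(d)) {
      ab <- (a - 1L) * d + b
      A <- A + Si[a, b] * blk$XtX[[ab]]
      bvec <- bvec + Si[a, b] * xty[[p]][[ab]]
    }
  }
  beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
  if (is.null(beta)) return(list(value = 1e10))

  fitted <- drop(st$X %*% beta)
  ll <- -0.5 * st$n * log(2 * pi)
  grad <- numeric(6)
  for (p in seq_along(st$blocks)) {
    blk <- st$blocks[[p]]
    idx <- blk$idx
    Si <- pats[[p]]$Sinv
    R <- matrix((y - fitted)[idx], nrow(idx), ncol(idx))
    CR <- crossprod(R)                  # d x d: sum over pairs of r r'
    ll <- ll - 0.5 * (nrow(idx) * pats[[p]]$logdet + sum(Si * CR))
    if (want_grad) {
      U <- R %*% Si
      CU <- crossprod(U)
      for (m in seq_along(blk$M)) {
        M <- blk$M[[m]]
        grad[m] <- grad[m] + 0.5 * (sum(M * CU) - nrow(idx) * sum(Si * M))
      }
    }
  }
  list(value = -ll, gradient = -grad, beta = beta, A = A)
}

#' Fit the six-component twin mixed model by maximum likelihood
#'
#' @param y numeric vector of per-observation values (one expression trait
#'   or eigengene), aligned with `design` rows.
#' @param design a `twin_structure` or the design data.frame to build one
#'   from.
#' @param covariates fixed-effect covariates when `design` is a data.frame.
#' @param n_starts random restarts in addition to the moment start.
#' @param seed seed for the restart draws.
#' @param fix_zero components constrained to zero, by short name among
#'   `"pair"`, `"zyg"`, `"ind"`, `"cv"`, `"iv"`, `"res"` (needed when the
#'   design cannot identify them, e.g. `cv` in a one-visit design).
#' @return object of class `twin_vc`: the six variances, `total`, `loglik`,
#'   `converged`, fixed-effect estimates `beta` and their covariance
#'   `beta_cov`.
#' @export
fit_twin_model <- function(y, design, covariates = "plate", n_starts = 5L,
                           seed = 1L, fix_zero = character()) {
  st <- if (inherits(design, "twin_structure")) design
        else twin_structure(design, covariates)
  stop_if(length(y) != st$n, "y length does not match design")
  y <- y[st$order]  # y arrives in the original design row order

  sc <- stats::sd(y)
  stop_if(!is.finite(sc) || sc == 0, "response is constant")
  ys <- (y - mean(y)) / sc
  v0 <- 1

  short <- c("pair", "zyg", "ind", "cv", "iv", "res")
  stop_if(!all(fix_zero %in% short), "unknown component in fix_zero")
  free <- which(!short %in% fix_zero)
  embed <- function(thf) {
    th <- numeric(6)
    th[free] <- thf
    th
  }
  xty <- twin_xty(st, ys)
  # optim calls fn and gr separately at the same point; memoize one eval
  cache <- new.env(parent = emptyenv())
  evaluate <- function(thf) {
    if (!is.null(cache$th) && identical(cache$th, thf)) return(cache$res)
    res <- twin_negloglik(embed(thf), st, ys, want_grad = TRUE, xty = xty)
    cache$th <- thf
    cache$res <- res
    res
  }
  fn <- function(thf) evaluate(thf)$value
  gr <- function(thf) {
    g <- evaluate(thf)$gradient
    if (is.null(g)) rep(0, length(free)) else g[free]
  }

  starts <- list(rep(v0 / length(free), length(free)))
  set.seed(derive_seed(seed, 777L))
  for (s in seq_len(n_starts)) {
    w <- stats::runif(length(free))
    starts[[s + 1L]] <- v0 * w / sum(w)
  }
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, fn, gr, method = "L-BFGS-B",
                   lower = rep(0, length(free)),
                   control = list(maxit = 200L, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  stop_if(is.null(best), "all optimization starts failed")
  final <- twin_negloglik(embed(best$par), st, ys, xty = xty)
  theta <- embed(best$par) * sc^2
  names(theta) <- VC_NAMES
  res <- list(loglik = -(best$value) - st$n * log(sc),
              converged = best$convergence == 0,
              beta = drop(final$beta) * sc,
              beta_cov = solve(final$A) * sc^2,
              total = sum(theta))
  res <- c(as.list(theta), res)
  class(res) <- "twin_vc"
  res
}

#' @rdname fit_twin_model
#' @param x,... print method arguments.
#' @method print twin_vc
#' @export
print.twin_vc <- function(x, ...) {
  cat("Twin variance components (ML):\n")
  print(round(unlist(x[VC_NAMES]), 5))
  cat(sprintf("familiality F = %.3f, heritability h2 = %.3f, loglik = %.2f%s\n",
              familiality(x), heritability(x), x$loglik,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Familiality and heritability from fitted variance components
#'
#' Familiality `F = (sigma2_pair + sigma2_zyg) / total` (additive genetics
#' plus common environment, since the pair variance is A/2 + C and the
#' MZ-extra variance is A/2); heritability `h2 = 2 * sigma2_zyg / total`.
#'
#' @param vc a `twin_vc` fit (or named list with the six variances).
#' @return numeric scalar.
#' @export
familiality <- function(vc) {
  tot <- sum(unlist(vc[VC_NAMES]))
  stop_if(tot == 0, "total variance is zero: familiality undefined")
  (vc$sigma2_pair + vc$sigma2_zyg) / tot
}

#' @rdname familiality
#' @export
heritability <- function(vc) {
  tot <- sum(unlist(vc[VC_NAMES]))
  stop_if(tot == 0, "total variance is zero: heritability undefined")
  2 * vc$sigma2_zyg / tot
}

#' Proportion summary of a twin fit
#'
#' @param vc a `twin_vc` fit.
#' @return one-row data.frame with the six variances, their proportions,
#'   familiality, heritability, and the convergence flag.
#' @export
heritability_summary <- function(vc) {
  v <- unlist(vc[VC_NAMES])
  tot <- sum(v)
  out <- as.data.frame(as.list(v))
  names(out) <- VC_NAMES
  props <- as.data.frame(as.list(v / tot))
  names(props) <- paste0("prop_", sub("sigma2_", "", VC_NAMES))
  cbind(out, props,
        data.frame(familiality = familiality(vc),
                   heritability = heritability(vc),
                   converged = vc$converged))
}

#' Variance decomposition of module eigengenes in a twin cohort
#'
#' Applies module assignments from another cohort: computes each module's
#' eigengene on the twin expression matrix (restricted to shared genes) and
#' fits the twin model to it.
#'
#' @param labels named gene -> module vector (from the reference cohort).
#' @param twin_expr probeset x sample matrix for the twin cohort.
#' @param design twin design data.frame (rows aligned to `twin_expr`
#'   columns).
#' @param covariates fixed-effect covariates.
#' @param n_starts,seed passed to [fit_twin_model()].
#' @return data.frame with one [heritability_summary()] row per module
#'   (modules with fewer than 2 shared genes are skipped with a message).
#' @export
decompose_eigengenes <- function(labels, twin_expr, design,
                                 covariates = "plate", n_starts = 5L,
                                 seed = 1L) {
  st <- twin_structure(design, covariates)
  mods <- setdiff(unique(labels), "grey")
  rows <- list()
  for (m in mods) {
    genes <- intersect(names(labels)[labels == m], rownames(twin_expr))
    if (length(genes) < 2L) {
      message("module '", m, "' has <2 shared genes: skipped")
      next
    }
    e <- module_eigengene(twin_expr[genes, , drop = FALSE],
                          stats::setNames(rep(m, length(genes)), genes))
    fit <- fit_twin_model(drop(e), design, covariates, n_starts, seed)
    rows[[m]] <- cbind(data.frame(module = m), heritability_summary(fit))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare familiality distributions between groups
#'
#' Paired comparisons use the Wilcoxon signed-rank test, unpaired the
#' Wilcoxon rank-sum test; two-sided. Medians and IQRs of both groups are
#' reported.
#'
#' @param group_a,group_b numeric vectors of familiality estimates.
#' @param paired logical.
#' @return list with `statistic`, `p`, `median_a`, `median_b`, `iqr_a`,
#'   `iqr_b`.
#' @export
compare_familiality <- function(group_a, group_b, paired = FALSE) {
  if (paired) {
    stop_if(length(group_a) != length(group_b),
            "paired comparison needs equal lengths")
    if (all(group_a == group_b)) {
      message("all paired differences are zero; p = 1 by convention")
      return(list(statistic = NA_real_, p = 1,
                  median_a = stats::median(group_a),
                  median_b = stats::median(group_b),
                  iqr_a = stats::IQR(group_a), iqr_b = stats::IQR(group_b)))
    }
  }
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, paired = paired))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_a = stats::median(group_a), median_b = stats::median(group_b),
       iqr_a = stats::IQR(group_a), iqr_b = stats::IQR(group_b))
}
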