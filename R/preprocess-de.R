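## Expression filtering, replicate averaging, single-gene differential
## expression, FDR control, and overlap summaries.

#' Average technical replicates
#'
#' Collapses a probeset x sample matrix to one column per
#' subject x tissue x visit group by arithmetic mean; non-replicated samples
#' pass through unchanged.
#'
#' @param expr probeset x sample matrix.
#' @param annotation data.frame with `sample_id`, `subject_id`, and
#'   optionally `tissue`, `visit`, `replicate_id`.
#' @return list with `expr` (collapsed matrix, columns named by group) and
#'   `annotation` (one row per group, first-sample metadata retained).
#' @export
average_technical_replicates <- function(expr, annotation) {
  stop_if(!all(colnames(expr) %in% annotation$sample_id),
          "every expression sample must be annotated")
  ann <- annotation[match(colnames(expr), annotation$sample_id), , drop = FALSE]
  tissue <- ann$tissue %||% rep("NA", nrow(ann))
  visit <- ann$visit %||% rep(1L, nrow(ann))
  if (!is.null(ann$replicate_id)) {
    span <- tapply(tissue, ann$replicate_id, function(x) length(unique(x)))
    stop_if(any(span > 1), "a replicate group spans multiple tissues")
  }
  key <- paste(ann$subject_id, tissue, visit, sep = ".")
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  out <- matrix(vapply(groups, function(ix) rowMeans(expr[, ix, drop = FALSE]),
                       numeric(nrow(expr))),
                nrow(expr), length(groups))
  dimnames(out) <- list(rownames(expr), names(groups))
  first <- vapply(groups, `[`, integer(1), 1L)
  ann_out <- ann[first, , drop = FALSE]
  ann_out$sample_id <- names(groups)
  rownames(ann_out) <- NULL
  list(expr = out, annotation = ann_out)
}

#' Filter to expressed autosomal probesets
#'
#' Default rule: retain a probeset iff (optionally) autosomal and its
#' replicate-averaged intensity exceeds `threshold` in at least
#' `min_fraction` of individuals (boundary inclusive). The alternative
#' reading — overall mean across individuals above the threshold — is
#' available as `rule = "overall_mean"`.
#'
#' @param expr probeset x individual matrix (replicates already averaged).
#' @param threshold log2-intensity cutoff (default 4).
#' @param min_fraction minimum fraction of individuals above threshold.
#' @param autosomal_ids optional character vector; probesets outside it are
#'   dropped regardless of intensity.
#' @param rule `"per_individual"` (default) or `"overall_mean"`.
#' @return character vector of retained probeset ids.
#' @export
filter_expressed <- function(expr, threshold = 4.0, min_fraction = 0.10,
                             autosomal_ids = NULL,
                             rule = c("per_individual", "overall_mean")) {
  rule <- match.arg(rule)
  stop_if(nrow(expr) == 0L || ncol(expr) == 0L, "empty expression matrix")
  if (rule == "per_individual") {
    frac <- rowMeans(expr > threshold)
    keep <- frac >= min_fraction
  } else {
    keep <- rowMeans(expr) > threshold
  }
  ids <- rownames(expr)[keep]
  if (!is.null(autosomal_ids)) ids <- intersect(ids, autosomal_ids)
  ids
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1; `NA` p-values
#' propagate as `NA` and are excluded from `m`.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return numeric vector of q-values, same order as input.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  stop_if(any(p < 0 | p > 1), "p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(pvals))
  if (m) {
    o <- order(p, decreasing = TRUE)
    qs <- pmin(1, cummin(p[o] * m / seq(m, 1)))
    q[ok][o] <- qs
  }
  q
}

# vectorized OLS of many probesets on one common design matrix;
# returns effect/se/t/p for the column named `term`
ols_many <- function(Y, X, term) {
  qrX <- qr(X)
  stop_if(qrX$rank < ncol(X), "design matrix is rank deficient")
  n <- nrow(X)
  df <- n - ncol(X)
  coefs <- qr.coef(qrX, t(Y))                      # p_design x n_probesets
  res <- t(Y) - X %*% coefs
  rss <- colSums(res^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrX))
  j <- match(term, colnames(X))
  stop_if(is.na(j), "term not found in design")
  se <- sqrt(sigma2 * XtXinv[j, j])
  eff <- coefs[j, ]
  tt <- eff / se
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  data.frame(effect = eff, se = se, t = tt, p = p, row.names = NULL)
}

# build a model matrix from annotation columns, dropping constant covariates
# with a warning (rank-deficiency guard)
build_design <- function(ann, response, covariates) {
  cols <- c(response, covariates)
  keep <- vapply(cols, function(cn) {
    v <- ann[[cn]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      if (cn == response) stop("response '", cn, "' is constant", call. = FALSE)
      warning("dropping constant covariate '", cn, "'", call. = FALSE)
      return(FALSE)
    }
    TRUE
  }, logical(1))
  cols <- cols[keep]
  fm <- stats::as.formula(paste("~", paste(cols, collapse = " + ")))
  stats::model.matrix(fm, data = ann)
}

#' Single-gene differential expression by ordinary least squares
#'
#' Regresses each probeset's expression on the response (case/control status
#' or a quantitative trait) adjusting for covariates; two-sided t-test on
#' the response coefficient, BH FDR across probesets.
#'
#' @param expr probeset x sample matrix.
#' @param annotation sample annotation data.frame (must include `sample_id`,
#'   the response column and covariates). `case_status` is coded
#'   control = 0, case = 1.
#' @param response column name of the response.
#' @param covariates character vector of adjustment covariates.
#' @return data.frame: probeset_id, effect, se, p, fdr_q, contrast.
#' @export
de_single_gene <- function(expr, annotation, response,
                           covariates = c("gender", "plate")) {
  ann <- annotation[match(colnames(expr), annotation$sample_id), , drop = FALSE]
  if (response == "case_status")
    ann$case_status <- as.integer(ann$case_status == "case")
  cc <- stats::complete.cases(ann[, c(response, covariates), drop = FALSE])
  ann <- ann[cc, , drop = FALSE]
  Y <- expr[, cc, drop = FALSE]
  X <- build_design(ann, response, covariates)
  term <- if (is.numeric(ann[[response]])) response else
    grep(paste0("^", response), colnames(X), value = TRUE)[1]
  fit <- ols_many(Y, X, term)
  data.frame(probeset_id = rownames(expr), effect = fit$effect, se = fit$se,
             p = fit$p, fdr_q = bh_fdr(fit$p),
             contrast = if (response == "case_status") "case_vs_control" else response,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Between-depot differential expression (paired mixed model)
#'
#' Per probeset, fits a linear mixed model with tissue, case/control status,
#' gender and plate as fixed effects and subject as a random intercept
#' (maximum likelihood); Wald normal p-value for the tissue coefficient,
#' BH FDR across probesets.
#'
#' @param expr_abd,expr_glu probeset x sample matrices for the two depots
#'   (same probesets); columns map to subjects via `annotation`.
#' @param annotation data.frame with `sample_id`, `subject_id`, and optional
#'   `case_status`, `gender`, `plate` columns.
#' @return data.frame: probeset_id, effect (tissue2 - tissue1), se, p, fdr_q,
#'   contrast = "depot".
#' @export
de_between_depots <- function(expr_abd, expr_glu, annotation) {
  stop_if(!identical(rownames(expr_abd), rownames(expr_glu)),
          "depot matrices must share probesets")
  ann_a <- annotation[match(colnames(expr_abd), annotation$sample_id), , drop = FALSE]
  ann_g <- annotation[match(colnames(expr_glu), annotation$sample_id), , drop = FALSE]
  stop_if(length(intersect(ann_a$subject_id, ann_g$subject_id)) == 0L,
          "no subject contributes both depots")
  long <- rbind(
    data.frame(subject = ann_a$subject_id, tissue = "ABD",
               case_status = ann_a$case_status %||% NA,
               gender = ann_a$gender %||% NA, plate = ann_a$plate %||% NA,
               col = seq_len(ncol(expr_abd)), mat = 1L),
    data.frame(subject = ann_g$subject_id, tissue = "GLU",
               case_status = ann_g$case_status %||% NA,
               gender = ann_g$gender %||% NA, plate = ann_g$plate %||% NA,
               col = seq_len(ncol(expr_glu)), mat = 2L))
  fixed <- "y ~ tissue"
  for (cn in c("case_status", "gender", "plate")) {
    v <- long[[cn]]
    if (!all(is.na(v)) && length(unique(v[!is.na(v)])) > 1L)
      fixed <- paste(fixed, "+", cn)
  }
  fm <- stats::as.formula(paste(fixed, "+ (1 | subject)"))
  n <- nrow(expr_abd)
  eff <- se <- p <- numeric(n)
  fallback <- 0L
  for (i in seq_len(n)) {
    long$y <- ifelse(long$mat == 1L, expr_abd[i, long$col], expr_glu[i, long$col])
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(fm, data = long, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- summary(fit)$coefficients
    } else {
      # degenerate fits (e.g. zero residual variance): within-subject OLS
      # with subject as fixed effect gives the same tissue estimand
      fallback <- fallback + 1L
      fmf <- stats::as.formula(paste(fixed, "+ subject"))
      cf <- suppressWarnings(summary(stats::lm(fmf, data = long)))$coefficients
    }
    j <- grep("^tissue", rownames(cf))[1]
    eff[i] <- cf[j, "Estimate"]
    se[i] <- cf[j, "Std. Error"]
    p[i] <- 2 * stats::pnorm(abs(cf[j, "Estimate"] / cf[j, "Std. Error"]),
                             lower.tail = FALSE)
  }
  if (fallback)
    message(fallback, " probeset(s) fell back to fixed-effects OLS")
  data.frame(probeset_id = rownames(expr_abd), effect = eff, se = se, p = p,
             fdr_q = bh_fdr(p), contrast = "depot",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-set overlap summary with percentages of the union
#'
#' @param set_a,set_b character vectors over the same id universe.
#' @param digits decimal places for the reported percentages (the raw values
#'   are also returned).
#' @return list with counts `a_only`, `b_only`, `both`, `union`, raw
#'   percentages `pct_a_only`, `pct_b_only`, `pct_both`, and the same rounded
#'   to `digits`.
#' @export
overlap_summary <- function(set_a, set_b, digits = 1) {
  stop_if(length(set_a) == 0L && length(set_b) == 0L, "both sets are empty")
  a_only <- length(setdiff(set_a, set_b))
  b_only <- length(setdiff(set_b, set_a))
  both <- length(intersect(set_a, set_b))
  u <- a_only + b_only + both
  pct <- 100 * c(a_only, b_only, both) / u
  list(a_only = a_only, b_only = b_only, both = both, union = u,
       pct_a_only = pct[1], pct_b_only = pct[2], pct_both = pct[3],
       pct_a_only_rounded = round(pct[1], digits),
       pct_b_only_rounded = round(pct[2], digits),
       pct_both_rounded = round(pct[3], digits))
}
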