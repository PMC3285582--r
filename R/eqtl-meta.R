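## Genotype QC, cis-pair definition, per-study eQTL regression (OLS and
## twin mixed model), inverse-variance fixed-effects meta-analysis with
## Cochran heterogeneity, permutation empirical p, and module-eigengene QTL.

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test on the heterozygote count given the minor-allele
#' count (two-sided by summing the probabilities of all heterozygote counts
#' no more likely than the observed one).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_minor <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n == 0 || n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # P(het = h | n, n_minor) via log-factorials
  logp <- lgamma(n + 1) - lgamma((n_minor - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma(n - (n_minor + hets) / 2 + 1) +
    hets * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
    lgamma(2 * n + 1)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  if (is.na(obs)) return(NA_real_)
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Drops a SNP when MAF < `maf_lo`, when its call rate is below `callrate_a`
#' with MAF > `maf_mid`, when its call rate is below `callrate_b` with
#' MAF <= `maf_mid`, or when the HWE exact-test p (computed on unrelated
#' samples) is below `hwe_p`.
#'
#' @param geno snp x sample dosage matrix in \{0,1,2, NA\}.
#' @param maf_lo,callrate_a,maf_mid,callrate_b,hwe_p thresholds (defaults
#'   1%, 95%, 5%, 99%, 1e-4).
#' @param unrelated_ids sample ids to use for HWE (e.g. one twin per pair);
#'   default all samples. If empty, HWE is skipped with a warning.
#' @return list with `geno` (filtered matrix) and `report` (per-SNP
#'   data.frame: snp_id, maf, call_rate, hwe_p, kept, reason).
#' @export
genotype_qc <- function(geno, maf_lo = 0.01, callrate_a = 0.95,
                        maf_mid = 0.05, callrate_b = 0.99, hwe_p = 1e-4,
                        unrelated_ids = NULL) {
  stop_if(!all(geno %in% c(0, 1, 2, NA)), "dosages must be 0/1/2 or missing")
  call_rate <- rowMeans(!is.na(geno))
  freq <- rowMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0

  unrel <- if (is.null(unrelated_ids)) colnames(geno)
           else intersect(unrelated_ids, colnames(geno))
  if (length(unrel) == 0L) {
    warning("no unrelated samples: HWE filter skipped", call. = FALSE)
    hwe <- rep(NA_real_, nrow(geno))
  } else {
    gu <- geno[, unrel, drop = FALSE]
    hwe <- vapply(seq_len(nrow(gu)), function(i) {
      g <- gu[i, ]
      hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                     sum(g == 2, na.rm = TRUE))
    }, numeric(1))
  }
  reason <- rep("", nrow(geno))
  fail_maf <- maf < maf_lo
  fail_cr <- (call_rate < callrate_a & maf > maf_mid) |
    (call_rate < callrate_b & maf <= maf_mid)
  fail_hwe <- !is.na(hwe) & hwe < hwe_p
  reason[fail_hwe] <- "hwe"
  reason[fail_cr] <- "call_rate"
  reason[fail_maf] <- "maf"
  kept <- !(fail_maf | fail_cr | fail_hwe)
  report <- data.frame(snp_id = rownames(geno), maf = maf,
                       call_rate = call_rate, hwe_p = hwe, kept = kept,
                       reason = reason, stringsAsFactors = FALSE,
                       row.names = NULL)
  list(geno = geno[kept, , drop = FALSE], report = report)
}

#' Define cis SNP-gene pairs
#'
#' A SNP is cis to a gene when on the same chromosome and within `window`
#' bp of the gene's start or stop (boundaries inclusive, positions 1-based).
#'
#' @param snps data.frame: snp_id, chrom, pos.
#' @param genes data.frame: probeset_id, chrom, start, stop.
#' @param window bp window (default 500 kb).
#' @return data.frame of (snp_id, probeset_id) pairs.
#' @export
define_cis_pairs <- function(snps, genes, window = 500000) {
  rows <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    s <- snps[snps$chrom == ch, , drop = FALSE]
    if (!nrow(s) || !nrow(g)) next
    for (i in seq_len(nrow(g))) {
      hit <- s$pos >= g$start[i] - window & s$pos <= g$stop[i] + window
      if (any(hit))
        rows[[length(rows) + 1L]] <-
          data.frame(snp_id = s$snp_id[hit], probeset_id = g$probeset_id[i],
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(snp_id = character(), probeset_id = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-study cis-eQTL regression (OLS, additive coding)
#'
#' Per (SNP, probeset) pair: OLS of expression on minor-allele dosage plus
#' covariates; missing dosages are dropped pairwise; pairs with fewer than
#' `min_n` complete observations are skipped with a message.
#'
#' @param expr probeset x sample matrix.
#' @param geno snp x sample dosage matrix (shared sample ids).
#' @param pairs data.frame from [define_cis_pairs()].
#' @param annotation sample annotation (for covariates); may be NULL when
#'   `covariates` is empty.
#' @param covariates adjustment covariates (default gender and plate).
#' @param min_n minimum complete observations per pair.
#' @return data.frame: snp_id, probeset_id, beta, se, p, n.
#' @export
eqtl_single_study <- function(expr, geno, pairs, annotation = NULL,
                              covariates = c("gender", "plate"),
                              min_n = 10L) {
  samples <- intersect(colnames(expr), colnames(geno))
  stop_if(length(samples) < min_n, "too few shared samples")
  Z <- matrix(1, length(samples), 1)
  if (length(covariates) && !is.null(annotation)) {
    ann <- annotation[match(samples, annotation$sample_id), , drop = FALSE]
    for (cn in covariates) {
      v <- ann[[cn]]
      if (is.null(v) || length(unique(v[!is.na(v)])) < 2L) next
      Z <- cbind(Z, stats::model.matrix(~v)[, -1, drop = FALSE])
    }
  }
  res <- vector("list", nrow(pairs))
  skipped <- 0L
  for (r in seq_len(nrow(pairs))) {
    g <- geno[pairs$snp_id[r], samples]
    y <- expr[pairs$probeset_id[r], samples]
    ok <- !is.na(g) & !is.na(y)
    if (sum(ok) < min_n || stats::var(g[ok]) == 0) {
      skipped <- skipped + 1L
      next
    }
    X <- cbind(g[ok], Z[ok, , drop = FALSE])
    fit <- stats::lm.fit(X, y[ok])
    df <- sum(ok) - fit$rank
    if (df < 1L || fit$rank < ncol(X)) { skipped <- skipped + 1L; next }
    sigma2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(sigma2 * XtXinv[1, 1])
    beta <- fit$coefficients[1]
    res[[r]] <- data.frame(snp_id = pairs$snp_id[r],
                           probeset_id = pairs$probeset_id[r],
                           beta = beta, se = se,
                           p = 2 * stats::pt(abs(beta / se), df,
                                             lower.tail = FALSE),
                           n = sum(ok), stringsAsFactors = FALSE)
  }
  if (skipped) message(skipped, " pair(s) skipped (too few observations)")
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(snp_id = character(), probeset_id = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      n = integer())
  rownames(out) <- NULL
  out
}

#' Twin-cohort cis-eQTL (mixed model, Wald test)
#'
#' Fits the six-component twin covariance with dosage and plate as fixed
#' effects; Wald normal test on the dosage coefficient. Genotypes are per
#' subject (co-twins may share a column via `subject_id`).
#'
#' @param expr probeset x sample matrix (twin samples).
#' @param geno snp x subject dosage matrix.
#' @param design twin design data.frame aligned with `expr` columns
#'   (`sample_id`, `subject_id`, pair/zygosity/visit/aliquot, plate).
#' @param pairs data.frame of (snp_id, probeset_id) pairs.
#' @param covariates fixed-effect covariates (default plate).
#' @param n_starts restarts for the variance optimization (default 2 for
#'   throughput; the full model uses 5).
#' @param seed restart seed.
#' @return data.frame: snp_id, probeset_id, beta, se, p, n.
#' @export
eqtl_twin_study <- function(expr, geno, design, pairs,
                            covariates = "plate", n_starts = 2L, seed = 1L) {
  des <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
  res <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    dose <- geno[pairs$snp_id[r], des$subject_id]
    ok <- !is.na(dose)
    if (sum(ok) < 10L || stats::var(dose[ok]) == 0) next
    st <- twin_structure(des[ok, , drop = FALSE], covariates,
                         extra_fixed = matrix(dose[ok], ncol = 1,
                                              dimnames = list(NULL, "dosage")))
    y <- expr[pairs$probeset_id[r], ok]
    fit <- fit_twin_model(y, st, n_starts = n_starts, seed = seed)
    j <- match("dosage", names(fit$beta) %||% colnames(st$X))
    if (is.na(j)) j <- length(fit$beta)
    beta <- fit$beta[j]
    se <- sqrt(fit$beta_cov[j, j])
    res[[r]] <- data.frame(snp_id = pairs$snp_id[r],
                           probeset_id = pairs$probeset_id[r],
                           beta = beta, se = se,
                           p = 2 * stats::pnorm(abs(beta / se),
                                                lower.tail = FALSE),
                           n = sum(ok), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(snp_id = character(), probeset_id = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      n = integer())
  rownames(out) <- NULL
  out
}

#' Inverse-variance fixed-effects meta-analysis with heterogeneity
#'
#' Combines per-study (beta, se) by `w_i = 1/se_i^2`:
#' `beta_meta = sum(w b) / sum(w)`, `se_meta = 1/sqrt(sum(w))`, two-sided
#' normal p on `z = beta_meta/se_meta`; Cochran's
#' `Q = sum(w (b - beta_meta)^2)` with a chi-square (k-1) p-value. BH FDR
#' across all pairs. With a single study the study values pass through and
#' Q is NA.
#'
#' @param study_results list of per-study data.frames (snp_id, probeset_id,
#'   beta, se, p, n); studies with nonpositive se are excluded per pair with
#'   a warning.
#' @return data.frame: snp_id, probeset_id, k_studies, beta_meta, se_meta,
#'   z, p, het_q, het_p, fdr_q.
#' @export
meta_fixed_effects <- function(study_results) {
  stop_if(length(study_results) == 0L, "no studies supplied")
  stacked <- do.call(rbind, lapply(seq_along(study_results), function(i) {
    s <- study_results[[i]]
    s$study <- i
    s
  }))
  bad <- !is.finite(stacked$se) | stacked$se <= 0
  if (any(bad)) {
    warning(sum(bad), " study result(s) with invalid SE excluded",
            call. = FALSE)
    stacked <- stacked[!bad, , drop = FALSE]
  }
  stop_if(nrow(stacked) == 0L, "no valid study results")
  key <- paste(stacked$snp_id, stacked$probeset_id, sep = "\r")
  groups <- split(seq_len(nrow(stacked)), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(ix) {
    b <- stacked$beta[ix]
    w <- 1 / stacked$se[ix]^2
    k <- length(ix)
    bm <- sum(w * b) / sum(w)
    sem <- sqrt(1 / sum(w))
    z <- bm / sem
    if (k > 1L) {
      q <- sum(w * (b - bm)^2)
      het_p <- stats::pchisq(q, k - 1L, lower.tail = FALSE)
    } else {
      q <- NA_real_
      het_p <- NA_real_
    }
    data.frame(snp_id = stacked$snp_id[ix[1]],
               probeset_id = stacked$probeset_id[ix[1]],
               k_studies = k, beta_meta = bm, se_meta = sem, z = z,
               p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
               het_q = q, het_p = het_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Permutation empirical p-value for a gene's best cis SNP
#'
#' Permutes the expression vector across samples `B` times; the empirical p
#' is `(1 + #permutations with min cis p <= observed min p) / (B + 1)`.
#'
#' @param y expression vector (one gene), named by sample.
#' @param cis_geno snp x sample dosage matrix of the gene's cis SNPs.
#' @param covariate_matrix optional sample x q covariate matrix.
#' @param B number of permutations (default 1000; below 100 warns).
#' @param seed RNG seed.
#' @return list with `p_empirical`, `min_p_observed`, `best_snp`.
#' @export
empirical_p <- function(y, cis_geno, covariate_matrix = NULL, B = 1000L,
                        seed = 1L) {
  stop_if(nrow(cis_geno) == 0L, "no cis SNPs")
  if (B < 100L) warning("B < 100 gives a coarse empirical p", call. = FALSE)
  n <- length(y)
  Z <- cbind(rep(1, n), covariate_matrix)
  # residualize y and genotypes on covariates once; then min-p reduces to
  # the max absolute correlation, invariant to the residualized scale
  Mg <- t(stats::lm.fit(Z, t(cis_geno))$residuals)
  sdg <- sqrt(rowSums(Mg^2))
  keep <- sdg > 0
  stop_if(!any(keep), "all cis SNPs constant after residualization")
  Mg <- Mg[keep, , drop = FALSE] / sdg[keep]
  # max |partial cor| over cis SNPs is a monotone transform of min p, so the
  # permutation comparison on it reproduces the min-p comparison exactly
  stat <- function(yy) {
    r <- stats::lm.fit(Z, yy)$residuals
    max(abs(Mg %*% r) / sqrt(sum(r^2)))
  }
  obs <- stat(y)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    if (stat(y[sample.int(n)]) >= obs - 1e-12) hits <- hits + 1L
  }
  df <- n - ncol(Z) - 1L
  tt <- obs * sqrt(df) / sqrt(max(1 - obs^2, .Machine$double.eps))
  ry <- stats::lm.fit(Z, y)$residuals
  list(p_empirical = (1 + hits) / (B + 1),
       min_p_observed = 2 * stats::pt(tt, df, lower.tail = FALSE),
       best_snp = rownames(cis_geno)[keep][which.max(abs(Mg %*% ry))])
}

#' Genome-wide module-eigengene QTL scan
#'
#' OLS of a module eigengene on every SNP plus covariates; BH FDR across
#' SNPs at `fdr_level`.
#'
#' @param eigengene numeric vector (one module), named by sample.
#' @param geno snp x sample dosage matrix.
#' @param annotation sample annotation for covariates (optional).
#' @param covariates adjustment covariates.
#' @param fdr_level significance level on the q-values (default 0.05).
#' @return data.frame: snp_id, beta, se, p, fdr_q, significant.
#' @export
module_qtl <- function(eigengene, geno, annotation = NULL,
                       covariates = character(), fdr_level = 0.05) {
  samples <- intersect(names(eigengene), colnames(geno))
  pairs <- data.frame(snp_id = rownames(geno),
                      probeset_id = "eigengene", stringsAsFactors = FALSE)
  expr <- matrix(eigengene[samples], 1, length(samples),
                 dimnames = list("eigengene", samples))
  res <- eqtl_single_study(expr, geno[, samples, drop = FALSE], pairs,
                           annotation, covariates)
  res$probeset_id <- NULL
  res$fdr_q <- bh_fdr(res$p)
  res$significant <- res$fdr_q < fdr_level
  res
}
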