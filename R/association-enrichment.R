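## Eigengene-trait association, Fisher gene-set enrichment, eSNP
## prioritization, and exact binomial enrichment arithmetic.

#' Eigengene-trait association
#'
#' Regresses each module eigengene on each trait plus covariates (OLS);
#' BH FDR within each trait across modules; significance flagged at
#' `q_threshold` (default 1% FDR).
#'
#' @param eigengenes sample x module matrix.
#' @param annotation sample annotation aligned by `sample_id` to the
#'   eigengene rows; `case_status` is coded control = 0, case = 1 when used
#'   as a trait.
#' @param traits character vector of annotation columns to test.
#' @param covariates adjustment covariates (default plate and gender).
#' @param q_threshold FDR significance cutoff.
#' @return data.frame: module, trait, effect, se, p, fdr_q, direction,
#'   significant.
#' @export
eigengene_trait_association <- function(eigengenes, annotation, traits,
                                        covariates = c("plate", "gender"),
                                        q_threshold = 0.01) {
  ann <- annotation[match(rownames(eigengenes), annotation$sample_id), ,
                    drop = FALSE]
  if ("case_status" %in% names(ann))
    ann$case_status <- as.integer(ann$case_status == "case")
  out <- list()
  for (tr in traits) {
    cc <- stats::complete.cases(ann[, c(tr, covariates), drop = FALSE])
    X <- build_design(ann[cc, , drop = FALSE], tr, covariates)
    term <- if (is.numeric(ann[[tr]])) tr else
      grep(paste0("^", tr), colnames(X), value = TRUE)[1]
    fit <- ols_many(t(eigengenes[cc, , drop = FALSE]), X, term)
    out[[tr]] <- data.frame(module = sub("^ME", "", colnames(eigengenes)),
                            trait = tr, effect = fit$effect, se = fit$se,
                            p = fit$p, fdr_q = bh_fdr(fit$p),
                            direction = sign(fit$effect),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$significant <- res$fdr_q < q_threshold
  res
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (tab-separated: set id, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1L)
  sets
}

# one-sided (greater) Fisher exact p for a 2x2 enrichment table:
# overlap k, module size m, set size s, background N
fisher_p_greater <- function(k, m, s, N) {
  stats::phyper(k - 1, s, N - s, m, lower.tail = FALSE)
}

#' Gene-set enrichment of a module by Fisher's exact test
#'
#' One-sided (greater) Fisher exact test of the module against each gene
#' set, relative to the expressed background; fold enrichment
#' `FE = (k/m) / (s/N)` and percent `100 k/m`; BH FDR across sets.
#'
#' @param module_genes character vector (must be a subset of the background).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]);
#'   sets are intersected with the background.
#' @param background_genes character vector of expressed genes.
#' @param q_threshold FDR significance cutoff (default 0.01).
#' @return data.frame: gene_set, count, percent, fold_enrichment, p, fdr_q,
#'   significant.
#' @export
fisher_enrichment <- function(module_genes, gene_sets, background_genes,
                              q_threshold = 0.01) {
  stop_if(length(background_genes) == 0L, "empty background")
  stop_if(!all(module_genes %in% background_genes),
          "module genes must be contained in the background")
  N <- length(unique(background_genes))
  m <- length(unique(module_genes))
  rows <- lapply(names(gene_sets), function(id) {
    s_genes <- intersect(gene_sets[[id]], background_genes)
    s <- length(s_genes)
    k <- length(intersect(module_genes, s_genes))
    data.frame(gene_set = id, count = k, percent = 100 * k / m,
               fold_enrichment = if (s > 0) (k / m) / (s / N) else NA_real_,
               p = if (s > 0) fisher_p_greater(k, m, s, N) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr_q <- bh_fdr(res$p)
  res$significant <- !is.na(res$fdr_q) & res$fdr_q < q_threshold
  rownames(res) <- NULL
  res
}

#' Assemble an eSNP follow-up panel
#'
#' Selects eSNPs whose expression probeset satisfies either criterion:
#' (i) differentially expressed between cases and controls (FDR q below
#' `de_q`) AND high module membership (p below `mm_p`) in a designated top
#' module of either tissue; or (ii) member of the designated consensus
#' module OR case-control significant in the single-gene model, AND
#' differentially expressed between depots (FDR q below `interdepot_q`).
#' Probesets without an eQTL record are skipped with a message.
#'
#' @param de_results single-gene case-control `DeResult` data.frame
#'   (probeset_id, fdr_q).
#' @param mm_results data.frame with probeset_id, module, mm_p (e.g. the
#'   `table` from [module_membership()], possibly stacked over tissues).
#' @param interdepot_de between-depot `DeResult` data.frame.
#' @param eqtl_results data.frame with probeset_id, snp_id (best cis eQTL
#'   per probeset).
#' @param consensus_labels named gene -> consensus module vector.
#' @param top_modules module names counting as "top" for criterion i.
#' @param consensus_module consensus module name for criterion ii.
#' @param de_q,mm_p,interdepot_q thresholds (defaults 0.01, from the study
#'   design).
#' @return data.frame: snp_id, probeset_id, criterion_i, criterion_ii;
#'   unique eSNP/probeset rows, ordered by probeset id.
#' @export
prioritize_esnps <- function(de_results, mm_results, interdepot_de,
                             eqtl_results, consensus_labels,
                             top_modules, consensus_module,
                             de_q = 0.01, mm_p = 0.01, interdepot_q = 0.01) {
  de_sig <- de_results$probeset_id[de_results$fdr_q < de_q]
  mm_sig <- unique(mm_results$probeset_id[
    mm_results$module %in% top_modules & mm_results$mm_p < mm_p])
  dd_sig <- interdepot_de$probeset_id[interdepot_de$fdr_q < interdepot_q]
  cons <- names(consensus_labels)[consensus_labels %in% consensus_module]

  all_ps <- unique(c(de_results$probeset_id, interdepot_de$probeset_id,
                     mm_results$probeset_id))
  crit_i <- all_ps %in% de_sig & all_ps %in% mm_sig
  crit_ii <- (all_ps %in% cons | all_ps %in% de_sig) & all_ps %in% dd_sig
  qual <- all_ps[crit_i | crit_ii]
  hit <- match(qual, eqtl_results$probeset_id)
  if (anyNA(hit)) {
    message("skipping ", sum(is.na(hit)),
            " qualifying probeset(s) without an eQTL record")
    keep <- !is.na(hit)
    qual <- qual[keep]
    hit <- hit[keep]
  }
  out <- data.frame(snp_id = eqtl_results$snp_id[hit], probeset_id = qual,
                    criterion_i = crit_i[match(qual, all_ps)],
                    criterion_ii = crit_ii[match(qual, all_ps)],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$probeset_id), , drop = FALSE]
}

#' Exact binomial enrichment probability
#'
#' For `X ~ Binomial(n_tests, per_test_alpha)`, reports both
#' `P(X = n_observed)` and `P(X >= n_observed)` by direct summation of the
#' binomial formula.
#'
#' @param n_tests number of independent tests.
#' @param per_test_alpha per-test significance level in (0, 1).
#' @param n_observed observed count of significant tests.
#' @return list with `p_equal` and `p_at_least`.
#' @export
binomial_enrichment <- function(n_tests, per_test_alpha, n_observed) {
  stop_if(n_observed < 0 || n_observed > n_tests,
          "observed count must lie in [0, n_tests]")
  stop_if(per_test_alpha <= 0 || per_test_alpha >= 1,
          "per_test_alpha must lie in (0, 1)")
  term <- function(k) exp(lchoose(n_tests, k) + k * log(per_test_alpha) +
                            (n_tests - k) * log1p(-per_test_alpha))
  ks <- n_observed:n_tests
  list(p_equal = term(n_observed), p_at_least = sum(term(ks)))
}

#' Bonferroni-adjusted per-test threshold
#'
#' @param alpha family-wise error target.
#' @param n_tests number of tests.
#' @param sig_figs significant figures for the reported value (default 2).
#' @return list with `threshold` (exact) and `reported` (rounded).
#' @export
bonferroni_threshold <- function(alpha, n_tests, sig_figs = 2) {
  stop_if(n_tests < 1, "n_tests must be >= 1")
  th <- alpha / n_tests
  list(threshold = th, reported = signif(th, sig_figs))
}
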