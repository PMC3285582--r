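## Seeded generators for a two-depot adipose expression study with traits,
## a twin cohort, and genotypes carrying planted cis effects. All generators
## use R's default Mersenne-Twister RNG seeded once from the spec, so a fixed
## seed gives byte-identical output on any platform.

#' Specification for the two-tissue coexpression simulator
#'
#' Defines a rank-1 factor model per module: gene g in module m is
#' `x_g = w_g * F_m + sqrt(1 - w_g^2) * eps`, with `w_g` drawn uniformly from
#' `membership_range` and `F_m` a standard-normal latent factor (the true
#' eigengene). Tissue-2 factors correlate with tissue-1 factors at
#' `inter_tissue_eigengene_cor`. Background genes are pure noise. Values are
#' shifted/scaled to resemble log2 microarray intensities.
#'
#' @param n_samples number of samples per tissue.
#' @param n_genes total number of probesets.
#' @param module_sizes integer vector of planted module sizes; the remainder
#'   of `n_genes` is background.
#' @param membership_range length-2 numeric in \[0,1\]: range of the target
#'   correlation between a gene and its module's latent factor.
#' @param inter_tissue_eigengene_cor correlation in \[-1,1\] between a
#'   module's latent factors across the two tissues.
#' @param trait_effects named numeric vector (names = module indices) of
#'   standardized case-control shifts, consumed by [simulate_traits()].
#' @param location,scale affine transform applied to the standardized values
#'   so the expression filter (intensity > 4) is non-trivial.
#' @param seed integer RNG seed.
#' @return object of class `coexpr_sim_spec`.
#' @export
coexpr_sim_spec <- function(n_samples = 100L,
                            n_genes = 1000L,
                            module_sizes = c(150L, 120L, 100L, 80L, 50L),
                            membership_range = c(0.5, 0.9),
                            inter_tissue_eigengene_cor = 0.8,
                            trait_effects = c(`1` = 2),
                            location = 7,
                            scale = 1,
                            seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
               module_sizes = as.integer(module_sizes),
               membership_range = as.numeric(membership_range),
               inter_tissue_eigengene_cor = as.numeric(inter_tissue_eigengene_cor),
               trait_effects = trait_effects,
               location = location, scale = scale, seed = as.integer(seed))
  stop_if(!all(is.finite(unlist(spec[c("n_samples", "n_genes", "module_sizes",
                                       "membership_range",
                                       "inter_tissue_eigengene_cor",
                                       "location", "scale")]))),
          "non-finite values in simulation spec")
  stop_if(sum(spec$module_sizes) > spec$n_genes,
          "module sizes exceed total number of genes")
  stop_if(any(spec$membership_range < 0) || any(spec$membership_range > 1),
          "membership_range must lie in [0, 1]")
  stop_if(abs(spec$inter_tissue_eigengene_cor) > 1,
          "inter_tissue_eigengene_cor must lie in [-1, 1]")
  structure(spec, class = "coexpr_sim_spec")
}

#' Simulate two-tissue expression with shared, partially preserved modules
#'
#' @param spec a [coexpr_sim_spec()].
#' @return list with `tissue1`, `tissue2` (probeset x sample matrices on a
#'   log2-like scale), `labels` (integer module index per probeset, 0 =
#'   background), `memberships` (the generating w per gene), and
#'   `eigengenes` (list of sample x module latent-factor matrices per tissue).
#' @export
simulate_two_tissue_expression <- function(spec) {
  stopifnot(inherits(spec, "coexpr_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  g <- spec$n_genes
  m <- length(spec$module_sizes)
  rho <- spec$inter_tissue_eigengene_cor

  labels <- integer(g)
  idx <- 1L
  for (k in seq_len(m)) {
    labels[idx:(idx + spec$module_sizes[k] - 1L)] <- k
    idx <- idx + spec$module_sizes[k]
  }

  f1 <- matrix(stats::rnorm(n * m), n, m)
  f2 <- rho * f1 + sqrt(1 - rho^2) * matrix(stats::rnorm(n * m), n, m)
  w <- numeric(g)
  in_mod <- labels > 0L
  w[in_mod] <- stats::runif(sum(in_mod), spec$membership_range[1],
                            spec$membership_range[2])

  gen_tissue <- function(f) {
    x <- matrix(stats::rnorm(g * n), g, n)  # noise, overwritten in-module part
    for (k in seq_len(m)) {
      rows <- which(labels == k)
      wk <- w[rows]
      x[rows, ] <- wk %o% f[, k] + sqrt(1 - wk^2) * x[rows, ]
    }
    spec$location + spec$scale * x
  }
  t1 <- gen_tissue(f1)
  t2 <- gen_tissue(f2)
  ids <- sprintf("ps%04d", seq_len(g))
  samples <- sprintf("S%03d", seq_len(n))
  dimnames(t1) <- dimnames(t2) <- list(ids, samples)
  colnames(f1) <- colnames(f2) <- sprintf("M%d", seq_len(m))
  rownames(f1) <- rownames(f2) <- samples
  names(labels) <- ids
  names(w) <- ids
  list(tissue1 = t1, tissue2 = t2, labels = labels, memberships = w,
       eigengenes = list(tissue1 = f1, tissue2 = f2))
}

#' Simulate case/control status and quantitative traits from eigengenes
#'
#' Binary status follows a logistic model on the designated module
#' eigengenes; each quantitative trait is linear in its designated eigengene
#' plus Gaussian noise.
#'
#' @param eigengenes sample x module matrix of (standardized) latent factors.
#' @param trait_effects named numeric vector: names are module column indices,
#'   values the logistic coefficient (and, scaled, the case-control shift).
#' @param quant_effects optional module x trait coefficient matrix for the
#'   quantitative traits; defaults to one trait per entry of `trait_effects`.
#' @param quant_noise_sd residual sd of the quantitative traits.
#' @param seed integer RNG seed.
#' @return data.frame with `sample_id`, `case_status` ("case"/"control"),
#'   and quantitative trait columns (waist, hdl, tg, dbp, sbp, glucose
#'   recycled as needed).
#' @export
simulate_traits <- function(eigengenes, trait_effects, quant_effects = NULL,
                            quant_noise_sd = 1, seed = 1L) {
  set.seed(seed)
  e <- as.matrix(eigengenes)
  mods <- as.integer(names(trait_effects) %||% seq_along(trait_effects))
  stop_if(any(mods < 1L) || any(mods > ncol(e)),
          "trait effect refers to a nonexistent module")
  eta <- drop(e[, mods, drop = FALSE] %*% as.numeric(trait_effects))
  status <- stats::rbinom(nrow(e), 1L, stats::plogis(eta))

  trait_names <- c("waist", "hdl", "tg", "dbp", "sbp", "glucose")
  if (is.null(quant_effects)) {
    quant_effects <- matrix(0, ncol(e), length(mods))
    for (j in seq_along(mods)) quant_effects[mods[j], j] <- trait_effects[j]
  }
  q <- e %*% quant_effects +
    matrix(stats::rnorm(nrow(e) * ncol(quant_effects), sd = quant_noise_sd),
           nrow(e), ncol(quant_effects))
  colnames(q) <- trait_names[((seq_len(ncol(q)) - 1L) %% length(trait_names)) + 1L]
  out <- data.frame(sample_id = rownames(e) %||% sprintf("S%03d", seq_len(nrow(e))),
                    case_status = ifelse(status == 1L, "case", "control"),
                    q, check.names = FALSE, stringsAsFactors = FALSE)
  out
}

#' Specification for the twin repeated-measures expression simulator
#'
#' Variance components are given on the genetics scale: additive genetic `A`
#' and common environment `C` map to the model's pair variance (`A/2 + C`,
#' shared by co-twins of either zygosity) and MZ-extra variance (`A/2`,
#' shared only within MZ pairs). Defaults mirror a twin registry design of
#' 56 MZ and 21 DZ pairs with up to two visits and a fraction of samples in
#' technical duplicate.
#'
#' @param n_mz_pairs,n_dz_pairs pair counts.
#' @param n_visits_per_pair 1 or 2 visits (co-twins visit together).
#' @param replicate_fraction fraction of biological samples measured in
#'   technical duplicate.
#' @param variance_components named numeric: `A`, `C`, `ind_env`,
#'   `common_visit`, `ind_visit`, `residual` (all >= 0).
#' @param n_probesets number of expression traits to simulate.
#' @param location grand mean on the log2-like scale.
#' @param n_plates number of 96-well plates (fixed-effect batch); plate
#'   effects are zero by default so the batch term is estimable but null.
#' @param seed integer RNG seed.
#' @return object of class `twin_sim_spec`.
#' @export
twin_sim_spec <- function(n_mz_pairs = 56L, n_dz_pairs = 21L,
                          n_visits_per_pair = 2L, replicate_fraction = 0.15,
                          variance_components = c(A = 0.4, C = 0.1,
                                                  ind_env = 0.2,
                                                  common_visit = 0.1,
                                                  ind_visit = 0.1,
                                                  residual = 0.1),
                          n_probesets = 100L, location = 7, n_plates = 2L,
                          seed = 1L) {
  vc <- variance_components
  stop_if(!all(c("A", "C", "ind_env", "common_visit", "ind_visit",
                 "residual") %in% names(vc)),
          "variance_components must name A, C, ind_env, common_visit, ind_visit, residual")
  stop_if(any(vc < 0), "variance components must be nonnegative")
  stop_if(!n_visits_per_pair %in% 1:2, "n_visits_per_pair must be 1 or 2")
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_visits_per_pair = as.integer(n_visits_per_pair),
                 replicate_fraction = replicate_fraction,
                 variance_components = vc,
                 n_probesets = as.integer(n_probesets),
                 location = location, n_plates = as.integer(n_plates),
                 seed = as.integer(seed)),
            class = "twin_sim_spec")
}

#' Simulate twin expression with the six-component covariance structure
#'
#' Each probeset value is `mu + pair + mz_extra + individual + common_visit +
#' individual_visit + residual`, giving co-twin covariance `A + C` (MZ) and
#' `A/2 + C` (DZ), plus `common_visit` when sampled at the same visit.
#'
#' @param spec a [twin_sim_spec()].
#' @return list with `expr` (probeset x sample matrix) and `design`
#'   (data.frame: sample_id, subject_id, pair_id, zygosity, twin_index,
#'   visit, aliquot, plate).
#' @export
simulate_twin_expression <- function(spec) {
  stopifnot(inherits(spec, "twin_sim_spec"))
  set.seed(spec$seed)
  vc <- spec$variance_components
  n_pairs <- spec$n_mz_pairs + spec$n_dz_pairs
  zyg <- rep(c("MZ", "DZ"), c(spec$n_mz_pairs, spec$n_dz_pairs))

  obs <- expand.grid(aliquot = 1L, visit = seq_len(spec$n_visits_per_pair),
                     twin = 1:2, pair = seq_len(n_pairs),
                     KEEP.OUT.ATTRS = FALSE)[, 4:1]
  # technical duplicates for a seeded subset of biological samples
  dup <- stats::runif(nrow(obs)) < spec$replicate_fraction
  if (any(dup)) {
    extra <- obs[dup, ]
    extra$aliquot <- 2L
    obs <- rbind(obs, extra)
  }
  obs <- obs[order(obs$pair, obs$twin, obs$visit, obs$aliquot), ]
  rownames(obs) <- NULL
  n_obs <- nrow(obs)
  p <- spec$n_probesets

  pair_i <- obs$pair
  twin_key <- (obs$pair - 1L) * 2L + obs$twin
  visit_key <- (obs$pair - 1L) * 2L + obs$visit
  twin_visit_key <- (twin_key - 1L) * 2L + obs$visit
  is_mz <- zyg[obs$pair] == "MZ"
  # zygosity effect: shared across an MZ pair, per-twin for DZ
  zyg_key <- ifelse(is_mz, twin_key * 0L + pair_i, n_pairs + twin_key)

  expr <- matrix(0, p, n_obs)
  for (t in seq_len(p)) {
    pair_eff <- stats::rnorm(n_pairs, sd = sqrt(vc[["A"]] / 2 + vc[["C"]]))
    zyg_eff <- stats::rnorm(n_pairs + 2L * n_pairs, sd = sqrt(vc[["A"]] / 2))
    ind_eff <- stats::rnorm(2L * n_pairs, sd = sqrt(vc[["ind_env"]]))
    cv_eff <- stats::rnorm(2L * n_pairs, sd = sqrt(vc[["common_visit"]]))
    iv_eff <- stats::rnorm(4L * n_pairs, sd = sqrt(vc[["ind_visit"]]))
    res <- stats::rnorm(n_obs, sd = sqrt(vc[["residual"]]))
    expr[t, ] <- spec$location + pair_eff[pair_i] + zyg_eff[zyg_key] +
      ind_eff[twin_key] + cv_eff[visit_key] + iv_eff[twin_visit_key] + res
  }

  ids <- sprintf("T%04d", seq_len(n_obs))
  design <- data.frame(
    sample_id = ids,
    subject_id = sprintf("subj%03d", twin_key),
    pair_id = sprintf("pair%03d", obs$pair),
    zygosity = zyg[obs$pair],
    twin_index = obs$twin,
    visit = obs$visit,
    aliquot = obs$aliquot,
    plate = sprintf("plate%d", ((obs$pair - 1L) %% spec$n_plates) + 1L),
    stringsAsFactors = FALSE)
  dimnames(expr) <- list(sprintf("ps%04d", seq_len(p)), ids)
  list(expr = expr, design = design)
}

#' Specification for the genotype simulator
#'
#' @param n_snps,n_samples dimensions.
#' @param maf_range minor-allele-frequency range in (0, 0.5\]; a MAF is drawn
#'   uniformly per SNP and genotypes follow Hardy-Weinberg proportions
#'   (dosage ~ Binomial(2, maf)).
#' @param planted_effects data.frame with columns `snp`, `probeset_id`,
#'   `beta` (expression shift per minor-allele copy), `distance` (bp offset
#'   of the SNP from its gene); may be empty.
#' @param chrom chromosome name for the synthetic layout.
#' @param gene_spacing bp between consecutive gene starts; gene length fixed
#'   at 10 kb.
#' @param seed integer RNG seed.
#' @return object of class `geno_sim_spec`.
#' @export
geno_sim_spec <- function(n_snps = 5000L, n_samples = 100L,
                          maf_range = c(0.05, 0.5),
                          planted_effects = NULL, chrom = "chr1",
                          gene_spacing = 1e6, seed = 1L) {
  stop_if(any(maf_range <= 0) || any(maf_range > 0.5),
          "maf_range must lie in (0, 0.5]")
  structure(list(n_snps = as.integer(n_snps), n_samples = as.integer(n_samples),
                 maf_range = maf_range, planted_effects = planted_effects,
                 chrom = chrom, gene_spacing = gene_spacing,
                 seed = as.integer(seed)),
            class = "geno_sim_spec")
}

#' Simulate genotypes in HWE and plant additive cis effects into expression
#'
#' Genes are laid out every `gene_spacing` bp on one synthetic chromosome
#' (10 kb long each, 1-based); SNP positions are uniform over the layout
#' except planted SNPs, which are placed at their declared distance from
#' their target gene's start.
#'
#' @param spec a [geno_sim_spec()].
#' @param expression probeset x sample matrix; planted probesets must exist.
#' @return list with `geno` (snp x sample dosage matrix in \{0,1,2\}),
#'   `snp_annot` (snp_id, chrom, pos, alleles, maf), `gene_annot`
#'   (probeset_id, chrom, start, stop), and `expr` (expression with
#'   `beta * dosage` added to planted probesets).
#' @export
simulate_genotypes <- function(spec, expression) {
  stopifnot(inherits(spec, "geno_sim_spec"))
  set.seed(spec$seed)
  g <- nrow(expression)
  gene_annot <- data.frame(
    probeset_id = rownames(expression),
    chrom = spec$chrom,
    start = as.integer(seq_len(g) - 1L) * spec$gene_spacing + 1,
    stringsAsFactors = FALSE)
  gene_annot$stop <- gene_annot$start + 10000 - 1

  span <- max(gene_annot$stop) + 5e5
  pos <- sort(sample.int(span, spec$n_snps))
  maf <- stats::runif(spec$n_snps, spec$maf_range[1], spec$maf_range[2])
  geno <- matrix(stats::rbinom(spec$n_snps * spec$n_samples, 2L,
                               rep(maf, spec$n_samples)),
                 spec$n_snps, spec$n_samples)
  expr <- expression

  pe <- spec$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    stop_if(!all(pe$probeset_id %in% rownames(expression)),
            "planted effect targets a probeset absent from the expression matrix")
    for (r in seq_len(nrow(pe))) {
      s <- pe$snp[r]
      tgt <- match(pe$probeset_id[r], gene_annot$probeset_id)
      pos[s] <- gene_annot$start[tgt] + pe$distance[r]
      if (ncol(expr) != ncol(geno))
        stop("expression and genotype sample counts differ", call. = FALSE)
      expr[pe$probeset_id[r], ] <- expr[pe$probeset_id[r], ] +
        pe$beta[r] * geno[s, ]
    }
  }
  snp_ids <- sprintf("rs%06d", seq_len(spec$n_snps))
  dimnames(geno) <- list(snp_ids, colnames(expression))
  snp_annot <- data.frame(snp_id = snp_ids, chrom = spec$chrom,
                          pos = as.numeric(pos), alleles = "A/G", maf = maf,
                          stringsAsFactors = FALSE)
  list(geno = geno, snp_annot = snp_annot, gene_annot = gene_annot, expr = expr)
}
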