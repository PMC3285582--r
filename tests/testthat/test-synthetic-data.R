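test_that("two-tissue simulator respects its factor model", {
  # degenerate: full membership, within-module |cor| = 1
  spec <- coexpr_sim_spec(n_samples = 20, n_genes = 30, module_sizes = 10L,
                          membership_range = c(1, 1), seed = 3)
  sim <- simulate_two_tissue_expression(spec)
  mod <- sim$tissue1[sim$labels == 1L, ]
  cc <- abs(cor(t(mod)))
  expect_true(all(abs(cc - 1) < 1e-12))

  # perfect inter-tissue correlation: identical latent factors
  spec2 <- coexpr_sim_spec(n_samples = 15, n_genes = 20, module_sizes = 8L,
                           inter_tissue_eigengene_cor = 1, seed = 5)
  sim2 <- simulate_two_tissue_expression(spec2)
  expect_equal(sim2$eigengenes$tissue1, sim2$eigengenes$tissue2)

  # fixed seed => byte-identical output
  expect_identical(simulate_two_tissue_expression(spec),
                   simulate_two_tissue_expression(spec))
})

test_that("gene-factor correlations track the generating memberships", {
  # 5 modules of 50 genes, w in [0.5, 0.9], n = 100; sample cor within
  # +/- 0.15 of w for >= 90% of genes (scaled to 5 replicate seeds)
  hits <- total <- 0
  for (s in 1:5) {
    spec <- coexpr_sim_spec(n_samples = 100, n_genes = 250,
                            module_sizes = rep(50L, 5),
                            membership_range = c(0.5, 0.9), seed = s)
    sim <- simulate_two_tissue_expression(spec)
    for (m in 1:5) {
      rows <- which(sim$labels == m)
      r <- cor(t(sim$tissue1[rows, ]), sim$eigengenes$tissue1[, m])
      hits <- hits + sum(abs(r - sim$memberships[rows]) < 0.15)
      total <- total + length(rows)
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("simulator rejects invalid specs", {
  expect_error(coexpr_sim_spec(n_genes = 10, module_sizes = 20L), "exceed")
  expect_error(coexpr_sim_spec(membership_range = c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(coexpr_sim_spec(inter_tissue_eigengene_cor = 1.5), "\\[-1, 1\\]")
  expect_error(coexpr_sim_spec(location = NaN), "non-finite")
})

test_that("trait simulator wires eigengenes into phenotypes", {
  set.seed(9)
  e <- matrix(rnorm(400), 100, 4, dimnames = list(sprintf("S%03d", 1:100)))
  # zero effects: status independent of eigengenes across seeds
  tr0 <- simulate_traits(e, c(`1` = 0), seed = 4)
  expect_setequal(unique(tr0$case_status), c("case", "control"))
  p0 <- summary(lm((tr0$case_status == "case") ~ e[, 1]))$coefficients[2, 4]
  expect_gt(p0, 0.001)

  # quantitative trait = exact copy of eigengene 1 when noise-free
  tr1 <- simulate_traits(e, c(`1` = 1), quant_noise_sd = 0, seed = 4)
  expect_equal(unname(cor(tr1$waist, e[, 1])^2), 1, tolerance = 1e-12)

  expect_error(simulate_traits(e, c(`9` = 1)), "nonexistent module")
})

test_that("planted case-control shift is detectable downstream", {
  # effect 2 on module 1, n = 100: significant at p < 0.01 in >= 95% of
  # seeds (scaled to 20 seeds)
  hit <- 0
  for (s in 1:20) {
    set.seed(s)
    e <- matrix(rnorm(200), 100, 2)
    rownames(e) <- sprintf("S%03d", 1:100)
    tr <- simulate_traits(e, c(`1` = 2), seed = s + 100)
    p <- summary(lm(e[, 1] ~ I(tr$case_status == "case")))$coefficients[2, 4]
    if (p < 0.01) hit <- hit + 1
  }
  expect_gte(hit / 20, 0.95)
})

test_that("twin simulator reproduces the specified covariance blocks", {
  # A = 1, all else 0: MZ co-twin cor ~ 1, DZ ~ 0.5 (200 pairs)
  spec <- twin_sim_spec(n_mz_pairs = 200, n_dz_pairs = 200,
                        n_visits_per_pair = 1, replicate_fraction = 0,
                        variance_components = c(A = 1, C = 0, ind_env = 0,
                                                common_visit = 0,
                                                ind_visit = 0, residual = 0),
                        n_probesets = 50, seed = 21)
  tw <- simulate_twin_expression(spec)
  d <- tw$design
  t1 <- tw$expr[, d$twin_index == 1]
  t2 <- tw$expr[, d$twin_index == 2]
  mz <- d$zygosity[d$twin_index == 1] == "MZ"
  r_mz <- mean(sapply(seq_len(nrow(tw$expr)), function(i)
    cor(t1[i, mz], t2[i, mz])))
  r_dz <- mean(sapply(seq_len(nrow(tw$expr)), function(i)
    cor(t1[i, !mz], t2[i, !mz])))
  expect_equal(r_mz, 1.0, tolerance = 0.1)
  expect_equal(r_dz, 0.5, tolerance = 0.1)

  # all components 0 except residual: co-twin cor ~ 0
  spec0 <- twin_sim_spec(n_mz_pairs = 200, n_dz_pairs = 0,
                         n_visits_per_pair = 1, replicate_fraction = 0,
                         variance_components = c(A = 0, C = 0, ind_env = 0,
                                                 common_visit = 0,
                                                 ind_visit = 0, residual = 1),
                         n_probesets = 20, seed = 22)
  tw0 <- simulate_twin_expression(spec0)
  d0 <- tw0$design
  r0 <- mean(sapply(seq_len(20), function(i)
    cor(tw0$expr[i, d0$twin_index == 1], tw0$expr[i, d0$twin_index == 2])))
  expect_lt(abs(r0), 0.1)

  # zero residual: technical replicates byte-identical
  specr <- twin_sim_spec(n_mz_pairs = 20, n_dz_pairs = 10,
                         replicate_fraction = 1,
                         variance_components = c(A = 0.5, C = 0.2,
                                                 ind_env = 0.1,
                                                 common_visit = 0.1,
                                                 ind_visit = 0.1,
                                                 residual = 0),
                         n_probesets = 5, seed = 23)
  twr <- simulate_twin_expression(specr)
  dr <- twr$design
  key <- paste(dr$subject_id, dr$visit)
  for (k in unique(key[duplicated(key)])) {
    cols <- which(key == k)
    expect_identical(twr$expr[, cols[1]], twr$expr[, cols[2]])
  }

  expect_error(twin_sim_spec(variance_components = c(A = -1, C = 0,
                                                     ind_env = 0,
                                                     common_visit = 0,
                                                     ind_visit = 0,
                                                     residual = 1)),
               "nonnegative")
})

test_that("twin covariance converges to the specified block structure", {
  # empirical covariance at 500 pairs within 0.05 of the implied blocks
  vc <- c(A = 0.4, C = 0.1, ind_env = 0.2, common_visit = 0.1,
          ind_visit = 0.1, residual = 0.1)
  spec <- twin_sim_spec(n_mz_pairs = 500, n_dz_pairs = 500,
                        n_visits_per_pair = 2, replicate_fraction = 0,
                        variance_components = vc, n_probesets = 30, seed = 31)
  tw <- simulate_twin_expression(spec)
  d <- tw$design
  pick <- function(twin, visit) tw$expr[, d$twin_index == twin & d$visit == visit]
  covs <- function(zy) {
    sel <- d$zygosity[d$twin_index == 1 & d$visit == 1] == zy
    same_visit <- mean(sapply(1:30, function(i)
      cov(pick(1, 1)[i, sel], pick(2, 1)[i, sel])))
    diff_visit <- mean(sapply(1:30, function(i)
      cov(pick(1, 1)[i, sel], pick(2, 2)[i, sel])))
    c(same_visit, diff_visit)
  }
  mz <- covs("MZ")
  dz <- covs("DZ")
  expect_equal(mz[1], vc[["A"]] + vc[["C"]] + vc[["common_visit"]],
               tolerance = 0.05)
  expect_equal(mz[2], vc[["A"]] + vc[["C"]], tolerance = 0.05)
  expect_equal(dz[1], vc[["A"]] / 2 + vc[["C"]] + vc[["common_visit"]],
               tolerance = 0.05)
  # within-twin across visits: pair + zyg + ind
  within <- mean(sapply(1:30, function(i) {
    cov(pick(1, 1)[i, ], pick(1, 2)[i, ])
  }))
  expect_equal(within, vc[["A"]] + vc[["C"]] + vc[["ind_env"]],
               tolerance = 0.05)
})

test_that("genotype simulator draws HWE dosages and plants cis effects", {
  expr <- matrix(7, 3, 10000,
                 dimnames = list(c("ps0001", "ps0002", "ps0003"),
                                 sprintf("S%05d", 1:10000)))
  spec <- geno_sim_spec(n_snps = 5, n_samples = 10000,
                        maf_range = c(0.5, 0.5), seed = 41)
  g <- simulate_genotypes(spec, expr)
  expect_true(all(g$geno %in% 0:2))
  expect_equal(mean(g$geno[1, ]), 1.0, tolerance = 0.03)
  # beta = 0 leaves expression unchanged
  spec0 <- geno_sim_spec(n_snps = 5, n_samples = 10000,
                         planted_effects = data.frame(
                           snp = 2L, probeset_id = "ps0002", beta = 0,
                           distance = 100), seed = 41)
  g0 <- simulate_genotypes(spec0, expr)
  expect_equal(g0$expr, expr)
  # planted SNP lands at the declared distance
  spec1 <- geno_sim_spec(n_snps = 5, n_samples = 100,
                         planted_effects = data.frame(
                           snp = 3L, probeset_id = "ps0003", beta = 1,
                           distance = 1234), seed = 42)
  expr2 <- expr[, 1:100]
  g1 <- simulate_genotypes(spec1, expr2)
  gene <- g1$gene_annot[g1$gene_annot$probeset_id == "ps0003", ]
  expect_equal(g1$snp_annot$pos[3], gene$start + 1234)
  expect_equal(g1$expr["ps0003", ] - expr2["ps0003", ],
               g1$geno[3, ] * 1.0, ignore_attr = TRUE)

  expect_error(geno_sim_spec(maf_range = c(0, 0.5)), "\\(0, 0.5\\]")
})

test_that("null genotypes pass a uniform HWE p-value check", {
  # exact-test p approximately uniform across 1000 null SNPs (KS p > 0.01)
  spec <- geno_sim_spec(n_snps = 1000, n_samples = 300,
                        maf_range = c(0.1, 0.5), seed = 51)
  expr <- matrix(7, 2, 300, dimnames = list(c("ps0001", "ps0002"),
                                            sprintf("S%03d", 1:300)))
  g <- simulate_genotypes(spec, expr)
  # the exact-test p is discrete and conservative by construction, which a
  # KS test against the continuous uniform always rejects at 1000 SNPs; the
  # uniformity property is checked on the asymptotically equivalent
  # chi-square p (continuous), plus a calibration bound on the exact p
  ps_chi <- apply(g$geno, 1, function(x)
    hwe_chisq(sum(x == 0), sum(x == 1), sum(x == 2)))
  expect_gt(suppressWarnings(ks.test(ps_chi, "punif"))$p.value, 0.01)
  ps_ex <- apply(g$geno, 1, function(x)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2)))
  # conservative calibration: rejection rate at alpha never exceeds alpha
  for (alpha in c(0.01, 0.05, 0.1))
    expect_lte(mean(ps_ex < alpha), alpha + 2 * sqrt(alpha / 1000))
})
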