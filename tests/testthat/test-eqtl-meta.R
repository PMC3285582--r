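test_that("HWE exact test matches enumeration and chi-square asymptotics", {
  # (20, 60, 20) at n = 100: full enumeration over heterozygote counts
  enum_p <- function(n_aa, n_ab, n_bb) {
    n <- n_aa + n_ab + n_bb
    nm <- 2 * min(n_aa, n_bb) + n_ab
    hets <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
    pr <- sapply(hets, function(h) {
      naa <- (nm - h) / 2
      choose(n, naa) * choose(n - naa, h) * 2^h /
        choose(2 * n, nm) * choose(n - naa - h, n - naa - h)
    })
    # literal conditional probability: n! / (naa! nab! nbb!) 2^nab * ... use
    # factorial form to stay independent of the implementation
    pr <- sapply(hets, function(h) {
      naa <- (nm - h) / 2
      nbb <- n - naa - h
      exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
            h * log(2) + lfactorial(nm) + lfactorial(2 * n - nm) -
            lfactorial(2 * n))
    })
    obs <- pr[hets == n_ab]
    sum(pr[pr <= obs * (1 + 1e-12)])
  }
  expect_equal(hwe_exact_test(20, 60, 20), enum_p(20, 60, 20),
               tolerance = 1e-12)
  expect_equal(hwe_exact_test(5, 10, 35), enum_p(5, 10, 35),
               tolerance = 1e-12)
  # asymptotic agreement at n = 10,000 under HWE
  set.seed(121)
  g <- rbinom(10000, 2, 0.3)
  cnt <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p_ex <- hwe_exact_test(cnt[1], cnt[2], cnt[3])
  expect_lt(abs(p_ex - hwe_chisq(cnt[1], cnt[2], cnt[3])), 0.01)
})

test_that("genotype QC applies the MAF/call-rate/HWE rules", {
  set.seed(122)
  n <- 200
  geno <- rbind(
    mono = rep(0, n),                                   # MAF 0 -> dropped
    ok_common = rbinom(n, 2, 0.3),                      # kept
    low_cr_common = ifelse(runif(n) < 0.93, rbinom(n, 2, 0.3), NA), # drop
    low_cr_rare = ifelse(runif(n) < 0.98, rbinom(n, 2, 0.04), NA),  # drop
    hwe_fail = c(rep(1, n))                             # all-het: HWE fail
  )
  colnames(geno) <- sprintf("s%03d", 1:n)
  qc <- genotype_qc(geno)
  expect_false(qc$report$kept[qc$report$snp_id == "mono"])
  expect_true(qc$report$kept[qc$report$snp_id == "ok_common"])
  expect_false(qc$report$kept[qc$report$snp_id == "low_cr_common"])
  expect_false(qc$report$kept[qc$report$snp_id == "low_cr_rare"])
  expect_false(qc$report$kept[qc$report$snp_id == "hwe_fail"])
  expect_equal(qc$report$reason[qc$report$snp_id == "hwe_fail"], "hwe")
  # MAF 0.04 with call rate 0.98 needs >= 0.99: dropped
  expect_equal(qc$report$reason[qc$report$snp_id == "low_cr_rare"],
               "call_rate")
  # permutation invariance over samples
  perm <- sample(n)
  qc2 <- genotype_qc(geno[, perm])
  expect_equal(qc$report$kept, qc2$report$kept)
  expect_error(genotype_qc(matrix(3, 1, 4)), "0/1/2")
})

test_that("cis pair definition is inclusive and matches brute force", {
  genes <- data.frame(probeset_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
                      start = c(1e6, 5e6), stop = c(1.01e6, 5.02e6))
  snps <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "chr1",
                     pos = c(1e6 - 500000, 1.01e6 + 500000, 1.01e6 + 500001))
  pairs <- define_cis_pairs(snps, genes)
  hits <- pairs[pairs$probeset_id == "gA", "snp_id"]
  expect_setequal(hits, c("s1", "s2"))  # boundaries inclusive, +1 excluded

  # random layout vs brute-force double loop (spec: exact, 100 trials;
  # 20 here)
  for (s in 1:20) {
    set.seed(s + 1200)
    g <- data.frame(probeset_id = sprintf("g%d", 1:10),
                    chrom = sample(c("chr1", "chr2"), 10, TRUE),
                    start = sort(sample.int(2e7, 10)))
    g$stop <- g$start + sample.int(50000, 10)
    sn <- data.frame(snp_id = sprintf("s%d", 1:100),
                     chrom = sample(c("chr1", "chr2"), 100, TRUE),
                     pos = sample.int(2.2e7, 100))
    got <- define_cis_pairs(sn, g)
    want <- do.call(rbind, lapply(seq_len(10), function(i) {
      hit <- sn$chrom == g$chrom[i] & sn$pos >= g$start[i] - 5e5 &
        sn$pos <= g$stop[i] + 5e5
      if (any(hit)) data.frame(snp_id = sn$snp_id[hit],
                               probeset_id = g$probeset_id[i])
    }))
    if (is.null(want)) want <- data.frame(snp_id = character(),
                                          probeset_id = character())
    key <- function(d) sort(paste(d$snp_id, d$probeset_id))
    expect_identical(key(got), key(want))
  }
})

test_that("single-study eQTL recovers exact, null, and planted effects", {
  n <- 150
  ann <- toy_annotation(n, seed = 131)
  set.seed(131)
  g <- matrix(rbinom(n, 2, 0.3), 1, n,
              dimnames = list("rs1", ann$sample_id))
  expr <- matrix(g[1, ], 1, n, dimnames = list("psX", ann$sample_id))
  pairs <- data.frame(snp_id = "rs1", probeset_id = "psX")
  res <- eqtl_single_study(expr, g, pairs, ann, covariates = character())
  expect_equal(res$beta, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-50)

  # sampling distribution of a planted beta = 0.5 (MAF 0.3, sd 1, n = 150):
  # theoretical se = 1/sqrt(n * 2 maf (1-maf)) ~ 0.126, so the +/- 0.2 band
  # captures 2*pnorm(0.2/se) - 1 ~ 0.89 of estimates
  covered <- sapply(1:40, function(s) {
    set.seed(s + 1300)
    dose <- rbinom(n, 2, 0.3)
    y <- 0.5 * dose + rnorm(n)
    e <- matrix(y, 1, n, dimnames = list("psX", ann$sample_id))
    gm <- matrix(dose, 1, n, dimnames = list("rs1", ann$sample_id))
    r <- eqtl_single_study(e, gm, pairs, ann, covariates = character())
    abs(r$beta - 0.5) < 0.2
  })
  theory <- 2 * pnorm(0.2 / (1 / sqrt(n * 2 * 0.3 * 0.7))) - 1
  expect_lt(abs(mean(covered) - theory), 0.12)

  # pairs with too few observations are skipped
  g_na <- g
  g_na[1, 1:145] <- NA
  expect_message(
    r0 <- eqtl_single_study(expr, g_na, pairs, ann, covariates = character()),
    "skipped")
  expect_equal(nrow(r0), 0)
})

test_that("null eQTL p-values are uniform", {
  n <- 100
  ann <- toy_annotation(n, seed = 132)
  set.seed(132)
  n_pairs <- 2000
  geno <- matrix(rbinom(n_pairs * n, 2, 0.3), n_pairs, n,
                 dimnames = list(sprintf("rs%04d", 1:n_pairs), ann$sample_id))
  expr <- matrix(rnorm(n_pairs * n), n_pairs, n,
                 dimnames = list(sprintf("ps%04d", 1:n_pairs), ann$sample_id))
  pairs <- data.frame(snp_id = rownames(geno), probeset_id = rownames(expr))
  res <- eqtl_single_study(expr, geno, pairs, ann)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("twin eQTL matches OLS when random variances vanish", {
  # residual-only twin world: mixed-model beta equals OLS beta
  vc <- c(A = 0, C = 0, ind_env = 0, common_visit = 0, ind_visit = 0,
          residual = 1)
  tw <- simulate_twin_expression(twin_sim_spec(
    n_mz_pairs = 30, n_dz_pairs = 15, n_visits_per_pair = 1,
    replicate_fraction = 0, variance_components = vc, n_probesets = 1,
    seed = 133))
  d <- tw$design
  set.seed(134)
  dose <- setNames(rbinom(length(unique(d$subject_id)), 2, 0.3),
                   unique(d$subject_id))
  geno <- matrix(dose, 1, length(dose),
                 dimnames = list("rs1", names(dose)))
  y <- tw$expr[1, ] + 0.4 * dose[d$subject_id]
  expr <- matrix(y, 1, length(y), dimnames = list("ps0001", d$sample_id))
  pairs <- data.frame(snp_id = "rs1", probeset_id = "ps0001")
  twin_res <- eqtl_twin_study(expr, geno, d, pairs, covariates = character())
  ols <- coef(summary(lm(y ~ dose[d$subject_id])))
  expect_equal(twin_res$beta, ols[2, 1], tolerance = 1e-4)

  # planted effect recovered within 2 SE (10 seeds; spec example uses 100)
  vc2 <- c(A = 0.3, C = 0.1, ind_env = 0.2, common_visit = 0.1,
           ind_visit = 0.1, residual = 0.2)
  hits <- sapply(1:10, function(s) {
    tw2 <- simulate_twin_expression(twin_sim_spec(
      n_mz_pairs = 40, n_dz_pairs = 20, n_visits_per_pair = 1,
      replicate_fraction = 0, variance_components = vc2, n_probesets = 1,
      seed = 1340 + s))
    d2 <- tw2$design
    set.seed(2340 + s)
    dd <- setNames(rbinom(length(unique(d2$subject_id)), 2, 0.3),
                   unique(d2$subject_id))
    g2 <- matrix(dd, 1, length(dd), dimnames = list("rs1", names(dd)))
    y2 <- tw2$expr[1, ] + 0.5 * dd[d2$subject_id]
    e2 <- matrix(y2, 1, length(y2), dimnames = list("ps0001", d2$sample_id))
    r <- eqtl_twin_study(e2, g2, d2, pairs, covariates = character())
    abs(r$beta - 0.5) < 2 * r$se
  })
  expect_gte(mean(hits), 0.8)
})

test_that("twin eQTL type-I error is calibrated", {
  # scaled-down null calibration (400 fits on a compact one-visit design)
  vc <- c(A = 0.3, C = 0.1, ind_env = 0.2, common_visit = 0,
          ind_visit = 0, residual = 0.4)
  tw <- simulate_twin_expression(twin_sim_spec(
    n_mz_pairs = 30, n_dz_pairs = 15, n_visits_per_pair = 1,
    replicate_fraction = 0, variance_components = vc, n_probesets = 400,
    seed = 135))
  d <- tw$design
  subj <- unique(d$subject_id)
  set.seed(136)
  geno <- matrix(rbinom(400 * length(subj), 2, 0.3), 400,
                 dimnames = list(sprintf("rs%03d", 1:400), subj))
  pairs <- data.frame(snp_id = rownames(geno),
                      probeset_id = rownames(tw$expr))
  res <- eqtl_twin_study(tw$expr, geno, d, pairs, covariates = character(),
                         n_starts = 1L)
  rate <- mean(res$p < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("fixed-effects meta-analysis combines studies correctly", {
  s1 <- data.frame(snp_id = "rs1", probeset_id = "ps1", beta = 1, se = 1,
                   p = 0.3, n = 50)
  s2 <- data.frame(snp_id = "rs1", probeset_id = "ps1", beta = 3, se = 1,
                   p = 0.01, n = 60)
  m <- meta_fixed_effects(list(s1, s2))
  expect_equal(m$beta_meta, 2)
  expect_equal(m$se_meta, 1 / sqrt(2))
  expect_equal(m$het_q, 1 * (1 - 2)^2 + 1 * (3 - 2)^2)

  # single study passes through, Q undefined
  m1 <- meta_fixed_effects(list(s1))
  expect_equal(m1$beta_meta, s1$beta)
  expect_equal(m1$se_meta, s1$se)
  expect_true(is.na(m1$het_q))

  # k identical studies: se_meta = se / sqrt(k)
  for (k in c(2, 5, 9)) {
    mk <- meta_fixed_effects(rep(list(s1), k))
    expect_equal(mk$se_meta, s1$se / sqrt(k))
    expect_equal(mk$beta_meta, s1$beta)
  }

  # invalid SE excluded with warning
  s_bad <- s2; s_bad$se <- 0
  expect_warning(mb <- meta_fixed_effects(list(s1, s_bad)), "invalid SE")
  expect_equal(mb$beta_meta, s1$beta)
})

test_that("split-half meta-analysis tracks full-data OLS", {
  set.seed(141)
  n <- 200
  dose <- rbinom(n, 2, 0.3)
  y <- 0.4 * dose + rnorm(n)
  ids <- sprintf("s%03d", 1:n)
  halves <- list(1:100, 101:200)
  studies <- lapply(halves, function(ix) {
    e <- matrix(y[ix], 1, dimnames = list("ps1", ids[ix]))
    g <- matrix(dose[ix], 1, dimnames = list("rs1", ids[ix]))
    eqtl_single_study(e, g, data.frame(snp_id = "rs1", probeset_id = "ps1"),
                      covariates = character())
  })
  m <- meta_fixed_effects(studies)
  full <- summary(lm(y ~ dose))$coefficients
  expect_lt(abs(m$beta_meta - full[2, 1]), 2 * full[2, 2])
})

test_that("empirical p is exact in the extreme and degenerate cases", {
  set.seed(151)
  n <- 80
  geno <- matrix(rbinom(5 * n, 2, 0.4), 5, n,
                 dimnames = list(sprintf("rs%d", 1:5), sprintf("s%d", 1:n)))
  # overwhelming planted effect: empirical p hits the floor 1/(B+1)
  y <- 3 * geno[2, ] + rnorm(n, sd = 0.1)
  res <- empirical_p(y, geno, B = 999, seed = 7)
  expect_equal(res$p_empirical, 1 / 1000)
  expect_equal(res$best_snp, "rs2")
  # null gene: empirical p spread over the grid
  y0 <- rnorm(n)
  res0 <- empirical_p(y0, geno, B = 200, seed = 8)
  expect_gte(res0$p_empirical, 1 / 201)
  expect_lte(res0$p_empirical, 1)
  expect_warning(empirical_p(y0, geno, B = 10, seed = 9), "coarse")
})

test_that("module QTL flags a planted driver SNP", {
  set.seed(161)
  n <- 150
  n_snps <- 300
  geno <- matrix(rbinom(n_snps * n, 2, 0.3), n_snps, n,
                 dimnames = list(sprintf("rs%04d", 1:n_snps),
                                 sprintf("s%03d", 1:n)))
  # SNP 17 drives the eigengene with R2 ~ 0.25
  dose <- geno[17, ]
  e <- sqrt(0.25) * scale(dose)[, 1] + sqrt(0.75) * rnorm(n)
  names(e) <- colnames(geno)
  res <- module_qtl(e, geno)
  expect_equal(res$snp_id[which.min(res$p)], "rs0017")
  expect_true(res$significant[res$snp_id == "rs0017"])
  # null scan: no discoveries expected
  e0 <- setNames(rnorm(n), colnames(geno))
  res0 <- module_qtl(e0, geno)
  expect_lte(sum(res0$significant), 1)
  # eigengene equal to a standardized dosage: p ~ 0
  e1 <- setNames(scale(geno[5, ])[, 1], colnames(geno))
  res1 <- module_qtl(e1, geno)
  expect_lt(res1$p[res1$snp_id == "rs0005"], 1e-100)
})
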