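## Configuration, orchestration, input validation, and the command-line
## entry point. Configuration is JSON (lossless round-trip via jsonlite);
## every threshold defaults to the study's published value.

#' Default pipeline configuration
#'
#' All analysis thresholds with their published defaults: expression filter
#' (intensity > 4 in >= 10% of individuals), scale-free target R2 0.8,
#' minimum module size 30, FDR 0.01 for DE / module-trait / enrichment and
#' 0.05 for module QTL, cis window 500 kb, genotype QC cutoffs
#' (MAF 1%/5%, call rates 95%/99%, HWE 1e-4), MM p 0.01, Bonferroni family
#' alpha 0.05.
#'
#' @param ... named overrides of any default.
#' @return object of class `adiponet_config` (a named list).
#' @export
adiponet_config <- function(...) {
  cfg <- list(
    expr_threshold = 4.0, expr_min_fraction = 0.10,
    target_r2 = 0.8, soft_power_candidates = 1:20,
    min_module_size = 30L, cut_height = 0.99,
    fdr_de = 0.01, fdr_module_trait = 0.01, fdr_enrichment = 0.01,
    fdr_eqtl = 0.01, fdr_module_qtl = 0.05,
    mm_p = 0.01, cis_window = 500000,
    qc_maf_lo = 0.01, qc_callrate_a = 0.95, qc_maf_mid = 0.05,
    qc_callrate_b = 0.99, qc_hwe_p = 1e-4,
    bonferroni_alpha = 0.05,
    seed = 1L,
    stages = c("simulate", "de", "network", "consensus", "assoc",
               "varcomp", "eqtl"),
    sim = list(n_samples = 100L, n_genes = 1000L, n_snps = 5000L),
    out_dir = NULL)
  over <- list(...)
  stop_if(length(over) && is.null(names(over)), "overrides must be named")
  unknown <- setdiff(names(over), names(cfg))
  stop_if(length(unknown) > 0, "unknown config field(s): ",
          paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "adiponet_config")
}

#' Read/write a pipeline configuration (lossless JSON round-trip)
#'
#' @param config an `adiponet_config`.
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` an
#'   `adiponet_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(adiponet_config, raw[setdiff(names(raw), "")])
  # restore integer-ish fields
  for (f in c("min_module_size", "seed"))
    cfg[[f]] <- as.integer(cfg[[f]])
  cfg
}

#' Validate cross-consistency of pipeline inputs
#'
#' Checks id agreement between expression, annotation, genotypes and
#' coordinate tables, duplicated ids, and missingness; returns every
#' problem found (not just the first).
#'
#' @param expr probeset x sample matrix (optional).
#' @param annotation sample annotation (optional).
#' @param geno genotype matrix (optional).
#' @param snp_annot,gene_annot coordinate tables (optional).
#' @return character vector of problems; empty when clean.
#' @export
validate_inputs <- function(expr = NULL, annotation = NULL, geno = NULL,
                            snp_annot = NULL, gene_annot = NULL) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  if (!is.null(expr)) {
    if (anyDuplicated(rownames(expr)))
      add("duplicated probeset ids in expression")
    if (anyDuplicated(colnames(expr)))
      add("duplicated sample ids in expression")
    if (any(!is.finite(expr))) add("non-finite expression values")
  }
  if (!is.null(expr) && !is.null(annotation)) {
    missing <- setdiff(colnames(expr), annotation$sample_id)
    for (m in missing)
      add(paste0("expression sample '", m, "' missing from annotation"))
  }
  if (!is.null(geno)) {
    if (anyDuplicated(rownames(geno))) add("duplicated SNP ids in genotypes")
    if (!all(geno %in% c(0, 1, 2, NA))) add("genotype dosages outside {0,1,2,NA}")
  }
  if (!is.null(geno) && !is.null(snp_annot)) {
    missing <- setdiff(rownames(geno), snp_annot$snp_id)
    if (length(missing))
      add(paste0(length(missing), " genotyped SNP(s) missing coordinates"))
  }
  if (!is.null(snp_annot) && any(snp_annot$pos < 1))
    add("SNP positions must be 1-based positive")
  if (!is.null(gene_annot) && any(gene_annot$start > gene_annot$stop))
    add("gene annotation with start > stop")
  if (!is.null(expr) && !is.null(gene_annot)) {
    missing <- setdiff(rownames(expr), gene_annot$probeset_id)
    if (length(missing))
      add(paste0(length(missing), " expressed probeset(s) missing coordinates"))
  }
  problems
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Run the full pipeline on synthetic data
#'
#' Stage order: simulate -> filtering/DE -> per-tissue networks ->
#' consensus/preservation -> eigengene-trait association -> twin variance
#' components -> cis-eQTL with meta-analysis. Each stage's outputs are
#' written to `out_dir` before the next starts; a manifest (config hash,
#' per-stage row counts and timings) is written at the end. Fixed seeds
#' make a rerun byte-identical.
#'
#' @param config an [adiponet_config()]; `out_dir` must be set.
#' @return the manifest, invisibly (list: config_hash, stages, outputs).
#' @export
run_pipeline <- function(config = adiponet_config()) {
  stopifnot(inherits(config, "adiponet_config"))
  out <- config$out_dir
  stop_if(is.null(out), "config$out_dir must be set")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out, "config.json")
  write_config(config, cfg_path)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   stages = list())
  note <- function(stage, t0, counts) {
    manifest$stages[[stage]] <<- c(list(seconds = round(
      as.numeric(Sys.time()) - t0, 2)), counts)
  }
  st <- config$stages
  env <- new.env()

  if ("simulate" %in% st) {
    t0 <- as.numeric(Sys.time())
    sizes <- pmax(30L, as.integer(round(config$sim$n_genes *
                                          c(0.15, 0.12, 0.10, 0.08, 0.05))))
    spec <- coexpr_sim_spec(n_samples = config$sim$n_samples,
                            n_genes = config$sim$n_genes,
                            module_sizes = sizes, seed = config$seed)
    env$sim <- simulate_two_tissue_expression(spec)
    env$traits <- simulate_traits(env$sim$eigengenes$tissue1,
                                  spec$trait_effects,
                                  seed = derive_seed(config$seed, 2L))
    env$traits$gender <- rep(c("F", "M"), length.out = nrow(env$traits))
    env$traits$plate <- rep(c("p1", "p2"),
                            c(ceiling(nrow(env$traits) / 2),
                              floor(nrow(env$traits) / 2)))
    gspec <- geno_sim_spec(n_snps = config$sim$n_snps,
                           n_samples = config$sim$n_samples,
                           planted_effects = data.frame(
                             snp = 1L, probeset_id = rownames(env$sim$tissue1)[1],
                             beta = 0.8, distance = 1000),
                           seed = derive_seed(config$seed, 3L))
    env$gen <- simulate_genotypes(gspec, env$sim$tissue1)
    write_matrix_tsv(env$gen$expr, file.path(out, "expression_tissue1.tsv"),
                     "probeset_id")
    write_matrix_tsv(env$sim$tissue2, file.path(out, "expression_tissue2.tsv"),
                     "probeset_id")
    write_tsv(env$traits, file.path(out, "sample_annotation.tsv"))
    write_matrix_tsv(env$gen$geno, file.path(out, "genotypes.tsv"), "snp_id")
    write_tsv(env$gen$snp_annot, file.path(out, "snp_annotation.tsv"))
    write_tsv(env$gen$gene_annot, file.path(out, "gene_annotation.tsv"))
    jsonlite::write_json(list(labels = as.list(env$sim$labels)),
                         file.path(out, "truth.json"), auto_unbox = TRUE)
    note("simulate", t0, list(n_genes = nrow(env$sim$tissue1),
                              n_samples = ncol(env$sim$tissue1),
                              n_snps = nrow(env$gen$geno)))
  }

  if ("de" %in% st && !is.null(env$sim)) {
    t0 <- as.numeric(Sys.time())
    keep1 <- filter_expressed(env$gen$expr, config$expr_threshold,
                              config$expr_min_fraction)
    keep2 <- filter_expressed(env$sim$tissue2, config$expr_threshold,
                              config$expr_min_fraction)
    env$keep <- intersect(keep1, keep2)
    env$de1 <- de_single_gene(env$gen$expr[env$keep, , drop = FALSE],
                              env$traits, "case_status")
    write_tsv(env$de1, file.path(out, "de_tissue1.tsv"))
    note("de", t0, list(retained_t1 = length(keep1),
                        retained_t2 = length(keep2),
                        de_sig = sum(env$de1$fdr_q < config$fdr_de)))
  }

  if ("network" %in% st && !is.null(env$sim)) {
    t0 <- as.numeric(Sys.time())
    env$nets <- lapply(list(t1 = env$gen$expr[env$keep, , drop = FALSE],
                            t2 = env$sim$tissue2[env$keep, , drop = FALSE]),
                       function(x) {
      cc <- correlation_matrix(x)
      beta <- pick_soft_power(cc, config$soft_power_candidates,
                              config$target_r2)
      tom <- topological_overlap(adjacency(cc, beta))
      labels <- detect_modules(tom, config$min_module_size,
                               config$cut_height)
      me <- module_eigengene(x, labels)
      list(tom = tom, labels = labels, eigengenes = me, beta = as.integer(beta))
    })
    for (tn in names(env$nets)) {
      write_tsv(data.frame(probeset_id = names(env$nets[[tn]]$labels),
                           module = env$nets[[tn]]$labels),
                file.path(out, paste0("modules_", tn, ".tsv")))
      write_matrix_tsv(env$nets[[tn]]$eigengenes,
                       file.path(out, paste0("eigengenes_", tn, ".tsv")),
                       "sample_id")
    }
    note("network", t0,
         list(modules_t1 = length(setdiff(unique(env$nets$t1$labels), "grey")),
              modules_t2 = length(setdiff(unique(env$nets$t2$labels), "grey")),
              beta_t1 = env$nets$t1$beta, beta_t2 = env$nets$t2$beta))
  }

  if ("consensus" %in% st && !is.null(env$nets)) {
    t0 <- as.numeric(Sys.time())
    d <- consensus_dissimilarity(env$nets$t1$tom, env$nets$t2$tom)
    env$cons <- detect_consensus_modules(d, config$min_module_size,
                                         config$cut_height)
    pres <- tryCatch({
      e1 <- module_eigengene(env$gen$expr[env$keep, , drop = FALSE], env$cons)
      e2 <- module_eigengene(env$sim$tissue2[env$keep, , drop = FALSE], env$cons)
      preservation(eigengene_network(e1), eigengene_network(e2))
    }, error = function(e) NULL)
    write_tsv(data.frame(probeset_id = names(env$cons), module = env$cons),
              file.path(out, "consensus_modules.tsv"))
    if (!is.null(pres))
      jsonlite::write_json(list(density_D = pres$density_D,
                                per_module = as.list(pres$per_module_density)),
                           file.path(out, "preservation.json"),
                           auto_unbox = TRUE, digits = NA)
    note("consensus", t0,
         list(consensus_modules = length(setdiff(unique(env$cons), "grey")),
              density_D = if (is.null(pres)) NA else pres$density_D))
  }

  if ("assoc" %in% st && !is.null(env$nets)) {
    t0 <- as.numeric(Sys.time())
    env$assoc <- eigengene_trait_association(
      env$nets$t1$eigengenes, env$traits,
      traits = c("case_status", "waist"),
      q_threshold = config$fdr_module_trait)
    write_tsv(env$assoc, file.path(out, "module_trait.tsv"))
    note("assoc", t0, list(n_tests = nrow(env$assoc),
                           n_significant = sum(env$assoc$significant)))
  }

  if ("varcomp" %in% st) {
    t0 <- as.numeric(Sys.time())
    tw <- simulate_twin_expression(
      twin_sim_spec(n_probesets = 20L, seed = derive_seed(config$seed, 4L)))
    stc <- twin_structure(tw$design)
    vc <- lapply(seq_len(nrow(tw$expr)), function(i)
      fit_twin_model(tw$expr[i, ], stc, seed = config$seed))
    tab <- do.call(rbind, lapply(vc, heritability_summary))
    tab <- cbind(data.frame(probeset_id = rownames(tw$expr)), tab)
    write_tsv(tab, file.path(out, "twin_varcomp.tsv"))
    note("varcomp", t0, list(n_probesets = nrow(tab),
                             median_F = stats::median(tab$familiality)))
  }

  if ("eqtl" %in% st && !is.null(env$gen)) {
    t0 <- as.numeric(Sys.time())
    qc <- genotype_qc(env$gen$geno, config$qc_maf_lo, config$qc_callrate_a,
                      config$qc_maf_mid, config$qc_callrate_b, config$qc_hwe_p)
    cis <- define_cis_pairs(env$gen$snp_annot[
      env$gen$snp_annot$snp_id %in% rownames(qc$geno), , drop = FALSE],
      env$gen$gene_annot[env$gen$gene_annot$probeset_id %in% env$keep, ,
                         drop = FALSE],
      config$cis_window)
    cis <- cis[seq_len(min(nrow(cis), 2000L)), , drop = FALSE]
    eq <- eqtl_single_study(env$gen$expr, qc$geno, cis, env$traits)
    eq$fdr_q <- bh_fdr(eq$p)
    write_tsv(eq, file.path(out, "eqtl.tsv"))
    note("eqtl", t0, list(n_pairs = nrow(eq),
                          n_sig = sum(eq$fdr_q < config$fdr_eqtl)))
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Command-line entry point
#'
#' `adiponet run --config config.json [--out DIR] [--seed N]`. Exit codes:
#' 0 ok, 1 input error, 2 stage failure.
#'
#' @param args character vector of CLI arguments (default: the command
#'   line).
#' @return exit status, invisibly.
#' @export
adiponet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    usage = "adiponet run [options]",
    option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--out", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NULL)))
  cmd <- if (length(args) && !startsWith(args[1], "-")) args[1] else "run"
  rest <- setdiff(args, cmd)
  opt <- tryCatch(optparse::parse_args(parser, rest),
                  error = function(e) NULL)
  if (is.null(opt) || !cmd %in% "run") {
    message("unknown usage; see ?adiponet_main")
    return(invisible(1L))
  }
  cfg <- tryCatch({
    c0 <- if (!is.null(opt$config)) read_config(opt$config)
          else adiponet_config()
    if (!is.null(opt$seed)) c0$seed <- opt$seed
    if (!is.null(opt$out)) c0$out_dir <- opt$out
    c0
  }, error = function(e) {
    message("input error: ", conditionMessage(e))
    NULL
  })
  if (is.null(cfg)) return(invisible(1L))
  ok <- tryCatch({
    run_pipeline(cfg)
    TRUE
  }, error = function(e) {
    message("stage failure: ", conditionMessage(e))
    FALSE
  })
  invisible(if (ok) 0L else 2L)
}
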