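write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

manifest_entry <- function(paths) {
  data.frame(file = basename(paths), md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}

#' Diversity-to-core pipeline
#'
#' Chains the whole distance-based core-collection workflow on a VCF:
#' four-step SNP filtering, per-site/per-accession statistics, IBS
#' distances, square-root (Euclidean) transform, neighbor joining (with
#' optional bootstrap supports), maximum-length-subtree pruning to
#' `target_size` (or to the sphericity-curve knee when `"auto"`), synonym
#' detection, and core-vs-whole retention evaluation. Every output is
#' written under `out_dir` and checksummed into a JSON run manifest so a
#' rerun with the same config is byte-comparable.
#'
#' @param vcf input VCF path
#' @param out_dir output directory (created)
#' @param filter a [filter_config()]
#' @param target_size core size, or `"auto"` for knee selection on the
#'   sphericity curve
#' @param must_keep accession ids (or a one-id-per-line file path) never
#'   pruned
#' @param synonym_threshold Euclidean removed-edge threshold (default
#'   0.0008)
#' @param bootstrap_reps NJ bootstrap replicates (0 = point tree only)
#' @param seed root RNG seed, recorded in the manifest
#' @return the manifest, invisibly (list; also written as `manifest.json`)
#' @export
run_core_pipeline <- function(vcf, out_dir, filter = filter_config(),
                              target_size = "auto",
                              must_keep = character(),
                              synonym_threshold = 0.0008,
                              bootstrap_reps = 0L, seed = 1L) {
  if (!file.exists(vcf)) stop("input VCF not found: ", vcf)
  if (length(must_keep) == 1L && file.exists(must_keep) &&
      !must_keep %in% c("", NA)) must_keep <- readLines(must_keep)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  geno <- stage("read_vcf", read_vcf(vcf))
  flt <- stage("filter", filter_panel(geno, filter))
  kept <- flt$geno
  paths <- character()
  p <- function(f) file.path(out_dir, f)
  write_vcf(kept, p("kept.vcf"))
  write_tsv(as.data.frame(flt$report), p("filter_report.tsv"))
  write_tsv(site_stats(kept), p("site_stats.tsv"))
  write_tsv(sample_heterozygosity(kept), p("sample_stats.tsv"))
  dmat <- stage("ibs_distance", ibs_distance(kept))
  write_square_matrix(dmat, p("distances.phylip"))
  emat <- sqrt_transform(dmat)
  tree <- stage("nj_tree", if (bootstrap_reps > 0L)
    bootstrap_support(kept, bootstrap_reps, seed = seed) else
      neighbor_joining(emat))
  write_newick(tree, p("tree.nwk"))
  min_size <- max(2L, length(must_keep))
  full <- stage("max_length_subtree",
                max_length_subtree(tree, min_size, must_keep,
                                   distances = emat))
  if (identical(target_size, "auto")) {
    target_size <- choose_core_size(full$trace, "sphericity")
  }
  target_size <- as.integer(target_size)
  tr <- full$trace
  keep_steps <- tr$retained_size >= target_size
  removed <- tr$removed[keep_steps]
  core_ids <- setdiff(read_newick(p("tree.nwk"))$tip.label, removed)
  core <- list(retained = core_ids, target_size = target_size,
               must_keep = must_keep, trace = tr)
  class(core) <- "core_set"
  writeLines(core_ids, p("core.txt"))
  write_tsv(as.data.frame(tr), p("trace.tsv"))
  syn <- detect_synonyms(tr[keep_steps, , drop = FALSE], synonym_threshold)
  write_tsv(syn, p("synonyms.tsv"))
  ev <- stage("evaluate_core", evaluate_core(geno, core_ids))
  write_tsv(data.frame(metric = c("n_full", "n_core", "segregating_full",
                                  "segregating_core", "retention_pct",
                                  "ho_ratio", "pic_ratio", "maf_ratio",
                                  "freq_delta_max", "freq_delta_mean"),
                       value = c(ev$n_full, ev$n_core, ev$segregating_full,
                                 ev$segregating_core, ev$retention_pct,
                                 ev$ratios, ev$freq_delta_max,
                                 ev$freq_delta_mean)),
            p("retention_report.tsv"))
  outs <- c("kept.vcf", "filter_report.tsv", "site_stats.tsv",
            "sample_stats.tsv", "distances.phylip", "tree.nwk", "core.txt",
            "trace.tsv", "synonyms.tsv", "retention_report.tsv")
  manifest <- list(pipeline = "core", input_vcf = normalizePath(vcf),
                   seed = seed, bootstrap_reps = bootstrap_reps,
                   target_size = target_size,
                   synonym_threshold = synonym_threshold,
                   n_input_sites = n_sites(geno),
                   n_kept_sites = n_sites(kept),
                   n_samples = n_samples(geno),
                   n_core = length(core_ids),
                   retention_pct = ev$retention_pct,
                   outputs = manifest_entry(file.path(out_dir, outs)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Trait GWAS pipeline
#'
#' Per trait and season: mixed-linear-model association with kinship plus
#' structure covariates, genomic-inflation estimate, Bonferroni threshold at
#' `alpha` over the tested marker count, and the significant-hit list. When
#' a Q matrix is supplied, both the Q+K and P+K models are fitted and the
#' one with inflation factor closest to 1 is reported per trait (the other
#' model's lambda is kept in the manifest for comparison).
#'
#' @param vcf filtered VCF path
#' @param pheno phenotype table path (see [read_phenotypes()])
#' @param out_dir output directory
#' @param traits trait columns to test
#' @param q_matrix optional TSV of admixture proportions (rownames =
#'   accession ids); when absent, principal components are used
#' @param n_pcs PCs for the P matrix (default 3)
#' @param kinship_method `"ibs"` or `"vanraden"`
#' @param mode `"p3d"` or `"exact"`
#' @param alpha family-wise significance level (default 0.05)
#' @param seed recorded in the manifest
#' @return the manifest, invisibly
#' @export
run_gwas_pipeline <- function(vcf, pheno, out_dir,
                              traits = c("MLL", "MLW", "MLA", "MLSI"),
                              q_matrix = NULL, n_pcs = 3L,
                              kinship_method = "ibs", mode = "p3d",
                              alpha = 0.05, seed = 1L) {
  if (!file.exists(vcf)) stop("input VCF not found: ", vcf)
  if (!file.exists(pheno)) stop("phenotype table not found: ", pheno)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  geno <- read_vcf(vcf)
  ph <- derive_traits(read_phenotypes(pheno))
  missing_traits <- setdiff(traits, names(ph))
  if (length(missing_traits))
    stop("trait(s) absent from phenotype table: ",
         paste(missing_traits, collapse = ", "))
  if (sum(ph$accession %in% geno$sample_ids) < 2L)
    stop("phenotypes cover fewer than 2 panel accessions")
  K <- kinship(geno, kinship_method)
  covs <- list(P = pca_covariates(geno, n_pcs))
  if (!is.null(q_matrix)) {
    qm <- as.matrix(utils::read.table(q_matrix, header = TRUE,
                                      row.names = 1L, sep = "\t"))
    covs$Q <- q_covariates(qm)
  }
  thr <- bonferroni_threshold(alpha, n_sites(geno))
  summary_rows <- list()
  hits <- list()
  outs <- character()
  for (tr in traits) for (se in unique(ph$season)) {
    sub <- ph[ph$season == se, ]
    y <- stats::setNames(sub[[tr]], sub$accession)
    fits <- lapply(covs, function(cv)
      mlm_associate(y, geno, K, covariates = cv, mode = mode))
    lam <- vapply(fits, function(f)
      genomic_inflation(f$assoc$p_value)$lambda, numeric(1))
    best <- names(lam)[which.min(abs(lam - 1))]
    assoc <- fits[[best]]$assoc
    assoc$trait <- tr
    assoc$season <- se
    f <- sprintf("assoc_%s_%s.tsv", tr, se)
    write_tsv(assoc, p(f))
    outs <- c(outs, f)
    gi <- genomic_inflation(assoc$p_value)
    qf <- sprintf("qq_%s_%s.tsv", tr, se)
    write_tsv(gi$qq, p(qf))
    mf <- sprintf("manhattan_%s_%s.tsv", tr, se)
    write_tsv(manhattan_table(assoc), p(mf))
    outs <- c(outs, qf, mf)
    sig <- assoc[!is.na(assoc$p_value) & assoc$p_value <= thr$threshold, ]
    hits[[paste(tr, se)]] <- sig
    summary_rows[[paste(tr, se)]] <- data.frame(
      trait = tr, season = se, model = paste0(best, "+K"),
      lambda = gi$lambda,
      lambda_P = unname(lam["P"]),
      lambda_Q = if ("Q" %in% names(lam)) unname(lam["Q"]) else NA_real_,
      n_tests = sum(!is.na(assoc$p_value)),
      threshold = thr$threshold, n_hits = nrow(sig),
      stringsAsFactors = FALSE)
  }
  hit_df <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  write_tsv(hit_df, p("significant_hits.tsv"))
  model_summary <- do.call(rbind, c(summary_rows,
                                    list(make.row.names = FALSE)))
  write_tsv(model_summary, p("model_summary.tsv"))
  outs <- c(outs, "significant_hits.tsv", "model_summary.tsv")
  manifest <- list(pipeline = "gwas", input_vcf = normalizePath(vcf),
                   phenotypes = normalizePath(pheno), seed = seed,
                   kinship_method = kinship_method, mode = mode,
                   alpha = alpha, bonferroni = thr$threshold,
                   n_sites = n_sites(geno), n_samples = n_samples(geno),
                   models = model_summary,
                   outputs = manifest_entry(file.path(out_dir, outs)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
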