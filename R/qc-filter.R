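#' SNP filter configuration
#'
#' Bundles the four-step retention criteria applied to GBS SNP panels:
#' (1) biallelic SNPs only; (2) hard INFO/QUAL thresholds
#' (QUAL < 50, QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < -12.5,
#' ReadPosRankSum < -8.0 remove a site); (3) MAF < `maf_min` or missing
#' fraction > `missing_max` removed; (4) sliding-window LD pruning
#' (50-site windows, 10-site step, r^2 > 0.2).
#'
#' @param maf_min minimum minor allele frequency retained (default 0.05)
#' @param missing_max maximum per-site missing fraction retained (default 0.10)
#' @param biallelic_only drop non-biallelic records (default TRUE)
#' @param hard_filters named list of `list(op, value)` pairs; `op` is `"lt"`
#'   or `"gt"`, a site is removed when its annotation satisfies the
#'   comparison. Keys match the per-site annotation table (QUAL + INFO keys).
#' @param ld_window_sites,ld_step_sites,ld_r2_max sliding-window LD pruning
#'   parameters, in sites (not bp)
#' @return a list of class `filter_config`
#' @export
filter_config <- function(maf_min = 0.05, missing_max = 0.10,
                          biallelic_only = TRUE,
                          hard_filters = list(
                            QUAL = list("lt", 50),
                            QD = list("lt", 2.0),
                            FS = list("gt", 60.0),
                            MQ = list("lt", 40.0),
                            MQRankSum = list("lt", -12.5),
                            ReadPosRankSum = list("lt", -8.0)),
                          ld_window_sites = 50L, ld_step_sites = 10L,
                          ld_r2_max = 0.2) {
  stopifnot(maf_min >= 0, maf_min < 0.5,
            missing_max >= 0, missing_max <= 1,
            ld_window_sites >= ld_step_sites, ld_step_sites >= 1)
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 biallelic_only = isTRUE(biallelic_only),
                 hard_filters = hard_filters,
                 ld_window_sites = as.integer(ld_window_sites),
                 ld_step_sites = as.integer(ld_step_sites),
                 ld_r2_max = ld_r2_max),
            class = "filter_config")
}

new_filter_report <- function(stage, n_in, n_out, removed, note = "") {
  structure(data.frame(stage = stage, n_in = n_in, n_out = n_out,
                       n_removed = n_in - n_out, note = note,
                       stringsAsFactors = FALSE),
            removed = removed, class = c("filter_report", "data.frame"))
}

#' Hard INFO/QUAL threshold filter
#'
#' Removes a site iff any annotation key *present* for that site violates its
#' configured threshold; sites lacking an annotation key are kept and the
#' omission is noted in the report (a missing key is not evidence of failure).
#'
#' @param geno a [genotype_matrix]
#' @param cfg a [filter_config]
#' @return list with elements `geno` (filtered panel) and `report`
#'   (a `filter_report`; attribute `removed` holds removed site indices
#'   relative to the input panel)
#' @export
hard_filter_info <- function(geno, cfg = filter_config()) {
  info <- site_info(geno)
  n <- n_sites(geno)
  bad <- rep(FALSE, n)
  note <- ""
  if (is.null(info) || !ncol(info)) {
    note <- "no per-site annotations present; hard filter skipped"
    warning(note)
  } else {
    absent <- setdiff(names(cfg$hard_filters), names(info))
    if (length(absent))
      note <- paste("annotation key(s) absent, not enforced:",
                    paste(absent, collapse = ", "))
    for (k in intersect(names(cfg$hard_filters), names(info))) {
      rule <- cfg$hard_filters[[k]]
      v <- info[[k]]
      viol <- if (rule[[1]] == "lt") v < rule[[2]] else v > rule[[2]]
      bad <- bad | (!is.na(viol) & viol)
    }
  }
  keep <- which(!bad)
  list(geno = subset_panel(geno, sites = keep),
       report = new_filter_report("hard_info", n, length(keep),
                                  list(hard_info = which(bad)), note))
}

#' Biallelic / MAF / missingness site filter
#'
#' Drops non-biallelic records, then sites whose minor allele frequency
#' (computed on non-missing alleles) falls below `maf_min` or whose missing
#' fraction exceeds `missing_max`. Sites with every genotype missing are
#' removed. Removing every site yields an empty panel with a warning, not an
#' error.
#'
#' @inheritParams hard_filter_info
#' @return list(`geno`, `report`) as in [hard_filter_info()]
#' @export
site_sample_filter <- function(geno, cfg = filter_config()) {
  n0 <- n_sites(geno)
  bi_keep <- if (cfg$biallelic_only) which(geno$sites$biallelic) else
    seq_len(n0)
  g1 <- subset_panel(geno, sites = bi_keep)
  p <- colMeans(g1$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(g1$dosage))
  ok <- !is.na(maf) & maf >= cfg$maf_min & miss <= cfg$missing_max
  keep2 <- which(ok)
  out <- subset_panel(g1, sites = keep2)
  if (n_sites(out) == 0L) warning("all sites removed by MAF/missing filter")
  rep1 <- new_filter_report("biallelic", n0, length(bi_keep),
                            list(biallelic = setdiff(seq_len(n0), bi_keep)))
  rep2 <- new_filter_report("maf_missing", length(bi_keep), length(keep2),
                            list(maf_missing = bi_keep[!ok]))
  report <- rbind(rep1, rep2)
  attr(report, "removed") <- c(attr(rep1, "removed"), attr(rep2, "removed"))
  class(report) <- c("filter_report", "data.frame")
  list(geno = out, report = report)
}

# pairwise-complete squared Pearson correlation of dosage columns,
# computed with crossproducts of mask/zero-filled matrices (no per-pair loop)
pairwise_r2 <- function(X) {
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  storage.mode(X0) <- "double"; storage.mode(M) <- "double"
  n <- crossprod(M)
  sx <- crossprod(X0, M)          # sum of x_a over samples shared with b
  sxx <- crossprod(X0^2, M)
  sxy <- crossprod(X0)
  cov <- sxy - sx * t(sx) / n
  vx <- sxx - sx^2 / n
  r2 <- cov^2 / (vx * t(vx))
  r2[!is.finite(r2)] <- NA_real_
  r2[n < 2] <- NA_real_
  r2
}

#' Sliding-window LD pruning
#'
#' Scans windows of `ld_window_sites` sites advanced by `ld_step_sites`
#' (counted in sites over the input order, per chromosome). Within a window,
#' pairs are visited in (i, j) order; when both sites of a pair are still
#' retained and their dosage r^2 (pairwise-complete Pearson, squared) exceeds
#' `ld_r2_max`, the site with the lower panel-wide MAF is removed (tie: the
#' later site). The sweep is fully deterministic. Windows with fewer than two
#' sites are no-ops.
#'
#' @inheritParams hard_filter_info
#' @return list(`geno`, `report`) as in [hard_filter_info()]
#' @export
ld_prune <- function(geno, cfg = filter_config()) {
  n <- n_sites(geno)
  removed <- rep(FALSE, n)
  if (n >= 2L) {
    p <- colMeans(geno$dosage, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    for (chr in unique(geno$sites$chrom)) {
      idx <- which(geno$sites$chrom == chr)
      m <- length(idx)
      if (m < 2L) next
      starts <- unique(c(seq(1L, max(1L, m - 1L), by = cfg$ld_step_sites)))
      for (s in starts) {
        w <- idx[s:min(m, s + cfg$ld_window_sites - 1L)]
        if (length(w) < 2L) next
        r2 <- pairwise_r2(geno$dosage[, w, drop = FALSE])
        for (a in seq_len(length(w) - 1L)) {
          if (removed[w[a]]) next
          for (b in seq((a + 1L), length(w))) {
            if (removed[w[a]]) break
            if (removed[w[b]]) next
            v <- r2[a, b]
            if (!is.na(v) && v > cfg$ld_r2_max) {
              drop_site <- if (is.na(maf[w[a]]) || is.na(maf[w[b]])) w[b]
                else if (maf[w[a]] < maf[w[b]]) w[a]
                else if (maf[w[b]] < maf[w[a]]) w[b]
                else w[b]                     # tie: later site
              removed[drop_site] <- TRUE
            }
          }
        }
      }
    }
  }
  keep <- which(!removed)
  list(geno = subset_panel(geno, sites = keep),
       report = new_filter_report("ld_prune", n, length(keep),
                                  list(ld_prune = which(removed))))
}

#' Full four-step SNP retention pipeline
#'
#' Applies, in order: hard INFO/QUAL filter, biallelic restriction,
#' MAF/missingness filter, sliding-window LD pruning. Stage reports are
#' concatenated with removed-site indices mapped back to the input panel, so
#' stage kept-sets nest.
#'
#' @inheritParams hard_filter_info
#' @return list(`geno`, `report`)
#' @export
filter_panel <- function(geno, cfg = filter_config()) {
  idx <- seq_len(n_sites(geno))   # surviving sites, input-panel indexing
  steps <- list()
  remap <- function(rep, idx_map) {
    rem <- attr(rep, "removed")
    attr(rep, "removed") <- lapply(rem, function(r) idx_map[r])
    rep
  }
  s1 <- hard_filter_info(geno, cfg)
  steps[[1]] <- remap(s1$report, idx)
  idx <- setdiff(idx, unlist(attr(steps[[1]], "removed"), use.names = FALSE))
  s2 <- site_sample_filter(s1$geno, cfg)
  steps[[2]] <- remap(s2$report, idx)
  idx <- setdiff(idx, unlist(attr(steps[[2]], "removed"), use.names = FALSE))
  s3 <- ld_prune(s2$geno, cfg)
  steps[[3]] <- remap(s3$report, idx)
  report <- do.call(rbind, steps)
  attr(report, "removed") <- do.call(c, lapply(steps, attr, "removed"))
  class(report) <- c("filter_report", "data.frame")
  list(geno = s3$geno, report = report)
}
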