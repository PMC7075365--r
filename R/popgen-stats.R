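#' Per-site marker statistics: allele frequencies, MAF, PIC, genotype counts
#'
#' Frequencies are computed on non-missing alleles. For a biallelic locus
#' with allele frequencies p and q the polymorphism information content is
#' \deqn{PIC = 1 - (p^2 + q^2) - 2 p^2 q^2,} i.e. the general
#' \eqn{1 - \sum P_i^2 - \sum\sum 2 P_i^2 P_j^2} specialized to two alleles;
#' it is 0 for a monomorphic site and maximal (0.375) at p = 0.5. The major
#' allele is the observed majority allele (REF on an exact 50/50 tie), not
#' necessarily REF.
#'
#' @param geno a [genotype_matrix] (biallelic sites)
#' @return data.frame, one row per site: `chrom`, `pos`, `ref`, `alt`,
#'   `p_alt`, `maf`, `pic`, `missing_frac`, `major_allele`, `minor_allele`,
#'   `n_hom_major`, `n_het`, `n_hom_minor`, `n_missing`, `defined`
#'   (FALSE when every genotype at the site is missing).
#' @export
site_stats <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  n_called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0L] <- NA_real_
  q <- 1 - p
  maf <- pmin(p, q)
  pic <- 1 - (p^2 + q^2) - 2 * p^2 * q^2
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  alt_major <- !is.na(p) & p > 0.5
  data.frame(
    chrom = geno$sites$chrom, pos = geno$sites$pos,
    ref = geno$sites$ref, alt = geno$sites$alt,
    p_alt = p, maf = maf, pic = pic,
    missing_frac = 1 - n_called / nrow(d),
    major_allele = ifelse(alt_major, geno$sites$alt, geno$sites$ref),
    minor_allele = ifelse(alt_major, geno$sites$ref, geno$sites$alt),
    n_hom_major = ifelse(alt_major, n2, n0),
    n_het = n1,
    n_hom_minor = ifelse(alt_major, n0, n2),
    n_missing = nrow(d) - n_called,
    defined = n_called > 0L,
    stringsAsFactors = FALSE)
}

#' Per-accession observed heterozygosity
#'
#' Ho = (heterozygous calls) / (non-missing calls) for each accession.
#' An accession with no called sites gets `NA` (undefined).
#'
#' @param geno a [genotype_matrix]
#' @return data.frame with `sample_id`, `ho`, `n_called`
#' @export
sample_heterozygosity <- function(geno) {
  d <- geno$dosage
  n_called <- rowSums(!is.na(d))
  ho <- rowSums(d == 1L, na.rm = TRUE) / n_called
  ho[n_called == 0L] <- NA_real_
  data.frame(sample_id = geno$sample_ids, ho = ho, n_called = n_called,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Identity-by-state genetic distance
#'
#' For accessions a, b, `d(a, b)` is the mean over pairwise-non-missing sites
#' of `|x_a - x_b| / 2` where x is the ALT dosage: 0 for identical genotypes
#' (heterozygote vs heterozygote counts as full sharing), 0.5 when one allele
#' differs, 1 for opposite homozygotes. Computed with masked crossproducts,
#' no per-pair loop.
#'
#' @param geno a [genotype_matrix] with at least 2 samples
#' @return a [square_matrix] of distances in `[0, 1]`
#' @export
ibs_distance <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (n_samples(geno) < 2L) stop("need at least 2 samples")
  d <- geno$dosage
  C <- (!is.na(d)) * 1
  N0 <- (d == 0L & !is.na(d)) * 1
  N1 <- (d == 1L & !is.na(d)) * 1
  N2 <- (d == 2L & !is.na(d)) * 1
  shared <- tcrossprod(C)
  if (any(shared[upper.tri(shared)] == 0)) {
    ij <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1L, ]
    stop("no shared called sites for pair (",
         geno$sample_ids[ij[1L]], ", ", geno$sample_ids[ij[2L]], ")")
  }
  absdiff <- tcrossprod(N0, N1) + tcrossprod(N1, N0) +
    tcrossprod(N1, N2) + tcrossprod(N2, N1) +
    2 * (tcrossprod(N0, N2) + tcrossprod(N2, N0))
  m <- absdiff / (2 * shared)
  diag(m) <- 0
  square_matrix(m, geno$sample_ids, tol = 1e-9)
}

se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Group-level diversity summary
#'
#' For each group of accessions: sample size S, average non-missing site
#' count per accession (ASC), mean and standard error of Ho, and of PIC and
#' MAF *recomputed within the group*, and the min/mean/max of within-group
#' pairwise IBS distances. Also attaches per-group allele-frequency and mean
#' genotype-frequency spectra as the `"spectra"` attribute. Singleton groups
#' have distance fields `NA` and are flagged.
#'
#' @param geno a [genotype_matrix]
#' @param distances a [square_matrix] of pairwise distances labeled by
#'   sample id (e.g. from [ibs_distance()])
#' @param groups named character vector: `names()` are sample ids (a subset
#'   of the panel), values are group labels
#' @return data.frame, one row per group, plus attribute `spectra`
#' @export
diversity_summary <- function(geno, distances, groups) {
  stopifnot(inherits(geno, "genotype_matrix"))
  unknown <- setdiff(names(groups), geno$sample_ids)
  if (length(unknown)) stop("group labels reference unknown sample(s): ",
                            paste(unknown, collapse = ", "))
  labs <- unique(groups)
  spectra <- list()
  rows <- lapply(labs, function(g) {
    ids <- names(groups)[groups == g]
    sub <- subset_panel(geno, samples = ids)
    ss <- site_stats(sub)
    hh <- sample_heterozygosity(sub)
    if (length(ids) >= 2L) {
      dm <- unclass(distances)[ids, ids, drop = FALSE]
      dv <- dm[upper.tri(dm)]
      gd <- c(min(dv), mean(dv), max(dv))
    } else gd <- c(NA_real_, NA_real_, NA_real_)
    nc <- length(ids)
    spectra[[g]] <<- list(
      allele_freq = ss$p_alt,
      genotype_freq = c(
        hom_ref = mean(colMeans(sub$dosage == 0L, na.rm = TRUE), na.rm = TRUE),
        het = mean(colMeans(sub$dosage == 1L, na.rm = TRUE), na.rm = TRUE),
        hom_alt = mean(colMeans(sub$dosage == 2L, na.rm = TRUE), na.rm = TRUE)))
    data.frame(group = g, S = nc,
               avg_site_count = mean(hh$n_called),
               ho_mean = mean(hh$ho, na.rm = TRUE), ho_se = se_mean(hh$ho),
               pic_mean = mean(ss$pic, na.rm = TRUE), pic_se = se_mean(ss$pic),
               maf_mean = mean(ss$maf, na.rm = TRUE), maf_se = se_mean(ss$maf),
               gd_min = gd[1], gd_mean = gd[2], gd_max = gd[3],
               singleton = nc < 2L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "spectra") <- spectra
  out
}
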