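#' Kinship matrix estimators
#'
#' `"ibs"`: similarity = 1 - IBS distance (diagonal 1, duplicates 1).
#' `"vanraden"`: centered-cross-product — dosages are standardized per site
#' (mean-imputed missing, monomorphic sites dropped) and K = Z Z' / m.
#' Either way a small ridge (1e-6) is added to the diagonal so K is
#' numerically positive semidefinite.
#'
#' @param geno a [genotype_matrix]
#' @param method `"ibs"` or `"vanraden"`
#' @param ridge diagonal ridge (default 1e-6)
#' @return symmetric matrix with sample-id dimnames and attribute
#'   `method`
#' @export
kinship <- function(geno, method = c("ibs", "vanraden"), ridge = 1e-6) {
  method <- match.arg(method)
  if (n_sites(geno) == 0L) stop("no sites: cannot estimate kinship")
  if (method == "ibs") {
    K <- 1 - unclass(ibs_distance(geno))
  } else {
    d <- geno$dosage
    storage.mode(d) <- "double"
    mu <- colMeans(d, na.rm = TRUE)
    sdv <- apply(d, 2, stats::sd, na.rm = TRUE)
    keep <- which(!is.na(sdv) & sdv > 0)
    if (!length(keep)) stop("all sites monomorphic: cannot estimate kinship")
    Z <- sweep(d[, keep, drop = FALSE], 2, mu[keep])
    Z[is.na(Z)] <- 0
    Z <- sweep(Z, 2, sdv[keep], "/")
    K <- tcrossprod(Z) / length(keep)
  }
  diag(K) <- diag(K) + ridge
  dimnames(K) <- list(geno$sample_ids, geno$sample_ids)
  attr(K, "method") <- method
  K
}

#' Principal-component structure covariates
#'
#' PCs of the centered, mean-imputed dosage matrix (monomorphic sites
#' contribute nothing after centering). Sign convention: each component is
#' flipped so its largest-magnitude site loading is positive, making output
#' deterministic across LAPACK builds.
#'
#' @param geno a [genotype_matrix]
#' @param n_pcs number of components (default 3)
#' @return n_samples x n_pcs score matrix with attribute `kind = "P"`
#' @export
pca_covariates <- function(geno, n_pcs = 3L) {
  if (n_pcs <= 0L) stop("n_pcs must be positive")
  if (n_pcs >= min(n_samples(geno), n_sites(geno)))
    stop("n_pcs must be smaller than both panel dimensions")
  d <- geno$dosage
  storage.mode(d) <- "double"
  mu <- colMeans(d, na.rm = TRUE)
  X <- sweep(d, 2, mu)
  X[is.na(X)] <- 0
  sv <- svd(X, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u, 2, sv$d[seq_len(n_pcs)] * flip, "*")
  dimnames(scores) <- list(geno$sample_ids, paste0("PC", seq_len(n_pcs)))
  attr(scores, "kind") <- "P"
  scores
}

#' Admixture-proportion (Q) covariates
#'
#' Drops the last ancestry column (proportions sum to 1, so the full matrix
#' is collinear with the intercept) and tags the result for the MLM.
#'
#' @param Q n x k matrix of admixture proportions with sample-id rownames
#' @return n x (k-1) matrix with attribute `kind = "Q"`
#' @export
q_covariates <- function(Q) {
  Q <- as.matrix(Q)
  if (ncol(Q) < 2L) stop("Q matrix needs at least 2 ancestry columns")
  out <- Q[, -ncol(Q), drop = FALSE]
  attr(out, "kind") <- "Q"
  out
}

# REML of the variance ratio delta = sigma_e^2 / sigma_g^2 by spectral
# decomposition: coarse grid on log(delta) in [-10, 10] (100 points)
# refined by golden-section search.
reml_fit <- function(y, X, K, eig = NULL) {
  n <- length(y)
  p <- ncol(X)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  U <- eig$vectors
  ty <- crossprod(U, y)
  tX <- crossprod(U, X)
  ev <- pmax(eig$values, 0)
  obj <- function(logd) {
    w <- ev + exp(logd)
    sw <- sqrt(w)
    qr0 <- qr(tX / sw)
    rss <- sum(qr.resid(qr0, ty / sw)^2)
    ldXX <- 2 * sum(log(abs(diag(qr.R(qr0)))))
    -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(w)) + ldXX + (n - p))
  }
  grid <- seq(-10, 10, length.out = 100)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  gr <- (sqrt(5) - 1) / 2                      # golden-section (maximize)
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- obj(x1); f2 <- obj(x2)
  while (b - a > 1e-6) {
    if (f1 < f2) { a <- x1; x1 <- x2; f1 <- f2
                   x2 <- a + gr * (b - a); f2 <- obj(x2)
    } else       { b <- x2; x2 <- x1; f2 <- f1
                   x1 <- b - gr * (b - a); f1 <- obj(x1) }
  }
  logd <- (a + b) / 2
  delta <- exp(logd)
  w <- ev + delta
  sw <- sqrt(w)
  qr0 <- qr(tX / sw)
  rss <- sum(qr.resid(qr0, ty / sw)^2)
  sigma_g2 <- rss / (n - p)
  list(delta = delta, sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2,
       reml_ll = obj(logd), eig = eig, ty = ty, tX = tX, w = w)
}

#' Genotype-class allele effects (Table-5-style)
#'
#' The major (minor) allele effect is the mean phenotype of the homozygous
#' major (minor) class minus the grand mean over all phenotyped, genotyped
#' accessions at the marker; an empty homozygote class gives a missing
#' effect. Major/minor status comes from observed allele frequencies, not
#' REF/ALT.
#'
#' @param y phenotype vector
#' @param dosage ALT-dosage vector aligned with `y`
#' @return list: `major_effect`, `minor_effect`, `counts` (named: hom_major,
#'   het, hom_minor), `grand_mean`
#' @export
allele_class_effects <- function(y, dosage) {
  ok <- !is.na(y) & !is.na(dosage)
  if (!any(ok)) stop("no accession is both phenotyped and genotyped")
  y <- y[ok]; dosage <- dosage[ok]
  p_alt <- mean(dosage) / 2
  hom_major <- if (p_alt > 0.5) 2L else 0L
  hom_minor <- 2L - hom_major
  gm <- mean(y)
  eff <- function(cls) {
    sel <- dosage == cls
    if (!any(sel)) NA_real_ else mean(y[sel]) - gm
  }
  list(major_effect = eff(hom_major), minor_effect = eff(hom_minor),
       counts = c(hom_major = sum(dosage == hom_major),
                  het = sum(dosage == 1L),
                  hom_minor = sum(dosage == hom_minor)),
       grand_mean = gm)
}

#' Mixed-linear-model marker association (Q+K / P+K)
#'
#' Per-marker test of y = X beta + marker + u + e with u ~ N(0, sigma_g^2 K),
#' fitted by REML on the spectral decomposition of K. `mode = "p3d"`
#' estimates the variance ratio once on the no-marker null model and reuses
#' it for every marker; `mode = "exact"` re-estimates it per marker. The
#' marker test is the F test on the additive dosage coefficient in the
#' whitened model; `marker_r2` is the proportional reduction in whitened
#' residual sum of squares relative to the covariate-only model. Accessions
#' with a missing phenotype are dropped globally; accessions missing the
#' tested marker are dropped for that marker only (pairwise deletion, via a
#' per-marker Cholesky of the subset covariance).
#'
#' @param y named phenotype vector (names = sample ids)
#' @param geno a [genotype_matrix]
#' @param K kinship matrix from [kinship()] (labels must cover the samples)
#' @param covariates optional n x c matrix of structure covariates
#'   ([pca_covariates()] or [q_covariates()]), rownames = sample ids
#' @param mode `"p3d"` or `"exact"`
#' @return list with `assoc` (data.frame, one row per site: site identity,
#'   major/minor allele, maf, n_used, beta, se, p_value, marker_r2,
#'   major/minor class effects and counts) and `fit` (null-model variance
#'   components: `delta`, `sigma_g2`, `sigma_e2`, `reml_ll`, plus
#'   `covariate_kind` and `kinship_method` metadata)
#' @export
mlm_associate <- function(y, geno, K, covariates = NULL,
                          mode = c("p3d", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geno, "genotype_matrix"))
  if (is.null(names(y))) stop("y must be named by sample id")
  ids <- intersect(geno$sample_ids, names(y)[!is.na(y)])
  if (length(ids) < 5L) stop("fewer than 5 phenotyped panel accessions")
  if (!all(ids %in% rownames(K)))
    stop("kinship labels do not cover the phenotyped panel")
  yv <- y[ids]
  if (stats::sd(yv) == 0) stop("phenotype is constant")
  Km <- K[ids, ids]
  X0 <- matrix(1, length(ids), 1, dimnames = list(ids, "intercept"))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (is.null(rownames(C))) stop("covariates must have sample-id rownames")
    if (!all(ids %in% rownames(C)))
      stop("covariates do not cover the phenotyped panel")
    C <- C[ids, , drop = FALSE]
    if (any(apply(C, 2, stats::sd) == 0))
      stop("constant covariate column")
    X0 <- cbind(X0, C)
  }
  n <- length(ids)
  p0 <- ncol(X0)
  null_fit <- reml_fit(yv, X0, Km)
  eig <- null_fit$eig
  U <- eig$vectors
  ev <- pmax(eig$values, 0)
  D <- geno$dosage[ids, , drop = FALSE]
  storage.mode(D) <- "double"
  m <- ncol(D)

  res <- data.frame(chrom = geno$sites$chrom, pos = geno$sites$pos,
                    ref = geno$sites$ref, alt = geno$sites$alt,
                    major_allele = NA_character_,
                    minor_allele = NA_character_,
                    maf = NA_real_, n_used = NA_integer_,
                    beta = NA_real_, se = NA_real_, p_value = NA_real_,
                    marker_r2 = NA_real_,
                    major_effect = NA_real_, minor_effect = NA_real_,
                    n_hom_major = NA_integer_, n_het = NA_integer_,
                    n_hom_minor = NA_integer_, stringsAsFactors = FALSE)

  # fast path: whiten once at the null delta, vectorize complete markers
  w <- ev + null_fit$delta
  sw <- sqrt(w)
  tyw <- drop(crossprod(U, yv)) / sw
  tX0w <- crossprod(U, X0) / sw
  qr0 <- qr(tX0w)
  rss0_full <- sum(qr.resid(qr0, tyw)^2)
  yres_full <- qr.resid(qr0, tyw)

  complete <- !colAnyNA(D)
  if (mode == "p3d" && any(complete)) {
    MW <- crossprod(U, D[, complete, drop = FALSE]) / sw
    Mres <- qr.resid(qr0, MW)
    den <- colSums(Mres^2)
    num <- colSums(Mres * yres_full)
    ok <- den > 1e-12
    rss1 <- rss0_full - ifelse(ok, num^2 / den, 0)
    dfr <- n - p0 - 1L
    beta <- ifelse(ok, num / den, NA_real_)
    se <- ifelse(ok, sqrt(rss1 / dfr / den), NA_real_)
    fstat <- ifelse(ok, (rss0_full - rss1) / (rss1 / dfr), NA_real_)
    idx <- which(complete)
    res$beta[idx] <- beta
    res$se[idx] <- se
    res$p_value[idx] <- stats::pf(fstat, 1, dfr, lower.tail = FALSE)
    res$marker_r2[idx] <- ifelse(ok, (rss0_full - rss1) / rss0_full,
                                 NA_real_)
    res$n_used[idx] <- n
  }
  slow <- if (mode == "p3d") which(!complete) else seq_len(m)
  for (j in slow) {
    g <- D[, j]
    s <- which(!is.na(g))
    if (length(s) <= p0 + 1L || stats::sd(g[s]) == 0) next
    Xs <- cbind(X0[s, , drop = FALSE], marker = g[s])
    if (mode == "exact") {
      fitj <- reml_fit(yv[s], Xs, Km[s, s])
      deltaj <- fitj$delta
    } else deltaj <- null_fit$delta
    R <- chol(Km[s, s] + deltaj * diag(length(s)))
    A <- backsolve(R, cbind(yv[s], Xs), transpose = TRUE)
    yw <- A[, 1L]
    X0w <- A[, 2:(p0 + 1L), drop = FALSE]
    mw <- A[, p0 + 2L]
    q0 <- qr(X0w)
    yres <- qr.resid(q0, yw)
    mres <- qr.resid(q0, mw)
    den <- sum(mres^2)
    if (den <= 1e-12) next
    num <- sum(mres * yres)
    rss0 <- sum(yres^2)
    rss1 <- rss0 - num^2 / den
    dfr <- length(s) - p0 - 1L
    res$beta[j] <- num / den
    res$se[j] <- sqrt(rss1 / dfr / den)
    res$p_value[j] <- stats::pf((rss0 - rss1) / (rss1 / dfr), 1, dfr,
                                lower.tail = FALSE)
    res$marker_r2[j] <- (rss0 - rss1) / rss0
    res$n_used[j] <- length(s)
  }

  # allele framing and class effects (pairwise-complete per marker)
  for (j in seq_len(m)) {
    g <- D[, j]
    s <- !is.na(g)
    if (!any(s)) next
    p_alt <- mean(g[s]) / 2
    alt_major <- p_alt > 0.5
    res$major_allele[j] <- if (alt_major) geno$sites$alt[j] else
      geno$sites$ref[j]
    res$minor_allele[j] <- if (alt_major) geno$sites$ref[j] else
      geno$sites$alt[j]
    res$maf[j] <- min(p_alt, 1 - p_alt)
    ace <- allele_class_effects(yv, g)
    res$major_effect[j] <- ace$major_effect
    res$minor_effect[j] <- ace$minor_effect
    res$n_hom_major[j] <- ace$counts[["hom_major"]]
    res$n_het[j] <- ace$counts[["het"]]
    res$n_hom_minor[j] <- ace$counts[["hom_minor"]]
  }
  fit <- list(delta = null_fit$delta, sigma_g2 = null_fit$sigma_g2,
              sigma_e2 = null_fit$sigma_e2, reml_ll = null_fit$reml_ll,
              mode = mode,
              covariate_kind = if (is.null(covariates)) "none" else
                attr(covariates, "kind") %||% "custom",
              kinship_method = attr(K, "method") %||% "unknown")
  list(assoc = res, fit = fit)
}

colAnyNA <- function(m) colSums(is.na(m)) > 0L

#' Bonferroni significance threshold
#'
#' @param alpha family-wise significance level in (0, 1)
#' @param m number of tests (>= 1)
#' @return list with `threshold` (alpha/m at full precision) and `rounded`
#'   (3 significant digits)
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  t <- alpha / m
  list(threshold = t, rounded = signif(t, 3))
}

#' Genomic inflation factor and Q-Q table
#'
#' lambda = median observed 1-df chi-square quantile of the p-values divided
#' by the theoretical null median (qchisq(0.5, 1) = 0.4549). Also returns
#' the Q-Q table of expected vs observed -log10 p for plotting.
#'
#' @param p vector of p-values in (0, 1]
#' @return list: `lambda`, `n`, `qq` (data.frame `expected`, `observed`)
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no valid p-values")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  k <- length(p)
  qq <- data.frame(expected = -log10(stats::ppoints(k)),
                   observed = -log10(sort(p)))
  list(lambda = lambda, n = k, qq = qq)
}

#' Manhattan-plot table from an association result
#'
#' @param assoc data.frame from [mlm_associate()]`$assoc`
#' @return data.frame `chrom`, `pos`, `p_value`, `neg_log10_p`
#' @export
manhattan_table <- function(assoc) {
  data.frame(chrom = assoc$chrom, pos = assoc$pos, p_value = assoc$p_value,
             neg_log10_p = -log10(assoc$p_value), stringsAsFactors = FALSE)
}
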