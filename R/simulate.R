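#' Configuration for the structured SNP panel simulator
#'
#' The generator follows the Balding-Nichols construction with admixture —
#' exactly the covariance structure the Q+K association model assumes:
#' ancestral frequencies uniform on `anc_range`; subpopulation frequencies
#' Beta(p(1-F)/F, (1-p)(1-F)/F) around each ancestral p; individual
#' ancestries Dirichlet(`admix_alpha`) (0.2 gives mostly-assigned, partly
#' admixed accessions); genotypes Binomial(2, ancestry-weighted frequency);
#' missingness uniform at random. Defaults scale the reference design of a
#' few hundred accessions x tens of thousands of GBS SNPs down ~6x in sites
#' for desk-speed runs.
#'
#' @param n_samples accessions (default 400)
#' @param n_sites SNP sites (default 5000)
#' @param n_subpops subpopulations (default 3)
#' @param fst Balding-Nichols differentiation per subpopulation
#'   (default 0.10)
#' @param admix_alpha Dirichlet concentration for individual admixture
#'   (default 0.2)
#' @param anc_range ancestral allele-frequency range (default 0.05-0.95)
#' @param missing_rate genotype missingness (default 0.02)
#' @param n_chrom pseudo-group count for site coordinates (default 20)
#' @param seed RNG seed
#' @return list of class `panel_sim_config`
#' @export
panel_sim_config <- function(n_samples = 400L, n_sites = 5000L,
                             n_subpops = 3L, fst = 0.10,
                             admix_alpha = 0.2,
                             anc_range = c(0.05, 0.95),
                             missing_rate = 0.02, n_chrom = 20L,
                             seed = 1L) {
  stopifnot(fst > 0, fst < 1, n_subpops >= 1, missing_rate >= 0,
            missing_rate <= 1, anc_range[1] >= 0, anc_range[2] <= 1,
            anc_range[1] < anc_range[2], admix_alpha > 0)
  structure(as.list(environment()), class = "panel_sim_config")
}

#' Simulate a structured biallelic SNP panel
#'
#' @param cfg a [panel_sim_config()]
#' @return list: `geno` (a [genotype_matrix]) and `truth` (ancestral
#'   frequencies, per-subpopulation frequencies, the true admixture Q
#'   matrix, the modal subpopulation per accession, and the config) — the
#'   truth record plus config regenerate the panel bit-identically.
#' @export
simulate_panel <- function(cfg = panel_sim_config()) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; m <- cfg$n_sites; k <- cfg$n_subpops; F <- cfg$fst
  p_anc <- stats::runif(m, cfg$anc_range[1], cfg$anc_range[2])
  P <- vapply(seq_len(k), function(s)
    stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F),
    numeric(m))                                   # m x k
  G <- matrix(stats::rgamma(n * k, shape = cfg$admix_alpha), n, k)
  Q <- G / rowSums(G)                             # n x k admixture
  freq <- Q %*% t(P)                              # n x m individual freq
  dos <- matrix(stats::rbinom(n * m, 2L, pmin(pmax(freq, 0), 1)), n, m)
  if (cfg$missing_rate > 0)
    dos[matrix(stats::runif(n * m) < cfg$missing_rate, n, m)] <- NA_integer_
  ids <- sprintf("acc%03d", seq_len(n))
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), "")
  chrom <- sprintf("PG_%d", rep(seq_len(cfg$n_chrom), length.out = m))
  sites <- data.frame(chrom = chrom, pos = integer(m), ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  # unique ascending positions within each pseudo-group
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    sites$pos[idx] <- sort(sample.int(1e8, length(idx)))
  }
  ord <- order(sites$chrom, sites$pos)
  geno <- genotype_matrix(dos[, ord, drop = FALSE],
                          sites[ord, , drop = FALSE], ids)
  truth <- list(ancestral_p = p_anc[ord], subpop_freq = P[ord, , drop = FALSE],
                admixture = `rownames<-`(Q, ids),
                subpop = stats::setNames(max.col(Q), ids),
                site_order = ord, config = cfg)
  list(geno = geno, truth = truth)
}

#' Configuration for the leaf-trait simulator
#'
#' Traits are built from a standardized latent value per accession
#' decomposed into variance shares: causal SNPs (`causal_r2`, one share per
#' planted SNP — the per-marker variance fractions the association stage
#' should recover), a polygenic remainder up to `h2`, a season-shared
#' environmental share lifting the cross-season correlation to
#' `season_cor`, and independent per-season noise `1 - season_cor`.
#' Requires `sum(causal_r2) <= h2 <= season_cor <= 1`; `h2 = 1` with
#' `season_cor < 1` (nonzero noise) is rejected. Optional per-subpopulation
#' mean shifts (`subpop_shift`, latent-SD units) switch structure
#' confounding on for type-I-error experiments. Leaf width and length are
#' scaled to reference means/SDs (MLW 3.748 +/- 0.933 cm, MLL
#' 8.655 +/- 2.251 cm, within-season correlation `rho_lw`); shape index and
#' area follow by their defining formulas.
#'
#' @param causal_idx site indices of planted SNPs (`NULL` = auto-pick
#'   spread, high-MAF sites)
#' @param causal_r2 per-SNP variance fractions (default 0.03, 0.05, 0.08)
#' @param h2 narrow-sense heritability of the latent trait (default 0.4)
#' @param season_cor target cross-season correlation (default 0.9)
#' @param subpop_shift per-subpopulation latent mean shifts (default 0 =
#'   no confounding); recycled to the number of subpopulations
#' @param rho_lw within-season correlation between leaf width and length
#'   latents (default 0.86)
#' @param seed RNG seed
#' @return list of class `trait_sim_config`
#' @export
trait_sim_config <- function(causal_idx = NULL,
                             causal_r2 = c(0.03, 0.05, 0.08),
                             h2 = 0.4, season_cor = 0.9,
                             subpop_shift = 0, rho_lw = 0.86,
                             seed = 1L) {
  if (length(causal_r2) && any(causal_r2 < 0)) stop("causal_r2 must be >= 0")
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (sum(causal_r2) > h2 + 1e-12)
    stop("sum of causal variance shares exceeds h2")
  if (season_cor < h2 - 1e-12)
    stop("season_cor below h2: per-season noise share would be negative ",
         "while genetic variance is shared across seasons")
  if (season_cor > 1) stop("season_cor must be <= 1")
  structure(as.list(environment()), class = "trait_sim_config")
}

#' Simulate two-season leaf-size phenotypes on a panel
#'
#' @param geno a [genotype_matrix]
#' @param cfg a [trait_sim_config()]
#' @param truth optional panel truth record from [simulate_panel()] (used
#'   for subpopulation mean shifts)
#' @return list: `pheno` (data.frame accession/season/MLL/MLW/MLSI/MLA, two
#'   seasons) and `truth` (causal sites, their latent shares, the implied
#'   per-dosage effects in MLW and MLL trait units, and the config)
#' @export
simulate_traits <- function(geno, cfg = trait_sim_config(), truth = NULL) {
  stopifnot(inherits(cfg, "trait_sim_config"))
  set.seed(cfg$seed)
  n <- n_samples(geno)
  m <- n_sites(geno)
  d <- geno$dosage
  storage.mode(d) <- "double"
  mu <- colMeans(d, na.rm = TRUE)
  sdv <- apply(d, 2, stats::sd, na.rm = TRUE)
  causal <- cfg$causal_idx
  r2 <- cfg$causal_r2
  if (length(r2) && is.null(causal)) {
    eligible <- which(!is.na(sdv) & sdv > 0 & pmin(mu / 2, 1 - mu / 2) > 0.1)
    if (length(eligible) < length(r2))
      stop("not enough polymorphic sites to plant causal SNPs")
    causal <- sort(sample(eligible, length(r2)))
  }
  if (length(causal) != length(r2))
    stop("causal_idx and causal_r2 lengths differ")
  if (length(causal) && (min(causal) < 1L || max(causal) > m))
    stop("causal indices outside panel")
  std <- function(j) {
    x <- d[, j]
    x[is.na(x)] <- mu[j]
    (x - mu[j]) / sdv[j]
  }
  latent_part <- function() {           # one independent structured latent
    gen_c <- 0
    if (length(causal))
      gen_c <- rowSums(vapply(seq_along(causal), function(i)
        sqrt(r2[i]) * std(causal[i]), numeric(n)))
    poly_share <- cfg$h2 - sum(r2)
    gen_p <- if (poly_share > 1e-12) {
      a <- stats::rnorm(m, 0, 1)
      Z <- vapply(seq_len(m), function(j)
        if (is.na(sdv[j]) || sdv[j] == 0) numeric(n) else std(j),
        numeric(n))
      raw <- drop(Z %*% a)
      sqrt(poly_share) * raw / stats::sd(raw)
    } else numeric(n)
    env_share <- cfg$season_cor - cfg$h2
    env <- if (env_share > 1e-12)
      sqrt(env_share) * stats::rnorm(n) else numeric(n)
    shared <- gen_c + gen_p + env
    noise_sd <- sqrt(max(0, 1 - cfg$season_cor))
    list(shared = shared,
         season = function() shared + stats::rnorm(n, 0, noise_sd))
  }
  shift <- numeric(n)
  if (any(cfg$subpop_shift != 0)) {
    if (is.null(truth)) stop("subpop_shift needs the panel truth record")
    Q <- truth$admixture[geno$sample_ids, , drop = FALSE]
    sh <- rep_len(cfg$subpop_shift, ncol(Q))
    shift <- drop(Q %*% sh)
  }
  zW <- latent_part()                   # width latent (carries the causals)
  zE <- latent_part()                   # independent structured latent
  seasons <- c("spring", "fall")
  rows <- lapply(seasons, function(se) {
    w <- zW$season() + shift
    l <- cfg$rho_lw * w + sqrt(1 - cfg$rho_lw^2) * zE$season()
    MLW <- pmax(3.748 + 0.933 * w, 0.05)
    MLL <- pmax(8.655 + 2.251 * l, 0.05)
    data.frame(accession = geno$sample_ids, season = se,
               MLL = MLL, MLW = MLW, stringsAsFactors = FALSE)
  })
  pheno <- derive_traits(do.call(rbind, rows))
  beta_latent <- if (length(causal)) sqrt(r2) / sdv[causal] else numeric(0)
  truth_out <- list(causal_idx = causal, causal_r2 = r2,
                    beta_mlw = 0.933 * beta_latent,
                    beta_mll = 2.251 * cfg$rho_lw * beta_latent,
                    config = cfg)
  list(pheno = pheno, truth = truth_out)
}
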