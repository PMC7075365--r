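test_that("kinship estimators satisfy their invariants", {
  set.seed(1)
  d <- random_panel(10, 40, seed = 1)$dosage
  d[2, ] <- d[1, ]                       # duplicated individuals
  g <- make_panel(d)
  K <- kinship(g, "ibs")
  expect_equal(attr(K, "method"), "ibs")
  expect_equal(K[1, 2], 1)               # duplicates maximally similar
  expect_equal(K, t(K))
  expect_true(all(diag(K) >= apply(K, 1, max) - 1e-12))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  Kv <- kinship(g, "vanraden")
  expect_equal(Kv, t(Kv))
  expect_gte(min(eigen(Kv, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("centered-cross-product kinship equals a hand-computed product", {
  g <- make_panel(matrix(c(0L, 1L, 2L, 1L,
                           2L, 0L, 1L, 1L,
                           0L, 0L, 2L, 2L,
                           1L, 1L, 0L, 2L,
                           0L, 2L, 1L, 1L,
                           2L, 1L, 0L, 1L), 4))
  K <- kinship(g, "vanraden", ridge = 0)
  # explicit double-loop oracle
  d <- g$dosage
  m <- ncol(d)
  oracle <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4) {
    s <- 0
    for (j in 1:m) {
      mu <- mean(d[, j]); sj <- sd(d[, j])
      s <- s + (d[a, j] - mu) * (d[b, j] - mu) / sj^2
    }
    oracle[a, b] <- s / m
  }
  expect_equal(unname(unclass(K)), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PCA covariates separate simulated subpopulations", {
  sim <- simulate_panel(panel_sim_config(n_samples = 80, n_sites = 200,
                                         n_subpops = 2, fst = 0.3,
                                         admix_alpha = 0.05,
                                         missing_rate = 0, seed = 2))
  P <- pca_covariates(sim$geno, 3)
  pop <- sim$truth$subpop
  pc1 <- P[, 1]
  # between-group separation on PC1 exceeds within-group spread
  mu <- tapply(pc1, pop, mean)
  expect_gt(abs(diff(mu)), 2 * max(tapply(pc1, pop, sd)))
  # orthogonality
  cp <- crossprod(P)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-6 * max(diag(cp)))
  # monomorphic sites change nothing
  g2 <- sim$geno
  aug <- make_panel(cbind(sim$geno$dosage, matrix(2L, 80, 3)))
  expect_equal(unclass(pca_covariates(aug, 3)), unclass(P),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(pca_covariates(sim$geno, 0), "positive")
  expect_error(pca_covariates(sim$geno, 90), "smaller")
})

test_that("MLM reduces exactly to OLS when K is the identity", {
  set.seed(3)
  g <- random_panel(30, 25, miss = 0.05, seed = 3)
  y <- setNames(rnorm(30, 10, 2) + 0.8 * ifelse(is.na(g$dosage[, 5]), 0,
                                                g$dosage[, 5]),
                g$sample_ids)
  Ki <- diag(30)
  dimnames(Ki) <- list(g$sample_ids, g$sample_ids)
  for (mode in c("p3d", "exact")) {
    fit <- mlm_associate(y, g, Ki, mode = mode)
    for (j in c(1, 5, 12, 25)) {
      dos <- g$dosage[, j]
      ok <- !is.na(dos)
      if (sd(dos[ok]) == 0) next
      ols <- summary(lm(y[ok] ~ dos[ok]))
      expect_equal(fit$assoc$p_value[j],
                   unname(ols$coefficients[2, 4]), tolerance = 1e-8)
      expect_equal(fit$assoc$beta[j], unname(ols$coefficients[2, 1]),
                   tolerance = 1e-8)
      expect_equal(fit$assoc$n_used[j], sum(ok))
    }
  }
})

test_that("P3D and exact modes agree closely on structured panels", {
  sim <- simulate_panel(panel_sim_config(n_samples = 60, n_sites = 80,
                                         missing_rate = 0, seed = 4))
  ts <- simulate_traits(sim$geno, trait_sim_config(causal_r2 = 0.15,
                                                   h2 = 0.4, seed = 4))
  ph <- ts$pheno[ts$pheno$season == "spring", ]
  y <- setNames(ph$MLW, ph$accession)
  K <- kinship(sim$geno, "ibs")
  P <- pca_covariates(sim$geno, 3)
  f1 <- mlm_associate(y, sim$geno, K, covariates = P, mode = "p3d")
  f2 <- mlm_associate(y, sim$geno, K, covariates = P, mode = "exact")
  dlp <- abs(log10(f1$assoc$p_value) - log10(f2$assoc$p_value))
  expect_lt(max(dlp, na.rm = TRUE), 0.2)
  expect_equal(f1$fit$covariate_kind, "P")
})

test_that("MLM rejects degenerate inputs", {
  g <- random_panel(20, 10, seed = 5)
  Ki <- diag(20)
  dimnames(Ki) <- list(g$sample_ids, g$sample_ids)
  y_const <- setNames(rep(1, 20), g$sample_ids)
  expect_error(mlm_associate(y_const, g, Ki), "constant")
  y <- setNames(rnorm(20), g$sample_ids)
  K_bad <- Ki
  rownames(K_bad) <- paste0("x", 1:20)
  expect_error(mlm_associate(y, g, K_bad), "kinship labels")
  expect_error(mlm_associate(unname(y), g, Ki), "named")
})

test_that("allele-class effects are class-mean deviations from grand mean", {
  # hom-major class mean 10, grand mean 9 -> major effect +1
  y <- c(10, 10, 8, 8, 9)
  dos <- c(0, 0, 1, 1, 2)               # p_alt = 0.4 -> REF major
  a <- allele_class_effects(y, dos)
  expect_equal(a$grand_mean, 9)
  expect_equal(a$major_effect, 1)
  expect_equal(a$minor_effect, 0)
  expect_equal(unname(a$counts), c(2, 2, 1))
  expect_equal(sum(a$counts), 5)
  # empty hom-minor class: effect missing, counts (n0, n1, 0)
  b <- allele_class_effects(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_true(is.na(b$minor_effect))
  expect_equal(unname(b$counts), c(2, 2, 0))
  expect_error(allele_class_effects(c(NA, NA), c(0, 1)), "no accession")
})

test_that("Bonferroni threshold matches the reference computation", {
  t1 <- bonferroni_threshold(0.05, 30282)
  expect_equal(t1$threshold, 0.05 / 30282)
  expect_equal(t1$rounded, 1.65e-6)     # printed reference value
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.01, 10)$threshold, 0.001)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("genomic inflation factor behaves at the null", {
  expect_equal(genomic_inflation(rep(0.5, 11))$lambda, 1)
  set.seed(6)
  gi <- genomic_inflation(runif(1e5))
  expect_gt(gi$lambda, 0.97)
  expect_lt(gi$lambda, 1.03)
  expect_equal(nrow(gi$qq), 1e5)
  expect_error(genomic_inflation(numeric(0)), "no valid")
  expect_error(genomic_inflation(c(0.5, 1.5)), "must lie")
})
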