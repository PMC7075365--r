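# frozen oracle values, hand-evaluated from the biallelic PIC identity
# 1 - (p^2 + q^2) - 2 p^2 q^2:
#   p = 0.375: 1 - (0.140625 + 0.390625) - 2*0.140625*0.390625
#            = 0.35888671875
#   p = 0.5  : 1 - 0.5 - 2*0.0625 = 0.375 (the biallelic maximum)
test_that("site_stats reproduces the PIC identity and genotype counts", {
  g <- make_panel(cbind(c(0L, 0L, 1L, 2L),      # p_alt = 3/8 = 0.375
                        c(0L, 0L, 0L, 0L),      # monomorphic
                        c(0L, 1L, 1L, 2L),      # p_alt = 0.5
                        c(2L, 2L, 1L, NA)))     # ALT-major, one missing
  ss <- site_stats(g)
  expect_equal(ss$p_alt, c(0.375, 0, 0.5, 5 / 6))
  expect_equal(ss$maf, c(0.375, 0, 0.5, 1 / 6))
  expect_equal(ss$pic[1], 0.35888671875)
  expect_equal(ss$pic[2], 0)
  expect_equal(ss$pic[3], 0.375)
  # allele framing by frequency, not REF/ALT
  expect_equal(ss$major_allele[4], "G")
  expect_equal(ss$n_hom_major[4], 2L)
  expect_equal(ss$n_hom_minor[4], 0L)
  expect_equal(ss$n_missing[4], 1L)
  expect_equal(ss$n_hom_major + ss$n_het + ss$n_hom_minor + ss$n_missing,
               rep(4L, 4))
  # fully missing site flagged undefined
  g2 <- make_panel(cbind(rep(NA_integer_, 4)))
  expect_false(site_stats(g2)$defined)
})

test_that("PIC is invariant under allele relabeling and properly bounded", {
  for (seed in 1:5) {
    g <- random_panel(12, 25, miss = 0.05, seed = seed)
    ss <- site_stats(g)
    flipped <- make_panel(2L - g$dosage)
    expect_equal(site_stats(flipped)$pic, ss$pic)
    ok <- ss$defined
    expect_true(all(ss$pic[ok] <= 1 - 2 * ss$maf[ok] * (1 - ss$maf[ok])
                    + 1e-12))
    expect_true(all((ss$pic[ok] == 0) == (ss$maf[ok] == 0)))
  }
})

test_that("sample heterozygosity follows the definition", {
  g <- make_panel(rbind(c(0L, 1L, 1L, 2L),
                        c(0L, 0L, 2L, 2L),
                        c(NA, NA, NA, NA)))
  h <- sample_heterozygosity(g)
  expect_equal(h$ho, c(0.5, 0, NA))
  expect_equal(h$n_called, c(4L, 4L, 0L))
})

test_that("IBS distance matches its per-site allele-sharing definition", {
  g <- make_panel(rbind(c(0L, 2L, 1L),
                        c(0L, 2L, 1L),
                        c(2L, 0L, 1L)))
  d <- ibs_distance(g)
  expect_equal(d["s01", "s02"], 0)        # identical rows
  expect_equal(d["s01", "s03"], 2 / 3)    # (1 + 1 + 0) / 3
  g2 <- make_panel(rbind(c(0L, 0L), c(2L, 2L)))
  expect_equal(ibs_distance(g2)["s01", "s02"], 1)
  g3 <- make_panel(rbind(0L, 1L))
  expect_equal(ibs_distance(g3)["s01", "s02"], 0.5)
  # pair sharing no called site is an error naming the pair
  g4 <- make_panel(rbind(c(0L, NA), c(NA, 1L), c(1L, 1L)))
  expect_error(ibs_distance(g4), "s01.*s02")
})

test_that("IBS distance is a metric on complete data", {
  for (seed in 1:5) {
    g <- random_panel(7, 30, seed = seed + 10)
    d <- unclass(ibs_distance(g))
    expect_equal(diag(d), rep(0, 7), ignore_attr = TRUE)
    expect_equal(d, t(d))
    for (i in 1:7) for (j in 1:7) for (k in 1:7)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("diversity summary equals a spreadsheet-style hand computation", {
  set.seed(5)
  g <- random_panel(5, 10, miss = 0.1, seed = 5)
  d <- ibs_distance(g)
  groups <- setNames(c("A", "A", "A", "B", "B"), g$sample_ids)
  out <- diversity_summary(g, d, groups)
  # independent recompute with explicit loops
  for (grp in c("A", "B")) {
    ids <- names(groups)[groups == grp]
    sub <- g$dosage[ids, , drop = FALSE]
    ho <- apply(sub, 1, function(r) sum(r == 1, na.rm = TRUE) /
                  sum(!is.na(r)))
    p <- apply(sub, 2, function(cc) mean(cc, na.rm = TRUE) / 2)
    maf <- pmin(p, 1 - p)
    pic <- 1 - (p^2 + (1 - p)^2) - 2 * p^2 * (1 - p)^2
    row <- out[out$group == grp, ]
    expect_equal(row$S, length(ids))
    expect_equal(row$avg_site_count,
                 mean(apply(sub, 1, function(r) sum(!is.na(r)))))
    expect_equal(row$ho_mean, mean(ho))
    expect_equal(row$ho_se, sd(ho) / sqrt(length(ho)))
    expect_equal(row$pic_mean, mean(pic, na.rm = TRUE))
    expect_equal(row$maf_mean, mean(maf, na.rm = TRUE))
    dv <- unclass(d)[ids, ids][upper.tri(diag(length(ids)))]
    expect_equal(c(row$gd_min, row$gd_mean, row$gd_max),
                 c(min(dv), mean(dv), max(dv)))
  }
  # whole panel as one group hits the matrix extremes
  whole <- diversity_summary(g, d, setNames(rep("all", 5), g$sample_ids))
  dv <- unclass(d)[upper.tri(unclass(d))]
  expect_equal(whole$gd_min, min(dv))
  expect_equal(whole$gd_max, max(dv))
  # two identical accessions -> zero mean distance; singleton flagged
  g6 <- make_panel(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L), c(2L, 1L, 0L)))
  d6 <- ibs_distance(g6)
  s6 <- diversity_summary(g6, d6, setNames(c("dup", "dup", "solo"),
                                           g6$sample_ids))
  expect_equal(s6$gd_mean[s6$group == "dup"], 0)
  expect_true(s6$singleton[s6$group == "solo"])
  expect_true(is.na(s6$gd_mean[s6$group == "solo"]))
})

test_that("removing samples never increases segregating sites", {
  for (seed in 1:4) {
    g <- random_panel(10, 40, miss = 0.05, seed = seed + 20)
    full_seg <- sum(site_stats(g)$maf > 0, na.rm = TRUE)
    for (k in c(8, 5, 3)) {
      sub <- subset_panel(g, samples = seq_len(k))
      expect_lte(sum(site_stats(sub)$maf > 0, na.rm = TRUE), full_seg)
    }
  }
})
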