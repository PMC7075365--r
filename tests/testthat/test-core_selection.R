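# small helper: panel -> Euclidean distances + NJ tree
panel_tree <- function(g) {
  e <- sqrt_transform(ibs_distance(g))
  list(d = e, tree = neighbor_joining(e))
}

test_that("pruning to full size is the identity", {
  g <- random_panel(8, 40, seed = 1)
  pt <- panel_tree(g)
  cs <- max_length_subtree(pt$tree, 8, distances = pt$d)
  expect_equal(nrow(cs$trace), 0L)
  expect_setequal(cs$retained, g$sample_ids)
})

test_that("duplicates are pruned first, at removed-edge value 0", {
  set.seed(2)
  d <- random_panel(9, 60, seed = 2)$dosage
  d[5, ] <- d[4, ]                       # s05 duplicates s04
  g <- make_panel(d)
  pt <- panel_tree(g)
  cs <- max_length_subtree(pt$tree, 5, distances = pt$d)
  expect_equal(cs$trace$removed[1], "s05")   # lexicographically later twin
  expect_equal(cs$trace$removed_edge[1], 0)
  expect_equal(cs$trace$partner[1], "s04")
  # the duplicate removal is flagged at the default synonym threshold
  syn <- detect_synonyms(cs$trace)
  expect_equal(syn$removed, "s05")
  expect_equal(syn$partner, "s04")
  # a well-spread panel yields no synonyms
  g2 <- random_panel(8, 80, seed = 9)
  pt2 <- panel_tree(g2)
  cs2 <- max_length_subtree(pt2$tree, 4, distances = pt2$d)
  expect_true(all(cs2$trace$removed_edge >= 0.0008))
  expect_equal(nrow(detect_synonyms(cs2$trace)), 0L)
})

test_that("must_keep protects even the most redundant accession", {
  set.seed(3)
  d <- random_panel(9, 60, seed = 3)$dosage
  d[5, ] <- d[4, ]
  g <- make_panel(d)
  pt <- panel_tree(g)
  cs <- max_length_subtree(pt$tree, 5, must_keep = "s05", distances = pt$d)
  expect_true("s05" %in% cs$retained)
  expect_equal(cs$trace$removed[1], "s04")   # twin goes instead
  expect_error(max_length_subtree(pt$tree, 5, must_keep = "ghost"),
               "unknown")
  expect_error(max_length_subtree(pt$tree, 99), "exceeds")
})

test_that("trace invariants hold and cores are nested", {
  g <- random_panel(12, 80, seed = 4)
  pt <- panel_tree(g)
  cs <- max_length_subtree(pt$tree, 3, distances = pt$d)
  tr <- cs$trace
  expect_equal(tr$retained_size, seq(11, 3))
  expect_true(all(diff(tr$retained_length) <= 1e-12))
  expect_true(all(tr$retained_length <= attr(tr, "initial_length") + 1e-12))
  # nested cores: the size-k core from the same trace contains the (k-1) core
  all_ids <- g$sample_ids
  core_at <- function(k) setdiff(all_ids, tr$removed[tr$retained_size >= k])
  for (k in 4:11) expect_true(all(core_at(k - 1) %in% core_at(k)))
})

test_that("greedy cores beat random same-size subsets in retained length", {
  # retained tree length of a leaf subset = total length of the spanning
  # subtree; computed independently via ape::keep.tip
  wins <- 0L
  trials <- 0L
  for (seed in 1:10) {
    g <- random_panel(14, 60, miss = 0.02, seed = 100 + seed)
    pt <- panel_tree(g)
    cs <- max_length_subtree(pt$tree, 7, distances = pt$d)
    greedy_len <- sum(ape::keep.tip(pt$tree, cs$retained)$edge.length)
    set.seed(seed)
    for (r in 1:10) {
      rnd <- sample(g$sample_ids, 7)
      rnd_len <- sum(ape::keep.tip(pt$tree, rnd)$edge.length)
      trials <- trials + 1L
      if (greedy_len >= rnd_len - 1e-12) wins <- wins + 1L
    }
    # the trace's retained_length agrees with the independent subtree length
    expect_equal(cs$trace$retained_length[nrow(cs$trace)], greedy_len,
                 tolerance = 1e-9)
  }
  expect_gte(wins / trials, 0.95)
})

test_that("removed-edge values trend upward on ultrametric-like panels", {
  set.seed(6)
  # hierarchical panel: clusters of near-duplicates around distinct centers
  centers <- matrix(rbinom(4 * 60, 2L, 0.5), 4)
  rows <- do.call(rbind, lapply(1:4, function(i) {
    t(vapply(1:4, function(j) {
      x <- centers[i, ]
      flip <- runif(60) < 0.03 * j
      x[flip] <- rbinom(sum(flip), 2L, 0.5)
      as.integer(x)
    }, integer(60)))
  }))
  g <- make_panel(rows)
  pt <- panel_tree(g)
  cs <- max_length_subtree(pt$tree, 4, distances = pt$d)
  expect_gt(cor(cs$trace$step, cs$trace$removed_edge, method = "spearman"),
            0)
})

test_that("sphericity index follows its mean/max definition", {
  m <- square_matrix(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3), letters[1:3])
  expect_equal(sphericity_index(m, letters[1:3]), 1)   # all equal
  expect_equal(sphericity_index(m, c("a", "b")), 1)    # single pair
  m2 <- square_matrix(matrix(c(0, 1, 1, 1, 0, 4, 1, 4, 0), 3),
                      letters[1:3], tol = 1)
  expect_equal(sphericity_index(m2, letters[1:3]), 0.5)  # mean 2 / max 4
  z <- square_matrix(matrix(0, 2, 2), c("a", "b"))
  expect_equal(sphericity_index(z, c("a", "b")), 1)    # degenerate: max 0
  expect_error(sphericity_index(m, "a"), "at least 2")
})

test_that("knee selection follows the chord rule", {
  mk_trace <- function(sizes, values) {
    tr <- data.frame(step = seq_along(sizes) - 1, removed = "x",
                     removed_edge = 0, partner = "y",
                     retained_size = sizes, retained_length = values,
                     sphericity = values)[-1, ]
    attr(tr, "initial_size") <- sizes[1]
    attr(tr, "initial_length") <- values[1]
    attr(tr, "initial_sphericity") <- values[1]
    class(tr) <- c("core_trace", "data.frame")
    tr
  }
  # ideal L-curve: flat then cliff; corner known by construction
  lt <- mk_trace(10:4, c(1, 0.999, 0.998, 0.997, 0.5, 0.25, 0.1))
  expect_equal(choose_core_size(lt, "sphericity"), 7L)
  # monotone convex toy: chord distances (hand-computed, chord from
  # (10, 1.0) to (6, 0.40)) are prop. to (0, 0.56, 1.08, 1.00, 0):
  # the knee the stated rule yields is retained size 8
  ct <- mk_trace(10:6, c(1, 0.99, 0.97, 0.80, 0.40))
  expect_equal(choose_core_size(ct, "sphericity"), 8L)
  # perfectly linear curve: no knee, largest size returned with a flag
  lin <- mk_trace(10:5, seq(1, 0.5, length.out = 6))
  expect_warning(k <- choose_core_size(lin, "retained_length"), "linear")
  expect_equal(as.integer(k), 10L)
  expect_true(attr(k, "no_knee"))
  expect_error(choose_core_size(mk_trace(c(5, 4), c(1, 0)), "sphericity"),
               "at least 3")
})

test_that("core evaluation is exact in the identity and loss cases", {
  g <- random_panel(10, 50, seed = 8)
  ev <- evaluate_core(g, g$sample_ids)
  expect_equal(ev$retention_pct, 100)
  expect_equal(ev$freq_delta_max, 0)
  expect_equal(unname(ev$ratios), rep(1, 3))
  # drop every carrier of one site's minor allele -> that site is lost
  d <- cbind(c(1L, 1L, rep(0L, 8)), matrix(1L, 10, 1),
             random_panel(10, 20, seed = 88)$dosage)
  d[, 2] <- rep(c(0L, 2L), 5)
  g2 <- make_panel(d)
  core_ids <- g2$sample_ids[3:10]        # excludes both carriers of site 1
  ev2 <- evaluate_core(g2, core_ids)
  seg_full <- sum(site_stats(g2)$maf > 0, na.rm = TRUE)
  expect_lte(ev2$segregating_core, seg_full - 1L)
  expect_error(evaluate_core(g2, character()), "empty")
  expect_error(evaluate_core(g2, "nope"), "not in panel")
})
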