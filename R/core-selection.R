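# nearest retained tip (by path length) from a given tip; tie -> smallest
# label. Fast path: a tip sharing the victim's parent node (cherry partner);
# otherwise fall back to full node distances.
nearest_tip <- function(tree, tip) {
  n <- length(tree$tip.label)
  parent <- tree$edge[match(tip, tree$edge[, 2]), 1]
  sibs <- tree$edge[tree$edge[, 1] == parent, 2]
  sibs <- setdiff(sibs[sibs <= n], tip)
  if (length(sibs)) {
    ter <- tree$edge.length[match(sibs, tree$edge[, 2])]
    hits <- sibs[ter <= min(ter) + 1e-15]
    return(tree$tip.label[hits[order(tree$tip.label[hits])[1L]]])
  }
  dn <- ape::dist.nodes(tree)[tip, seq_len(n)]
  dn[tip] <- Inf
  hits <- which(dn <= min(dn) + 1e-15)
  tree$tip.label[hits[order(tree$tip.label[hits])[1L]]]
}

terminal_edge_lengths <- function(tree) {
  n <- length(tree$tip.label)
  tipe <- match(seq_len(n), tree$edge[, 2])
  stats::setNames(tree$edge.length[tipe], tree$tip.label)
}

#' Maximum-length-subtree core selection
#'
#' Stepwise pruning of the most redundant accessions from an (NJ) tree:
#' at each step the retained leaf with the *shortest terminal edge* —
#' excluding `must_keep` accessions — is removed (the leaf with the longest
#' edge carries the most uncommon characters and is the most diverse, so it
#' is kept); the resulting degree-2 node is suppressed by merging its two
#' incident edges (lengths add), preserving the tree backbone. The tree is
#' never re-estimated between removals. Ties remove the lexicographically
#' latest tied leaf, so the smallest label survives. Every step is logged:
#' removed
#' accession, its removed (terminal) edge length on the input tree's scale,
#' its cherry partner at removal time (the tip sibling when one exists, else
#' the nearest tip by path length), the retained total tree
#' length, the retained sphericity index (when `distances` is supplied) and
#' the retained size — so one call yields the whole nested family of cores
#' from n down to `target_size`.
#'
#' @param tree a `phylo`, typically from [neighbor_joining()] on
#'   square-root-transformed IBS distances
#' @param target_size number of accessions to retain
#'   (`>= max(2, length(must_keep))`)
#' @param must_keep accession ids never removed (e.g. reference cultivars
#'   re-added to a mini-core)
#' @param distances optional [square_matrix] on the same scale as the tree,
#'   used to log the per-step sphericity index
#' @return list of class `core_set`: `retained` (ids), `target_size`,
#'   `must_keep`, `trace` (class `core_trace`: one row per removal with
#'   columns `step`, `removed`, `removed_edge`, `partner`, `retained_size`,
#'   `retained_length`, `sphericity`; attributes `initial_size`,
#'   `initial_length`, `initial_sphericity`)
#' @export
max_length_subtree <- function(tree, target_size, must_keep = character(),
                               distances = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  n <- length(labs)
  must_keep <- as.character(must_keep)
  unknown <- setdiff(must_keep, labs)
  if (length(unknown)) stop("must_keep contains unknown id(s): ",
                            paste(unknown, collapse = ", "))
  if (target_size > n) stop("target_size (", target_size,
                            ") exceeds leaf count (", n, ")")
  if (target_size < max(2L, length(must_keep)))
    stop("target_size must be >= max(2, length(must_keep))")
  has_d <- !is.null(distances)
  sph <- function(ids) if (has_d) sphericity_index(distances, ids) else
    NA_real_
  init_len <- sum(tree$edge.length)
  init_sph <- sph(labs)
  steps <- vector("list", n - target_size)
  k <- 0L
  while (length(tree$tip.label) > target_size) {
    ter <- terminal_edge_lengths(tree)
    cand <- setdiff(names(ter), must_keep)
    vmin <- min(ter[cand])
    hits <- cand[ter[cand] <= vmin + 1e-15]
    victim <- sort(hits)[length(hits)]  # tie: keep the smallest label
    partner <- nearest_tip(tree, match(victim, tree$tip.label))
    tree <- ape::drop.tip(tree, victim, collapse.singles = TRUE)
    k <- k + 1L
    steps[[k]] <- data.frame(
      step = k, removed = victim, removed_edge = unname(ter[victim]),
      partner = partner, retained_size = length(tree$tip.label),
      retained_length = sum(tree$edge.length),
      sphericity = sph(tree$tip.label), stringsAsFactors = FALSE)
  }
  trace <- if (k) do.call(rbind, steps[seq_len(k)]) else
    data.frame(step = integer(), removed = character(),
               removed_edge = numeric(), partner = character(),
               retained_size = integer(), retained_length = numeric(),
               sphericity = numeric(), stringsAsFactors = FALSE)
  attr(trace, "initial_size") <- n
  attr(trace, "initial_length") <- init_len
  attr(trace, "initial_sphericity") <- init_sph
  class(trace) <- c("core_trace", "data.frame")
  structure(list(retained = tree$tip.label, target_size = target_size,
                 must_keep = must_keep, trace = trace),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat("<core_set> ", length(x$retained), " accessions retained (",
      nrow(x$trace), " pruned; ", length(x$must_keep), " protected)\n",
      sep = "")
  invisible(x)
}

#' Sphericity index of a subset of accessions
#'
#' Mean pairwise distance within the subset divided by the maximum pairwise
#' distance within it — a bounded (0, 1] score of how evenly the retained
#' set fills the distance space; pruning near-duplicates drives it up toward
#' 1. A subset of identical points (max distance 0) and a single pair are
#' both defined as 1.
#'
#' @param d a [square_matrix]
#' @param subset ids (labels of `d`), at least 2
#' @return a fraction in (0, 1]
#' @export
sphericity_index <- function(d, subset) {
  subset <- as.character(subset)
  if (length(subset) < 2L) stop("subset must contain at least 2 ids")
  m <- unclass(d)[subset, subset, drop = FALSE]
  v <- m[upper.tri(m)]
  mx <- max(v)
  if (mx == 0) return(1)
  mean(v) / mx
}

#' Stopping size from the knee of a pruning curve
#'
#' Plots the selected per-step diagnostic (sphericity index or retained tree
#' length) against retained size — including the pre-pruning point — and
#' returns the retained size with maximum perpendicular distance from the
#' chord joining the curve's endpoints. Ties break toward the larger
#' retained size. A (near-)linear curve has no knee: the largest retained
#' size is returned with attribute `no_knee = TRUE` and a warning.
#'
#' @param trace a `core_trace` with at least 3 usable points
#' @param curve `"sphericity"` or `"retained_length"`
#' @return integer retained size (with attribute `no_knee` when degenerate)
#' @export
choose_core_size <- function(trace, curve = c("sphericity",
                                              "retained_length")) {
  curve <- match.arg(curve)
  x <- c(attr(trace, "initial_size"), trace$retained_size)
  y <- c(if (curve == "sphericity") attr(trace, "initial_sphericity") else
           attr(trace, "initial_length"),
         if (curve == "sphericity") trace$sphericity else
           trace$retained_length)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 curve points to locate a knee")
  ord <- order(-x)
  x <- x[ord]; y <- y[ord]
  m <- length(x)
  dx <- x[m] - x[1L]; dy <- y[m] - y[1L]
  dist <- abs(dx * (y - y[1L]) - dy * (x - x[1L])) / sqrt(dx^2 + dy^2)
  if (max(dist) < 1e-12 * max(1, abs(diff(range(y))))) {
    warning("curve is linear within tolerance; no knee found")
    return(structure(as.integer(x[1L]), no_knee = TRUE))
  }
  best <- which(dist >= max(dist) - 1e-15)
  as.integer(max(x[best]))
}

#' Presumptive synonym (duplicate accession) detection
#'
#' Any pruning step whose removed terminal-edge value falls below
#' `threshold` (default 0.0008, on the Euclidean — square-root-transformed —
#' distance scale) flags the removed accession as a presumptive synonym of
#' its nearest retained neighbor at removal time.
#'
#' @param trace a `core_trace`
#' @param threshold Euclidean-distance threshold (default 0.0008)
#' @return data.frame with `removed`, `partner`, `removed_edge`, `step`
#' @export
detect_synonyms <- function(trace, threshold = 0.0008) {
  hit <- !is.na(trace$removed_edge) & trace$removed_edge < threshold
  out <- trace[hit, c("removed", "partner", "removed_edge", "step")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Evaluate how well a core set retains whole-panel diversity
#'
#' Reports, for a candidate core against its full panel: the percentage of
#' the panel's segregating (polymorphic) sites still segregating within the
#' core; core vs whole means and ratios of Ho, PIC and MAF; the maximum and
#' mean absolute ALT-allele frequency difference; mean genotype-class
#' frequency spectra; within-core IBS distance min/mean/max; and a Welch
#' two-sample t-test of per-accession Ho between core and whole set.
#'
#' @param geno the full-panel [genotype_matrix]
#' @param core a `core_set` or character vector of retained ids
#' @return list of class `core_eval`
#' @export
evaluate_core <- function(geno, core) {
  ids <- if (inherits(core, "core_set")) core$retained else as.character(core)
  if (!length(ids)) stop("core set is empty")
  unknown <- setdiff(ids, geno$sample_ids)
  if (length(unknown)) stop("core ids not in panel: ",
                            paste(unknown, collapse = ", "))
  ss_full <- site_stats(geno)
  sub <- subset_panel(geno, samples = ids)
  ss_core <- site_stats(sub)
  seg_full <- which(ss_full$defined & ss_full$maf > 0)
  seg_core <- ss_core$defined & ss_core$maf > 0
  retention <- 100 * sum(seg_core[seg_full]) / length(seg_full)
  ho_full <- sample_heterozygosity(geno)$ho
  ho_core <- sample_heterozygosity(sub)$ho
  both <- ss_full$defined & ss_core$defined
  dp <- abs(ss_core$p_alt - ss_full$p_alt)[both]
  gfreq <- function(g) c(
    hom_ref = mean(colMeans(g$dosage == 0L, na.rm = TRUE), na.rm = TRUE),
    het = mean(colMeans(g$dosage == 1L, na.rm = TRUE), na.rm = TRUE),
    hom_alt = mean(colMeans(g$dosage == 2L, na.rm = TRUE), na.rm = TRUE))
  dmat <- if (length(ids) >= 2L) unclass(ibs_distance(sub)) else NULL
  dv <- if (!is.null(dmat)) dmat[upper.tri(dmat)] else NA_real_
  tt <- if (length(ids) >= 2L)
    stats::t.test(ho_core, ho_full) else NULL
  structure(list(
    n_full = n_samples(geno), n_core = length(ids),
    segregating_full = length(seg_full),
    segregating_core = sum(seg_core[seg_full]),
    retention_pct = retention,
    means = data.frame(
      set = c("whole", "core"),
      ho = c(mean(ho_full, na.rm = TRUE), mean(ho_core, na.rm = TRUE)),
      pic = c(mean(ss_full$pic, na.rm = TRUE),
              mean(ss_core$pic, na.rm = TRUE)),
      maf = c(mean(ss_full$maf, na.rm = TRUE),
              mean(ss_core$maf, na.rm = TRUE))),
    ratios = c(
      ho = mean(ho_core, na.rm = TRUE) / mean(ho_full, na.rm = TRUE),
      pic = mean(ss_core$pic, na.rm = TRUE) / mean(ss_full$pic, na.rm = TRUE),
      maf = mean(ss_core$maf, na.rm = TRUE) / mean(ss_full$maf, na.rm = TRUE)),
    freq_delta_max = max(dp), freq_delta_mean = mean(dp),
    genotype_freq = rbind(whole = gfreq(geno), core = gfreq(sub)),
    core_distance = c(min = min(dv), mean = mean(dv), max = max(dv)),
    ho_test = tt), class = "core_eval")
}

#' @export
print.core_eval <- function(x, ...) {
  cat("<core_eval> core ", x$n_core, "/", x$n_full, " accessions; ",
      sprintf("%.2f", x$retention_pct), "% of ", x$segregating_full,
      " segregating sites retained\n", sep = "")
  cat("  Ho/PIC/MAF ratios (core/whole): ",
      paste(sprintf("%.3f", x$ratios), collapse = " / "), "\n", sep = "")
  invisible(x)
}
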