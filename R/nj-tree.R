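#' Square-root (Euclidean) transform of a dissimilarity matrix
#'
#' Element-wise square root. For IBS-style dissimilarities in `[0, 1]` the
#' result is Euclidean-embeddable and is the scale on which the core-selection
#' edge thresholds operate.
#'
#' @param d a [square_matrix] with non-negative entries
#' @return a [square_matrix]
#' @export
sqrt_transform <- function(d) {
  d <- square_matrix(unclass(d))
  if (any(d < 0)) stop("negative dissimilarity entries cannot be transformed")
  square_matrix(sqrt(unclass(d)), rownames(d))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic (unweighted) Saitou-Nei agglomeration with the rate-corrected
#' selection criterion Q(i, j) = (m - 2) d(i, j) - r_i - r_j. Ties in Q are
#' broken toward the lexicographically smallest pair of cluster labels (a
#' cluster is labeled by its smallest member leaf), so the result is fully
#' deterministic. Negative estimated branch lengths are clamped to 0 without
#' transferring length to sibling edges. Exact on additive matrices.
#'
#' @param d a [square_matrix], n >= 2
#' @return an unrooted `phylo` tree (2-leaf input yields the single edge
#'   split as two half-length branches around a degree-2 node, preserving the
#'   leaf-to-leaf path length)
#' @export
neighbor_joining <- function(d) {
  d <- square_matrix(unclass(d))     # validates symmetry / labels
  labels <- rownames(d)
  n <- nrow(d)
  fmt <- function(x) sprintf("%.17g", max(x, 0))
  if (n == 2L) {
    nwk <- paste0("(", labels[1L], ":", fmt(d[1, 2] / 2), ",",
                  labels[2L], ":", fmt(d[1, 2] / 2), ");")
    return(ape::read.tree(text = nwk))
  }
  D <- unclass(d)
  sub <- labels                      # newick fragment per active cluster
  lab <- labels                      # smallest leaf label per cluster
  while (length(lab) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= abs(qmin) * 1e-12 + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(lab[cand[, 1]], lab[cand[, 2]]),
                 pmax(lab[cand[, 1]], lab[cand[, 2]]), sep = "\r")
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    new_sub <- paste0("(", sub[i], ":", fmt(vi), ",", sub[j], ":", fmt(vj),
                      ")")
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    sub <- c(sub[keep], new_sub)
    lab <- c(lab[keep], min(lab[c(i, j)]))
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", sub[1L], ":", fmt(va), ",", sub[2L], ":", fmt(vb), ",",
                sub[3L], ":", fmt(vc), ");")
  ape::read.tree(text = nwk)
}

# canonical keys for the non-trivial bipartitions induced by internal edges:
# each internal node's tip set, expressed as the side not containing the
# alphabetically first leaf, as a sorted collapsed label string
bipartition_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    side <- sort(tree$tip.label[idx])
    if (anchor %in% side) side <- setdiff(tips, side)
    paste(side, collapse = "\r")
  }, "")
  keys                                  # one per internal node, node order
}

#' Bootstrap support for the IBS neighbor-joining tree
#'
#' Builds the point-estimate tree (IBS distance, square-root transform, NJ),
#' then resamples sites with replacement `n_reps` times, recomputing the tree
#' per replicate. The support of each internal node's bipartition is the
#' fraction of replicate trees containing it; supports are stored in
#' `$node.label` (root: `NA`). Fully determined by `seed`.
#'
#' @param geno a [genotype_matrix]
#' @param n_reps number of bootstrap replicates (>= 1)
#' @param seed integer RNG seed
#' @return a `phylo` with numeric `node.label` supports in `[0, 1]`
#' @export
bootstrap_support <- function(geno, n_reps, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  base_tree <- neighbor_joining(sqrt_transform(ibs_distance(geno)))
  keys <- bipartition_keys(base_tree)
  counts <- numeric(length(keys))
  m <- n_sites(geno)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(m, m, replace = TRUE)
    rep_tree <- neighbor_joining(
      sqrt_transform(ibs_distance(subset_panel(geno, sites = idx))))
    counts <- counts + (keys %in% bipartition_keys(rep_tree))
  }
  support <- counts / n_reps
  support[1L] <- NA_real_               # root pseudo-bipartition (all tips)
  base_tree$node.label <- support
  base_tree
}

#' Cut a tree into k groups by removing its longest internal edges
#'
#' Removes the k - 1 longest internal (node-to-node) edges; the connected
#' components of the remaining tree define the groups, numbered by
#' decreasing leaf count (ties by smallest member label). A reproducible
#' stand-in for expert visual delineation of clusters.
#'
#' @param tree a `phylo`
#' @param k number of groups, `1 <= k <= n_leaves`
#' @return named integer vector mapping leaf label to group number
#' @export
cut_into_groups <- function(tree, k) {
  n <- length(tree$tip.label)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  internal <- which(tree$edge[, 1] > n & tree$edge[, 2] > n)
  if (k - 1L > length(internal))
    stop("tree has only ", length(internal),
         " internal edges; cannot form ", k, " groups")
  drop <- internal[order(-tree$edge.length[internal], internal)][
    seq_len(k - 1L)]
  edges <- tree$edge[setdiff(seq_len(nrow(tree$edge)), drop), , drop = FALSE]
  n_nodes <- max(tree$edge)
  comp <- seq_len(n_nodes)              # union-find
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) comp[min(a, b)] <- max(a, b)
  }
  tip_comp <- vapply(seq_len(n), find, integer(1))
  grp_sizes <- table(tip_comp)
  first_lab <- vapply(names(grp_sizes), function(g)
    min(tree$tip.label[tip_comp == as.integer(g)]), "")
  ord <- order(-as.integer(grp_sizes), first_lab)
  renum <- stats::setNames(seq_along(ord), names(grp_sizes)[ord])
  out <- renum[as.character(tip_comp)]
  names(out) <- tree$tip.label
  out
}
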