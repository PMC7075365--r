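# shared fixture builders; everything is generated in code at test time

# panel from an explicit samples x sites dosage matrix
make_panel <- function(dosage, chrom = NULL, pos = NULL, info = NULL,
                       ids = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  sites <- data.frame(
    chrom = chrom %||% rep("PG_1", m),
    pos = pos %||% seq_len(m) * 100L,
    ref = rep("A", m), alt = rep("G", m), stringsAsFactors = FALSE)
  genotype_matrix(dosage, sites,
                  ids %||% sprintf("s%02d", seq_len(nrow(dosage))),
                  info = info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small panel with optional missingness, uniform allele frequencies
random_panel <- function(n = 8, m = 20, miss = 0, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  d <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  if (miss > 0) d[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
  make_panel(d)
}

# a tiny hand-written VCF fixture; returns the path
write_toy_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

toy_vcf_header <- function(samples = c("s1", "s2")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

expect_tree_equal <- function(a, b, tol = 1e-9) {
  expect_setequal(a$tip.label, b$tip.label)
  da <- ape::cophenetic.phylo(a)
  db <- ape::cophenetic.phylo(b)[rownames(da), colnames(da)]
  expect_lt(max(abs(da - db)), tol)
}

# independent brute-force LD-pruning oracle: literal windowed all-pairs scan
# over the stated rule (windows of `win` sites advanced by `step` on input
# order; violating pair -> drop the lower-MAF site, tie -> later site)
brute_force_prune <- function(geno, win = 50, step = 10, r2max = 0.2) {
  d <- geno$dosage
  maf <- pmin(colMeans(d, na.rm = TRUE) / 2,
              1 - colMeans(d, na.rm = TRUE) / 2)
  removed <- rep(FALSE, ncol(d))
  for (chr in unique(geno$sites$chrom)) {
    idx <- which(geno$sites$chrom == chr)
    if (length(idx) < 2) next
    for (s in seq(1, max(1, length(idx) - 1), by = step)) {
      w <- idx[s:min(length(idx), s + win - 1)]
      for (a in seq_along(w)) for (b in seq_along(w)) {
        if (a >= b || removed[w[a]] || removed[w[b]]) next
        r <- suppressWarnings(
          cor(d[, w[a]], d[, w[b]], use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2max) {
          removed[if (maf[w[a]] < maf[w[b]]) w[a] else w[b]] <- TRUE
        }
      }
    }
  }
  which(!removed)
}
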