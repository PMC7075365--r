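#' SNP genotype panel container
#'
#' A `genotype_matrix` holds a panel of accessions typed at biallelic (or
#' to-be-filtered multiallelic) SNP sites as ALT-allele dosages. Dosages are
#' integers in \{0, 1, 2\}; missing genotypes are `NA` (never 0, which is a
#' legal homozygote). Major/minor allele status is *not* taken from REF/ALT:
#' it is computed from observed frequencies where needed.
#'
#' @param dosage integer matrix, samples in rows, sites in columns; entries in
#'   \{0, 1, 2, NA\}. Row names, if present, must match `sample_ids`.
#' @param sites data.frame with one row per site and at least columns
#'   `chrom` (character), `pos` (1-based integer), `ref`, `alt`
#'   (single-character alleles for biallelic sites; comma-separated ALT string
#'   marks a multiallelic record awaiting filtering). An optional logical
#'   column `biallelic` is added when absent. Numeric per-site annotations
#'   (QUAL, QD, FS, ...) travel in an optional data.frame attribute `info`.
#' @param sample_ids character vector of unique accession identifiers, one per
#'   row of `dosage`.
#' @param info optional data.frame of numeric per-site annotations (one row
#'   per site) used by the hard INFO filter.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `sites`, `sample_ids`.
#' @export
genotype_matrix <- function(dosage, sites, sample_ids, info = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (nrow(dosage) != length(sample_ids))
    stop("dosage has ", nrow(dosage), " rows but ", length(sample_ids),
         " sample ids")
  if (nrow(sites) != ncol(dosage))
    stop("dosage has ", ncol(dosage), " columns but ", nrow(sites), " sites")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("non-missing dosages must lie in {0, 1, 2}")
  sites <- as.data.frame(sites)
  needed <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(needed, names(sites))
  if (length(miss)) stop("sites table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(sites$pos < 1L)) stop("site positions must be >= 1")
  if (is.null(sites$biallelic))
    sites$biallelic <- !grepl(",", sites$alt) & nchar(sites$alt) == 1L &
      nchar(sites$ref) == 1L & sites$ref != sites$alt
  rownames(dosage) <- sample_ids
  obj <- list(dosage = dosage, sites = sites, sample_ids = sample_ids)
  if (!is.null(info)) {
    info <- as.data.frame(info)
    if (nrow(info) != nrow(sites))
      stop("info table must have one row per site")
    attr(obj$sites, "info") <- info
  }
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", n_samples(x), " accessions x ", n_sites(x),
      " sites; ", sum(x$sites$biallelic), " biallelic; missing rate ",
      signif(mean(is.na(x$dosage)), 3), "\n", sep = "")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname genotype_matrix
#' @export
n_sites <- function(x) nrow(x$sites)

#' Per-site numeric annotations (QUAL and INFO keys), or NULL
#' @param x a `genotype_matrix`
#' @keywords internal
#' @export
site_info <- function(x) attr(x$sites, "info")

#' Subset a genotype panel by samples and/or sites
#'
#' Order of retained sites/samples follows the index arguments; the `info`
#' annotation table, when present, is subset in step.
#'
#' @param x a `genotype_matrix`
#' @param samples sample indices, logical mask, or ids
#' @param sites site indices or logical mask
#' @return a `genotype_matrix`
#' @export
subset_panel <- function(x, samples = NULL, sites = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- seq_len(n_samples(x))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$sample_ids) else
      si[samples]
    if (anyNA(si)) stop("unknown sample id(s): ",
                        paste(samples[is.na(match(samples, x$sample_ids))],
                              collapse = ", "))
  }
  vi <- seq_len(n_sites(x))
  if (!is.null(sites)) vi <- vi[sites]
  info <- site_info(x)
  genotype_matrix(x$dosage[si, vi, drop = FALSE],
                  x$sites[vi, , drop = FALSE],
                  x$sample_ids[si],
                  info = if (!is.null(info)) info[vi, , drop = FALSE])
}

#' Labeled symmetric dissimilarity matrix
#'
#' Validates and tags a square numeric matrix as a pairwise
#' distance/dissimilarity: symmetric to `tol`, zero diagonal, unique labels.
#'
#' @param values square numeric matrix
#' @param labels optional character labels (defaults to existing dimnames)
#' @param tol symmetry/diagonal tolerance
#' @return the matrix with dimnames set and class `square_matrix` prepended
#' @export
square_matrix <- function(values, labels = rownames(values), tol = 1e-12) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix is not square")
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(values)))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (length(labels) != nrow(values)) stop("label/dimension mismatch")
  if (max(abs(values - t(values))) > tol)
    stop("matrix is asymmetric beyond tolerance ", tol)
  if (any(abs(diag(values)) > tol))
    stop("diagonal entries must be zero (found ", max(abs(diag(values))), ")")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  class(values) <- c("square_matrix", "matrix", "array")
  values
}

#' @export
print.square_matrix <- function(x, ...) {
  cat("<square_matrix> ", nrow(x), " x ", nrow(x), "; range [",
      signif(min(x[upper.tri(x)]), 4), ", ", signif(max(x), 4), "]\n", sep = "")
  invisible(x)
}
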