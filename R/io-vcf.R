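#' Read a multi-sample VCF into a genotype panel
#'
#' Parses a VCF 4.x file (via Bioconductor's `VariantAnnotation`) and codes
#' each genotype as the dosage of the ALT allele: 0/0 -> 0, 0/1 -> 1,
#' 1/1 -> 2, with `./.` (or any partially missing call) -> `NA`. Phased (`|`)
#' and unphased (`/`) separators are both accepted. Records with more than one
#' ALT allele are loaded with `NA` dosages and flagged `biallelic = FALSE` so
#' the filter stage can drop them. The QUAL column and all numeric scalar INFO
#' keys are carried as per-site annotations for the hard filter.
#'
#' @param path path to a VCF file (plain text or bgzipped)
#' @return a [genotype_matrix]
#' @export
read_vcf <- function(path) {
  con <- gzfile(path, "rt")          # duplicate-sample pre-check
  on.exit(close(con), add = TRUE)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("no #CHROM header line in ", path)
    if (startsWith(ln, "#CHROM")) {
      cols <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      smp <- cols[-seq_len(9L)]
      if (anyDuplicated(smp))
        stop("duplicated sample name(s) in VCF: ",
             paste(unique(smp[duplicated(smp)]), collapse = ", "))
      break
    }
    if (!startsWith(ln, "#")) stop("no #CHROM header line in ", path)
  }
  vcf <- VariantAnnotation::readVcf(path)
  if (!("GT" %in% names(VariantAnnotation::geno(vcf))))
    stop("VCF has no GT field in FORMAT; genotypes cannot be read")
  gt <- VariantAnnotation::geno(vcf)$GT   # variants x samples
  samples <- colnames(gt)
  if (anyDuplicated(samples))
    stop("duplicated sample name(s) in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))

  rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                function(a) paste(as.character(a), collapse = ","), "")

  # map each distinct GT string once, then index
  u <- unique(as.vector(gt))
  ud <- vapply(strsplit(u, "[/|]"), function(al) {
    if (length(al) != 2L || any(al == "." | al == "")) return(NA_integer_)
    v <- suppressWarnings(as.integer(al))
    if (anyNA(v) || any(v > 1L)) return(NA_integer_)  # multiallelic call
    sum(v)
  }, integer(1))
  dosage <- matrix(ud[match(as.vector(gt), u)], nrow = nrow(gt))
  dosage <- t(dosage)                      # samples x sites

  sites <- data.frame(chrom = as.character(rr$seqnames), pos = rr$start,
                      ref = ref, alt = alt, stringsAsFactors = FALSE)

  info <- VariantAnnotation::info(vcf)
  keep <- vapply(seq_along(info), function(j) {
    v <- info[[j]]
    is.atomic(v) && is.numeric(v) && length(v) == nrow(sites)
  }, logical(1))
  idf <- data.frame(QUAL = as.numeric(rr$QUAL %||% NA_real_))
  if (any(keep))
    idf <- cbind(idf, as.data.frame(info[, keep, drop = FALSE]))
  if (is.null(rr$QUAL)) {
    q <- VariantAnnotation::fixed(vcf)$QUAL
    if (!is.null(q)) idf$QUAL <- as.numeric(q)
  }
  genotype_matrix(dosage, sites, samples, info = idf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a genotype panel as a minimal VCF 4.2 file
#'
#' Emits a GT-only VCF: dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`,
#' `NA` -> `./.`. Per-site numeric annotations are written back to the QUAL
#' column and INFO field so a write/read cycle preserves them.
#'
#' @param x a [genotype_matrix]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  info <- site_info(x)
  ikeys <- setdiff(names(info), "QUAL")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   ikeys, ikeys),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$sample_ids), collapse = "\t"))
  gt <- matrix(c("0/0", "0/1", "1/1")[x$dosage + 1L], nrow = n_samples(x))
  gt[is.na(x$dosage)] <- "./."
  gt <- t(gt)                              # sites x samples
  qual <- rep(".", n_sites(x))
  if (!is.null(info$QUAL)) {
    ok <- !is.na(info$QUAL)
    qual[ok] <- format(info$QUAL[ok], digits = 10, trim = TRUE)
  }
  if (length(ikeys)) {
    parts <- lapply(ikeys, function(k) {
      v <- info[[k]]
      ifelse(is.na(v), NA_character_,
             paste0(k, "=", format(v, digits = 10, trim = TRUE)))
    })
    istr <- apply(do.call(cbind, parts), 1L,
                  function(r) paste(r[!is.na(r)], collapse = ";"))
    istr[istr == ""] <- "."
  } else istr <- rep(".", n_sites(x))
  fixed <- paste(x$sites$chrom, x$sites$pos,
                 paste0(x$sites$chrom, "_", x$sites$pos),
                 x$sites$ref, x$sites$alt, qual, "PASS", istr, "GT",
                 sep = "\t")
  body <- paste(fixed, do.call(paste,
                c(as.data.frame(gt, stringsAsFactors = FALSE), sep = "\t")),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
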