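#' Derive the four mature-leaf size traits
#'
#' From mature leaf length (MLL, cm) and width (MLW, cm), per accession and
#' season: the leaf shape index MLSI = MLL / MLW and the leaf area
#' MLA = 0.75 * MLW * MLL (cm^2). Records with MLL or MLW missing keep `NA`
#' derived traits; MLW = 0 is an error (shape index undefined), negative
#' dimensions are errors.
#'
#' @param table data.frame with columns `accession`, `season`, `MLL`, `MLW`
#'   (e.g. from [read_phenotypes()])
#' @return the table with `MLSI` and `MLA` columns (re)computed
#' @export
derive_traits <- function(table) {
  for (cl in c("accession", "season", "MLL", "MLW")) {
    if (!cl %in% names(table)) stop("phenotype table lacks column ", cl)
  }
  bad0 <- !is.na(table$MLW) & table$MLW == 0
  if (any(bad0)) stop("MLW = 0 for accession ",
                      table$accession[which(bad0)[1L]],
                      "; shape index undefined")
  neg <- (!is.na(table$MLL) & table$MLL < 0) |
    (!is.na(table$MLW) & table$MLW < 0)
  if (any(neg)) stop("negative leaf dimension for accession ",
                     table$accession[which(neg)[1L]])
  table$MLSI <- table$MLL / table$MLW
  table$MLA <- 0.75 * table$MLW * table$MLL
  table
}

#' Adjusted sample skewness / excess kurtosis with closed-form SEs
#'
#' The small-sample adjusted estimators used by mainstream descriptive
#' statistics software: skewness G1 = m3 / m2^{3/2} * sqrt(n(n-1)) / (n-2)
#' and excess kurtosis G2 = ((n+1)(m4/m2^2 - 3) + 6) (n-1)/((n-2)(n-3)),
#' with SE(G1) = sqrt(6n(n-1)/((n-2)(n+1)(n+3))) and
#' SE(G2) = 2 SE(G1) sqrt((n^2-1)/((n-3)(n+5))).
#'
#' @param x numeric vector (NAs dropped)
#' @return named vector `skewness`, `skew_se`, `kurtosis`, `kurt_se`
#'   (`NA` when n < 4 or the sample is constant)
#' @export
skew_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  out <- c(skewness = NA_real_, skew_se = NA_real_,
           kurtosis = NA_real_, kurt_se = NA_real_)
  if (n < 3L) return(out)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(out)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  out["skewness"] <- g1 * sqrt(n * (n - 1)) / (n - 2)
  out["skew_se"] <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  if (n >= 4L) {
    out["kurtosis"] <- ((n + 1) * (m4 / m2^2 - 3) + 6) * (n - 1) /
      ((n - 2) * (n - 3))
    out["kurt_se"] <- 2 * out["skew_se"] *
      sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  }
  out
}

#' Descriptive trait summary (mean, spread, shape)
#'
#' Per trait and (optionally) per season: n, mean, sd, min, max, adjusted
#' skewness and excess kurtosis with their closed-form standard errors.
#' Constant traits get sd 0 and missing shape statistics.
#'
#' @param records data.frame from [derive_traits()]
#' @param traits trait columns to summarize
#' @param by_season summarize each season separately (default FALSE pools)
#' @return data.frame, one row per trait (x season)
#' @export
trait_summary <- function(records,
                          traits = c("MLL", "MLW", "MLA", "MLSI"),
                          by_season = FALSE) {
  traits <- intersect(traits, names(records))
  seasons <- if (by_season) unique(records$season) else "all"
  rows <- list()
  for (se in seasons) {
    sub <- if (by_season) records[records$season == se, ] else records
    for (tr in traits) {
      x <- sub[[tr]]
      x <- x[!is.na(x)]
      sk <- skew_kurtosis(x)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, season = se, n = length(x),
        mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
        skewness = sk[["skewness"]], skew_se = sk[["skew_se"]],
        kurtosis = sk[["kurtosis"]], kurt_se = sk[["kurt_se"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pearson correlations among traits and across seasons
#'
#' Within each season, Pearson r (and two-sided p from the t transform) for
#' every trait pair on pairwise-complete records; and, per trait, the
#' cross-season correlation of accession-matched values. Zero-variance
#' traits yield `NA` correlations.
#'
#' @param records data.frame from [derive_traits()] with a `season` column
#' @param traits trait columns to correlate
#' @return list with `within` (data.frame: season, trait1, trait2, r, p, n)
#'   and `between` (data.frame: trait, season1, season2, r, p, n)
#' @export
trait_correlations <- function(records,
                               traits = c("MLL", "MLW", "MLA", "MLSI")) {
  traits <- intersect(traits, names(records))
  cor_p <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(r = NA_real_, p = NA_real_, n = n))
    r <- stats::cor(x[ok], y[ok])
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    c(r = r, p = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE), n = n)
  }
  seasons <- unique(records$season)
  within <- list()
  for (se in seasons) {
    sub <- records[records$season == se, ]
    for (i in seq_along(traits)) for (j in seq_len(i - 1L)) {
      v <- cor_p(sub[[traits[i]]], sub[[traits[j]]])
      within[[length(within) + 1L]] <- data.frame(
        season = se, trait1 = traits[j], trait2 = traits[i],
        r = v[["r"]], p = v[["p"]], n = v[["n"]], stringsAsFactors = FALSE)
    }
  }
  between <- list()
  if (length(seasons) >= 2L) {
    pairs <- utils::combn(seasons, 2L, simplify = FALSE)
    for (pr in pairs) for (tr in traits) {
      a <- records[records$season == pr[1L], c("accession", tr)]
      b <- records[records$season == pr[2L], c("accession", tr)]
      mrg <- merge(a, b, by = "accession")
      v <- cor_p(mrg[[2L]], mrg[[3L]])
      between[[length(between) + 1L]] <- data.frame(
        trait = tr, season1 = pr[1L], season2 = pr[2L],
        r = v[["r"]], p = v[["p"]], n = v[["n"]], stringsAsFactors = FALSE)
    }
  }
  list(within = if (length(within)) do.call(rbind, within),
       between = if (length(between)) do.call(rbind, between))
}
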