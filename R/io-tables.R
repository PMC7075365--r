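#' Read a phenotype table
#'
#' Reads a delimited text file with a header naming at least `accession` and
#' `season` plus one column per trait (typically `MLL` and `MLW`, in cm).
#' Field separator is auto-detected (tab or comma) unless given. Empty trait
#' cells become `NA`; a non-numeric trait cell or a duplicated
#' (accession, season) pair is an error.
#'
#' @param path delimited text file
#' @param sep field separator; `NULL` (default) auto-detects `\t` vs `,`
#' @return data.frame with columns `accession`, `season`, and numeric trait
#'   columns
#' @export
read_phenotypes <- function(path, sep = NULL) {
  if (is.null(sep)) {
    l1 <- readLines(path, n = 1L)
    sep <- if (grepl("\t", l1)) "\t" else ","
  }
  tb <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(tb) <- trimws(names(tb))
  lower <- tolower(names(tb))
  for (req in c("accession", "season")) {
    j <- match(req, lower)
    if (is.na(j)) stop("phenotype table lacks a '", req, "' column")
    names(tb)[j] <- req
  }
  traits <- setdiff(names(tb), c("accession", "season"))
  if (!length(traits)) stop("phenotype table has no trait columns")
  key <- paste(tb$accession, tb$season, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicated (accession, season) pair: ",
         gsub("\r", ", ", d, fixed = TRUE))
  }
  for (tr in traits) {
    raw <- tb[[tr]]
    blank <- is.na(raw) | raw == "" | raw == "NA"
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(val))
    if (length(bad))
      stop("non-numeric value '", raw[bad[1L]], "' for trait ", tr,
           " in row ", bad[1L], " (accession ", tb$accession[bad[1L]], ")")
    tb[[tr]] <- val
  }
  tb
}

#' PHYLIP square distance matrix IO
#'
#' `write_square_matrix()` writes the PHYLIP square dialect: a count line,
#' then one row per label followed by all n values. Labels containing
#' whitespace are rejected (documented rule; the dialect is
#' whitespace-delimited). Values are written at full precision so a
#' write/read cycle is an identity well beyond 10 significant digits.
#' `read_square_matrix()` validates symmetry and the zero diagonal on read.
#'
#' @param m a [square_matrix] (or plain symmetric matrix with labels)
#' @param path file path
#' @param tol symmetry / zero-diagonal tolerance applied on read
#' @return `write_square_matrix()` returns `path` invisibly;
#'   `read_square_matrix()` returns a [square_matrix].
#' @export
write_square_matrix <- function(m, path) {
  m <- square_matrix(unclass(m))
  labels <- rownames(m)
  if (any(grepl("[[:space:]]", labels)))
    stop("labels containing whitespace cannot be written to PHYLIP format")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(labels[i], sprintf("%.17g", m[i, ])), collapse = " "), "")
  writeLines(c(as.character(nrow(m)), rows), path)
  invisible(path)
}

#' @rdname write_square_matrix
#' @export
read_square_matrix <- function(path, tol = 1e-8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("first line must be the matrix dimension")
  if (length(lines) != n + 1L)
    stop("expected ", n, " matrix rows, found ", length(lines) - 1L)
  labels <- character(n)
  vals <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    if (length(tok) != n + 1L)
      stop("row ", i, " has ", length(tok) - 1L, " values, expected ", n)
    labels[i] <- tok[1L]
    vals[i, ] <- as.numeric(tok[-1L])
  }
  if (anyNA(vals)) stop("non-numeric matrix entry")
  tryCatch(square_matrix(vals, labels, tol = tol),
           error = function(e) stop("invalid distance matrix in ", path,
                                    ": ", conditionMessage(e), call. = FALSE))
}

#' Newick tree IO
#'
#' Thin wrappers over `ape::write.tree()` / `ape::read.tree()` that add a
#' parenthesis-balance pre-check (reporting the first offending character
#' position) and guarantee an error, not `NULL`, on malformed input.
#'
#' @param tree an `ape` `phylo` object
#' @param path file path
#' @return `write_newick()` returns `path` invisibly; `read_newick()` a
#'   `phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("unbalanced ')' at character ", i, " of Newick input")
  }
  if (depth != 0L)
    stop("unbalanced '(' in Newick input: ", depth,
         " unclosed at end of text (length ", length(chars), ")")
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("failed to parse Newick tree in ", path)
  tr
}
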