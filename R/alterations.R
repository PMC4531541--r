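#' Construct a binary alteration matrix
#'
#' The central data structure: an m x n binary matrix \code{A = [a_ij]} with
#' \code{a_ij = 1} iff alteration i occurs in sample j. Rows are alterations
#' (somatic mutations, copy-number events, fusions, splice events, or subtype
#' indicator rows), columns are samples. Samples with zero alterations are
#' retained: they populate the empty cell of contingency tables and contribute
#' to the sample count n that the exclusivity test conditions on.
#'
#' @param entries numeric/integer/logical matrix of 0/1 entries with unique
#'   rownames (alteration names) and unique colnames (sample names).
#' @param is_subtype logical vector of length m flagging subtype indicator
#'   rows; recycled from FALSE if omitted.
#' @return An object of class \code{alteration_matrix}: a list with elements
#'   \code{mat} (integer matrix) and \code{is_subtype} (named logical vector).
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("G1", "G2"), c("s1", "s2")))
#' A <- alteration_matrix(m)
#' alteration_frequencies(A)
#' @export
alteration_matrix <- function(entries, is_subtype = NULL) {
  if (!is.matrix(entries)) stop("'entries' must be a matrix")
  mode(entries) <- "integer"
  if (nrow(entries) < 1L || ncol(entries) < 1L)
    stop("alteration matrix must have at least one row and one column")
  if (is.null(rownames(entries)) || is.null(colnames(entries)))
    stop("alteration matrix requires row (alteration) and column (sample) names")
  if (anyDuplicated(rownames(entries)))
    stop("duplicate alteration names: ",
         paste(unique(rownames(entries)[duplicated(rownames(entries))]),
               collapse = ", "))
  if (anyDuplicated(colnames(entries)))
    stop("duplicate sample names: ",
         paste(unique(colnames(entries)[duplicated(colnames(entries))]),
               collapse = ", "))
  if (anyNA(entries) || !all(entries == 0L | entries == 1L))
    stop("alteration matrix entries must all be 0 or 1")
  if (is.null(is_subtype)) {
    is_subtype <- rep(FALSE, nrow(entries))
  } else {
    stopifnot(is.logical(is_subtype), length(is_subtype) == nrow(entries))
  }
  names(is_subtype) <- rownames(entries)
  structure(list(mat = entries, is_subtype = is_subtype),
            class = "alteration_matrix")
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf("alteration_matrix: %d alterations x %d samples (%d subtype rows, %d ones)\n",
              nrow(x$mat), ncol(x$mat), sum(x$is_subtype), sum(x$mat)))
  invisible(x)
}

#' @export
dim.alteration_matrix <- function(x) dim(x$mat)

#' Alteration names and sample names
#' @param A an \code{alteration_matrix}.
#' @return character vector.
#' @export
alteration_names <- function(A) rownames(A$mat)

#' @rdname alteration_names
#' @export
sample_names <- function(A) colnames(A$mat)

#' Per-alteration frequency (fraction of altered samples)
#' @param A an \code{alteration_matrix}.
#' @return named numeric vector of length m.
#' @export
alteration_frequencies <- function(A) rowSums(A$mat) / ncol(A$mat)

.strip_comments <- function(lines) lines[!startsWith(lines, "#") & nzchar(lines)]

#' Read an alteration matrix from TSV
#'
#' Two dialects are supported. \code{"matrix"}: a header row of sample names
#' followed by one row per alteration (name, then 0/1 entries). The canonical
#' interchange dialect \code{"sample_list"}: one line per sample with the
#' sample name, a TAB, and a comma-separated list of the alterations observed
#' in that sample (the list may be empty for unaltered samples). In both
#' dialects lines starting with '#' are ignored.
#'
#' @param path path to a UTF-8 tab-delimited file.
#' @param format one of \code{"matrix"}, \code{"sample_list"}.
#' @return an \code{\link{alteration_matrix}}.
#' @export
read_alteration_matrix <- function(path, format = c("sample_list", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- .strip_comments(readLines(path, encoding = "UTF-8"))
  if (length(lines) < 1L) stop("empty input file: ", path)
  if (format == "matrix") {
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    samples <- header[-1L]
    if (length(samples) < 1L) stop("parse error at line 1: no sample columns")
    rows <- lapply(seq_along(lines[-1L]), function(i) {
      f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
      if (length(f) != length(samples) + 1L)
        stop(sprintf("parse error at line %d: expected %d fields, got %d",
                     i + 1L, length(samples) + 1L, length(f)))
      vals <- suppressWarnings(as.integer(f[-1L]))
      if (anyNA(vals) || !all(vals %in% c(0L, 1L)))
        stop(sprintf("non-binary entry at line %d", i + 1L))
      vals
    })
    entries <- do.call(rbind, rows)
    rownames(entries) <- vapply(strsplit(lines[-1L], "\t", fixed = TRUE),
                                `[`, "", 1L)
    colnames(entries) <- samples
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) > 2L | lengths(fields) < 1L)
    if (length(bad))
      stop(sprintf("parse error at line %d: expected 'sample<TAB>alt1,alt2,...'",
                   bad[1L]))
    samples <- vapply(fields, `[`, "", 1L)
    alts <- lapply(fields, function(f) {
      if (length(f) < 2L || !nzchar(f[2L])) character(0)
      else strsplit(f[2L], ",", fixed = TRUE)[[1L]]
    })
    universe <- sort(unique(unlist(alts)))
    if (length(universe) == 0L) stop("no alterations listed in ", path)
    entries <- matrix(0L, length(universe), length(samples),
                      dimnames = list(universe, samples))
    for (j in seq_along(samples)) entries[alts[[j]], j] <- 1L
  }
  alteration_matrix(entries)
}

#' Write an alteration matrix to TSV
#'
#' Round-trips bit-exactly with \code{\link{read_alteration_matrix}} for both
#' dialects (for \code{"sample_list"}, up to row order, which is normalized to
#' alphabetical by the reader).
#'
#' @param A an \code{alteration_matrix}.
#' @param path output path.
#' @param format output dialect, see \code{\link{read_alteration_matrix}}.
#' @export
write_alteration_matrix <- function(A, path, format = c("sample_list", "matrix")) {
  format <- match.arg(format)
  if (format == "matrix") {
    lines <- c(paste(c("gene", colnames(A$mat)), collapse = "\t"),
               vapply(seq_len(nrow(A$mat)), function(i)
                 paste(c(rownames(A$mat)[i], A$mat[i, ]), collapse = "\t"), ""))
  } else {
    lines <- vapply(seq_len(ncol(A$mat)), function(j) {
      alt <- rownames(A$mat)[A$mat[, j] == 1L]
      paste0(colnames(A$mat)[j], "\t", paste(alt, collapse = ","))
    }, "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a sample-to-subtype map
#'
#' Two-column TSV: sample name, TAB, subtype name. Samples may be unassigned
#' (absent from the file); each sample maps to at most one subtype.
#'
#' @param path path to the TSV file.
#' @return named character vector (names are sample names, values subtypes).
#' @export
read_subtype_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- .strip_comments(readLines(path, encoding = "UTF-8"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected 'sample<TAB>subtype'", bad[1L]))
  s <- vapply(fields, `[`, "", 2L)
  names(s) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(s)))
    stop("sample assigned to more than one subtype: ",
         paste(unique(names(s)[duplicated(names(s))]), collapse = ", "))
  s
}

#' Filter alterations by frequency
#'
#' Keeps the non-subtype rows whose alteration frequency f (fraction of
#' altered samples) satisfies \code{min_freq <= f} and, when \code{max_freq}
#' is given, \code{f <= max_freq}. Subtype rows are always kept and the sample
#' set is unchanged. Idempotent at fixed thresholds.
#'
#' @param A an \code{alteration_matrix}.
#' @param min_freq minimum frequency in [0, 1]. A typical choice for large
#'   gene backgrounds is 0.01, removing genes mutated in fewer than 1\% of
#'   samples.
#' @param max_freq optional maximum frequency in (0, 1].
#' @return the filtered \code{alteration_matrix}.
#' @export
filter_alterations <- function(A, min_freq = 0, max_freq = NULL) {
  stopifnot(min_freq >= 0, min_freq <= 1)
  f <- alteration_frequencies(A)
  keep <- f >= min_freq
  if (!is.null(max_freq)) {
    stopifnot(max_freq > 0, max_freq <= 1)
    keep <- keep & f <= max_freq
  }
  keep <- keep | A$is_subtype
  if (!any(keep)) stop("frequency filter removed every alteration")
  alteration_matrix(A$mat[keep, , drop = FALSE], A$is_subtype[keep])
}

#' Append subtype indicator rows
#'
#' For each distinct subtype S in the map, appends one row named after S that
#' is altered in exactly the samples NOT assigned to S. An alteration that is
#' mutually exclusive with such a row is therefore one whose occurrences are
#' concentrated inside the subtype, so subtype-enriched alterations can be
#' detected by the same exclusivity machinery as pathway alterations.
#' Subtypes covering zero samples or all samples are rejected: their rows
#' would be constant and carry no exclusivity information.
#'
#' @param A an \code{alteration_matrix}.
#' @param subtypes named character vector as from \code{\link{read_subtype_map}};
#'   every name must be a sample of \code{A}.
#' @return an \code{alteration_matrix} with the original rows followed by one
#'   flagged subtype row per subtype.
#' @export
add_subtype_rows <- function(A, subtypes) {
  if (length(subtypes) == 0L) stop("empty subtype map")
  unknown <- setdiff(names(subtypes), sample_names(A))
  if (length(unknown))
    stop("subtype map contains unknown samples: ", paste(unknown, collapse = ", "))
  subs <- unique(subtypes)
  clash <- intersect(subs, alteration_names(A))
  if (length(clash))
    stop("subtype names collide with alteration names: ",
         paste(clash, collapse = ", "))
  n <- ncol(A$mat)
  rows <- matrix(0L, length(subs), n, dimnames = list(subs, colnames(A$mat)))
  for (s in subs) {
    members <- names(subtypes)[subtypes == s]
    if (length(members) == 0L || length(members) == n)
      stop("subtype '", s, "' covers ", length(members),
           " of ", n, " samples; constant subtype rows are not allowed")
    rows[s, !(colnames(A$mat) %in% members)] <- 1L
  }
  alteration_matrix(rbind(A$mat, rows),
                    c(A$is_subtype, stats::setNames(rep(TRUE, length(subs)), subs)))
}
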