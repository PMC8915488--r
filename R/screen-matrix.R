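#' Construct a screen matrix
#'
#' The central container of the pipeline: a numeric genes-by-screens matrix
#' (rows are deletion strains, named by gene; columns are screens) carrying
#' two pieces of provenance that every transform must respect: what the
#' values are (`value_kind`) and which sign means "sensitive"
#' (`orientation`). The HIPLAB convention scores sensitivity as positive
#' (log2 control/treatment); the NIBR convention is the rough negative of it.
#'
#' @param values Numeric matrix with unique row and column names. `NA`
#'   encodes missing strains/measurements; infinite values are rejected.
#' @param value_kind One of `"raw_log2ratio"`, `"fd"`, `"madl"`, `"a_madl"`,
#'   `"z"`.
#' @param orientation `"sensitivity_positive"` (large positive = sensitive)
#'   or `"sensitivity_negative"`.
#'
#' @return A `screen_matrix` object.
#' @export
#' @examples
#' m <- screen_matrix(matrix(rnorm(6), 3, 2,
#'                    dimnames = list(c("G1", "G2", "G3"), c("s1", "s2"))),
#'                    value_kind = "fd")
#' orientation(m)
screen_matrix <- function(values,
                          value_kind = c("raw_log2ratio", "fd", "madl",
                                         "a_madl", "z"),
                          orientation = c("sensitivity_positive",
                                          "sensitivity_negative")) {
  value_kind <- match.arg(value_kind)
  orientation <- match.arg(orientation)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  rn <- rownames(values)
  cn <- colnames(values)
  if ((is.null(rn) && nrow(values) > 0L) ||
      (is.null(cn) && ncol(values) > 0L)) {
    abort("`values` must have row (strain) and column (screen) names.")
  }
  if (anyDuplicated(rn)) {
    abort(sprintf("Duplicated strain id(s): %s",
                  paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  }
  if (anyDuplicated(cn)) {
    abort(sprintf("Duplicated screen id(s): %s",
                  paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  }
  if (any(is.infinite(values))) {
    abort("`values` must not contain infinite entries.")
  }
  structure(values, value_kind = value_kind, orientation = orientation,
            class = c("screen_matrix", "matrix", "array"))
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("<screen_matrix> %d strains x %d screens [%s, %s]\n",
              nrow(x), ncol(x), value_kind(x), orientation(x)))
  cat(sprintf("  missing: %d of %d entries\n", sum(is.na(x)), length(x)))
  invisible(x)
}

#' Query the value kind or orientation of a screen matrix
#' @param x A `screen_matrix`.
#' @return A string.
#' @export
value_kind <- function(x) attr(x, "value_kind")

#' @rdname value_kind
#' @export
orientation <- function(x) attr(x, "orientation")

# rebuild a screen_matrix from plain values, keeping/overriding provenance
restamp <- function(values, template, value_kind = NULL, orientation = NULL) {
  screen_matrix(values,
                value_kind = value_kind %||% value_kind(template),
                orientation = orientation %||% orientation(template))
}

# drop the class and attributes, returning a plain numeric matrix
as_plain_matrix <- function(x) {
  matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
}

#' @exportS3Method tibble::as_tibble
as_tibble.screen_matrix <- function(x, ...) {
  tibble(strain_id = rownames(x)[row(x)],
         screen_id = colnames(x)[col(x)],
         value = as.numeric(x))
}

#' Read / write a screen matrix as tab-delimited text
#'
#' The on-disk format is a plain TSV: one header row of screen ids, first
#' column of strain ids, `.` decimal point, and missing values written as
#' empty cells (empty or `"NA"` accepted on read).
#'
#' @param path File path.
#' @param value_kind,orientation Provenance stamped on the matrix read; see
#'   [screen_matrix()].
#' @return `read_matrix()` returns a `screen_matrix`; `write_matrix()`
#'   returns `path` invisibly.
#' @export
read_matrix <- function(path,
                        value_kind = "fd",
                        orientation = "sensitivity_positive") {
  lines <- readLines(path)
  if (length(lines) == 0L) abort(sprintf("'%s' is empty.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  col_ids <- header[-1L]
  body <- fields[-1L]
  row_ids <- vapply(body, function(f) f[[1L]], character(1))
  n_col <- length(col_ids)
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col,
                 dimnames = list(row_ids, col_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    length(cells) <- n_col  # right-pad short lines (trailing empties)
    cells[is.na(cells) | cells == "" | cells == "NA"] <- NA_character_
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(!is.na(cells) & is.na(num))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric cell '%s' at strain '%s', screen '%s' in '%s'.",
        cells[bad[1L]], row_ids[i], col_ids[bad[1L]], path))
    }
    vals[i, ] <- num
  }
  screen_matrix(vals, value_kind = value_kind, orientation = orientation)
}

#' @rdname read_matrix
#' @param x A `screen_matrix` to write.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "screen_matrix") || is.matrix(x))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) abort(sprintf(
                    "Cannot open '%s' for writing: %s", path,
                    conditionMessage(e))))
  on.exit(close(con))
  writeLines(paste(c("strain_id", colnames(x)), collapse = "\t"), con)
  if (nrow(x) > 0L) {
    cells <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
    cells[is.na(x)] <- ""
    writeLines(paste(rownames(x), apply(cells, 1L, paste, collapse = "\t"),
                     sep = if (ncol(x) > 0L) "\t" else ""), con)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated, with set name, description,
#' then member genes. Duplicate genes within a line are collapsed.
#'
#' @param path File path.
#' @return A named list of unique character vectors of genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", short[1L]))
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    abort(sprintf("Duplicated gene-set name(s): %s",
                  paste(unique(names_[duplicated(names_)]), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Flip a matrix to the sensitivity-positive convention
#'
#' Scores in the NIBR convention are roughly the negative of the HIPLAB
#' fitness defect; harmonization multiplies a sensitivity-negative matrix by
#' -1 and flips the flag. Idempotent on sensitivity-positive input.
#'
#' @param x A `screen_matrix`.
#' @return A `screen_matrix` in `sensitivity_positive` orientation.
#' @export
harmonize_orientation <- function(x) {
  stopifnot(inherits(x, "screen_matrix"))
  if (orientation(x) == "sensitivity_positive") return(x)
  restamp(-as_plain_matrix(x), x, orientation = "sensitivity_positive")
}
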