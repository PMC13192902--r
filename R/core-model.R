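#' Construct an annotated matrix
#'
#' An `AnnotatedMatrix` bundles one or more `n x p` assay matrices with a
#' feature (row) metadata table of `n` records and a sample (column)
#' metadata table of `p` records. Features live on rows and samples on
#' columns throughout the package. The three components form three separate
#' namespaces -- the *assays*, *rows* and *cols* evaluation contexts -- so a
#' name may legally recur across contexts but not within one.
#'
#' @param assays named list of numeric, integer or logical matrices, all of
#'   identical shape `n x p`. May be empty if `dim` is supplied.
#' @param row_data data.frame (or named list of vectors) with `n` records of
#'   feature metadata. Defaults to an empty table of the right length.
#' @param col_data data.frame (or named list of vectors) with `p` records of
#'   sample metadata.
#' @param row_names,col_names optional unique identifier strings for the two
#'   axes.
#' @param dim optional `c(n, p)`; required only when it cannot be inferred
#'   from `assays`, `row_data`/`col_data`, or the names.
#' @return a validated `AnnotatedMatrix` with empty grouping state.
#' @examples
#' am <- annotated_matrix(
#'   assays   = list(counts = matrix(1:6, 3, 2)),
#'   row_data = data.frame(length = c(100L, 5000L, 200L)),
#'   col_data = data.frame(condition = c("trt", "untrt"))
#' )
#' dim(am)
#' @export
annotated_matrix <- function(assays = list(), row_data = NULL, col_data = NULL,
                             row_names = NULL, col_names = NULL, dim = NULL) {
  if (!is.list(assays)) stop("`assays` must be a named list of matrices")
  assays <- lapply(assays, function(m) {
    if (is.vector(m) && !is.list(m)) m <- matrix(m, nrow = length(m))
    m
  })

  shape <- NULL
  if (length(assays)) {
    shape <- base::dim(assays[[1L]])
  } else if (!is.null(dim)) {
    shape <- as.integer(dim)
  } else {
    n <- if (!is.null(row_data)) nrec(row_data) else if (!is.null(row_names)) length(row_names) else 0L
    p <- if (!is.null(col_data)) nrec(col_data) else if (!is.null(col_names)) length(col_names) else 0L
    shape <- c(n, p)
  }
  n <- as.integer(shape[1L]); p <- as.integer(shape[2L])

  row_data <- as_meta_table(row_data, n, "row_data")
  col_data <- as_meta_table(col_data, p, "col_data")

  obj <- structure(
    list(
      assays = assays,
      row_data = row_data,
      col_data = col_data,
      row_names = if (is.null(row_names)) NULL else as.character(row_names),
      col_names = if (is.null(col_names)) NULL else as.character(col_names),
      row_grouping = NULL,
      col_grouping = NULL,
      dim = c(n, p)
    ),
    class = "AnnotatedMatrix"
  )
  amx_validate(obj)
}

# normalize a metadata argument to a data.frame of exactly `len` records
as_meta_table <- function(x, len, what) {
  if (is.null(x)) {
    return(structure(list(), class = "data.frame",
                     row.names = if (len) seq_len(len) else integer()))
  }
  if (!is.data.frame(x)) {
    if (!is.list(x)) stop("`", what, "` must be a data.frame or named list")
    lens <- lengths(x)
    if (length(lens) && !all(lens == len))
      stop(what, " length mismatch: columns have ", paste(unique(lens), collapse = "/"),
           " records, expected ", len)
    x <- structure(as.list(x), class = "data.frame",
                   row.names = if (len) seq_len(len) else integer())
  }
  x
}

nrec <- function(x) if (is.data.frame(x)) nrow(x) else if (length(x)) length(x[[1L]]) else 0L

#' Validate an annotated matrix
#'
#' Checks every structural invariant of the container and either returns the
#' object unchanged or stops with one diagnostic per violation, naming the
#' offending component.
#'
#' @param obj an `AnnotatedMatrix`.
#' @return `obj`, invisibly unchanged, if valid.
#' @export
amx_validate <- function(obj) {
  if (!inherits(obj, "AnnotatedMatrix")) stop("not an AnnotatedMatrix")
  errs <- character()
  n <- obj$dim[1L]; p <- obj$dim[2L]

  anames <- names(obj$assays)
  if (length(obj$assays)) {
    if (is.null(anames) || any(!nzchar(anames)))
      errs <- c(errs, "assay names must be non-empty")
    if (anyDuplicated(anames))
      errs <- c(errs, sprintf("duplicate name in assays context: %s",
                              paste(unique(anames[duplicated(anames)]), collapse = ", ")))
    for (i in seq_along(obj$assays)) {
      m <- obj$assays[[i]]
      if (!is.matrix(m) || !(is.numeric(m) || is.logical(m))) {
        errs <- c(errs, sprintf("assay '%s' is not a numeric/logical matrix", anames[i]))
      } else if (!identical(base::dim(m), c(n, p)) &&
                 !identical(as.integer(base::dim(m)), c(n, p))) {
        errs <- c(errs, sprintf("assay '%s' has shape %dx%d, expected %dx%d",
                                anames[i], nrow(m), ncol(m), n, p))
      }
    }
  }

  if (nrow(obj$row_data) != n)
    errs <- c(errs, sprintf("row_data length mismatch: %d records, expected %d",
                            nrow(obj$row_data), n))
  if (nrow(obj$col_data) != p)
    errs <- c(errs, sprintf("col_data length mismatch: %d records, expected %d",
                            nrow(obj$col_data), p))
  for (tb in c("row_data", "col_data")) {
    nm <- names(obj[[tb]])
    if (anyDuplicated(nm))
      errs <- c(errs, sprintf("duplicate name in %s context: %s",
                              if (tb == "row_data") "rows" else "cols",
                              paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }

  if (!is.null(obj$row_names)) {
    if (length(obj$row_names) != n)
      errs <- c(errs, "row_names length mismatch")
    if (anyDuplicated(obj$row_names))
      errs <- c(errs, "row_names are not unique")
  }
  if (!is.null(obj$col_names)) {
    if (length(obj$col_names) != p)
      errs <- c(errs, "col_names length mismatch")
    if (anyDuplicated(obj$col_names))
      errs <- c(errs, "col_names are not unique")
  }

  for (ax in c("row", "col")) {
    gs <- obj[[paste0(ax, "_grouping")]]
    if (is.null(gs)) next
    tbl <- obj[[paste0(ax, "_data")]]
    missing_vars <- setdiff(gs$variables, names(tbl))
    if (length(missing_vars))
      errs <- c(errs, sprintf("%s grouping variable(s) not in %s_data: %s",
                              ax, ax, paste(missing_vars, collapse = ", ")))
    idx <- sort(unlist(gs$partition, use.names = FALSE))
    len <- if (ax == "row") n else p
    if (!identical(as.integer(idx), seq_len(len)))
      errs <- c(errs, sprintf("%s grouping partition is not exhaustive/disjoint", ax))
  }

  if (length(errs)) stop(paste(errs, collapse = "\n  "), call. = FALSE)
  obj
}

#' @export
dim.AnnotatedMatrix <- function(x) x$dim

#' @export
dimnames.AnnotatedMatrix <- function(x) list(x$row_names, x$col_names)

#' List assay, row-variable, or column-variable names
#'
#' @param obj an `AnnotatedMatrix`.
#' @param context one of `"assays"`, `"rows"`, `"cols"`.
#' @return character vector of the names owned by that context.
#' @export
context_names <- function(obj, context = c("assays", "rows", "cols")) {
  context <- match.arg(context)
  switch(context,
         assays = names(obj$assays) %||% character(),
         rows   = names(obj$row_data),
         cols   = names(obj$col_data))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.AnnotatedMatrix <- function(x, ...) {
  cat(sprintf("<AnnotatedMatrix> %d features x %d samples\n", x$dim[1L], x$dim[2L]))
  cat("assays:  ", paste(context_names(x, "assays"), collapse = ", "), "\n")
  cat("row_data:", paste(names(x$row_data), collapse = ", "), "\n")
  cat("col_data:", paste(names(x$col_data), collapse = ", "), "\n")
  if (!is.null(x$row_grouping))
    cat("rows grouped by:", paste(x$row_grouping$variables, collapse = ", "),
        sprintf("[%d groups]\n", length(x$row_grouping$partition)))
  if (!is.null(x$col_grouping))
    cat("cols grouped by:", paste(x$col_grouping$variables, collapse = ", "),
        sprintf("[%d groups]\n", length(x$col_grouping$partition)))
  invisible(x)
}

# subset both axes; recomputes grouping partitions on the survivors
amx_subset <- function(obj, rows = NULL, cols = NULL) {
  n <- obj$dim[1L]; p <- obj$dim[2L]
  ri <- if (is.null(rows)) seq_len(n) else as.integer(rows)
  ci <- if (is.null(cols)) seq_len(p) else as.integer(cols)
  obj$assays <- lapply(obj$assays, function(m) m[ri, ci, drop = FALSE])
  obj$row_data <- obj$row_data[ri, , drop = FALSE]
  attr(obj$row_data, "row.names") <- if (length(ri)) seq_along(ri) else integer()
  obj$col_data <- obj$col_data[ci, , drop = FALSE]
  attr(obj$col_data, "row.names") <- if (length(ci)) seq_along(ci) else integer()
  if (!is.null(obj$row_names)) obj$row_names <- obj$row_names[ri]
  if (!is.null(obj$col_names)) obj$col_names <- obj$col_names[ci]
  obj$dim <- c(length(ri), length(ci))
  if (!is.null(obj$row_grouping))
    obj$row_grouping <- grouping_spec("rows", obj$row_grouping$variables, obj$row_data)
  if (!is.null(obj$col_grouping))
    obj$col_grouping <- grouping_spec("cols", obj$col_grouping$variables, obj$col_data)
  obj
}

# data-field equality (grouping state ignored), NaN-aware, with tolerance
amx_equal <- function(a, b, tol = 1e-12) {
  if (!identical(sort(names(a$assays) %||% character()),
                 sort(names(b$assays) %||% character()))) return(FALSE)
  if (!identical(as.integer(a$dim), as.integer(b$dim))) return(FALSE)
  for (nm in names(a$assays))
    if (!values_equal(a$assays[[nm]], b$assays[[nm]], tol)) return(FALSE)
  for (tb in c("row_data", "col_data")) {
    if (!identical(sort(names(a[[tb]])), sort(names(b[[tb]])))) return(FALSE)
    for (nm in names(a[[tb]]))
      if (!values_equal(a[[tb]][[nm]], b[[tb]][[nm]], tol)) return(FALSE)
  }
  identical(a$row_names, b$row_names) && identical(a$col_names, b$col_names)
}

values_equal <- function(x, y, tol = 1e-12) {
  if (length(x) != length(y)) return(FALSE)
  if (is.numeric(x) && is.numeric(y)) {
    x <- as.double(x); y <- as.double(y)
    same_special <- identical(is.na(x), is.na(y)) &&
      identical(is.nan(x), is.nan(y)) &&
      identical(x == Inf & !is.na(x), y == Inf & !is.na(y)) &&
      identical(x == -Inf & !is.na(x), y == -Inf & !is.na(y))
    if (!same_special) return(FALSE)
    fin <- is.finite(x)
    if (!any(fin)) return(TRUE)
    d <- abs(x[fin] - y[fin])
    s <- pmax(abs(x[fin]), abs(y[fin]), 1)
    all(d <= tol * s)
  } else {
    identical(is.na(x), is.na(y)) &&
      all(as.character(x) == as.character(y), na.rm = TRUE)
  }
}
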