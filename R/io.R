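## On-disk bundle: a directory with a JSON manifest, one Matrix Market or
## dense CSV file per assay, and TSV row/col metadata tables. Everything is
## plain text; floats are written with 17 significant digits so the round
## trip is exact.

BUNDLE_VERSION <- "1.0"

fmt_num <- function(v) {
  out <- sprintf("%.17g", v)
  out[is.na(v) & !is.nan(v)] <- "NA"
  out
}

## ---- Matrix Market ------------------------------------------------------

#' Read / write a single matrix in Matrix Market format
#'
#' Writes `coordinate` layout for sparse content (more than half zeros) and
#' `array` layout otherwise; the field is `integer` for integer matrices and
#' `real` otherwise. Readers accept `coordinate` and `array`, `real` and
#' `integer`. Indices are 1-based as in the standard. Non-finite values
#' (`NaN`, `Inf`) and `NA` are written literally and restored on read; this
#' is a documented extension over the strict standard.
#'
#' @param m a numeric/integer matrix.
#' @param path file path (`.mtx`).
#' @param layout `"auto"`, `"coordinate"` or `"array"`.
#' @export
write_mtx <- function(m, path, layout = c("auto", "coordinate", "array")) {
  layout <- match.arg(layout)
  n <- nrow(m); p <- ncol(m)
  if (layout == "auto") {
    nz <- sum(m == 0, na.rm = TRUE)
    layout <- if (length(m) > 0L && nz > length(m) / 2) "coordinate" else "array"
  }
  field <- if (is.integer(m)) "integer" else "real"
  fmt1 <- if (field == "integer") function(v) {
    s <- as.character(v); s[is.na(v)] <- "NA"; s
  } else fmt_num
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%%%%MatrixMarket matrix %s %s general", layout, field), con)
  if (layout == "array") {
    writeLines(sprintf("%d %d", n, p), con)
    if (length(m)) writeLines(fmt1(as.vector(m)), con)
  } else {
    keep <- which(is.na(m) | m != 0)
    i <- ((keep - 1L) %% max(n, 1L)) + 1L
    j <- ((keep - 1L) %/% max(n, 1L)) + 1L
    writeLines(sprintf("%d %d %d", n, p, length(keep)), con)
    if (length(keep))
      writeLines(paste(i, j, fmt1(m[keep])), con)
  }
  invisible(path)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || !grepl("^%%MatrixMarket", lines[1L]))
    stop("malformed MTX header in ", path)
  hd <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hd) < 5L || hd[2L] != "matrix")
    stop("malformed MTX header in ", path)
  layout <- hd[3L]; field <- hd[4L]
  if (!layout %in% c("coordinate", "array"))
    stop("unsupported MTX layout '", layout, "' in ", path)
  if (!field %in% c("real", "integer"))
    stop("unsupported MTX field '", field, "' in ", path)
  body_at <- which(!startsWith(lines, "%"))
  body_at <- body_at[body_at > 1L]
  if (!length(body_at)) stop("truncated MTX file ", path, ": no size line")
  size_ln <- body_at[1L]
  size <- suppressWarnings(as.integer(strsplit(trimws(lines[size_ln]), "\\s+")[[1L]]))
  data_lns <- body_at[-1L]
  parse_num <- function(s) suppressWarnings(as.numeric(s))
  if (layout == "array") {
    if (length(size) < 2L || any(is.na(size[1:2])))
      stop("malformed MTX size line in ", path, " at line ", size_ln)
    n <- size[1L]; p <- size[2L]
    raw <- trimws(lines[data_lns])
    raw <- raw[nzchar(raw)]
    if (length(raw) != n * p)
      stop("truncated MTX file ", path, ": expected ", n * p,
           " values, found ", length(raw), " (near line ", size_ln + length(raw), ")")
    vals <- parse_num(raw)
    vals[raw == "NaN"] <- NaN
    m <- matrix(vals, n, p)
  } else {
    if (length(size) < 3L || any(is.na(size)))
      stop("malformed MTX size line in ", path, " at line ", size_ln)
    n <- size[1L]; p <- size[2L]; nnz <- size[3L]
    raw <- trimws(lines[data_lns]); raw <- raw[nzchar(raw)]
    if (length(raw) != nnz)
      stop("truncated MTX file ", path, ": expected ", nnz, " entries, found ",
           length(raw), " (near line ", size_ln + length(raw), ")")
    m <- matrix(0, n, p)
    if (nnz > 0L) {
      parts <- strsplit(raw, "\\s+")
      ijv <- do.call(rbind, parts)
      i <- as.integer(ijv[, 1L]); j <- as.integer(ijv[, 2L])
      if (any(is.na(i)) || any(is.na(j)) || any(i < 1L) || any(i > n) ||
          any(j < 1L) || any(j > p))
        stop("malformed MTX entry in ", path, " near line ", size_ln + 1L)
      v <- parse_num(ijv[, 3L])
      v[ijv[, 3L] == "NaN"] <- NaN
      m[cbind(i, j)] <- v
    }
  }
  if (field == "integer" && !anyNA(m) && all(is.finite(m))) storage.mode(m) <- "integer"
  m
}

## ---- metadata TSV -------------------------------------------------------

write_meta_tsv <- function(df, path, axis_names = NULL, name_col = "name") {
  out <- list()
  if (!is.null(axis_names)) out[[name_col]] <- axis_names
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.factor(v)) v <- as.character(v)
    if (is.list(v)) stop("unserializable metadata column type: '", nm, "' is a list")
    s <- if (is.double(v)) fmt_num(v) else as.character(v)
    s[is.na(v)] <- "NA"
    if (any(grepl("[\t\n\r]", s[!is.na(v)])))
      stop("unserializable metadata value in column '", nm,
           "': embedded tab/newline")
    out[[nm]] <- s
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(out)) {  # zero-column tables leave an empty file; the record
    writeLines(paste(names(out), collapse = "\t"), con)  # count lives in the
    len <- length(out[[1L]])                             # manifest
    if (len) writeLines(do.call(paste, c(out, sep = "\t")), con)
  }
  invisible(path)
}

meta_type <- function(v) {
  if (is.factor(v)) "character"
  else if (is.logical(v)) "logical"
  else if (is.integer(v)) "integer"
  else if (is.double(v)) "double"
  else "character"
}

read_meta_tsv <- function(path, types, has_names, expected_n, name_col = "name") {
  empty <- !file.exists(path) || length(readLines(path, n = 1L)) == 0L
  if (empty) {
    return(list(df = as_meta_table(NULL, expected_n, basename(path)),
                names = NULL))
  }
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          na.strings = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE)
  axis_names <- NULL
  if (has_names) {
    axis_names <- df[[1L]]
    df <- df[-1L]
  }
  out <- list()
  for (nm in names(df)) {
    s <- df[[nm]]
    ty <- types[[nm]] %||% "character"
    out[[nm]] <- switch(ty,
      double = { x <- suppressWarnings(as.numeric(s)); x[s == "NaN"] <- NaN; x },
      integer = suppressWarnings(as.integer(ifelse(s == "NA", NA, s))),
      logical = as.logical(ifelse(s == "NA", NA, s)),
      { x <- s; x[s == "NA"] <- NA; x })
  }
  nrecords <- if (has_names) length(axis_names) else nrow(df)
  list(df = as_meta_table(out, nrecords, basename(path)), names = axis_names)
}

## ---- bundle -------------------------------------------------------------

#' Write / read an annotated-matrix bundle directory
#'
#' A bundle is a directory holding `manifest.json`, one matrix file per
#' assay (Matrix Market or dense CSV), and `row_data.tsv` / `col_data.tsv`
#' metadata tables whose first column carries the axis identifiers when
#' present. Re-reading a bundle reproduces the container exactly: integers
#' and strings bit-for-bit, doubles to full precision (including `NA`,
#' `NaN` and infinities). Grouping state is part of the manifest.
#'
#' @param obj an `AnnotatedMatrix`.
#' @param path bundle directory (created if needed).
#' @param assay_format `"auto"` (Matrix Market for mostly-zero matrices,
#'   CSV otherwise), `"csv"` or `"mtx"`.
#' @return `write_bundle` returns the manifest invisibly; `read_bundle`
#'   returns the container.
#' @export
write_bundle <- function(obj, path, assay_format = c("auto", "csv", "mtx")) {
  assay_format <- match.arg(assay_format)
  amx_validate(obj)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory ", path)
  n <- obj$dim[1L]; p <- obj$dim[2L]

  assays_manifest <- list()
  for (nm in context_names(obj, "assays")) {
    m <- obj$assays[[nm]]
    dtype <- if (is.logical(m)) "logical" else if (is.integer(m)) "integer" else "double"
    fmt <- assay_format
    if (fmt == "auto") {
      nz <- sum(m == 0 | isFALSE(m), na.rm = TRUE)
      fmt <- if (length(m) > 0L && !is.logical(m) && nz > length(m) / 2) "mtx" else "csv"
    }
    safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
    file <- paste0("assay_", safe, ".", if (fmt == "mtx") "mtx" else "csv")
    mm <- m
    if (is.logical(mm)) storage.mode(mm) <- "integer"
    if (fmt == "mtx") {
      write_mtx(mm, file.path(path, file))
    } else {
      con <- file(file.path(path, file), "w", encoding = "UTF-8")
      if (n > 0L && p > 0L) {
        s <- if (is.integer(mm)) {
          x <- as.character(mm); x[is.na(mm)] <- "NA"; x
        } else fmt_num(as.vector(mm))
        sm <- matrix(s, n, p)
        writeLines(apply(sm, 1L, paste, collapse = ","), con)
      }
      close(con)
    }
    assays_manifest[[length(assays_manifest) + 1L]] <-
      list(name = nm, file = file, format = fmt, dtype = dtype)
  }

  write_meta_tsv(obj$row_data, file.path(path, "row_data.tsv"),
                 axis_names = obj$row_names, name_col = "row_name")
  write_meta_tsv(obj$col_data, file.path(path, "col_data.tsv"),
                 axis_names = obj$col_names, name_col = "col_name")

  manifest <- list(
    version = BUNDLE_VERSION,
    shape = c(n, p),
    assays = assays_manifest,
    row_data_file = "row_data.tsv",
    col_data_file = "col_data.tsv",
    row_names_present = !is.null(obj$row_names),
    col_names_present = !is.null(obj$col_names),
    row_data_types = lapply(obj$row_data, meta_type),
    col_data_types = lapply(obj$col_data, meta_type),
    row_grouping = if (!is.null(obj$row_grouping)) obj$row_grouping$variables,
    col_grouping = if (!is.null(obj$col_grouping)) obj$col_grouping$variables)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", path)
  man <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  if (is.null(man$version)) stop("manifest lacks a version field")
  n <- as.integer(man$shape[[1L]]); p <- as.integer(man$shape[[2L]])

  assays <- list()
  for (a in man$assays) {
    f <- file.path(path, a$file)
    if (!file.exists(f)) stop("missing assay file ", a$file, " in bundle ", path)
    m <- if (identical(a$format, "mtx")) {
      read_mtx(f)
    } else {
      lines <- readLines(f, encoding = "UTF-8")
      if (!length(lines)) matrix(numeric(), n, p)
      else {
        rows <- strsplit(lines, ",", fixed = TRUE)
        vals <- unlist(rows, use.names = FALSE)
        x <- suppressWarnings(as.numeric(vals))
        x[vals == "NaN"] <- NaN
        matrix(x, nrow = length(rows), byrow = TRUE)
      }
    }
    if (!identical(base::dim(m), c(n, p)) && !identical(as.integer(base::dim(m)), c(n, p)))
      stop(sprintf("assay '%s' has shape %dx%d but manifest says %dx%d",
                   a$name, nrow(m), ncol(m), n, p))
    dtype <- a$dtype %||% "double"
    storage.mode(m) <- dtype
    assays[[a$name]] <- m
  }

  rtypes <- man$row_data_types; ctypes <- man$col_data_types
  rmeta <- read_meta_tsv(file.path(path, man$row_data_file %||% "row_data.tsv"),
                         rtypes, isTRUE(man$row_names_present), n, "row_name")
  cmeta <- read_meta_tsv(file.path(path, man$col_data_file %||% "col_data.tsv"),
                         ctypes, isTRUE(man$col_names_present), p, "col_name")
  if (nrow(rmeta$df) != n)
    stop(sprintf("manifest says %d rows but row metadata has %d records",
                 n, nrow(rmeta$df)))
  if (nrow(cmeta$df) != p)
    stop(sprintf("manifest says %d cols but col metadata has %d records",
                 p, nrow(cmeta$df)))

  obj <- annotated_matrix(assays = assays, row_data = rmeta$df, col_data = cmeta$df,
                          row_names = rmeta$names, col_names = cmeta$names,
                          dim = c(n, p))
  if (!is.null(man$row_grouping))
    obj$row_grouping <- grouping_spec("rows", unlist(man$row_grouping), obj$row_data)
  if (!is.null(man$col_grouping))
    obj$col_grouping <- grouping_spec("cols", unlist(man$col_grouping), obj$col_data)
  obj
}

## ---- synthetic fixtures -------------------------------------------------

#' Generate a seeded synthetic fixture
#'
#' Emulates a small expression experiment: assay `"counts"` holds
#' overdispersed non-negative integers (negative binomial, mean 100,
#' dispersion size 2); a second assay `"tpm"` holds positive floats; further
#' assays are positive floats named `assay3`, `assay4`, ... Row metadata
#' always includes a positive integer `length` and a categorical `chr`
#' (additional requested variables alternate numeric / categorical); column
#' metadata includes a positive `lib_size` (the column sums of `counts`,
#' floored at 1) and a `condition` cycling over `"trt"` / `"untrt"`. The
#' generator is a pure function of its arguments: the RNG is
#' Mersenne-Twister with inversion normals, and the caller's RNG state is
#' left untouched.
#'
#' @param n,p numbers of features (rows) and samples (cols).
#' @param n_assays number of assays (>= 1).
#' @param n_row_vars,n_col_vars numbers of metadata variables (>= 2 are
#'   always produced; extras alternate numeric/categorical).
#' @param seed integer seed.
#' @param missing_rate fraction of extra metadata values set to `NA`.
#' @param names whether to attach row/col identifier names.
#' @return a validated `AnnotatedMatrix`.
#' @export
generate_fixture <- function(n, p, n_assays = 2, n_row_vars = 2, n_col_vars = 2,
                             seed = 1, missing_rate = 0, names = TRUE) {
  stopifnot(n >= 0, p >= 0, n_assays >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  assays <- list()
  if (n_assays >= 1) {
    cnt <- matrix(stats::rnbinom(n * p, mu = 100, size = 2), n, p)
    storage.mode(cnt) <- "integer"
    assays$counts <- cnt
  }
  if (n_assays >= 2)
    assays$tpm <- matrix(stats::rgamma(n * p, shape = 2, scale = 50), n, p)
  if (n_assays >= 3) {
    for (k in 3:n_assays)
      assays[[paste0("assay", k)]] <-
        matrix(stats::rgamma(n * p, shape = 1.5, scale = 20), n, p)
  }

  sprinkle <- function(v) {
    if (missing_rate > 0 && length(v)) {
      hit <- stats::runif(length(v)) < missing_rate
      v[hit] <- NA
    }
    v
  }
  rd <- list()
  if (n_row_vars >= 1)
    rd$length <- as.integer(round(stats::runif(n, 200, 10000)))
  if (n_row_vars >= 2)
    rd$chr <- sample(paste0("chr", 1:4), n, replace = TRUE)
  if (n_row_vars >= 3) {
    for (k in 3:n_row_vars) {
      nm <- paste0("rvar", k)
      rd[[nm]] <- if (k %% 2 == 1) sprinkle(stats::rnorm(n))
                  else sprinkle(sample(letters[1:3], n, replace = TRUE))
    }
  }
  cd <- list()
  if (n_col_vars >= 1)
    cd$lib_size <- if (n_assays >= 1 && n > 0) pmax(colSums(assays$counts), 1)
                   else round(stats::runif(p, 5e3, 2e4))
  if (n_col_vars >= 2)
    cd$condition <- rep(c("trt", "untrt"), length.out = p)
  if (n_col_vars >= 3) {
    for (k in 3:n_col_vars) {
      nm <- paste0("cvar", k)
      cd[[nm]] <- if (k %% 2 == 1) sprinkle(stats::rnorm(p))
                  else sprinkle(sample(c("x", "y"), p, replace = TRUE))
    }
  }

  annotated_matrix(
    assays = assays,
    row_data = if (length(rd)) rd else NULL,
    col_data = if (length(cd)) cd else NULL,
    row_names = if (names && n > 0) sprintf("gene%04d", seq_len(n)) else NULL,
    col_names = if (names && p > 0) sprintf("sample%03d", seq_len(p)) else NULL,
    dim = c(n, p))
}

## ---- interop ------------------------------------------------------------

#' Export / import via the annotated-HDF5 (AnnData) convention
#'
#' Writes the container as an `.h5ad` file: the first assay becomes the main
#' matrix `X`, remaining assays become named layers, `col_data` becomes
#' `obs` and `row_data` becomes `var`. The target convention puts
#' observations (samples) on rows, so matrices are transposed on the way
#' out and back. Conversion is delegated to a bundled Python helper
#' (requires `python` with `anndata` on the PATH).
#'
#' @param obj an `AnnotatedMatrix`.
#' @param path output `.h5ad` file.
#' @return `export_interop` returns `path` invisibly; `import_interop`
#'   returns an `AnnotatedMatrix` (features back on rows).
#' @export
export_interop <- function(obj, path) {
  helper <- system.file("python", "amx_h5ad.py", package = "amgram")
  if (!nzchar(helper)) stop("interop helper script not found")
  tmp <- tempfile("amx_bundle_")
  on.exit(unlink(tmp, recursive = TRUE))
  write_bundle(obj, tmp, assay_format = "csv")
  res <- system2("python", c(shQuote(helper), "to-h5ad", shQuote(tmp), shQuote(path)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status") %||% 0L
  if (status != 0L)
    stop("interop export failed:\n", paste(res, collapse = "\n"))
  invisible(path)
}

#' @rdname export_interop
#' @export
import_interop <- function(path) {
  helper <- system.file("python", "amx_h5ad.py", package = "amgram")
  if (!nzchar(helper)) stop("interop helper script not found")
  tmp <- tempfile("amx_bundle_")
  on.exit(unlink(tmp, recursive = TRUE))
  res <- system2("python", c(shQuote(helper), "from-h5ad", shQuote(path), shQuote(tmp)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status") %||% 0L
  if (status != 0L)
    stop("interop import failed:\n", paste(res, collapse = "\n"))
  read_bundle(tmp)
}
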