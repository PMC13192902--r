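## Long-form reference semantics. `unwind` flattens the container into one
## record per assay cell (column-major) with row/col metadata replicated;
## verbs then reduce to ordinary grouped table operations, implemented here
## with plain split-apply-combine so the oracle shares nothing with the
## masked evaluation path. `rewind` inverts the flattening.

#' Unwind a container into its long-form table
#'
#' One record per (row, column) cell, ordered column-major (all rows of
#' column 1, then column 2, ...). Metadata is replicated down: for a fixed
#' `row_index` every row-derived column is constant, and symmetrically for
#' columns. Name collisions between assays and metadata variables are
#' resolved by suffixing `.row` / `.col` with a warning.
#'
#' When an axis has zero length the grid has no records and the other
#' axis's metadata values cannot live in the records; in that case they are
#' kept in the `amx_schema` attribute (and its TSV sidecar) so the round
#' trip through [rewind()] stays exact.
#'
#' @param obj an `AnnotatedMatrix` (grouping state does not travel; grouping
#'   variables are ordinary columns of the result).
#' @return a `LongTable`: a data.frame with columns `row_index`,
#'   `col_index`, optional `row_name`/`col_name`, one column per assay, per
#'   row variable and per col variable, plus an `amx_schema` attribute
#'   recording the partition of names and the original dims.
#' @export
unwind <- function(obj) {
  n <- obj$dim[1L]; p <- obj$dim[2L]
  tbl <- list(
    row_index = rep(seq_len(n), times = max(p, 0L)),
    col_index = rep(seq_len(p), each = max(n, 0L))
  )
  if (!is.null(obj$row_names)) tbl$row_name <- rep(obj$row_names, times = max(p, 0L))
  if (!is.null(obj$col_names)) tbl$col_name <- rep(obj$col_names, each = max(n, 0L))

  taken <- names(tbl)
  anames <- context_names(obj, "assays")
  for (nm in anames) {
    tbl[[nm]] <- as.vector(obj$assays[[nm]])  # column-major by construction
  }
  taken <- c(taken, anames)

  rmap <- character(); cmap <- character()
  for (nm in names(obj$row_data)) {
    out_nm <- nm
    if (nm %in% taken) {
      out_nm <- paste0(nm, ".row")
      warning(sprintf("unwind: renaming row variable '%s' to '%s' (name collision)",
                      nm, out_nm))
    }
    tbl[[out_nm]] <- rep(obj$row_data[[nm]], times = max(p, 0L))
    rmap[out_nm] <- nm; taken <- c(taken, out_nm)
  }
  for (nm in names(obj$col_data)) {
    out_nm <- nm
    if (nm %in% taken) {
      out_nm <- paste0(nm, ".col")
      warning(sprintf("unwind: renaming col variable '%s' to '%s' (name collision)",
                      nm, out_nm))
    }
    tbl[[out_nm]] <- rep(obj$col_data[[nm]], each = max(n, 0L))
    cmap[out_nm] <- nm; taken <- c(taken, out_nm)
  }

  df <- structure(tbl, class = c("LongTable", "data.frame"),
                  row.names = if (n * p) seq_len(n * p) else integer())
  sch <- list(
    n = n, p = p,
    assay_names = anames,
    row_vars = names(rmap) %||% character(), row_var_src = rmap,
    col_vars = names(cmap) %||% character(), col_var_src = cmap,
    has_row_names = !is.null(obj$row_names),
    has_col_names = !is.null(obj$col_names))
  if (n * p == 0L) {
    # the grid cannot carry axis metadata; stash it for the round trip
    sch$row_table <- cbind(
      if (!is.null(obj$row_names)) data.frame(row_name = obj$row_names),
      obj$row_data)
    sch$col_table <- cbind(
      if (!is.null(obj$col_names)) data.frame(col_name = obj$col_names),
      obj$col_data)
  }
  attr(df, "amx_schema") <- sch
  df
}

#' Rebuild a container from a long-form table
#'
#' Inverse of [unwind()]: requires a complete `n x p` grid of
#' `(row_index, col_index)` records and metadata that is constant within
#' its axis index. Grouping state does not survive the round trip.
#'
#' @param tbl a `LongTable` (or plain data.frame with the same columns).
#' @param assay_names,row_vars,col_vars how to partition the value columns;
#'   defaults come from the table's `amx_schema` attribute.
#' @return an `AnnotatedMatrix`.
#' @export
rewind <- function(tbl, assay_names = NULL, row_vars = NULL, col_vars = NULL) {
  sch <- attr(tbl, "amx_schema") %||% list()
  assay_names <- assay_names %||% sch$assay_names %||% character()
  row_vars <- row_vars %||% sch$row_vars %||% character()
  col_vars <- col_vars %||% sch$col_vars %||% character()

  ri <- tbl$row_index; ci <- tbl$col_index
  if (is.null(ri) || is.null(ci)) stop("long table lacks row_index/col_index")
  n <- sch$n %||% if (length(ri)) max(ri) else 0L
  p <- sch$p %||% if (length(ci)) max(ci) else 0L
  if (nrow(tbl) != n * p) stop("incomplete grid: ", nrow(tbl), " records, expected ", n * p)
  key <- (ci - 1L) * max(n, 1L) + ri
  if (anyDuplicated(key) || (n * p > 0L && !setequal(key, seq_len(n * p))))
    stop("incomplete grid: duplicated or missing (row_index, col_index) cells")
  ord <- order(ci, ri)  # column-major

  assays <- list()
  for (nm in assay_names) {
    if (is.null(tbl[[nm]])) stop("long table lacks assay column '", nm, "'")
    assays[[nm]] <- matrix(tbl[[nm]][ord], n, p)
  }

  first_of <- function(idx_vec, k) match(seq_len(k), idx_vec)
  check_const <- function(v, idx_vec, k, nm, axis) {
    for (g in seq_len(k)) {
      vals <- v[idx_vec == g]
      if (length(unique(vals[!is.na(vals)])) > 1L ||
          (any(is.na(vals)) && !all(is.na(vals))))
        stop(sprintf("%s not constant within %s %d", nm, axis, g))
    }
  }
  src_of <- function(map, nm) {
    s <- (map %||% character())[nm]
    if (!is.na(s) && nzchar(s)) unname(s) else nm
  }
  empty_grid <- n * p == 0L
  rd <- list(); frow <- first_of(ri, n)
  for (nm in row_vars) {
    v <- if (empty_grid) (sch$row_table %||% list())[[nm]] else tbl[[nm]]
    if (is.null(v) && !empty_grid) stop("long table lacks row variable '", nm, "'")
    if (!empty_grid) check_const(v, ri, n, nm, "row")
    rd[[src_of(sch$row_var_src, nm)]] <- if (empty_grid) v else v[frow]
  }
  cd <- list(); fcol <- first_of(ci, p)
  for (nm in col_vars) {
    v <- if (empty_grid) (sch$col_table %||% list())[[nm]] else tbl[[nm]]
    if (is.null(v) && !empty_grid) stop("long table lacks col variable '", nm, "'")
    if (!empty_grid) check_const(v, ci, p, nm, "col")
    cd[[src_of(sch$col_var_src, nm)]] <- if (empty_grid) v else v[fcol]
  }

  row_names <- col_names <- NULL
  if (isTRUE(sch$has_row_names) || !is.null(tbl$row_name)) {
    row_names <- if (empty_grid) as.character((sch$row_table %||% list())$row_name %||% character())
                 else as.character(tbl$row_name[frow])
    if (!length(row_names) && n > 0L) row_names <- NULL
  }
  if (isTRUE(sch$has_col_names) || !is.null(tbl$col_name)) {
    col_names <- if (empty_grid) as.character((sch$col_table %||% list())$col_name %||% character())
                 else as.character(tbl$col_name[fcol])
    if (!length(col_names) && p > 0L) col_names <- NULL
  }

  annotated_matrix(
    assays = assays,
    row_data = if (length(rd)) rd else NULL,
    col_data = if (length(cd)) cd else NULL,
    row_names = row_names, col_names = col_names,
    dim = c(n, p))
}

#' Long-table serialization
#'
#' Fixed-layout TSV: `row_index`, `col_index`, optional `row_name` /
#' `col_name`, then assays, then row variables, then col variables. UTF-8,
#' `.` decimal separator, `NA` as missing marker. The schema (including the
#' empty-grid axis tables, if any) travels in a `.schema.json` sidecar.
#'
#' @param tbl a `LongTable`.
#' @param path file path.
#' @export
write_long_table <- function(tbl, path) {
  sch <- attr(tbl, "amx_schema")
  df <- as.data.frame(tbl)
  num <- vapply(df, is.double, logical(1))
  for (nm in names(df)[num]) {
    s <- fmt_num(df[[nm]])
    df[[nm]] <- s
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  if (!is.null(sch)) {
    meta <- sch[intersect(names(sch),
                          c("n", "p", "assay_names", "row_vars", "col_vars",
                            "has_row_names", "has_col_names",
                            "row_var_src", "col_var_src"))]
    meta$col_types <- lapply(as.data.frame(tbl), meta_type)
    if (!is.null(sch$row_table)) meta$row_table <- sch$row_table
    if (!is.null(sch$col_table)) meta$col_table <- sch$col_table
    jsonlite::write_json(meta, paste0(path, ".schema.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_long_table
#' @export
read_long_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          na.strings = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE)
  schema_path <- paste0(path, ".schema.json")
  sch <- NULL
  types <- list()
  if (file.exists(schema_path)) {
    sch <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
    for (f in c("assay_names", "row_vars", "col_vars"))
      sch[[f]] <- as.character(sch[[f]] %||% character())
    for (f in c("row_var_src", "col_var_src")) {
      v <- unlist(sch[[f]]) %||% character()
      sch[[f]] <- v
    }
    types <- as.list(sch$col_types %||% list())
    sch$col_types <- NULL
  }
  out <- list()
  for (nm in names(df)) {
    s <- df[[nm]]
    ty <- types[[nm]] %||%
      if (nm %in% c("row_index", "col_index")) "integer" else "character"
    out[[nm]] <- switch(ty,
      double = { x <- suppressWarnings(as.numeric(s)); x[s == "NaN"] <- NaN; x },
      integer = suppressWarnings(as.integer(ifelse(s == "NA", NA, s))),
      logical = as.logical(ifelse(s == "NA", NA, s)),
      { x <- s; x[s == "NA"] <- NA; x })
  }
  res <- structure(out, class = c("LongTable", "data.frame"),
                   row.names = if (length(out) && length(out[[1L]]))
                     seq_along(out[[1L]]) else integer())
  if (!is.null(sch)) attr(res, "amx_schema") <- sch
  res
}

## ---- oracle verb semantics ---------------------------------------------
##
## State: the cell table (row_index, col_index, one column per assay) plus
## the two axis tables, dims, name partitions, and the active grouping
## variables per axis. Assays-context expressions evaluate on the fully
## joined (unwound) table; metadata-context expressions on their axis
## table. All grouping is split/apply/combine on plain data.frames.

oracle_state <- function(obj) {
  n <- obj$dim[1L]; p <- obj$dim[2L]
  cells <- data.frame(row_index = rep(seq_len(n), times = max(p, 0L)),
                      col_index = rep(seq_len(p), each = max(n, 0L)))
  for (nm in context_names(obj, "assays"))
    cells[[nm]] <- as.vector(obj$assays[[nm]])
  rtab <- as.data.frame(obj$row_data)
  if (!is.null(obj$row_names)) rtab <- cbind(data.frame(row_name = obj$row_names), rtab)
  ctab <- as.data.frame(obj$col_data)
  if (!is.null(obj$col_names)) ctab <- cbind(data.frame(col_name = obj$col_names), ctab)
  list(cells = cells, rtab = rtab, ctab = ctab, n = n, p = p,
       assay_names = context_names(obj, "assays"),
       row_vars = names(obj$row_data), col_vars = names(obj$col_data),
       has_row_names = !is.null(obj$row_names),
       has_col_names = !is.null(obj$col_names),
       rg = if (!is.null(obj$row_grouping)) obj$row_grouping$variables else character(),
       cg = if (!is.null(obj$col_grouping)) obj$col_grouping$variables else character())
}

# the unwound view: cells with metadata replicated in
oracle_joined <- function(state) {
  j <- state$cells
  for (v in state$row_vars) j[[v]] <- state$rtab[[v]][j$row_index]
  for (v in state$col_vars) j[[v]] <- state$ctab[[v]][j$col_index]
  j
}

oracle_result <- function(state) {
  ord <- order(state$cells$col_index, state$cells$row_index)
  assays <- list()
  for (nm in state$assay_names)
    assays[[nm]] <- matrix(state$cells[[nm]][ord], state$n, state$p)
  rd <- state$rtab[state$row_vars]
  cd <- state$ctab[state$col_vars]
  annotated_matrix(
    assays = assays,
    row_data = if (length(rd)) rd else NULL,
    col_data = if (length(cd)) cd else NULL,
    row_names = if (isTRUE(state$has_row_names)) as.character(state$rtab$row_name) else NULL,
    col_names = if (isTRUE(state$has_col_names)) as.character(state$ctab$col_name) else NULL,
    dim = c(state$n, state$p))
}

# reshaped pronoun refs become column symbols in the joined table
oracle_translate <- function(e) {
  if (is.call(e) && is.symbol(e[[1L]]) && as.character(e[[1L]]) == "$") {
    tgt <- as.character(e[[2L]])
    if (grepl("_asis$", tgt))
      stop("asis pronouns have no long-form counterpart")
    return(as.symbol(as.character(e[[3L]])))
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) {
      if (identical(as.list(e)[i], list(quote(expr = )))) next
      e[[i]] <- oracle_translate(e[[i]])
    }
  }
  e
}

# group keys in first-appearance order; NA is its own group
oracle_keys <- function(df, vars) {
  len <- nrow(df)
  if (!length(vars)) return(rep("", len))
  parts <- lapply(vars, function(v) {
    x <- df[[v]]
    s <- as.character(x); s[is.na(x)] <- "\x01<NA>\x01"; s
  })
  do.call(paste, c(parts, sep = "\x02"))
}

oracle_fn_env <- function(group_n) {
  env <- new.env(parent = baseenv())
  env$n <- local({ k <- group_n; function() k })
  env$row_number <- local({ k <- group_n; function() seq_len(k) })
  env$if_else <- amx_if_else
  env$var <- function(x, na.rm = FALSE) stats::var(as.vector(x), na.rm = na.rm)
  env$sd <- function(x, na.rm = FALSE) stats::sd(as.vector(x), na.rm = na.rm)
  env$median <- stats::median
  env$desc <- function(x) structure(list(key = x), class = "amx_desc")
  env
}

oracle_eval_in <- function(df, idx, expr) {
  eval(expr, envir = df[idx, , drop = FALSE], enclos = oracle_fn_env(length(idx)))
}

# grouped mutate-style evaluation over table `df`
oracle_eval_grouped <- function(df, gvars, expr) {
  keys <- oracle_keys(df, gvars)
  ukeys <- unique(keys)
  out <- NULL
  for (k in ukeys) {
    idx <- which(keys == k)
    val <- oracle_eval_in(df, idx, expr)
    if (length(val) == 1L) val <- rep(val, length(idx))
    if (length(val) != length(idx))
      stop("oracle: non-size-stable result in group")
    if (is.null(out)) out <- rep(val[NA_integer_][1L], nrow(df))
    out[idx] <- val
  }
  if (is.null(out)) out <- vector(mode = "logical", length = 0L)
  out
}

oracle_apply <- function(state, vc) {
  stopifnot(inherits(vc, "VerbCall"))
  switch(vc$verb,
    mutate = {
      for (it in vc$items) {
        e <- oracle_translate(it$expr)
        if (it$context == "assays") {
          j <- oracle_joined(state)
          state$cells[[it$name]] <- oracle_eval_grouped(j, c(state$rg, state$cg), e)
          if (!it$name %in% state$assay_names)
            state$assay_names <- c(state$assay_names, it$name)
        } else if (it$context == "rows") {
          state$rtab[[it$name]] <- oracle_eval_grouped(state$rtab, state$rg, e)
          if (!it$name %in% state$row_vars)
            state$row_vars <- c(state$row_vars, it$name)
        } else {
          state$ctab[[it$name]] <- oracle_eval_grouped(state$ctab, state$cg, e)
          if (!it$name %in% state$col_vars)
            state$col_vars <- c(state$col_vars, it$name)
        }
      }
      state
    },
    filter = {
      for (it in vc$items) {
        if (it$context == "rows") {
          pred <- oracle_eval_grouped(state$rtab, state$rg, oracle_translate(it$expr))
          pred[is.na(pred)] <- FALSE
          kept <- which(pred)
          state$cells <- state$cells[state$cells$row_index %in% kept, , drop = FALSE]
          state$cells$row_index <- match(state$cells$row_index, kept)
          state$rtab <- state$rtab[kept, , drop = FALSE]
          attr(state$rtab, "row.names") <- seq_along(kept)
          state$n <- length(kept)
        } else {
          pred <- oracle_eval_grouped(state$ctab, state$cg, oracle_translate(it$expr))
          pred[is.na(pred)] <- FALSE
          kept <- which(pred)
          state$cells <- state$cells[state$cells$col_index %in% kept, , drop = FALSE]
          state$cells$col_index <- match(state$cells$col_index, kept)
          state$ctab <- state$ctab[kept, , drop = FALSE]
          attr(state$ctab, "row.names") <- seq_along(kept)
          state$p <- length(kept)
        }
      }
      state
    },
    arrange = {
      for (it in vc$items) {
        e <- oracle_translate(it$expr)
        tab <- if (it$context == "rows") state$rtab else state$ctab
        val <- oracle_eval_in(tab, seq_len(nrow(tab)), e)
        descending <- inherits(val, "amx_desc")
        if (descending) val <- val$key
        rk <- xtfrm(val); if (descending) rk <- -rk
        o <- if (nrow(tab)) order(rk, method = "radix") else integer()
        if (it$context == "rows") {
          state$rtab <- state$rtab[o, , drop = FALSE]
          attr(state$rtab, "row.names") <- seq_along(o)
          state$cells$row_index <- match(state$cells$row_index, o)
        } else {
          state$ctab <- state$ctab[o, , drop = FALSE]
          attr(state$ctab, "row.names") <- seq_along(o)
          state$cells$col_index <- match(state$cells$col_index, o)
        }
      }
      state
    },
    group_by = {
      rv <- character(); cv <- character()
      for (it in vc$items) {
        if (!is.symbol(it$expr)) stop("oracle group_by expects bare names")
        nm <- as.character(it$expr)
        if (it$context == "rows") rv <- c(rv, nm) else cv <- c(cv, nm)
      }
      if (length(rv)) state$rg <- rv
      if (length(cv)) state$cg <- cv
      state
    },
    ungroup = {
      state$rg <- character(); state$cg <- character()
      state
    },
    summarize = {
      rgrouped <- length(state$rg) > 0L
      cgrouped <- length(state$cg) > 0L
      rkeys_all <- oracle_keys(state$rtab, state$rg)
      ckeys_all <- oracle_keys(state$ctab, state$cg)
      if (rgrouped) {
        rkeys <- unique(rkeys_all); n2 <- length(rkeys)
        rtab2 <- state$rtab[match(rkeys, rkeys_all), state$rg, drop = FALSE]
      } else {
        rkeys <- ""; n2 <- 1L
        rtab2 <- as_meta_table(NULL, 1L, "row_data")
      }
      if (cgrouped) {
        ckeys <- unique(ckeys_all); p2 <- length(ckeys)
        ctab2 <- state$ctab[match(ckeys, ckeys_all), state$cg, drop = FALSE]
      } else {
        ckeys <- ""; p2 <- 1L
        ctab2 <- as_meta_table(NULL, 1L, "col_data")
      }
      attr(rtab2, "row.names") <- if (n2) seq_len(n2) else integer()
      attr(ctab2, "row.names") <- if (p2) seq_len(p2) else integer()

      cells2 <- data.frame(row_index = rep(seq_len(n2), times = max(p2, 0L)),
                           col_index = rep(seq_len(p2), each = max(n2, 0L)))
      new_assays <- character()
      new_rv <- if (rgrouped) state$rg else character()
      new_cv <- if (cgrouped) state$cg else character()
      j <- oracle_joined(state)
      cell_rk <- rkeys_all[state$cells$row_index]
      cell_ck <- ckeys_all[state$cells$col_index]
      if (!rgrouped) cell_rk <- rep("", nrow(state$cells))
      if (!cgrouped) cell_ck <- rep("", nrow(state$cells))
      for (it in vc$items) {
        e <- oracle_translate(it$expr)
        if (it$context == "assays") {
          vals <- vector("list", n2 * p2)
          for (gj in seq_len(p2)) for (gi in seq_len(n2)) {
            idx <- which(cell_rk == rkeys[gi] & cell_ck == ckeys[gj])
            v <- oracle_eval_in(j, idx, e)
            if (length(v) != 1L) stop("oracle: summarize result not scalar")
            vals[[(gj - 1L) * n2 + gi]] <- v
          }
          cells2[[it$name]] <- unlist(vals)
          new_assays <- c(new_assays, it$name)
        } else if (it$context == "rows") {
          out <- vector("list", n2)
          for (gi in seq_len(n2)) {
            idx <- if (rgrouped) which(rkeys_all == rkeys[gi]) else seq_len(state$n)
            v <- oracle_eval_in(state$rtab, idx, e)
            if (length(v) != 1L) stop("oracle: summarize result not scalar")
            out[[gi]] <- v
          }
          rtab2[[it$name]] <- unlist(out)
          new_rv <- c(new_rv, it$name)
        } else {
          out <- vector("list", p2)
          for (gj in seq_len(p2)) {
            idx <- if (cgrouped) which(ckeys_all == ckeys[gj]) else seq_len(state$p)
            v <- oracle_eval_in(state$ctab, idx, e)
            if (length(v) != 1L) stop("oracle: summarize result not scalar")
            out[[gj]] <- v
          }
          ctab2[[it$name]] <- unlist(out)
          new_cv <- c(new_cv, it$name)
        }
      }
      list(cells = cells2, rtab = rtab2, ctab = ctab2, n = n2, p = p2,
           assay_names = new_assays, row_vars = new_rv, col_vars = new_cv,
           has_row_names = FALSE, has_col_names = FALSE,
           rg = character(), cg = character())
    },
    stop("oracle has no counterpart for verb '", vc$verb, "'"))
}
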