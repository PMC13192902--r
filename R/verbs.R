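## Context-scoped tidy verbs. Bare expressions address the assays context;
## wrapping them in rows(...) / cols(...) redirects both evaluation and the
## destination of results to the metadata contexts.

#' Context sentinels
#'
#' `rows(...)` and `cols(...)` are syntax, not functions: inside a verb call
#' they redirect the enclosed expressions to the row- or column-metadata
#' context (and determine where results are stored). Calling them outside a
#' verb is an error.
#' @param ... expressions.
#' @export
rows <- function(...) stop("rows(...) may only be used inside a verb call")

#' @rdname rows
#' @export
cols <- function(...) stop("cols(...) may only be used inside a verb call")

# turn captured `...` expressions into a flat item list
# item: list(context =, name = NULL|string, expr = language)
capture_items <- function(exprs) {
  items <- list()
  nms <- names(exprs) %||% rep("", length(exprs))
  for (i in seq_along(exprs)) {
    e <- exprs[[i]]
    if (is.call(e) && is.symbol(e[[1L]]) &&
        as.character(e[[1L]]) %in% c("rows", "cols") && nms[i] == "") {
      ctx <- as.character(e[[1L]])
      inner <- as.list(e)[-1L]
      inms <- names(inner) %||% rep("", length(inner))
      for (j in seq_along(inner)) {
        items[[length(items) + 1L]] <-
          list(context = ctx, name = if (nzchar(inms[j])) inms[j] else NULL,
               expr = inner[[j]])
      }
    } else {
      items[[length(items) + 1L]] <-
        list(context = "assays", name = if (nzchar(nms[i])) nms[i] else NULL,
             expr = e)
    }
  }
  items
}

#' Construct a verb call description
#'
#' The package's internal (and the pipeline DSL's) representation of one
#' verb invocation: the verb plus an ordered list of
#' (target context, optional name, expression) items. [apply_verb()]
#' executes one against a container.
#'
#' @param verb one of `"mutate"`, `"filter"`, `"select"`, `"arrange"`,
#'   `"group_by"`, `"ungroup"`, `"summarize"`, `"pull"`, `"slice"`.
#' @param items list of `list(context, name, expr)` items.
#' @return a `VerbCall`.
#' @export
verb_call <- function(verb, items = list()) {
  verb <- match.arg(verb, c("mutate", "filter", "select", "arrange",
                            "group_by", "ungroup", "summarize", "pull", "slice"))
  structure(list(verb = verb, items = items), class = "VerbCall")
}

#' Execute a verb call against a container
#'
#' @param obj an `AnnotatedMatrix`.
#' @param call a [verb_call()].
#' @param caller environment used as symbol fallback for the expressions.
#' @return the transformed container (or the pulled value for `pull`).
#' @export
apply_verb <- function(obj, call, caller = parent.frame()) {
  stopifnot(inherits(call, "VerbCall"))
  switch(call$verb,
    mutate    = amx_mutate(obj, call$items, caller),
    filter    = amx_filter(obj, call$items, caller),
    select    = amx_select(obj, call$items),
    arrange   = amx_arrange(obj, call$items, caller),
    group_by  = amx_group_by(obj, call$items, caller),
    ungroup   = amx_ungroup_items(obj, call$items),
    summarize = amx_summarize(obj, call$items, caller),
    slice     = amx_slice(obj, call$items, caller),
    pull      = {
      it <- call$items[[1L]]
      if (!is.symbol(it$expr)) stop("pull expects a bare name")
      amx_pull(obj, as.character(it$expr), it$context)
    })
}

## ---- mutate -------------------------------------------------------------

#' Tidy verbs for annotated matrices
#'
#' Methods for the dplyr generics. Bare items evaluate (and store their
#' results) in the assays context; `rows(...)` / `cols(...)` sentinels
#' redirect to the metadata contexts. Items are evaluated strictly left to
#' right, so later items see earlier results even across contexts. Under
#' grouping, expressions run once per effective block (the assays context
#' sees the cross-product of row and column groups; each metadata context
#' only its own axis's groups) and the per-block results are stitched back
#' in original index order.
#'
#' @param .data an `AnnotatedMatrix`.
#' @param ... verb items, optionally wrapped in `rows()` / `cols()`.
#' @return an `AnnotatedMatrix` (`pull` returns the stored value).
#' @name amx-verbs
#' @examples
#' am <- generate_fixture(6, 4, n_assays = 1, seed = 1)
#' am |>
#'   dplyr::mutate(logcounts = log1p(counts),
#'                 cols(big = lib_size > 1e4)) |>
#'   dplyr::filter(rows(length < 3000))
NULL

#' @rdname amx-verbs
#' @method mutate AnnotatedMatrix
#' @export
mutate.AnnotatedMatrix <- function(.data, ...) {
  items <- capture_items(as.list(substitute(list(...)))[-1L])
  amx_mutate(.data, items, parent.frame())
}

amx_mutate <- function(obj, items, caller) {
  work <- obj
  for (it in items) {
    if (is.null(it$name))
      stop("every mutate item must be named (name = expression)")
    if (it$name %in% .amx_pronoun_names)
      stop(sprintf("'%s' is a reserved pronoun name", it$name))
    val <- eval_blockwise(work, it$context, it$expr, caller)
    work <- bind_result(work, it$context, it$name, val)
  }
  amx_validate(work)
}

# evaluate expr per effective block of `context` and stitch the results
# back into a full-size matrix / vector in original index order
eval_blockwise <- function(obj, context, expr, caller) {
  blocks <- effective_partition(obj, context)
  n <- obj$dim[1L]; p <- obj$dim[2L]
  if (!length(blocks)) {
    # a grouped axis of length zero has zero groups; evaluate once over the
    # degenerate full view so the result still has the right type and shape
    blocks <- list(list(rows = seq_len(n), cols = seq_len(p)))
  }
  if (length(blocks) == 1L) {
    fr <- build_frame(obj, context, caller, view = blocks[[1L]])
    val <- amx_evaluate(expr, fr)
    return(check_size_stable(val, context,
                             if (context == "assays") c(n, p) else
                               if (context == "rows") n else p))
  }
  if (context == "assays") {
    out <- NULL
    for (b in blocks) {
      fr <- build_frame(obj, context, caller, view = b)
      val <- check_size_stable(amx_evaluate(expr, fr), "assays",
                               c(length(b$rows), length(b$cols)))
      if (is.null(out)) out <- matrix(val[NA_integer_][1L], n, p)  # typed NA
      out[b$rows, b$cols] <- val
    }
    out
  } else {
    len <- if (context == "rows") n else p
    pieces <- vector("list", length(blocks))
    idx <- vector("list", length(blocks))
    for (k in seq_along(blocks)) {
      b <- blocks[[k]]
      own <- if (context == "rows") b$rows else b$cols
      fr <- build_frame(obj, context, caller, view = b)
      pieces[[k]] <- check_size_stable(amx_evaluate(expr, fr), context,
                                       length(own))
      idx[[k]] <- own
    }
    flat_idx <- unlist(idx, use.names = FALSE)
    islist <- any(vapply(pieces, is.list, logical(1)))
    flat <- if (islist) do.call(c, lapply(pieces, as.list))
            else unlist(pieces, use.names = FALSE)
    out <- flat
    out[flat_idx] <- flat
    out
  }
}

bind_result <- function(obj, context, name, val) {
  switch(context,
    assays = { obj$assays[[name]] <- val },
    rows = {
      obj$row_data[[name]] <- val
      if (!is.null(obj$row_grouping) && name %in% obj$row_grouping$variables)
        obj$row_grouping <- grouping_spec("rows", obj$row_grouping$variables,
                                          obj$row_data)
    },
    cols = {
      obj$col_data[[name]] <- val
      if (!is.null(obj$col_grouping) && name %in% obj$col_grouping$variables)
        obj$col_grouping <- grouping_spec("cols", obj$col_grouping$variables,
                                          obj$col_data)
    })
  obj
}

## ---- filter -------------------------------------------------------------

#' @rdname amx-verbs
#' @method filter AnnotatedMatrix
#' @export
filter.AnnotatedMatrix <- function(.data, ...) {
  items <- capture_items(as.list(substitute(list(...)))[-1L])
  amx_filter(.data, items, parent.frame())
}

amx_filter <- function(obj, items, caller) {
  if (any(vapply(items, function(it) it$context == "assays", logical(1))))
    stop(paste("filtering is only defined on rows or cols contexts:",
               "subsetting by arbitrary matrix elements cannot produce a",
               "valid sub-matrix"))
  keep <- list(rows = rep(TRUE, obj$dim[1L]), cols = rep(TRUE, obj$dim[2L]))
  for (it in items) {
    if (!is.null(it$name)) stop("filter predicates must be unnamed")
    pred <- eval_blockwise(obj, it$context, it$expr, caller)
    if (!is.logical(pred))
      stop(sprintf("filter predicate in %s context must be logical", it$context))
    n_na <- sum(is.na(pred))
    if (n_na > 0L)
      message(sprintf("filter: dropping %d record(s) with missing predicate values", n_na))
    pred[is.na(pred)] <- FALSE
    keep[[it$context]] <- keep[[it$context]] & pred
  }
  amx_subset(obj, rows = which(keep$rows), cols = which(keep$cols))
}

## ---- select -------------------------------------------------------------

#' @rdname amx-verbs
#' @method select AnnotatedMatrix
#' @export
select.AnnotatedMatrix <- function(.data, ...) {
  items <- capture_items(as.list(substitute(list(...)))[-1L])
  amx_select(.data, items)
}

amx_select <- function(obj, items) {
  wanted <- list(assays = character(), rows = character(), cols = character())
  for (it in items) {
    if (!is.symbol(it$expr)) stop("select expects bare variable names")
    wanted[[it$context]] <- c(wanted[[it$context]], as.character(it$expr))
  }
  if (length(wanted$assays)) {
    miss <- setdiff(wanted$assays, context_names(obj, "assays"))
    if (length(miss)) stop(sprintf("no assay named '%s'", miss[1L]))
    obj$assays <- obj$assays[wanted$assays]
  }
  if (length(wanted$rows)) {
    miss <- setdiff(wanted$rows, names(obj$row_data))
    if (length(miss)) stop(sprintf("no row variable named '%s'", miss[1L]))
    keep <- union(wanted$rows,
                  if (!is.null(obj$row_grouping)) obj$row_grouping$variables else character())
    obj$row_data <- obj$row_data[intersect(names(obj$row_data), keep)]
  }
  if (length(wanted$cols)) {
    miss <- setdiff(wanted$cols, names(obj$col_data))
    if (length(miss)) stop(sprintf("no col variable named '%s'", miss[1L]))
    keep <- union(wanted$cols,
                  if (!is.null(obj$col_grouping)) obj$col_grouping$variables else character())
    obj$col_data <- obj$col_data[intersect(names(obj$col_data), keep)]
  }
  amx_validate(obj)
}

## ---- arrange ------------------------------------------------------------

#' @rdname amx-verbs
#' @method arrange AnnotatedMatrix
#' @export
arrange.AnnotatedMatrix <- function(.data, ...) {
  items <- capture_items(as.list(substitute(list(...)))[-1L])
  amx_arrange(.data, items, parent.frame())
}

amx_arrange <- function(obj, items, caller) {
  if (any(vapply(items, function(it) it$context == "assays", logical(1))))
    stop(paste("arrange keys must live in the rows or cols contexts:",
               "ordering an axis by arbitrary matrix elements is ill-defined"))
  keys <- list(rows = list(), cols = list())
  for (it in items) {
    ungrp <- amx_ungroup(obj)  # keys are whole-axis, grouping is ignored
    fr <- build_frame(ungrp, it$context, caller)
    val <- amx_evaluate(it$expr, fr)
    descending <- inherits(val, "amx_desc")
    if (descending) val <- val$key
    len <- if (it$context == "rows") obj$dim[1L] else obj$dim[2L]
    val <- check_size_stable(val, it$context, len)
    rk <- xtfrm(val)
    keys[[it$context]][[length(keys[[it$context]]) + 1L]] <-
      if (descending) -rk else rk
  }
  ord <- function(ks, len) {
    if (!length(ks)) return(seq_len(len))
    if (len == 0L) return(integer())
    do.call(order, c(ks, list(method = "radix")))
  }
  amx_subset(obj,
             rows = ord(keys$rows, obj$dim[1L]),
             cols = ord(keys$cols, obj$dim[2L]))
}

## ---- group_by / ungroup -------------------------------------------------

#' @rdname amx-verbs
#' @param .add if `TRUE`, add to (rather than replace) the axis's existing
#'   grouping variables.
#' @method group_by AnnotatedMatrix
#' @export
group_by.AnnotatedMatrix <- function(.data, ..., .add = FALSE) {
  items <- capture_items(as.list(substitute(list(...)))[-1L])
  amx_group_by(.data, items, parent.frame(), add = .add)
}

amx_group_by <- function(obj, items, caller, add = FALSE) {
  if (any(vapply(items, function(it) it$context == "assays", logical(1))))
    stop(paste("grouping must partition rows or columns: there is no",
               "guarantee a partition of arbitrary matrix elements creates",
               "valid sub-matrices"))
  vars <- list(rows = character(), cols = character())
  work <- obj
  gen <- 0L
  for (it in items) {
    if (is.symbol(it$expr) &&
        as.character(it$expr) %in% context_names(work, it$context)) {
      vars[[it$context]] <- c(vars[[it$context]], as.character(it$expr))
    } else {
      # expression grouping: materialize first under a generated (or given) name
      gen <- gen + 1L
      nm <- it$name %||% paste0(".group", gen)
      work <- amx_mutate(work, list(list(context = it$context, name = nm,
                                         expr = it$expr)), caller)
      vars[[it$context]] <- c(vars[[it$context]], nm)
    }
  }
  if (length(vars$rows)) {
    prev <- if (add && !is.null(work$row_grouping)) work$row_grouping$variables else character()
    work$row_grouping <- grouping_spec("rows", union(prev, vars$rows), work$row_data)
  }
  if (length(vars$cols)) {
    prev <- if (add && !is.null(work$col_grouping)) work$col_grouping$variables else character()
    work$col_grouping <- grouping_spec("cols", union(prev, vars$cols), work$col_data)
  }
  work
}

#' Remove grouping from one or both axes
#'
#' @param x an `AnnotatedMatrix`.
#' @param axes subset of `c("rows", "cols")`; both when omitted.
#' @param ... ignored.
#' @method ungroup AnnotatedMatrix
#' @export
ungroup.AnnotatedMatrix <- function(x, ...) {
  items <- capture_items(as.list(substitute(list(...)))[-1L])
  amx_ungroup_items(x, items)
}

amx_ungroup_items <- function(obj, items = list()) {
  if (!length(items)) return(amx_ungroup(obj))
  axes <- vapply(items, function(it) {
    if (is.symbol(it$expr) && as.character(it$expr) %in% c("rows", "cols"))
      as.character(it$expr)
    else it$context
  }, character(1))
  amx_ungroup(obj, axes)
}

#' @rdname ungroup.AnnotatedMatrix
#' @export
amx_ungroup <- function(x, axes = c("rows", "cols")) {
  axes <- match.arg(axes, several.ok = TRUE)
  if ("rows" %in% axes) x$row_grouping <- NULL
  if ("cols" %in% axes) x$col_grouping <- NULL
  x
}

## ---- summarize ----------------------------------------------------------

#' @rdname amx-verbs
#' @method summarise AnnotatedMatrix
#' @export
summarise.AnnotatedMatrix <- function(.data, ...) {
  items <- capture_items(as.list(substitute(list(...)))[-1L])
  amx_summarize(.data, items, parent.frame())
}

#' @rdname amx-verbs
#' @method summarize AnnotatedMatrix
#' @export
summarize.AnnotatedMatrix <- summarise.AnnotatedMatrix

amx_summarize <- function(obj, items, caller) {
  rg <- obj$row_grouping; cg <- obj$col_grouping
  rparts <- if (!is.null(rg)) rg$partition else list(seq_len(obj$dim[1L]))
  cparts <- if (!is.null(cg)) cg$partition else list(seq_len(obj$dim[2L]))
  n2 <- length(rparts); p2 <- length(cparts)

  row_data2 <- if (!is.null(rg)) rg$keys else
    as_meta_table(NULL, n2, "row_data")
  if (is.null(rg)) attr(row_data2, "row.names") <- seq_len(n2)
  col_data2 <- if (!is.null(cg)) cg$keys else
    as_meta_table(NULL, p2, "col_data")
  if (is.null(cg)) attr(col_data2, "row.names") <- seq_len(p2)

  assays2 <- list()
  scalar1 <- function(v, what) {
    if (is.matrix(v) && length(v) == 1L) v <- v[1L]
    if (!(is.atomic(v) && length(v) == 1L))
      stop(sprintf("summarize expression '%s' must reduce each block to one value (got length %d)",
                   what, length(v)), call. = FALSE)
    v
  }
  for (it in items) {
    if (is.null(it$name)) stop("every summarize item must be named")
    lab <- it$name
    if (it$context == "assays") {
      vals <- matrix(NA_real_, n2, p2)
      first <- TRUE
      for (gi in seq_len(n2)) for (gj in seq_len(p2)) {
        fr <- build_frame(obj, "assays", caller,
                          view = list(rows = rparts[[gi]], cols = cparts[[gj]]))
        v <- scalar1(amx_evaluate(it$expr, fr), lab)
        if (first && !is.double(v)) { storage.mode(vals) <- storage.mode(v) }
        first <- FALSE
        vals[gi, gj] <- v
      }
      assays2[[lab]] <- vals
    } else if (it$context == "rows") {
      out <- vector("list", n2)
      for (gi in seq_len(n2)) {
        fr <- build_frame(obj, "rows", caller,
                          view = list(rows = rparts[[gi]], cols = seq_len(obj$dim[2L])))
        out[[gi]] <- scalar1(amx_evaluate(it$expr, fr), lab)
      }
      row_data2[[lab]] <- unlist(out)
    } else {
      out <- vector("list", p2)
      for (gj in seq_len(p2)) {
        fr <- build_frame(obj, "cols", caller,
                          view = list(rows = seq_len(obj$dim[1L]), cols = cparts[[gj]]))
        out[[gj]] <- scalar1(amx_evaluate(it$expr, fr), lab)
      }
      col_data2[[lab]] <- unlist(out)
    }
  }
  annotated_matrix(assays = assays2, row_data = row_data2, col_data = col_data2,
                   dim = c(n2, p2))
}

## ---- slice / pull -------------------------------------------------------

#' @rdname amx-verbs
#' @method slice AnnotatedMatrix
#' @export
slice.AnnotatedMatrix <- function(.data, ...) {
  items <- capture_items(as.list(substitute(list(...)))[-1L])
  amx_slice(.data, items, parent.frame())
}

# positional filtering: the expression yields 1-based positions into the axis
amx_slice <- function(obj, items, caller) {
  if (any(vapply(items, function(it) it$context == "assays", logical(1))))
    stop("slice positions must target the rows or cols context")
  ri <- NULL; ci <- NULL
  for (it in items) {
    ungrp <- amx_ungroup(obj)
    fr <- build_frame(ungrp, it$context, caller)
    pos <- amx_evaluate(it$expr, fr)
    len <- if (it$context == "rows") obj$dim[1L] else obj$dim[2L]
    pos <- as.integer(pos)
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > len))
      stop(sprintf("slice positions out of range 1..%d", len))
    if (it$context == "rows") ri <- pos else ci <- pos
  }
  amx_subset(obj, rows = ri %||% seq_len(obj$dim[1L]),
             cols = ci %||% seq_len(obj$dim[2L]))
}

#' Extract one stored value from a container
#'
#' @param .data an `AnnotatedMatrix`.
#' @param var bare name (optionally wrapped in `rows()` / `cols()`) or a
#'   string.
#' @param context used with a string `var`: `"assays"`, `"rows"` or
#'   `"cols"`.
#' @param ... ignored.
#' @return the stored matrix (assays) or vector (metadata), as-is.
#' @method pull AnnotatedMatrix
#' @export
pull.AnnotatedMatrix <- function(.data, var, context = NULL, ...) {
  ex <- substitute(var)
  if (is.character(ex))
    return(amx_pull(.data, ex, context %||% "assays"))
  if (is.symbol(ex) ||
      (is.call(ex) && is.symbol(ex[[1L]]) &&
       as.character(ex[[1L]]) %in% c("rows", "cols"))) {
    it <- capture_items(list(ex))[[1L]]
    if (!is.symbol(it$expr)) stop("pull expects a bare name or a string")
    return(amx_pull(.data, as.character(it$expr), context %||% it$context))
  }
  amx_pull(.data, as.character(var), context %||% "assays")
}

amx_pull <- function(obj, name, context) {
  nms <- context_names(obj, context)
  if (!name %in% nms)
    stop(sprintf("no name '%s' in %s context", name, context))
  switch(context,
    assays = obj$assays[[name]],
    rows = obj$row_data[[name]],
    cols = obj$col_data[[name]])
}
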