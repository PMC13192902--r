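## Evaluation engine: per-context symbol resolution, lazy memoized pronouns,
## the four reshaping transformations, whitelist enforcement, size stability.

#' Reshaping primitives
#'
#' The four size-stabilizing transformations that connect contexts. Row
#' metadata entering the assays context is replicated across the `p`
#' columns; column metadata is replicated down the `n` rows; an assay
#' matrix entering the rows (cols) context is sliced into a list of its
#' rows (columns), so each list element has the length of the other axis.
#'
#' @param v vector of row (length `n`) or column (length `p`) metadata.
#' @param n,p the target counts of rows / columns.
#' @param M an `n x p` matrix.
#' @param names optional names for the resulting list (axis identifiers).
#' @return `broadcast_*` return an `n x p` matrix with `result[i, j] = v[i]`
#'   (row variant) or `v[j]` (col variant); `slice_*` return an ordered list
#'   of the matrix's rows or columns.
#' @export
broadcast_row_to_assay <- function(v, p) {
  n <- length(v)
  matrix(rep(v, times = max(p, 0L)), nrow = n, ncol = p)
}

#' @rdname broadcast_row_to_assay
#' @export
broadcast_col_to_assay <- function(v, n) {
  p <- length(v)
  matrix(rep(v, each = max(n, 0L)), nrow = n, ncol = p)
}

#' @rdname broadcast_row_to_assay
#' @export
slice_assay_to_rows <- function(M, names = NULL) {
  out <- lapply(seq_len(nrow(M)), function(i) M[i, ])
  if (!is.null(names)) base::names(out) <- names
  out
}

#' @rdname broadcast_row_to_assay
#' @export
slice_assay_to_cols <- function(M, names = NULL) {
  out <- lapply(seq_len(ncol(M)), function(j) M[, j])
  if (!is.null(names)) base::names(out) <- names
  out
}

## ---- function whitelist -------------------------------------------------

.amx_registry <- new.env(parent = emptyenv())

#' Register a function for use inside mask expressions
#'
#' Expressions evaluated inside a context may only call functions present in
#' this registry; anything else is rejected before evaluation. The default
#' registry covers arithmetic, comparison and boolean operators, elementwise
#' math (`log`, `log1p`, `exp`, `sqrt`, `abs`), reductions (`mean`, `sum`,
#' `min`, `max`, `median`, `var`, `sd`), axis reductions (`row_means`,
#' `col_means`, `row_sums`, `col_sums`), `n()`, `row_number()`, `if_else()`,
#' `desc()`, `map_dbl()`, and the structural helpers `(`, `[`, `[[` and `c`.
#'
#' @param name function name as it appears in expressions.
#' @param fn the implementation.
#' @export
register_mask_function <- function(name, fn) {
  assign(name, fn, envir = .amx_registry)
  invisible(name)
}

#' @rdname register_mask_function
#' @export
mask_functions <- function() sort(ls(.amx_registry))

amx_if_else <- function(condition, true, false, missing = NA) {
  len <- length(condition)
  recyc <- function(v, what) {
    if (length(v) == len) return(v)
    if (length(v) == 1L) return(rep(v, length.out = max(len, 1L))[seq_len(len)])
    stop("if_else: `", what, "` has length ", length(v), ", expected 1 or ", len)
  }
  t <- recyc(true, "true"); f <- recyc(false, "false")
  out <- t
  sel <- !is.na(condition) & !condition
  out[sel] <- f[sel]
  out[is.na(condition)] <- missing
  dim(out) <- dim(condition)
  out
}

local({
  base_ops <- c("+", "-", "*", "/", "^", "%%", "%/%",
                "==", "!=", "<", "<=", ">", ">=", "!", "&", "|", "&&", "||",
                "(", "[", "[[", "c", ":",
                "log", "log1p", "log2", "log10", "exp", "sqrt", "abs",
                "round", "floor", "ceiling",
                "mean", "sum", "min", "max", "is.na")
  for (op in base_ops) assign(op, get(op, baseenv()), envir = .amx_registry)
  assign("median", stats::median, envir = .amx_registry)
  # var/sd reduce matrices to one scalar over all cells (stats::var on a
  # matrix would compute a covariance matrix, which is never size-stable)
  assign("var", function(x, na.rm = FALSE) stats::var(as.vector(x), na.rm = na.rm),
         envir = .amx_registry)
  assign("sd", function(x, na.rm = FALSE) stats::sd(as.vector(x), na.rm = na.rm),
         envir = .amx_registry)
  assign("row_means", function(x, na.rm = FALSE) rowMeans(x, na.rm = na.rm), envir = .amx_registry)
  assign("col_means", function(x, na.rm = FALSE) colMeans(x, na.rm = na.rm), envir = .amx_registry)
  assign("row_sums",  function(x, na.rm = FALSE) rowSums(x, na.rm = na.rm),  envir = .amx_registry)
  assign("col_sums",  function(x, na.rm = FALSE) colSums(x, na.rm = na.rm),  envir = .amx_registry)
  assign("if_else", amx_if_else, envir = .amx_registry)
  # purrr-style mapping over list-reshaped pronoun values
  assign("map_dbl", function(.x, .f, ...) vapply(.x, .f, numeric(1), ...),
         envir = .amx_registry)
  assign("desc", function(x) structure(list(key = x), class = "amx_desc"), envir = .amx_registry)
  # n() and row_number() are rebound per frame with the block sizes
  assign("n", function() stop("n() may only be used inside a verb"), envir = .amx_registry)
  assign("row_number", function() stop("row_number() may only be used inside a verb"),
         envir = .amx_registry)
})

## ---- pronouns -----------------------------------------------------------

.amx_pronoun_names <- c(".assays", ".rows", ".cols",
                        ".assays_asis", ".rows_asis", ".cols_asis")

make_pronoun <- function(frame, target, variant) {
  force(frame); force(target); force(variant)
  pr <- new.env(parent = emptyenv())
  pr[["..fetch"]] <- function(name) frame_fetch(frame, target, variant, name)
  class(pr) <- "amx_pronoun"
  pr
}

#' @export
`$.amx_pronoun` <- function(x, name) get("..fetch", envir = x)(name)

#' @export
`[[.amx_pronoun` <- function(x, name) get("..fetch", envir = x)(as.character(name))

#' @export
print.amx_pronoun <- function(x, ...) {
  cat("<context pronoun>\n")
  invisible(x)
}

## ---- context frames -----------------------------------------------------

#' Build an evaluation frame for one context
#'
#' The frame exposes the context's own names as direct (lazy) bindings,
#' pronouns into all three contexts in both `asis` and `reshaped` variants,
#' the registered function whitelist, and a caller fallback searched last --
#' symbols inside the mask always shadow the caller. Reshaped pronoun values
#' are computed lazily, on first access, and memoized for the lifetime of
#' the frame; the `reshape_count` counter records how many reshaping
#' computations actually ran.
#'
#' @param obj an `AnnotatedMatrix`.
#' @param context `"assays"`, `"rows"` or `"cols"`.
#' @param caller_fallback environment in which symbols not found in the mask
#'   are resolved.
#' @param view optional `list(rows=, cols=)` index vectors restricting the
#'   frame to one group block.
#' @return a `ContextFrame` (an environment; evaluate expressions in it with
#'   [amx_evaluate()]).
#' @export
build_frame <- function(obj, context = c("assays", "rows", "cols"),
                        caller_fallback = parent.frame(), view = NULL) {
  context <- match.arg(context)
  fr <- new.env(parent = emptyenv())
  fr$context <- context
  fr$obj <- obj
  ri <- if (is.null(view)) seq_len(obj$dim[1L]) else as.integer(view$rows)
  ci <- if (is.null(view)) seq_len(obj$dim[2L]) else as.integer(view$cols)
  fr$rows_idx <- ri
  fr$cols_idx <- ci
  fr$nb <- length(ri)
  fr$pb <- length(ci)
  fr$reshape_count <- 0L
  fr$cache <- new.env(parent = emptyenv())

  fn_env <- list2env(as.list(.amx_registry, all.names = TRUE),
                     parent = caller_fallback)
  block_records <- switch(context,
                          assays = fr$nb * fr$pb, rows = fr$nb, cols = fr$pb)
  fn_env$n <- local({ k <- block_records; function() k })
  fn_env$row_number <- local({ k <- block_records; function() seq_len(k) })

  pro_env <- new.env(parent = fn_env)
  for (tgt in c("assays", "rows", "cols")) {
    assign(paste0(".", tgt), make_pronoun(fr, tgt, "reshaped"), envir = pro_env)
    assign(paste0(".", tgt, "_asis"), make_pronoun(fr, tgt, "asis"), envir = pro_env)
  }

  data_env <- new.env(parent = pro_env)
  own <- context_names(obj, context)
  for (nm in own) {
    local({
      nm_ <- nm
      delayedAssign(nm_, frame_own_value(fr, nm_),
                    assign.env = data_env, eval.env = environment())
    })
  }

  fr$data_env <- data_env
  fr$fn_env <- fn_env
  class(fr) <- "ContextFrame"
  fr
}

# a context's own binding: the stored value restricted to the frame's view
frame_own_value <- function(fr, name) {
  obj <- fr$obj
  switch(fr$context,
    assays = obj$assays[[name]][fr$rows_idx, fr$cols_idx, drop = FALSE],
    rows   = obj$row_data[[name]][fr$rows_idx],
    cols   = obj$col_data[[name]][fr$cols_idx]
  )
}

# pronoun access with laziness + memoization; reshapes are counted
frame_fetch <- function(fr, target, variant, name) {
  key <- paste(target, variant, name, sep = "\x01")
  if (!is.null(fr$cache[[key]])) return(fr$cache[[key]])
  obj <- fr$obj
  stored <- switch(target,
    assays = {
      if (!name %in% context_names(obj, "assays"))
        stop(sprintf("no name '%s' in assays context", name))
      obj$assays[[name]][fr$rows_idx, fr$cols_idx, drop = FALSE]
    },
    rows = {
      if (!name %in% names(obj$row_data))
        stop(sprintf("no name '%s' in rows context", name))
      obj$row_data[[name]][fr$rows_idx]
    },
    cols = {
      if (!name %in% names(obj$col_data))
        stop(sprintf("no name '%s' in cols context", name))
      obj$col_data[[name]][fr$cols_idx]
    })

  val <- if (variant == "asis" || target == fr$context) {
    stored
  } else if (fr$context == "assays") {
    fr$reshape_count <- fr$reshape_count + 1L
    if (target == "rows") broadcast_row_to_assay(stored, fr$pb)
    else broadcast_col_to_assay(stored, fr$nb)
  } else if (target == "assays") {
    fr$reshape_count <- fr$reshape_count + 1L
    if (fr$context == "rows") {
      slice_assay_to_rows(stored, names = obj$row_names[fr$rows_idx])
    } else {
      slice_assay_to_cols(stored, names = obj$col_names[fr$cols_idx])
    }
  } else {
    stop(sprintf(paste0("no size-stable reshape of %s data into the %s ",
                        "context; use .%s_asis"), target, fr$context, target))
  }
  fr$cache[[key]] <- val
  val
}

#' @export
print.ContextFrame <- function(x, ...) {
  cat(sprintf("<ContextFrame: %s context, block %d x %d>\n",
              x$context, x$nb, x$pb))
  invisible(x)
}

## ---- evaluation ---------------------------------------------------------

# reject any call to a function outside the registry; `$` is only legal as
# pronoun access
assert_whitelisted <- function(expr) {
  if (is.symbol(expr) || is.atomic(expr) || is.null(expr)) return(invisible(TRUE))
  if (is.call(expr)) {
    head <- expr[[1L]]
    if (is.symbol(head) && as.character(head) == "$") {
      tgt <- expr[[2L]]
      if (!(is.symbol(tgt) && as.character(tgt) %in% .amx_pronoun_names))
        stop("`$` is only allowed after a context pronoun (",
             paste(.amx_pronoun_names, collapse = ", "), ")")
      return(invisible(TRUE))
    }
    if (!is.symbol(head))
      stop("anonymous or computed functions are not allowed in mask expressions")
    fn <- as.character(head)
    if (!exists(fn, envir = .amx_registry, inherits = FALSE))
      stop(sprintf("function '%s' is not in the evaluation whitelist", fn))
    args <- as.list(expr)[-1L]
    for (i in seq_along(args)) {
      if (identical(args[i], list(quote(expr = )))) next  # empty arg, e.g. x[1, ]
      assert_whitelisted(args[[i]])
    }
    return(invisible(TRUE))
  }
  stop("unsupported expression node: ", typeof(expr))
}

#' Evaluate an expression inside a context frame
#'
#' Symbols resolve mask-first: the context's own bindings shadow pronouns,
#' whitelisted functions, and finally the caller fallback. Calls to
#' functions outside the whitelist are rejected before any evaluation.
#'
#' @param expr an unevaluated R expression (quoted call, symbol or literal).
#' @param frame a `ContextFrame` from [build_frame()].
#' @return the value of the expression.
#' @export
amx_evaluate <- function(expr, frame) {
  assert_whitelisted(expr)
  withCallingHandlers(
    tryCatch(
      eval(expr, envir = frame$data_env),
      error = function(e) {
        msg <- conditionMessage(e)
        m <- regmatches(msg, regexec("^object '([^']+)' not found$", msg))[[1L]]
        if (length(m) == 2L)
          stop(sprintf("unresolved symbol '%s' in %s context", m[2L], frame$context),
               call. = FALSE)
        stop(e)
      }),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' Enforce size stability of an evaluation result
#'
#' An assays-context result must be an `n x p` matrix, a rows-context result
#' a vector of length `n`, a cols-context result a vector of length `p`
#' (block sizes under grouping). Scalars are recycled to the expected size;
#' any other size is an error.
#'
#' @param value the evaluation result.
#' @param context `"assays"`, `"rows"` or `"cols"`.
#' @param expected `c(n, p)` for assays, a single length otherwise.
#' @return `value`, possibly recycled.
#' @export
check_size_stable <- function(value, context, expected) {
  if (context == "assays") {
    nb <- expected[1L]; pb <- expected[2L]
    if (is.matrix(value) && nrow(value) == nb && ncol(value) == pb) return(value)
    if (is.atomic(value) && !is.matrix(value) && length(value) == 1L)
      return(matrix(value, nb, pb))
    got <- if (is.matrix(value)) paste0(nrow(value), "x", ncol(value))
           else paste0("length-", length(value))
    stop(sprintf("size-stability violation in assays context: got %s, want %dx%d",
                 got, nb, pb), call. = FALSE)
  }
  len <- expected[1L]
  if (is.matrix(value))
    stop(sprintf("size-stability violation in %s context: got %dx%d matrix, want length-%d vector",
                 context, nrow(value), ncol(value), len), call. = FALSE)
  if (length(value) == len) return(value)
  if (length(value) == 1L && is.atomic(value)) return(rep(value, len))
  stop(sprintf("size-stability violation in %s context: got length-%d, want length-%d",
               context, length(value), len), call. = FALSE)
}
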