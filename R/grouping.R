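#' Build a grouping specification for one axis
#'
#' A grouping is a partition of one axis's indices induced by one or more
#' metadata variables: every index belongs to exactly one group, group keys
#' appear in first-appearance order along the axis, and missing values form
#' their own group. Only partitions of whole rows or whole columns are
#' representable -- partitioning arbitrary matrix cells would not yield
#' valid sub-matrices.
#'
#' @param axis `"rows"` or `"cols"`.
#' @param variables character vector of metadata column names.
#' @param table the metadata table the variables live in.
#' @return a `GroupingSpec`: list with `axis`, `variables`, `partition`
#'   (named list of ascending 1-based index vectors, names are the composite
#'   group keys) and `keys` (data.frame of the variable values per group).
#' @export
grouping_spec <- function(axis = c("rows", "cols"), variables, table) {
  axis <- match.arg(axis)
  variables <- as.character(variables)
  bad <- setdiff(variables, names(table))
  if (length(bad))
    stop(sprintf("grouping variable(s) not found in %s metadata: %s",
                 axis, paste(bad, collapse = ", ")))
  len <- nrow(table)
  key <- group_key_strings(table[variables])
  ukey <- unique(key)                       # first-appearance order
  partition <- lapply(ukey, function(k) which(key == k))
  names(partition) <- ukey
  keys <- table[match(ukey, key), variables, drop = FALSE]
  attr(keys, "row.names") <- if (length(ukey)) seq_along(ukey) else integer()
  structure(list(axis = axis, variables = variables,
                 partition = partition, keys = keys),
            class = "GroupingSpec")
}

# composite key per record; NA gets a private sentinel so it groups with
# itself but never with the literal string "NA"
group_key_strings <- function(cols) {
  len <- if (length(cols)) length(cols[[1L]]) else 0L
  if (!length(cols)) return(rep("", len))
  parts <- lapply(cols, function(v) {
    s <- as.character(v)
    s[is.na(v)] <- "\x01<NA>\x01"
    s
  })
  do.call(paste, c(parts, sep = "\x02"))
}

#' Effective evaluation blocks for a context
#'
#' The assays context respects groupings on both axes and therefore sees the
#' cross-product of row groups and column groups; the rows context drops any
#' cols grouping and the cols context drops any rows grouping. An ungrouped
#' axis contributes a single group spanning the whole axis.
#'
#' @param obj an `AnnotatedMatrix`.
#' @param context `"assays"`, `"rows"` or `"cols"`.
#' @return ordered list of blocks, each `list(rows = <row index vector>,
#'   cols = <col index vector>)`. Assays blocks enumerate column groups
#'   within each row group (row-group-major over the group grid).
#' @export
effective_partition <- function(obj, context = c("assays", "rows", "cols")) {
  context <- match.arg(context)
  n <- obj$dim[1L]; p <- obj$dim[2L]
  rg <- if (!is.null(obj$row_grouping)) obj$row_grouping$partition else list(seq_len(n))
  cg <- if (!is.null(obj$col_grouping)) obj$col_grouping$partition else list(seq_len(p))
  switch(context,
    assays = {
      out <- vector("list", length(rg) * length(cg))
      k <- 1L
      for (ri in rg) for (cj in cg) {
        out[[k]] <- list(rows = ri, cols = cj); k <- k + 1L
      }
      out
    },
    rows = lapply(rg, function(ri) list(rows = ri, cols = seq_len(p))),
    cols = lapply(cg, function(cj) list(rows = seq_len(n), cols = cj))
  )
}
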