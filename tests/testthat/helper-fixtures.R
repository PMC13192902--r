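# shared fixtures and the random verb-chain generator used by the
# property-style and acceptance suites

amx_equal <- amgram:::amx_equal

tiny_amx <- function() {
  annotated_matrix(
    assays = list(counts = matrix(c(1, 3, 2, 4), 2, 2)),
    row_data = data.frame(len = c(10, 20)),
    col_data = data.frame(grp = c("a", "b")))
}

# the running example: counts + tpm, gene length / chromosome, library
# size / condition
demo_amx <- function(n = 3, p = 2, seed = 101) {
  generate_fixture(n, p, n_assays = 2, n_row_vars = 2, n_col_vars = 2,
                   seed = seed)
}

# random fixture within the acceptance envelope (n <= 40, p <= 12,
# <= 3 assays)
random_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(0:40, 1, prob = c(1, rep(3, 40)))  # rarely empty
  p <- sample(0:12, 1, prob = c(1, rep(3, 12)))
  generate_fixture(n, p,
                   n_assays = sample(1:3, 1),
                   n_row_vars = sample(2:4, 1),
                   n_col_vars = sample(2:4, 1),
                   seed = seed + 1L)
}

# --- random verb chains over the whitelist -------------------------------
# every template is expressible both through the masked path and through
# the long-table oracle (reshaped pronouns only)

chain_templates <- function(has_tpm) {
  mut_assays <- c(
    "counts * 2", "log1p(counts)", "counts - mean(counts)",
    "counts / .rows$length", "counts / .cols$lib_size",
    "sqrt(abs(counts)) + 1",
    if (has_tpm) "counts + tpm", if (has_tpm) "tpm / 2")
  list(
    mutate_assays = mut_assays,
    mutate_rows = c("length * 2", "length - mean(length)", "length / sum(length)"),
    mutate_cols = c("lib_size / sum(lib_size)", "lib_size - mean(lib_size)"),
    filter_rows = c("length < 5000", "length >= 3000", "length < median(length)"),
    filter_cols = c("lib_size > median(lib_size)", "condition == \"trt\""),
    arrange_rows = c("length", "desc(length)", "chr"),
    arrange_cols = c("lib_size", "desc(lib_size)", "condition"),
    group_rows = "chr", group_cols = "condition",
    sum_assays = c("sum(counts)", "mean(counts)", "max(counts)"),
    sum_rows = c("mean(length)", "sum(length)"),
    sum_cols = c("mean(lib_size)", "sum(lib_size)"))
}

random_chain <- function(seed, obj, max_len = 5) {
  set.seed(seed)
  tpl <- chain_templates("tpm" %in% context_names(obj, "assays"))
  len <- sample(1:max_len, 1)
  steps <- list()
  nm_i <- 0L
  new_name <- function() { nm_i <<- nm_i + 1L; paste0("v", nm_i) }
  item <- function(context, name, code)
    list(context = context, name = name, expr = str2lang(code))
  for (k in seq_len(len)) {
    kind <- sample(c("mutate", "filter", "arrange", "group_by", "summarize"),
                   1, prob = c(4, 2, 2, 2, 1))
    steps[[k]] <- switch(kind,
      mutate = {
        ctx <- sample(c("assays", "rows", "cols"), 1, prob = c(3, 1, 1))
        code <- sample(tpl[[paste0("mutate_", ctx)]], 1)
        verb_call("mutate", list(item(ctx, new_name(), code)))
      },
      filter = {
        ctx <- sample(c("rows", "cols"), 1)
        verb_call("filter", list(item(ctx, NULL,
                                      sample(tpl[[paste0("filter_", ctx)]], 1))))
      },
      arrange = {
        ctx <- sample(c("rows", "cols"), 1)
        verb_call("arrange", list(item(ctx, NULL,
                                       sample(tpl[[paste0("arrange_", ctx)]], 1))))
      },
      group_by = {
        ctx <- sample(c("rows", "cols"), 1)
        verb_call("group_by", list(item(ctx, NULL,
                                        tpl[[paste0("group_", ctx)]])))
      },
      summarize = {
        its <- list(item("assays", new_name(), sample(tpl$sum_assays, 1)))
        if (sample(c(TRUE, FALSE), 1))
          its <- c(its, list(item("rows", new_name(), sample(tpl$sum_rows, 1))))
        if (sample(c(TRUE, FALSE), 1))
          its <- c(its, list(item("cols", new_name(), sample(tpl$sum_cols, 1))))
        verb_call("summarize", its)
      })
    if (kind == "summarize") break  # summarize changes the vocabulary
  }
  steps
}

# run a chain through the container path
run_chain_container <- function(obj, steps) {
  for (vc in steps) obj <- apply_verb(obj, vc, caller = baseenv())
  obj
}

# run it through the long-form oracle and rebuild a container
run_chain_oracle <- function(obj, steps) {
  st <- amgram:::oracle_state(obj)
  for (vc in steps) st <- amgram:::oracle_apply(st, vc)
  amgram:::oracle_result(st)
}

expect_chain_equiv <- function(obj, steps, tol = 1e-12) {
  got <- amgram:::amx_ungroup(run_chain_container(obj, steps))
  want <- run_chain_oracle(obj, steps)
  expect_true(amx_equal(got, want, tol = tol),
              label = sprintf("container path == oracle path for chain: %s",
                              paste(vapply(steps, function(vc) vc$verb, ""),
                                    collapse = " |> ")))
  got
}
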