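test_that("mutate stores results in the addressed context", {
  am <- annotated_matrix(
    assays = list(counts = matrix(c(0, 2, 1, 3), 2, 2)),
    row_data = data.frame(len = c(5, 6)),
    col_data = data.frame(lib_size = c(5, 15)))
  m <- mutate(am, logcounts = log1p(counts), cols(filtered = lib_size > 10))
  expect_identical(m$assays$logcounts, log1p(am$assays$counts))
  expect_identical(m$assays$counts, am$assays$counts)  # original untouched
  expect_identical(m$col_data$filtered, c(FALSE, TRUE))
  # overwrite under an existing name
  m2 <- mutate(am, counts = counts * 0)
  expect_identical(m2$assays$counts, matrix(0, 2, 2))
  expect_error(mutate(am, .rows = counts), "reserved pronoun name")
  expect_error(mutate(am, counts + 1), "must be named")
})

test_that("mutate items evaluate left to right across contexts", {
  am <- tiny_amx()
  m <- mutate(am, rows(a = len * 2), b = .rows$a * counts)
  expect_identical(m$row_data$a, c(20, 40))
  expect_identical(m$assays$b, broadcast_row_to_assay(c(20, 40), 2) * am$assays$counts)
})

test_that("mutate(x = x) is the identity in every context", {
  fx <- generate_fixture(5, 3, seed = 11)
  expect_true(amx_equal(mutate(fx, counts = counts), fx))
  expect_true(amx_equal(mutate(fx, rows(length = length)), fx))
  expect_true(amx_equal(mutate(fx, cols(lib_size = lib_size)), fx))
})

test_that("grouped mutate centers by block and matches the oracle", {
  am <- annotated_matrix(
    assays = list(counts = matrix(c(1, 2, 3, 4, 10, 20), 2, 3)),
    col_data = data.frame(grp = c("a", "a", "b")),
    row_data = data.frame(id = 1:2))
  g <- group_by(am, cols(grp))
  m <- mutate(g, centered = counts - mean(counts))
  blk_a <- am$assays$counts[, 1:2]
  blk_b <- am$assays$counts[, 3, drop = FALSE]
  want <- cbind(blk_a - mean(blk_a), blk_b - mean(blk_b))
  expect_identical(m$assays$centered, want)
  # long-form oracle agrees
  st <- amgram:::oracle_state(g)
  st <- amgram:::oracle_apply(st, verb_call("mutate", list(
    list(context = "assays", name = "centered",
         expr = quote(counts - mean(counts))))))
  expect_true(amx_equal(amgram:::amx_ungroup(m), amgram:::oracle_result(st)))
})

test_that("filter subsets axes, ANDs predicates, and rejects assay predicates", {
  am <- annotated_matrix(
    assays = list(counts = matrix(1:6, 3, 2)),
    row_data = data.frame(len = c(100, 5000, 200)),
    col_data = data.frame(grp = c("a", "b")))
  f <- filter(am, rows(len < 1000))
  expect_identical(dim(f), c(2L, 2L))
  expect_identical(f$row_data$len, c(100, 200))

  f2 <- filter(am, rows(len < 1000), cols(grp == "a"))
  expect_identical(dim(f2), c(2L, 1L))

  f3 <- filter(am, rows(len < 1000), rows(len > 150))
  expect_identical(f3$row_data$len, 200)

  expect_error(filter(am, counts > 5), "rows or cols contexts")

  # missing predicate values drop the record, with a log message
  am_na <- mutate(am, rows(len = c(100, NA, 200)))
  expect_message(fna <- filter(am_na, rows(len < 1000)), "1 record")
  expect_identical(dim(fna), c(2L, 2L))

  # all-true is identity; all-false empties the axis but still validates
  expect_true(amx_equal(filter(am, rows(len > 0)), am))
  f0 <- filter(am, rows(len < 0))
  expect_identical(dim(f0), c(0L, 2L))
  expect_identical(amx_validate(f0), f0)
})

test_that("select keeps named variables per context and retains grouping vars", {
  fx <- generate_fixture(4, 3, n_assays = 2, n_row_vars = 3, seed = 5)
  s <- select(fx, counts)
  expect_identical(context_names(s, "assays"), "counts")
  expect_identical(names(s$row_data), names(fx$row_data))  # untargeted context
  s2 <- select(fx, rows(length))
  expect_identical(names(s2$row_data), "length")
  expect_error(select(fx, nope), "no assay named 'nope'")
  g <- group_by(fx, rows(chr))
  s3 <- select(g, rows(length))
  expect_true("chr" %in% names(s3$row_data))  # grouping var implicitly kept
})

test_that("arrange sorts stably with desc support and permutes everything", {
  am <- annotated_matrix(
    assays = list(counts = matrix(1:6, 3, 2)),
    row_data = data.frame(len = c(30, 10, 20)),
    col_data = data.frame(lib_size = c(1, 2)))
  a <- arrange(am, rows(len))
  expect_identical(a$row_data$len, c(10, 20, 30))
  expect_identical(a$assays$counts, am$assays$counts[c(2, 3, 1), ])

  # stability: all-equal keys leave the object unchanged
  expect_true(amx_equal(arrange(am, rows(len * 0)), am))

  d <- arrange(am, cols(desc(lib_size)))
  expect_identical(d$col_data$lib_size, c(2, 1))
  expect_identical(d$assays$counts, am$assays$counts[, c(2, 1)])

  expect_error(arrange(am, counts), "rows or cols")

  # ties broken by original order under a second key
  am2 <- annotated_matrix(row_data = data.frame(k = c(1, 1, 0), id = 1:3),
                          dim = c(3, 0))
  a2 <- arrange(am2, rows(k))
  expect_identical(a2$row_data$id, c(3L, 1L, 2L))
})

test_that("group_by partitions an axis; assays grouping is rejected", {
  am <- annotated_matrix(
    assays = list(counts = matrix(1:6, 2, 3)),
    row_data = data.frame(chr = c("c1", "c2")),
    col_data = data.frame(grp = c("a", "b", "a")))
  g <- group_by(am, cols(grp))
  expect_identical(g$col_grouping$partition, list(a = c(1L, 3L), b = 2L))
  g2 <- group_by(g, rows(chr))
  expect_identical(names(g2$row_grouping$partition), c("c1", "c2"))
  expect_identical(g2$col_grouping$partition, g$col_grouping$partition)
  expect_error(group_by(am, counts > 100), "partition rows or columns")
  # missing values form their own group
  am_na <- annotated_matrix(row_data = data.frame(x = c("a", NA, "a")),
                            dim = c(3, 0))
  gna <- group_by(am_na, rows(x))
  expect_identical(length(gna$row_grouping$partition), 2L)
  expect_identical(unname(gna$row_grouping$partition[[2L]]), 2L)
  # regrouping replaces the axis spec; ungroup clears
  g3 <- group_by(g, cols(grp))
  expect_identical(g3$col_grouping$variables, "grp")
  expect_true(amx_equal(ungroup(g), am))
  expect_null(ungroup(g)$col_grouping)
  # partial ungroup
  both <- group_by(am, rows(chr), cols(grp))
  ru <- amgram:::amx_ungroup(both, "rows")
  expect_null(ru$row_grouping)
  expect_false(is.null(ru$col_grouping))
})

test_that("effective_partition crosses assays blocks and drops the other axis", {
  am <- annotated_matrix(
    assays = list(counts = matrix(0, 3, 3)),
    row_data = data.frame(rg = c("A", "A", "B")),
    col_data = data.frame(cg = c("x", "y", "y")))
  g <- group_by(am, rows(rg), cols(cg))
  blocks <- effective_partition(g, "assays")
  expect_length(blocks, 4L)
  expect_identical(blocks[[1L]], list(rows = c(1L, 2L), cols = 1L))
  expect_identical(blocks[[2L]], list(rows = c(1L, 2L), cols = c(2L, 3L)))
  expect_identical(blocks[[4L]], list(rows = 3L, cols = c(2L, 3L)))
  rb <- effective_partition(g, "rows")
  expect_length(rb, 2L)
  expect_identical(rb[[1L]], list(rows = c(1L, 2L), cols = 1:3))
  cb <- effective_partition(g, "cols")
  expect_length(cb, 2L)
  expect_identical(cb[[2L]], list(rows = 1:3, cols = c(2L, 3L)))
  expect_length(effective_partition(am, "assays"), 1L)
})

test_that("summarize collapses to the group grid", {
  am <- annotated_matrix(assays = list(counts = matrix(c(1, 3, 2, 4), 2, 2)))
  s <- summarize(am, total = sum(counts))
  expect_identical(dim(s), c(1L, 1L))
  expect_identical(s$assays$total, matrix(10, 1, 1))
  expect_null(s$row_grouping)

  am2 <- annotated_matrix(assays = list(counts = matrix(c(1, 2, 3), 3, 1)),
                          row_data = data.frame(g = c("A", "A", "B")))
  s2 <- summarize(group_by(am2, rows(g)), s = sum(counts))
  expect_identical(s2$assays$s, matrix(c(3, 3), 2, 1))
  expect_identical(s2$row_data$g, c("A", "B"))

  am3 <- annotated_matrix(
    assays = list(counts = matrix(0, 1, 3)),
    col_data = data.frame(grp = c("a", "a", "b"), lib_size = c(2, 4, 9)))
  s3 <- summarize(group_by(am3, cols(grp)), cols(m = mean(lib_size)))
  expect_identical(dim(s3), c(1L, 2L))
  expect_identical(s3$col_data$m, c(3, 9))
  # long-form oracle computes the same grouped mean
  st <- amgram:::oracle_state(group_by(am3, cols(grp)))
  st <- amgram:::oracle_apply(st, verb_call("summarize", list(
    list(context = "cols", name = "m", expr = quote(mean(lib_size))))))
  expect_true(amx_equal(s3, amgram:::oracle_result(st), tol = 1e-12))

  # non-scalar block results are a size-stability error
  expect_error(summarize(am2, bad = counts * 1), "one value")
  # non-grouping metadata is dropped, not silently aggregated
  fx <- generate_fixture(6, 4, seed = 3)
  sg <- summarize(group_by(fx, rows(chr)), m = mean(counts))
  expect_identical(names(sg$row_data), "chr")
})

test_that("pull returns stored values and respects copy semantics", {
  am <- tiny_amx()
  expect_identical(pull(am, counts), am$assays$counts)
  expect_identical(pull(am, rows(len)), c(10, 20))
  expect_identical(pull(am, "len", context = "rows"), c(10, 20))
  expect_error(pull(am, cols(nope)), "no name 'nope' in cols context")
  v <- pull(am, counts)
  v[1, 1] <- 999
  expect_identical(am$assays$counts[1, 1], 1)  # container unaffected
})

test_that("slice keeps positional selections", {
  am <- annotated_matrix(assays = list(counts = matrix(1:6, 3, 2)),
                         row_data = data.frame(i = 1:3))
  s <- slice(am, rows(c(3, 1)))
  expect_identical(s$row_data$i, c(3L, 1L))
  s2 <- slice(am, rows(row_number()))   # identity positions
  expect_true(amx_equal(s2, am))
  expect_error(slice(am, rows(c(0, 5))), "out of range")
})

test_that("every verb output validates across a randomized suite", {
  for (s in 1:15) {
    fx <- random_fixture(300 + s)
    steps <- random_chain(400 + s, fx)
    out <- run_chain_container(fx, steps)
    expect_identical(amx_validate(out), out)
  }
})
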