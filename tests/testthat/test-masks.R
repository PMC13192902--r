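test_that("broadcast and slice primitives obey their defining rules", {
  expect_identical(broadcast_row_to_assay(c(1, 2, 3), 2),
                   matrix(c(1, 2, 3, 1, 2, 3), 3, 2))
  expect_identical(dim(broadcast_row_to_assay(numeric(), 4)), c(0L, 4L))
  expect_identical(broadcast_row_to_assay(5, 1), matrix(5, 1, 1))

  expect_identical(broadcast_col_to_assay(c(10, 20), 2),
                   matrix(c(10, 10, 20, 20), 2, 2))
  expect_identical(broadcast_col_to_assay(7, 3), matrix(7, 3, 1))
  expect_identical(dim(broadcast_col_to_assay(numeric(), 2)), c(2L, 0L))

  m <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_identical(slice_assay_to_rows(m), list(c(1, 2), c(3, 4)))
  expect_identical(slice_assay_to_rows(matrix(0, 0, 3)), list())
  expect_identical(slice_assay_to_rows(matrix(1:3, 1, 3),
                                       names = "g"), list(g = 1:3))
  expect_identical(slice_assay_to_cols(m), list(c(1, 3), c(2, 4)))
  expect_identical(slice_assay_to_cols(matrix(0, 3, 0)), list())
  expect_identical(slice_assay_to_cols(matrix(c(1, 2), 2, 1)), list(c(1, 2)))
})

test_that("broadcast/slice round trips and transpose duality hold", {
  set.seed(99)
  for (trial in 1:250) {
    n <- sample(0:8, 1); p <- sample(0:8, 1)
    v <- rnorm(n)
    M <- broadcast_row_to_assay(v, p)
    rows <- slice_assay_to_rows(M)
    for (i in seq_len(n)) expect_identical(rows[[i]], rep(v[i], p))
    # transpose duality
    w <- rnorm(p)
    expect_identical(broadcast_col_to_assay(w, n),
                     t(broadcast_row_to_assay(w, n)))
    # slicing is exact on random matrices
    A <- matrix(rnorm(n * p), n, p)
    cols <- slice_assay_to_cols(A)
    for (j in seq_len(p)) expect_identical(cols[[j]], A[, j])
  }
})

test_that("frames resolve pronouns via the four reshaping operations", {
  am <- demo_amx(3, 2)
  n <- 3; p <- 2
  fr_a <- build_frame(am, "assays")
  expect_identical(fr_a$context, "assays")
  got <- amx_evaluate(quote(.rows$length), fr_a)
  expect_identical(got, broadcast_row_to_assay(am$row_data$length, p))
  got2 <- amx_evaluate(quote(.cols$lib_size), fr_a)
  expect_identical(got2, broadcast_col_to_assay(am$col_data$lib_size, n))

  fr_r <- build_frame(am, "rows")
  lst <- amx_evaluate(quote(.assays$counts), fr_r)
  expect_identical(unname(lst), slice_assay_to_rows(am$assays$counts))
  expect_identical(names(lst), am$row_names)

  fr_c <- build_frame(am, "cols")
  expect_identical(amx_evaluate(quote(.assays_asis$counts), fr_c),
                   am$assays$counts)  # asis is identity on the stored value
  lstc <- amx_evaluate(quote(.assays$counts), fr_c)
  expect_identical(unname(lstc), slice_assay_to_cols(am$assays$counts))
})

test_that("evaluation matches the unwound per-cell computation", {
  am <- annotated_matrix(
    assays = list(counts = matrix(c(2, 6, 4, 8), 2, 2)),
    row_data = data.frame(len = c(1, 2)),
    col_data = data.frame(grp = c("a", "b")))
  fr <- build_frame(am, "assays")
  got <- amx_evaluate(quote(counts / .rows$len), fr)
  # independent oracle: per-cell division on the unwound table
  u <- unwind(am)
  want <- matrix((u$counts / u$len)[order(u$col_index, u$row_index)], 2, 2)
  expect_identical(got, want)
  expect_identical(got, matrix(c(2, 3, 4, 4), 2, 2))

  am2 <- annotated_matrix(assays = list(
    counts = matrix(c(0, exp(1) - 1, 1, exp(2) - 1), 2, 2)))
  fr2 <- build_frame(am2, "assays")
  expect_equal(amx_evaluate(quote(log1p(counts)), fr2),
               matrix(c(0, 1, log(2), 2), 2, 2))
})

test_that("evaluation errors name the unresolved symbol and blocked function", {
  am <- tiny_amx()
  fr <- build_frame(am, "assays", caller_fallback = emptyenv())
  expect_error(amx_evaluate(quote(mean(counts * weights)), fr),
               "unresolved symbol 'weights' in assays context")
  expect_error(amx_evaluate(quote(system("ls")), fr),
               "not in the evaluation whitelist")
  expect_error(amx_evaluate(quote(.nope$x), fr), "pronoun")
  fr_r <- build_frame(am, "rows")
  expect_error(amx_evaluate(quote(.cols$len), fr_r), "no name 'len' in cols context")
  # rows data has no size-stable reshape into cols context
  fr_c <- build_frame(am, "cols")
  expect_error(amx_evaluate(quote(.rows$len), fr_c), "asis")
})

test_that("symbols in the mask shadow the caller; fallback works", {
  am <- tiny_amx()
  env <- new.env()
  env$len <- "caller value"     # shadowed by the rows binding
  env$offset <- 100             # only in the caller
  fr <- build_frame(am, "rows", caller_fallback = env)
  expect_identical(amx_evaluate(quote(len), fr), c(10, 20))
  expect_identical(amx_evaluate(quote(len + offset), fr), c(110, 120))
})

test_that("reshaped pronouns are lazy and memoized", {
  am <- demo_amx(4, 3)
  fr <- build_frame(am, "assays")
  amx_evaluate(quote(counts * 2), fr)
  expect_identical(fr$reshape_count, 0L)      # no pronoun touched: no reshape
  amx_evaluate(quote(counts / .rows$length + .rows$length), fr)
  expect_identical(fr$reshape_count, 1L)      # two accesses, one computation
  amx_evaluate(quote(.rows$length), fr)
  expect_identical(fr$reshape_count, 1L)      # still cached within the frame
  amx_evaluate(quote(.cols$lib_size), fr)
  expect_identical(fr$reshape_count, 2L)
  # asis access never reshapes
  fr2 <- build_frame(am, "rows")
  amx_evaluate(quote(row_means(.assays_asis$counts)), fr2)
  expect_identical(fr2$reshape_count, 0L)
})

test_that("check_size_stable recycles scalars and rejects bad shapes", {
  expect_identical(check_size_stable(0, "rows", 3), c(0, 0, 0))
  expect_identical(check_size_stable(c(1, 2, 3), "rows", 3), c(1, 2, 3))
  expect_error(check_size_stable(matrix(0, 2, 2), "assays", c(3, 2)),
               "got 2x2, want 3x2")
  expect_identical(check_size_stable(5, "assays", c(2, 2)), matrix(5, 2, 2))
  expect_error(check_size_stable(c(1, 2), "rows", 3), "length-2.*length-3")
  expect_error(check_size_stable(matrix(0, 3, 1), "rows", 3), "matrix")
  # partial recycling (length neither 1 nor target) is always an error
  expect_error(check_size_stable(c(1, 2), "cols", 4), "size-stability")
})

test_that("the function registry is extensible", {
  am <- tiny_amx()
  fr <- build_frame(am, "assays")
  expect_error(amx_evaluate(quote(double_it(counts)), fr), "whitelist")
  register_mask_function("double_it", function(x) 2 * x)
  expect_true("double_it" %in% mask_functions())
  fr2 <- build_frame(am, "assays")
  expect_identical(amx_evaluate(quote(double_it(counts)), fr2),
                   am$assays$counts * 2)
})
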