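test_that("unwind produces the column-major long form", {
  am <- annotated_matrix(
    assays = list(counts = matrix(c(1, 3, 2, 4), 2, 2)),
    row_data = data.frame(len = c(10, 20)),
    col_data = data.frame(grp = c("a", "b")))
  u <- unwind(am)
  expect_identical(names(u), c("row_index", "col_index", "counts", "len", "grp"))
  expect_identical(u$row_index, c(1L, 2L, 1L, 2L))
  expect_identical(u$col_index, c(1L, 1L, 2L, 2L))
  expect_identical(u$counts, c(1, 3, 2, 4))
  expect_identical(u$len, c(10, 20, 10, 20))
  expect_identical(u$grp, c("a", "a", "b", "b"))

  # 1x1 and empty containers
  u1 <- unwind(annotated_matrix(assays = list(x = matrix(7, 1, 1))))
  expect_identical(nrow(u1), 1L)
  u0 <- unwind(annotated_matrix(dim = c(0, 0)))
  expect_identical(nrow(u0), 0L)
  expect_identical(names(u0), c("row_index", "col_index"))
})

test_that("unwind resolves cross-context name collisions by suffixing", {
  am <- annotated_matrix(assays = list(score = matrix(0, 2, 1)),
                         row_data = data.frame(score = 1:2),
                         col_data = data.frame(score = 3))
  expect_warning(expect_warning(u <- unwind(am), "score.row"), "score.col")
  expect_identical(attr(u, "amx_schema")$row_vars, "score.row")
  # and the round trip restores the original names
  r <- suppressWarnings(rewind(unwind(am)))
  expect_true(amx_equal(am, r))
})

test_that("rewind validates the grid and metadata constancy", {
  am <- tiny_amx()
  u <- unwind(am)
  # inconsistent replicated metadata
  u_bad <- u; u_bad$len[3] <- 11  # (1,2) cell of row 1
  expect_error(rewind(u_bad), "len not constant within row 1")
  # missing cell
  u_miss <- u[-4L, ]
  expect_error(rewind(u_miss), "incomplete grid")
  expect_error(rewind(u[c(1:3, 3), ]), "incomplete grid")
})

test_that("rewind . unwind is the identity on data fields", {
  for (s in 1:25) {
    fx <- random_fixture(500 + s)
    expect_true(amx_equal(fx, rewind(unwind(fx))),
                label = paste("round trip, seed", 500 + s))
    u <- unwind(fx)
    expect_identical(nrow(u), dim(fx)[1L] * dim(fx)[2L])
  }
  # empty-axis containers keep their off-axis metadata through the trip
  z <- generate_fixture(0, 4, seed = 9)
  expect_true(amx_equal(z, rewind(unwind(z))))
  z2 <- generate_fixture(3, 0, seed = 10)
  expect_true(amx_equal(z2, rewind(unwind(z2))))
})

test_that("long-table TSV round trips with schema sidecar", {
  fx <- generate_fixture(5, 3, n_row_vars = 3, n_col_vars = 3, seed = 21,
                         missing_rate = 0.2)
  fx$assays$tpm[2, 2] <- NaN
  fx$assays$tpm[1, 3] <- Inf
  u <- unwind(fx)
  path <- tempfile(fileext = ".tsv")
  write_long_table(u, path)
  u2 <- read_long_table(path)
  expect_identical(names(u2), names(u))
  for (nm in names(u))
    expect_true(amgram:::values_equal(u[[nm]], u2[[nm]], tol = 0),
                label = paste("column", nm))
  expect_true(amx_equal(fx, rewind(u2)))
})

test_that("oracle executor agrees with hand-computed tidy semantics", {
  am <- annotated_matrix(
    assays = list(counts = matrix(c(1, 2, 3, 4, 10, 20), 2, 3)),
    row_data = data.frame(len = c(5, 10)),
    col_data = data.frame(grp = c("a", "a", "b")))
  st <- amgram:::oracle_state(am)
  st <- amgram:::oracle_apply(st, verb_call("mutate", list(
    list(context = "assays", name = "norm", expr = quote(counts / .rows$len)))))
  got <- amgram:::oracle_result(st)
  expect_identical(got$assays$norm, am$assays$counts / c(5, 10))
  st2 <- amgram:::oracle_apply(st, verb_call("group_by", list(
    list(context = "cols", name = NULL, expr = quote(grp)))))
  st2 <- amgram:::oracle_apply(st2, verb_call("summarize", list(
    list(context = "assays", name = "tot", expr = quote(sum(counts))))))
  out <- amgram:::oracle_result(st2)
  expect_identical(out$assays$tot, matrix(c(sum(1:4), 30), 1, 2))
  expect_identical(out$col_data$grp, c("a", "b"))
})
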