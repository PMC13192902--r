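---
title: "A context-scoped grammar for annotated matrix data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A context-scoped grammar for annotated matrix data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amgram)
```

## The data model

High-throughput experiments are routinely summarized as one or more $n
\times p$ matrices — counts or abundances over $n$ genomic features (rows)
and $p$ samples or cells (columns) — that only make sense together with a
feature metadata table of $n$ records and a sample metadata table of $p$
records. `amgram`'s `AnnotatedMatrix` bundles exactly these parts and keeps
them structurally consistent: every assay has the shared shape, the
metadata tables have exactly $n$ and $p$ records, and every verb re-checks
these invariants on its output.

The three parts define three **evaluation contexts**, each a separate
namespace with its own canonical size:

| context  | owns                      | size-stable result |
|----------|---------------------------|--------------------|
| `assays` | the matrices              | an $n \times p$ matrix |
| `rows`   | feature metadata vectors  | a length-$n$ vector |
| `cols`   | sample metadata vectors   | a length-$p$ vector |

Verb expressions evaluate in the assays context by default; wrapping items
in the sentinels `rows(...)` / `cols(...)` redirects both the evaluation
and where the result is stored:

```{r}
am <- generate_fixture(50, 6, n_assays = 2, seed = 1)
am |>
  mutate(logcounts = log1p(counts),
         cols(high_depth = lib_size > median(lib_size))) |>
  filter(rows(length < 5000))
```

## Pronouns and size stability

Cross-context reads go through pronouns, each in two variants. The *asis*
variants (`.assays_asis`, `.rows_asis`, `.cols_asis`) return the stored
value in its native shape, useful for optimized whole-matrix operations.
The *reshaped* variants (`.assays`, `.rows`, `.cols`) return a size-stable
transform of the value for the current context, built from four
deterministic operations:

* row vector into assays: replicate across the $p$ columns
  (`result[i,j] = v[i]`);
* col vector into assays: replicate down the $n$ rows
  (`result[i,j] = v[j]`);
* matrix into rows (cols): a list of the matrix's $n$ rows ($p$ columns).

There is deliberately *no* reshaped path between the two metadata contexts
(lengths $n$ and $p$ are unrelated); such access must be explicit via an
asis pronoun. Reshaped values are computed lazily on first access and
memoized per evaluation frame, so expressions that never touch a pronoun
never pay for reshaping — this is observable through the frame's
`reshape_count`.

Symbol resolution is mask-first: a context's own names shadow the
whitelisted functions and the caller's variables; anything not found in
the mask falls back to the calling environment. Only registered functions
may be *called* inside expressions (see `mask_functions()`;
`register_mask_function()` extends the set). The whitelist is enforced on
the expression tree before evaluation, which is also what makes the
pipeline DSL safe to run on untrusted scripts.

A result must match its context's canonical size; scalars are recycled,
and any other length — including classic partial recycling — is an error.
We consider silent partial recycling a bug generator, so recycling of
length ≠ 1 is rejected even when it divides the target length.

## Grouping

Only partitions of whole rows or whole columns are allowed: a predicate
over arbitrary matrix cells (say `counts > 100`) does not induce valid
sub-matrices, and `group_by(counts > 100)` is rejected with that
explanation. Row and column groupings are independent:

* the **assays** context evaluates per block of the cross-product
  (row groups × col groups);
* the **rows** context iterates row groups over all columns, ignoring any
  col grouping, and symmetrically for **cols**.

Group keys are ordered by first appearance along the axis (not sorted), so
grouping is insensitive to label encodings and deterministic for tests.
Missing values in grouping variables form their own group, which keeps
every partition exhaustive. `summarize()` collapses each grouped axis to
its group count and an *ungrouped* axis to length 1 (mirroring tidy
summarize-to-one-row semantics; the grammar itself is silent here).
Summarized assay items stay assays of shape $n' \times p'$, and
non-grouping metadata is dropped rather than implicitly aggregated —
implicit first-value aggregation hides bugs.

## The unwound oracle

The package carries its own reference implementation: `unwind()` flattens
a container into a long table with one record per assay cell
(column-major), replicating row and column metadata down the records, and
`rewind()` inverts it. Each verb has a long-form counterpart implemented
with plain split/apply/combine on data.frames, sharing no code with the
masked path. The package's principal correctness property — checked over
hundreds of randomized fixture/verb-chain pairs — is that the masked path
and the unwound path agree to $10^{-12}$ relative tolerance.

Two representational caveats are worth knowing. A pure record table cannot
carry an axis's metadata once the other axis is empty (a $0 \times p$
container has no records at all), so `unwind()` stores the axis tables in
its schema attribute in exactly that case, and the oracle's internal state
keeps the axis tables alongside the cell table throughout. Grouping state
does not survive the round trip; only grouping *variables* travel, and the
oracle re-groups explicitly.

## Synthetic data

`generate_fixture()` emulates a small expression experiment: `counts`
draws overdispersed negative-binomial integers with mean 100 and
dispersion size 2 (a defensible bulk RNA-seq regime); `tpm` and further
assays are positive gamma floats; features carry a positive integer
`length` (uniform over 200–10000 bases) and a `chr` category; samples
carry `lib_size` (the column sums of `counts`, so it behaves like a real
sequencing depth) and a `condition` cycling over `"trt"`/`"untrt"`.
`missing_rate` sprinkles `NA` into the *extra* metadata variables only, so
the canonical grouping variables stay complete. The generator is a pure
function of its arguments — Mersenne-Twister with inversion normals, fixed
permanently so seeds reproduce across releases — and restores the
caller's RNG state.

What a green test does establish: the algebra of contexts, pronouns,
grouping and serialization on realistic shapes, types, missingness and
degenerate axes. What it does not: behavior on sparse storage (inputs are
densified), very large data, or the idiosyncrasies of real annotation
(factor levels, duplicated aliases, genomic coordinates).

## Numerical and formatting choices

* Oracle comparisons use $10^{-12}$ *relative* tolerance (floating-point
  sums associate differently between the matrix and long paths); exact
  equality is asserted wherever both paths perform identical operations.
* Bundles and long tables print doubles with 17 significant digits
  (`%.17g`), which round-trips IEEE doubles exactly; `NA`, `NaN` and
  signed infinities are written literally. Matrix Market files use the
  `coordinate` layout when more than half the entries are zero and
  `array` otherwise; accepting `NA`/`NaN`/`Inf` entries is a documented
  extension of the standard required by the round-trip guarantees.
* `arrange()` uses a stable radix sort; equal keys preserve original
  order, and `desc()` negates the sort key. Keys are evaluated on the
  whole axis with grouping ignored.
* Filter predicates treat `NA` as drop (with a logged count), matching
  dominant tidy-filter behavior.
* All user-visible indices, the DSL, and on-disk MTX are 1-based.

## Open design points, as resolved here

* Names may collide *across* contexts (they are separate namespaces);
  sentinels and pronouns always disambiguate. `unwind()` is the one place
  collisions meet, and it suffixes `.row`/`.col` with a warning.
* Pronouns are read-only. Writing into another context is expressed by the
  sentinel that owns the destination, never through a pronoun.
* The asis pronoun spelling is `.<context>_asis`; the reshaped spelling is
  the plain `.<context>`.
* `filter()` and `arrange()` reject assays-context items outright for the
  same sub-matrix reason as grouping — stricter than the grammar strictly
  requires, and documented as such. `slice()` is positional filtering on
  an axis.
* `summarize()` keeps assay-context results as $n' \times p'$ assays
  rather than promoting them to metadata.

## Limitations

Dense in-memory matrices only; no joins across containers, nest/unnest, or
window functions beyond the whitelist reductions; the DSL deliberately
cannot call unregistered functions; the HDF5 interop shells out to a
bundled Python helper (requiring `python` with `anndata`) rather than
linking an R HDF5 library.
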