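# amgram

Tidy, context-scoped verbs for **annotated matrix data**: one or more
`n x p` assay matrices (genes on rows, samples on columns) linked to a
feature metadata table and a sample metadata table, as produced by bulk
and single-cell expression experiments.

Matrix-centric containers keep data and metadata consistent but force
analysts to learn container-specific indexing. `amgram` instead lets the
familiar verbs (`mutate`, `filter`, `arrange`, `group_by`, `summarize`,
`select`, `pull`, `slice`) operate on the whole container, with three
rules that remove the ambiguity that a matrix otherwise introduces:

1. **Explicit contexts.** Expressions evaluate in one of three scopes —
   *assays* (the matrices, size `n x p`), *rows* (feature metadata,
   length `n`), *cols* (sample metadata, length `p`). Bare items address
   the assays; `rows(...)` / `cols(...)` sentinels redirect both the
   evaluation and where the result is stored.
2. **Pronouns across contexts.** `.rows$length` inside an assays
   expression broadcasts the length-`n` vector to `n x p`
   (`result[i,j] = v[i]`); `.cols$lib_size` broadcasts along the other
   axis; `.assays$counts` inside a rows expression becomes the list of
   the matrix's rows. Every pronoun also has an `_asis` variant returning
   the stored shape (e.g. `row_means(.assays_asis$counts)`). Reshaping is
   lazy and memoized.
3. **Size stability.** A result must match its context's canonical size
   (per group block under grouping); scalars recycle, anything else is an
   error — so every verb returns a valid container.

Grouping may only partition whole rows or whole columns (a predicate over
matrix cells does not induce valid sub-matrices). The assays context
respects both axes' groupings (cross-product blocks); each metadata
context sees only its own axis's grouping.

The package also ships its own correctness oracle — `unwind()` flattens a
container to the long form (one record per cell, metadata replicated),
`rewind()` inverts it, and every verb is property-tested against plain
grouped table semantics on that long form — plus a plain-text bundle
format (Matrix Market / CSV assays, TSV metadata, JSON manifest), a
seeded fixture generator, AnnData `.h5ad` interop, and a pipeline DSL
with a command-line runner.

## Worked example

```r
library(amgram)

am <- generate_fixture(50, 6, n_assays = 2, seed = 1)
am
#> <AnnotatedMatrix> 50 features x 6 samples
#> assays:   counts, tpm
#> row_data: length, chr
#> col_data: lib_size, condition

res <- am |>
  mutate(cpm = counts / .cols$lib_size * 1e6,
         cols(high_depth = lib_size > median(lib_size))) |>
  filter(rows(length < 5000)) |>
  group_by(cols(condition)) |>
  summarize(mean_cpm = mean(cpm), cols(depth = mean(lib_size)))

res
#> <AnnotatedMatrix> 1 features x 2 samples
#> assays:   mean_cpm
#> row_data:
#> col_data: condition, depth

res$assays$mean_cpm
#>          [,1]     [,2]
#> [1,] 19851.43 21142.34
res$col_data
#>   condition depth
#> 1       trt  4597
#> 2     untrt  4843
```

Reading: `cpm` rescales each count by its sample's library size (the
column-metadata pronoun broadcast against the matrix); the filter keeps
the 1-2 kb-scale genes; grouping the samples by condition and summarizing
collapses the container to one row group × two column groups, with
`mean_cpm` the per-condition average normalized expression and `depth`
the per-condition mean library size.

The same pipeline runs from the shell against an on-disk bundle:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "amgram", package = "amgram"))')
Rscript "$CLI" fixture --n 50 --p 6 --assays 2 --seed 1 --out in_bundle
echo 'mutate(cpm = counts / .cols$lib_size * 1000000) |>
      filter(rows(length < 5000)) |>
      group_by(cols(condition)) |>
      summarize(mean_cpm = mean(cpm))' > pipe.amg
Rscript "$CLI" run pipe.amg --in in_bundle --out out_bundle
```

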