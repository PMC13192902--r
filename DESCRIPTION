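Package: amgram
Title: A Tidy Grammar for Annotated Matrix Data
Version: 0.1.0
Authors@R: person("amgram", "developers", role = c("aut", "cre"),
    email = "amgram@example.org")
Description: Context-scoped tidy verbs for annotated matrix data: one or
    more n x p assay matrices linked to a feature (row) metadata table and
    a sample (column) metadata table. Expressions are evaluated inside one
    of three contexts (assays, rows, cols); cross-context access goes
    through pronouns offering both as-is and size-stable reshaped views;
    grouping partitions rows and/or columns and grouped verbs iterate over
    the induced blocks. Includes a long-form "unwound" reference
    implementation used as a correctness oracle, a plain-text bundle format
    (Matrix Market / CSV assays plus TSV metadata), a seeded synthetic
    fixture generator, and a small pipeline DSL with a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    dplyr,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
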