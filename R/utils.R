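# internal validation helpers shared across modules

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "%s is missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      class = "herb_format_error"
    )
  }
  invisible(df)
}

assert_unique_ids <- function(ids, what = "compound_id") {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(
      sprintf("duplicated %s: %s", what, paste(dup, collapse = ", ")),
      class = "herb_validation_error"
    )
  }
  invisible(ids)
}

# deterministic child seed (kept < 2^31) so one run seed drives many draws
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
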