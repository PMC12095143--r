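# internal helpers shared across modules

# validation failures are a distinct condition class so the CLI can map
# them to exit code 2 (input problem) rather than 1 (runtime error)
abort_validation <- function(message, ...) {
  rlang::abort(message, class = "dosenet_validation_error", ...)
}

assert_columns <- function(df, cols, what = "input") {
  if (!is.data.frame(df)) {
    abort_validation(sprintf("%s must be a data frame", what))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# case-normalize gene symbols so map/list/GMT sources agree
norm_symbols <- function(x) {
  x <- as.character(x)
  x <- trimws(x)
  toupper(x[!is.na(x) & nzchar(x)])
}
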