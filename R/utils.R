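# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state without clobbering the caller's
# random stream; seed = NULL leaves the stream alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_columns <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stopf("%s is missing mandatory column(s): %s", what,
          paste(missing, collapse = ", "))
  }
  invisible(dt)
}

# collapse a list-column to a delimited string for TSV export
collapse_list <- function(x, sep = "|") {
  vapply(x, function(v) paste(v, collapse = sep), character(1))
}

split_field <- function(x, sep = "|") {
  x[is.na(x)] <- ""
  out <- strsplit(x, sep, fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
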