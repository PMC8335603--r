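# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so generators are pure functions of their arguments.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# read a TSV with no quoting or type coercion; all columns character
read_tsv_raw <- function(path, required_cols) {
  df <- utils::read.delim(path,
    sep = "\t", quote = "", comment.char = "",
    stringsAsFactors = FALSE, colClasses = "character",
    check.names = FALSE, na.strings = NULL
  )
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf(
      "file '%s' is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  df
}

write_tsv_raw <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE,
    fileEnc = "UTF-8"
  )
  invisible(path)
}

# split a pipe-separated field into a character vector ("" -> character(0))
split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1L]]
}

join_pipe <- function(x) paste(x, collapse = "|")

# canonical unordered-pair key for undirected edge lookups
pair_key <- function(a, b) {
  swap <- a > b
  paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "\r")
}
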