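#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a local RNG seed
#'
#' Saves and restores the caller's `.Random.seed` so that seeded generator
#' functions never disturb the global random stream.
#'
#' @param seed integer seed, or NULL to leave the stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as tab-separated values
#' @param x data frame.
#' @param file output path.
#' @param row_names write row names as a first column with this header, or
#'   NULL to omit row names.
#' @return `file`, invisibly.
#' @export
write_tsv <- function(x, file, row_names = NULL) {
  if (!is.null(row_names)) {
    x <- cbind(stats::setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                               row_names),
               as.data.frame(x))
  }
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a tab-separated file
#' @param file input path.
#' @return data frame with character columns kept as-is.
#' @export
read_tsv <- function(file) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

stopifnot_prob <- function(x, what) {
  if (any(!is.na(x) & (x < 0 | x > 1))) {
    stop(sprintf("%s must lie in [0, 1]", what))
  }
}
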