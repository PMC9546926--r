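# Internal helpers shared across modules.

#' Derive a child seed from a run seed
#'
#' Deterministic counter-based fan-out so that one run-level seed can feed
#' several independent stochastic stages without reusing streams. Values stay
#' below 2^31 - 1 so they are valid R integer seeds.
#'
#' @param seed Integer run seed.
#' @param counter Non-negative integer stage counter.
#' @return An integer seed.
#' @examples
#' fan_seed(1L, 0:3)
#' @export
fan_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(counter))
  m <- 2147483647 # 2^31 - 1 (Mersenne prime); multiplicative congruential step
  a <- 48271      # MINSTD multiplier
  s <- (as.double(seed) %% m + 1)
  out <- vapply(as.double(counter), function(k) {
    x <- s
    for (i in seq_len(k + 1)) x <- (a * x) %% m
    x
  }, numeric(1))
  as.integer(out)
}

# Run `code` under a fixed seed without disturbing the caller's RNG state.
local_seed_eval <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind a list of data frames; NULL (not a stray matrix) when nothing to bind
rbind_rows <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# draw one integer uniformly from [lo, hi], avoiding sample()'s scalar rule
draw_int <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

stop_gv <- function(...) stop(sprintf(...), call. = FALSE)
warn_gv <- function(...) warning(sprintf(...), call. = FALSE)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_gv("%s is missing required column(s): %s", what,
            paste(missing, collapse = ", "))
  }
}

#' Read and write tab-separated tables
#'
#' Thin wrappers fixing the dialect used throughout the package: tab-separated,
#' header line, no quoting, no row names, `NA` written as empty string.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_tsv_table()` returns a data frame; `write_tsv_table()` returns
#'   `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
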