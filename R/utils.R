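#' Derive a reproducible substream seed
#'
#' Each stochastic component of the pipeline draws from its own named
#' substream so that stage-level reruns match full-run results. The substream
#' seed is a deterministic 31-bit hash of the master seed and the stream name.
#'
#' @param master_seed integer master seed.
#' @param name character stream name (e.g. `"region_perm_rep_17"`).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(master_seed, name) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(name), length(name) == 1L)
  h <- (as.double(master_seed) %% 2147483647) + 1
  for (cp in utf8ToInt(name)) {
    # 31-bit multiplicative string hash, kept in double-safe range
    h <- (h * 131 + cp) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression with a local RNG state
#'
#' Sets the RNG to a named substream for the duration of `expr` and restores
#' the caller's RNG state afterwards.
#'
#' @param master_seed integer master seed.
#' @param name substream name.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_substream <- function(master_seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master_seed, name))
  expr
}

log_msg <- function(..., level = "INFO") {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
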