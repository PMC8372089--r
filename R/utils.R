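#' @keywords internal
"_PACKAGE"

#' Derive reproducible child seeds from a master seed
#'
#' All stochastic stages draw their seeds through this helper so that a single
#' master seed determines every random step of a run. Seeds are kept below
#' 2^31 - 1 (R integers are 32-bit).
#'
#' @param master integer master seed.
#' @param n number of child seeds to derive.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) message("[fragpop] ", ...)

## weighted mean that tolerates zero total weight
wmean <- function(x, w) {
  sw <- sum(w)
  if (sw <= 0) return(NA_real_)
  sum(x * w) / sw
}
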