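#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Every stochastic stage of the package draws from a sub-seed computed
#' from the master seed and a stage key (e.g. `"sdm/sp12/rf/rep3"`), so
#' each stage is reproducible independently of the order in which stages
#' run. All arithmetic stays below 2^31 (R integers).
#'
#' @param seed Integer master seed.
#' @param key Character stage key.
#' @return An integer sub-seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, key) {
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  as.integer((((seed %% m) * 48271) %% m + h) %% m)
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state so
#' package functions never clobber the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mossgrad <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mossgrad_error")))
}
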