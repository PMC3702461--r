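#' Run an expression with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded internals never disturb
#' the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a sub-stream seed from a root seed
#'
#' Fixed arithmetic derivation so that every independent noise source
#' (per-contrast Rician noise, CT noise, bias-field coefficients, learning-set
#' subsampling) gets its own reproducible stream from one root seed.
#'
#' @param root Integer root seed.
#' @param tag Character tag naming the stream.
#' @return An integer seed below 2^31.
#' @keywords internal
derive_seed <- function(root, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(root) * 48271 + h * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
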