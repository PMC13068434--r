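#' Derive a reproducible stream seed from a master seed and a label path
#'
#' Hashes the master seed together with an arbitrary sequence of labels
#' (session, block, condition index, purpose tags, ...) into a positive
#' 31-bit integer. Every stochastic step of a simulation draws its own
#' named stream through this helper, so results are independent of
#' execution order and safely reproducible from one master seed.
#'
#' @param seed master seed (positive integer).
#' @param ... labels identifying the stream; coerced to character.
#' @return a positive integer < 2^31 suitable for [set.seed()].
#' @examples
#' derive_seed(1709026616, "trial", 1, 12, 5)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  txt <- paste(c(format(seed, scientific = FALSE), vapply(list(...),
    function(x) paste(format(x, scientific = FALSE), collapse = "_"),
    character(1))), collapse = "/")
  h <- 0
  for (code in utf8ToInt(txt)) h <- (h * 31 + code) %% 2147483587
  as.integer(h + 1L)
}

## evaluate expr under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards
with_stream <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) stop(..., call. = FALSE)
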