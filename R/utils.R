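#' @importFrom rlang abort warn %||%
#' @importFrom stats fft approx median mad coef lm.wfit pt pbinom dhyper
#'   rnorm runif rgeom sd setNames pnorm qnorm dnorm optim var
#' @importFrom utils read.csv write.csv head tail
#' @importFrom tools file_ext
NULL

# deterministic stream splitter: derives a child seed from a base seed and a
# sequence of labels/indices, so adding subjects or weeks never perturbs the
# draws of existing ones.  32-bit arithmetic done in doubles; result < 2^31.
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- (seed %% 2147483647) + 1
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    h <- (h * 48271 + v * 16807 + 11) %% 2147483647
    h <- (h * 69621 + 7) %% 2147483647  # second mix round per part
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
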