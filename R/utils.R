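# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a stage name
#'
#' One master seed fans out to per-stage seeds so that regenerating one layer
#' of a simulation (say, the expression table) never perturbs the random
#' stream of another (the genome or the methylomes).
#'
#' @param master integer master seed.
#' @param name character stage label, e.g. `"methylome"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' child_seed(1L, "genome")
#' @export
child_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1014741
  as.integer((abs(master) * 2113 + h * 7919 + 17) %% (.Machine$integer.max - 1))
}

# Evaluate `expr` under `seed` without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# stop() with sprintf formatting, no call in the condition.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(x == floor(x))

# Modal value of a character vector (ties broken by first occurrence).
mode_chr <- function(x) {
  if (!length(x)) return(NA_character_)
  tb <- table(x)
  names(tb)[which.max(tb)]
}
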