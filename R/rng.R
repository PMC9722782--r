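#' Derive a reproducible RNG sub-stream seed
#'
#' Federated simulations need many independent random streams (one per site
#' and round, one per generated case, ...) that are reproducible regardless
#' of iteration order.  `derive_seed()` maps a global seed plus an arbitrary
#' set of string/integer tags to a stable 31-bit seed via an FNV-1a style
#' hash, so `set.seed(derive_seed(seed, site, round))` always yields the
#' same stream for the same tags.
#'
#' @param seed Global integer seed.
#' @param ... Tags (coerced to character) identifying the sub-stream,
#'   e.g. a site id and a round index.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "site_A", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  tags <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  key <- paste0(format(seed, scientific = FALSE), "\r", tags)
  # FNV-1a over bytes, folded into 31 bits; exact in doubles (< 2^53)
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG state.
#'
#' @param seed Integer seed passed to [set.seed()].
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
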