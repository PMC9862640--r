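#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages: 0.05 at the last
#' kept digit always rounds up, unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Derive a per-item seed from a master seed
#'
#' A single run seed fans out to one seed per item (cocoon, CV iteration, ...)
#' by an integer hash of the item id, so any subset of items is reproducible
#' independently of the others. Result is always in [1, 2^31 - 2].
#'
#' @param master integer master seed.
#' @param id non-negative integer item identifier (scalar or vector).
#' @return integer seed(s).
#' @export
derive_seed <- function(master, id) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(id))
  # multiplicative hashing in double precision; all intermediates < 2^53
  h <- (abs(master) %% 2147483647) * 48271 + (id %% 2147483647) * 104729 + 12345
  as.integer(h %% 2147483629) + 1L
}

stop_cocoon <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "cocoonsort_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
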