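#' @keywords internal
"_PACKAGE"

# Integer mixing for reproducible sub-stream seeds.  All arithmetic stays
# below 2^53 so it is exact in doubles; results lie in [0, 2147483562].
.mix <- function(x) {
  x <- (x %% 2147483563)
  x <- (x * 69069 + 1234567) %% 2147483563
  x <- (x * 69069 + 1234567) %% 2147483563
  x
}

#' Derive a reproducible sub-stream seed
#'
#' Deterministically maps a master seed plus a stream identifier and an index
#' to a new seed, so that e.g. every replication and every interim analysis
#' within a replication consumes an independent, reproducible random stream.
#'
#' @param master integer master seed.
#' @param stream integer stream identifier (a small constant per use site).
#' @param index integer index within the stream (e.g. replication number or
#'   analysis number).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stream = 0L, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer(.mix(.mix(.mix(abs(master)) + abs(stream)) + abs(index)))
}

.assert_prob <- function(x, name, open0 = FALSE, open1 = FALSE) {
  ok <- is.numeric(x) & is.finite(x) &
    (if (open0) x > 0 else x >= 0) & (if (open1) x < 1 else x <= 1)
  if (!all(ok)) {
    stop(sprintf("'%s' must be probabilit%s in %s0,1%s",
                 name, if (length(x) > 1L) "ies" else "y",
                 if (open0) "(" else "[", if (open1) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}

.assert_count <- function(x, name) {
  if (!all(is.numeric(x) & is.finite(x) & x >= 0 & x == round(x))) {
    stop(sprintf("'%s' must contain nonnegative integer counts", name),
         call. = FALSE)
  }
  invisible(x)
}

# Stable label for a terminal classification: the whole population or the
# (sorted) set of enriched subsets.
classification_label <- function(enriched) {
  if (length(enriched) == 0L) "entire_population"
  else paste(sort(enriched), collapse = "+")
}
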