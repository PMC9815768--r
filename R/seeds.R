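#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows through explicit integer seeds.
#' Composite procedures (dataset construction, experiment runs) expand a
#' single master seed into named substreams so that, for example, changing
#' the selection regime never alters the dataset drawn under the same master
#' seed.  The derivation is a small deterministic string hash folded into
#' the seed modulo 2^31 - 1; it is platform independent.
#'
#' @param seed Single integer master seed.
#' @param stream Character tag naming the substream (e.g. `"data"`,
#'   `"layer"`, `"regime"`).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' derive_seed(1, "data")
#' derive_seed(1, "layer") # differs from the "data" stream
#' @export
derive_seed <- function(seed, stream) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    kr_stop("invalid_parameter", "`seed` must be a single integer")
  if (!is.character(stream) || length(stream) != 1L)
    kr_stop("invalid_parameter", "`stream` must be a single string")
  mod <- 2147483647
  h <- abs(as.double(seed)) %% mod
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% mod
  as.integer(h)
}
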