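#' @keywords internal
"_PACKAGE"

# Inverse logit with underflow guard: returns probabilities strictly inside
# machine range; errors on non-finite linear predictors.
inv_logit <- function(eta) {
  if (any(!is.finite(eta))) {
    stop("non-finite linear predictor; check model coefficients", call. = FALSE)
  }
  p <- ifelse(eta > 0, 1 / (1 + exp(-eta)), exp(eta) / (1 + exp(eta)))
  pmin(pmax(p, 0), 1)
}

logit <- function(p) log(p / (1 - p))

#' Deterministic child seed derivation
#'
#' Every random draw in the package flows from a single master seed through
#' this function, so that independent stages (population generation, each
#' survey draw, each bootstrap replicate) use reproducible, non-colliding
#' streams. The scheme hashes the master seed together with an arbitrary
#' sequence of labels/integers into a 31-bit integer.
#'
#' @param seed master integer seed.
#' @param ... labels (character) or integers identifying the stream.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' child_seed(42, "population")
#' child_seed(42, 7, "B")
child_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    bytes <- if (is.character(p)) {
      as.double(utf8ToInt(paste(p, collapse = "|")))
    } else {
      as.double(p)
    }
    for (b in bytes) {
      # 31-bit multiplicative polynomial hash; 69069 is a classic LCG multiplier
      h <- (h * 69069 + b + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483645) + 1L
}

# stop() with sprintf-style formatting
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Weighted mean of a 0/1 or numeric vector
wmean <- function(x, w) sum(w * x) / sum(w)
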