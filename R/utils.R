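#' Physical decay constant of iodine-131
#'
#' Computes `ln(2) / T_half` for the 8.02-day physical half-life of ^131I,
#' in inverse hours. The value rounds to 0.00360 h^-1, the default used
#' throughout the dosimetry layer.
#'
#' @param half_life_days Physical half-life in days (default 8.02).
#' @return Decay constant in h^-1.
#' @export
#' @examples
#' i131_decay_constant()      # 0.003601...
i131_decay_constant <- function(half_life_days = 8.02) {
  stopifnot(is.numeric(half_life_days), half_life_days > 0)
  log(2) / (half_life_days * 24)
}

# Evaluate an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards so library code never perturbs user-level randomness.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_rifkin <- function(...) stop(..., call. = FALSE)

# checks x is a finite numeric scalar
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_rifkin(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop_rifkin(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop_rifkin(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
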