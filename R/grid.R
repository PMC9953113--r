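#' Canonical 25-point logarithmic frequency grid
#'
#' The measurement grid used throughout the package: 25 logarithmically
#' distributed frequencies spanning 1 Hz to 1 MHz, i.e. \eqn{10^{k/4}} Hz for
#' \eqn{k = 0, \dots, 24} (four points per decade). The grid point
#' \eqn{10^{4.25} \approx 17.8} kHz is the usual analysis frequency for
#' irritancy scoring.
#'
#' @return Numeric vector of 25 strictly increasing frequencies in Hz.
#' @export
#' @examples
#' canonical_grid()[18] # ~17.8 kHz
canonical_grid <- function() {
  10^(seq.int(0L, 24L) / 4)
}

#' Map a target frequency onto a measurement grid
#'
#' Returns the grid frequency closest to `target` on a log scale, so that
#' nominal labels such as "17 kHz" can be resolved to an actual measured
#' frequency. Ties are broken toward the lower frequency.
#'
#' @param target Target frequency in Hz (> 0), length 1.
#' @param grid Strictly increasing vector of grid frequencies in Hz.
#' @return The grid frequency (length-1 numeric) minimizing
#'   `|log10(f) - log10(target)|`.
#' @export
#' @examples
#' nearest_grid_frequency(17000) # 10^4.25
nearest_grid_frequency <- function(target, grid = canonical_grid()) {
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target <= 0) {
    stop("`target` must be a single finite frequency > 0", call. = FALSE)
  }
  check_grid(grid)
  d <- abs(log10(grid) - log10(target))
  grid[which.min(d)] # which.min takes the first minimum: lower frequency
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) == 0L || anyNA(grid)) {
    stop("frequency grid must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    stop("frequency grid must be strictly increasing and positive",
         call. = FALSE)
  }
  invisible(grid)
}
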