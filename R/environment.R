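#' Patch network environment
#'
#' A flat set of breeding patches, each with an independent, temporally
#' autocorrelated environmental quality `Q` driving its carrying capacity
#' `K`. Quality follows a stationary AR(1) process: innovations are
#' `N(0, sigma)` and the autoregressive step is scaled by
#' `sqrt(1 - autocorr^2)`, so the marginal distribution of `Q` stays
#' `N(0, sigma^2)` at every time. There is no spatial structure: patches are
#' a list, not a map, and no distances exist anywhere in the model.
#'
#' @param n_patches number of breeding patches.
#' @param sigma standard deviation of the quality innovations (>= 0).
#' @param autocorr temporal autocorrelation coefficient in \[0, 1\].
#' @param K0 baseline carrying capacity (> 0), individuals.
#' @return An object of class `env_grid`: a list with `n_patches`, `sigma`,
#'   `autocorr`, `K0`, and (once initialized) numeric vectors `Q` and `K`.
#' @examples
#' g <- env_grid(n_patches = 25)
#' g <- init_quality(g)
#' g <- step_quality(g)
#' range(g$K)
#' @export
env_grid <- function(n_patches = 25, sigma = 1, autocorr = 0.8, K0 = 100) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (autocorr < 0 || autocorr > 1) stop("autocorr must be in [0, 1]")
  if (K0 <= 0) stop("K0 must be > 0")
  if (n_patches < 1) stop("n_patches must be >= 1")
  structure(list(n_patches = as.integer(n_patches), sigma = sigma,
                 autocorr = autocorr, K0 = K0, Q = NULL, K = NULL),
            class = "env_grid")
}

#' Initialize patch qualities
#'
#' Draws each patch's quality independently from `N(0, sigma)` and derives
#' carrying capacities.
#'
#' @param grid an [env_grid()].
#' @return The grid with `Q` and `K` filled in.
#' @export
init_quality <- function(grid) {
  stopifnot(inherits(grid, "env_grid"))
  grid$Q <- stats::rnorm(grid$n_patches, 0, grid$sigma)
  grid$K <- carrying_capacity(grid$Q, grid$K0)
  grid
}

#' Advance patch qualities one year
#'
#' Applies the stationary AR(1) update
#' `Q' = autocorr * Q + w * sqrt(1 - autocorr^2)` with fresh innovations
#' `w ~ N(0, sigma)` per patch, then refreshes `K`. With `autocorr = 1` the
#' quality freezes; with `autocorr = 0` it is white noise.
#'
#' @param grid an initialized [env_grid()].
#' @return The advanced grid.
#' @export
step_quality <- function(grid) {
  stopifnot(inherits(grid, "env_grid"))
  if (is.null(grid$Q)) stop("grid not initialized; call init_quality() first")
  w <- stats::rnorm(grid$n_patches, 0, grid$sigma)
  grid$Q <- grid$autocorr * grid$Q + w * sqrt(1 - grid$autocorr^2)
  grid$K <- carrying_capacity(grid$Q, grid$K0)
  grid
}

#' Carrying capacity from environmental quality
#'
#' `K = K0 + K0 * Q`, floored at zero. Quality itself is never clamped; only
#' the capacity is. `K` is kept real-valued and used as-is in the fecundity
#' function (no rounding).
#'
#' @param Q numeric vector of patch qualities.
#' @param K0 baseline carrying capacity (> 0).
#' @return Numeric vector of capacities, all >= 0.
#' @examples
#' carrying_capacity(c(0, 0.5, -1.5), K0 = 100)  # 100 150 0
#' @export
carrying_capacity <- function(Q, K0) {
  if (K0 <= 0) stop("K0 must be > 0")
  pmax(0, K0 + K0 * Q)
}
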