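#' Deterministic demographic profile
#'
#' Describes a census population size trajectory that changes deterministically
#' from `n0` diploid individuals to `round(n0 * ratio)` over `duration`
#' generations, then stays constant. The effective size is tied to the census
#' size through a constant factor `ne_over_n` (Ne = ne_over_n * N), so a
#' profile carries everything needed to evaluate fixation probabilities under
#' time-varying drift.
#'
#' @param n0 Census number of diploid individuals at generation 0 (>= 2).
#' @param ratio Final size divided by initial size (> 0). `ratio = 1` gives a
#'   constant-size population.
#' @param duration Number of generations over which the size changes (>= 0).
#'   `duration = 0` means the population is at its final size from the start.
#' @param shape Interpolation of the size change: `"linear"` in census size or
#'   `"exponential"` (constant per-generation growth factor).
#' @param ne_over_n Ratio of effective to census size, default 1.
#'
#' @return An object of class `"demography_profile"`.
#' @examples
#' constant <- demography_profile(1000)
#' fast_growth <- demography_profile(1000, ratio = 1.9, duration = 20)
#' slow_decline <- demography_profile(1000, ratio = 0.1, duration = 200)
#' @export
demography_profile <- function(n0, ratio = 1, duration = 0,
                               shape = c("linear", "exponential"),
                               ne_over_n = 1) {
  shape <- match.arg(shape)
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 2)
    stop("`n0` must be a single number >= 2", call. = FALSE)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
    stop("`ratio` must be a single positive number", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || duration < 0)
    stop("`duration` must be a single number >= 0", call. = FALSE)
  if (!is.numeric(ne_over_n) || length(ne_over_n) != 1L || ne_over_n <= 0)
    stop("`ne_over_n` must be a single positive number", call. = FALSE)
  duration <- as.integer(round(duration))
  obj <- structure(
    list(n0 = round(n0), ratio = ratio, duration = duration,
         shape = shape, ne_over_n = ne_over_n),
    class = "demography_profile"
  )
  # fail early on degenerate trajectories (any generation below 2 individuals)
  invisible(build_size_trajectory(obj, horizon = duration))
  obj
}

#' @export
print.demography_profile <- function(x, ...) {
  n_final <- round(x$n0 * x$ratio)
  if (x$ratio == 1 || x$duration == 0L) {
    cat(sprintf("Demography: constant N = %d", n_final))
  } else {
    cat(sprintf("Demography: N %d -> %d over %d generations (%s)",
                x$n0, n_final, x$duration, x$shape))
  }
  if (x$ne_over_n != 1) cat(sprintf(", Ne/N = %g", x$ne_over_n))
  cat("\n")
  invisible(x)
}

#' Census-size trajectory of a demographic profile
#'
#' Expands a [demography_profile()] into the per-generation census sizes
#' `N(0), N(1), ..., N(horizon)`. Sizes are rounded to the nearest integer;
#' the size is constant at `round(n0 * ratio)` from generation `duration`
#' onwards.
#'
#' @param profile A [demography_profile()].
#' @param horizon Last generation to include (>= `profile$duration`).
#' @return Integer vector of length `horizon + 1`; element `g + 1` is the
#'   census size at generation `g`.
#' @examples
#' p <- demography_profile(1000, ratio = 1.9, duration = 20)
#' build_size_trajectory(p, horizon = 20)[21] # 1900 at generation 20
#' @export
build_size_trajectory <- function(profile, horizon = profile$duration) {
  stopifnot(inherits(profile, "demography_profile"))
  if (horizon < profile$duration)
    stop("`horizon` must be at least the profile duration", call. = FALSE)
  n0 <- profile$n0
  n_final <- round(n0 * profile$ratio)
  gen <- 0:horizon
  if (profile$duration == 0L) {
    sizes <- rep.int(n_final, horizon + 1L)
  } else {
    frac <- pmin(gen / profile$duration, 1)
    sizes <- switch(profile$shape,
      linear = n0 + (n_final - n0) * frac,
      exponential = n0 * (n_final / n0)^frac
    )
    sizes <- round(sizes)
    sizes[gen >= profile$duration] <- n_final
  }
  if (any(sizes < 2))
    stop("degenerate demography: census size falls below 2 individuals",
         call. = FALSE)
  as.integer(sizes)
}

#' Final effective population size of a profile
#'
#' The post-change effective size `ne_over_n * round(n0 * ratio)`; this is the
#' Ne that enters the exponents of the general fixation-probability formula,
#' because after the change the population is constant and the formula is the
#' expectation of the constant-size fixation probability over the frequency
#' reached at the end of the change.
#'
#' @param profile A [demography_profile()].
#' @return A single number.
#' @export
ne_final <- function(profile) {
  stopifnot(inherits(profile, "demography_profile"))
  profile$ne_over_n * round(profile$n0 * profile$ratio)
}

#' Initial effective population size of a profile
#'
#' @param profile A [demography_profile()].
#' @return A single number, `ne_over_n * n0`.
#' @export
ne_initial <- function(profile) {
  stopifnot(inherits(profile, "demography_profile"))
  profile$ne_over_n * profile$n0
}
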