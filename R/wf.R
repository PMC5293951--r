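#' One Wright-Fisher generation with genic selection
#'
#' Advances an allele frequency by a single generation of binomial resampling
#' into a population of `n_next` diploid individuals. Selection is genic: a
#' derived allele at frequency `x` with selection coefficient `s` is sampled
#' with probability `x (1 + s) / (1 + x s)`. The boundaries 0 and 1 are
#' absorbing.
#'
#' @param x Allele frequency (or vector of frequencies) in `[0, 1]`.
#' @param s Selection coefficient (> -1). `s = 0` is neutral.
#' @param n_next Census diploid size of the next generation (>= 2).
#' @return Frequencies after one generation, same length as `x`.
#' @export
wf_step <- function(x, s, n_next) {
  check_selection(s)
  if (any(n_next < 2)) stop("`n_next` must be >= 2", call. = FALSE)
  if (any(x < 0 | x > 1)) stop("frequencies must lie in [0, 1]", call. = FALSE)
  p <- x * (1 + s) / (1 + x * s)
  stats::rbinom(length(x), size = 2L * as.integer(n_next), prob = p) /
    (2 * n_next)
}

check_selection <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || s <= -1)
    stop("selection coefficient must be a single number > -1", call. = FALSE)
  invisible(s)
}

#' Replicate allele frequencies at the end of a demographic change
#'
#' Simulates `n_replicates` independent Wright-Fisher trajectories from
#' initial frequency `x0` through the size changes of `profile`, and returns
#' the frequency of each replicate at generation `T = profile$duration`. These
#' are the X(T) values whose expectation enters the general
#' fixation-probability formula.
#'
#' @param x0 Initial frequency in `(0, 1)`.
#' @param s Selection coefficient (> -1).
#' @param profile A [demography_profile()].
#' @param n_replicates Number of independent replicates.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_replicates` with values in `[0, 1]`.
#'   A profile with `duration = 0` returns `x0` for every replicate.
#' @export
simulate_frequency_at_T <- function(x0, s, profile, n_replicates = 500000L,
                                    seed = NULL) {
  stopifnot(inherits(profile, "demography_profile"))
  check_selection(s)
  if (x0 <= 0 || x0 >= 1)
    stop("`x0` must lie strictly inside (0, 1)", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- rep.int(x0, n_replicates)
  if (profile$duration == 0L) return(x)
  sizes <- build_size_trajectory(profile, profile$duration)
  for (g in seq_len(profile$duration)) {
    n_next <- sizes[g + 1L]
    p <- x * (1 + s) / (1 + x * s)
    x <- stats::rbinom(n_replicates, size = 2L * n_next, prob = p) /
      (2 * n_next)
  }
  x
}

#' Kimura's closed-form fixation probability at constant size
#'
#' `(1 - exp(-4 Ne s x0)) / (1 - exp(-4 Ne s))` for `s != 0`, and its neutral
#' limit `x0` for `s = 0`.
#'
#' @param ne Effective population size.
#' @param s Selection coefficient.
#' @param x0 Initial allele frequency.
#' @return Fixation probability.
#' @export
kimura_pfix <- function(ne, s, x0) {
  check_selection(s)
  if (s == 0) return(x0)
  # expm1 keeps precision when 4*ne*s*x0 is tiny
  (-expm1(-4 * ne * s * x0)) / (-expm1(-4 * ne * s))
}

new_fixation_estimate <- function(p_fix, std_error, n_replicates, method) {
  stopifnot(p_fix >= -1e-12, p_fix <= 1 + 1e-12, std_error >= 0)
  structure(
    list(p_fix = min(max(p_fix, 0), 1), std_error = std_error,
         n_replicates = n_replicates, method = method),
    class = "fixation_estimate"
  )
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("Fixation probability: %.6g (method: %s", x$p_fix, x$method))
  if (x$std_error > 0) cat(sprintf(", MC std. error %.3g", x$std_error))
  cat(")\n")
  invisible(x)
}

#' Fixation probability under a demographic profile
#'
#' Evaluates the general fixation-probability formula for a new mutation under
#' deterministic demographic change,
#' \deqn{P_{fix} = \frac{1 - E[e^{-4 N_e s X(T)}]}{1 - e^{-4 N_e s}},}
#' where `X(T)` is the allele frequency at the end of the size change and
#' `Ne` is the final effective size (the population is constant after `T`).
#' The expectation is approximated by Wright-Fisher Monte-Carlo replicates.
#' For `s = 0` the neutral limit `P_fix = E[X(T)]` is used (analytically
#' `x0`, by the martingale property of neutral resampling). For a
#' constant-size profile the Kimura closed form is returned directly unless
#' `method = "monte_carlo"` forces the simulation branch.
#'
#' @param s Selection coefficient (> -1).
#' @param profile A [demography_profile()].
#' @param x0 Initial frequency; defaults to a single new copy, `1 / (2 n0)`.
#' @param n_replicates Monte-Carlo replicates for the expectation.
#' @param seed Optional integer seed.
#' @param method `"auto"` (analytic where exact, Monte-Carlo otherwise),
#'   `"analytic"` (constant-size closed form; errors if the profile changes
#'   size), or `"monte_carlo"` (always simulate).
#' @return A `fixation_estimate` with fields `p_fix`, `std_error` (delta-method
#'   propagation from the replicate mean; 0 for analytic branches),
#'   `n_replicates` and `method`.
#' @examples
#' p <- demography_profile(1000)
#' fixation_probability(s = 0, p)$p_fix # 1/2000
#' @export
fixation_probability <- function(s, profile, x0 = 1 / (2 * profile$n0),
                                 n_replicates = 500000L, seed = NULL,
                                 method = c("auto", "analytic",
                                            "monte_carlo")) {
  stopifnot(inherits(profile, "demography_profile"))
  method <- match.arg(method)
  check_selection(s)
  if (x0 <= 0 || x0 >= 1)
    stop("`x0` must lie strictly inside (0, 1)", call. = FALSE)

  constant <- profile$ratio == 1 || profile$duration == 0L
  ne_fin <- ne_final(profile)

  if (method != "monte_carlo" && constant) {
    if (s == 0)
      return(new_fixation_estimate(x0, 0, 0L, "neutral_limit"))
    return(new_fixation_estimate(kimura_pfix(ne_fin, s, x0), 0, 0L,
                                 "analytic_kimura"))
  }
  if (method == "analytic")
    stop("analytic branch requires a constant-size profile", call. = FALSE)

  x_t <- simulate_frequency_at_T(x0, s, profile, n_replicates, seed)
  if (s == 0) {
    p <- mean(x_t)
    se <- stats::sd(x_t) / sqrt(n_replicates)
    return(new_fixation_estimate(p, se, n_replicates, "neutral_limit"))
  }
  y <- exp(-4 * ne_fin * s * x_t)
  denom <- -expm1(-4 * ne_fin * s)
  p <- (1 - mean(y)) / denom
  # p is linear in mean(y), so the delta method is exact here
  se <- stats::sd(y) / sqrt(n_replicates) / abs(denom)
  new_fixation_estimate(p, se, n_replicates, "monte_carlo")
}

#' Exact fixation probability from the absorbing Markov chain
#'
#' Solves the fixation probability of the Wright-Fisher chain on allele counts
#' `0..2n` with the same binomial/genic-selection kernel as [wf_step()], by a
#' dense linear solve over the transient states. Intended as an exact oracle
#' for small populations.
#'
#' @param n Census diploid individuals; `2 n` must be at most 200.
#' @param s Selection coefficient.
#' @param x0 Initial frequency; must equal `j / (2 n)` for an integer `j`.
#' @return A `fixation_estimate` with `method = "matrix_exact"` and zero
#'   standard error.
#' @export
exact_matrix_fixation <- function(n, s, x0) {
  check_selection(s)
  two_n <- 2L * as.integer(n)
  if (two_n > 200L)
    stop("2n exceeds the dense-matrix size limit of 200", call. = FALSE)
  j <- x0 * two_n
  if (abs(j - round(j)) > 1e-9)
    stop("`x0` must be a lattice frequency j/(2n)", call. = FALSE)
  j <- as.integer(round(j))
  if (j == 0L) return(new_fixation_estimate(0, 0, 0L, "matrix_exact"))
  if (j == two_n) return(new_fixation_estimate(1, 0, 0L, "matrix_exact"))

  counts <- 0:two_n
  freq <- counts / two_n
  p_next <- freq * (1 + s) / (1 + freq * s)
  # row i: transition probabilities from count i to counts 0..2n
  trans <- t(vapply(p_next, function(p) stats::dbinom(counts, two_n, p),
                    numeric(two_n + 1L)))
  transient <- 2:two_n                # counts 1..2n-1 (1-based indexing)
  q <- trans[transient, transient, drop = FALSE]
  r_fix <- trans[transient, two_n + 1L]
  h <- solve(diag(length(transient)) - q, r_fix)
  new_fixation_estimate(h[j], 0, 0L, "matrix_exact")
}

#' Monte-Carlo fixation fraction run to absorption
#'
#' Simulates replicates of a constant-size Wright-Fisher population until
#' every replicate is absorbed at frequency 0 or 1, and returns the fraction
#' fixed. Complements [fixation_probability()], whose Monte-Carlo branch
#' evaluates the fixation formula from frequencies at the end of a
#' demographic change instead of running to absorption.
#'
#' @param n Census diploid individuals (constant).
#' @param s Selection coefficient.
#' @param x0 Initial frequency, default one new copy.
#' @param n_replicates Number of replicates.
#' @param seed Optional integer seed.
#' @param max_generations Safety cap on the number of generations.
#' @return A `fixation_estimate` with `method = "monte_carlo"` and binomial
#'   standard error.
#' @export
simulate_fixation_fraction <- function(n, s, x0 = 1 / (2 * n),
                                       n_replicates = 10000L, seed = NULL,
                                       max_generations = 1e6) {
  check_selection(s)
  if (x0 <= 0 || x0 >= 1)
    stop("`x0` must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  two_n <- 2L * as.integer(n)
  x <- rep.int(x0, n_replicates)
  fixed <- 0L
  gen <- 0
  while (length(x) && gen < max_generations) {
    p <- x * (1 + s) / (1 + x * s)
    x <- stats::rbinom(length(x), two_n, p) / two_n
    fixed <- fixed + sum(x == 1)
    x <- x[x > 0 & x < 1]
    gen <- gen + 1
  }
  if (length(x))
    warning("some replicates unabsorbed at `max_generations`; treated as lost")
  p_hat <- fixed / n_replicates
  se <- sqrt(p_hat * (1 - p_hat) / n_replicates)
  new_fixation_estimate(p_hat, se, n_replicates, "monte_carlo")
}
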