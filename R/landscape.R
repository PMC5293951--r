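#' Holey-landscape / incompatibility model
#'
#' Parameters of the Dobzhansky-Muller incompatibility model on a holey
#' adaptive landscape: a genotype with `big_l` mutational targets walks the
#' landscape by substitutions, each of which falls into a fitness "hole"
#' (creates an incompatibility) with probability `epsilon`. Incompatibilities
#' between two diverging populations accumulate either linearly in the number
#' of substitutions `d` (all incompatible alleles paired) or quadratically
#' (every derived allele can conflict with every other; the snowball).
#'
#' @param big_l Number of mutational targets L (integer >= 1).
#' @param epsilon Per-substitution probability of causing an incompatibility,
#'   strictly inside (0, 1).
#' @param accumulation `"pairwise_linear"` or `"snowball_quadratic"`.
#' @return An object of class `"landscape_model"`.
#' @examples
#' m <- landscape_model(big_l = 100, epsilon = 0.02)
#' snowball_condition(m)
#' @export
landscape_model <- function(big_l, epsilon,
                            accumulation = c("pairwise_linear",
                                             "snowball_quadratic")) {
  accumulation <- match.arg(accumulation)
  if (!is.numeric(big_l) || length(big_l) != 1L || big_l < 1)
    stop("`big_l` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 1)
    stop("`epsilon` must lie strictly inside (0, 1)", call. = FALSE)
  structure(list(big_l = as.integer(round(big_l)), epsilon = epsilon,
                 accumulation = accumulation),
            class = "landscape_model")
}

#' @export
print.landscape_model <- function(x, ...) {
  cat(sprintf("Holey landscape: L = %d, epsilon = %g, accumulation = %s\n",
              x$big_l, x$epsilon, x$accumulation))
  invisible(x)
}

#' Expected number of incompatibilities at a given divergence
#'
#' Pairwise-linear accumulation gives `epsilon * d`; snowball accumulation
#' counts all unordered pairs of derived alleles, `epsilon * d (d - 1) / 2`.
#'
#' @param d Number of substitutions separating the two populations (>= 0;
#'   vectorized).
#' @param model A [landscape_model()].
#' @return Expected incompatibility count(s).
#' @export
incompatibility_count <- function(d, model) {
  stopifnot(inherits(model, "landscape_model"))
  if (any(d < 0)) stop("`d` must be >= 0", call. = FALSE)
  switch(model$accumulation,
    pairwise_linear = model$epsilon * d,
    snowball_quadratic = model$epsilon * d * (d - 1) / 2
  )
}

#' Expected number of viable one-substitution paths
#'
#' From a starting genotype with `L` mutational targets, a single substitution
#' avoids a hole with probability `1 - epsilon`, so on average `L (1 - epsilon)`
#' viable steps exist. Evolution can keep moving along the landscape when this
#' exceeds 1.
#'
#' @param model A [landscape_model()].
#' @return List with `expected_paths` and logical `viable`
#'   (`expected_paths > 1`, strict).
#' @export
expected_paths <- function(model) {
  stopifnot(inherits(model, "landscape_model"))
  ep <- model$big_l * (1 - model$epsilon)
  list(expected_paths = ep, viable = ep > 1)
}

#' Snowball condition
#'
#' Quadratic (snowball) accumulation of incompatibilities is compatible with
#' continued movement along the holey landscape only when
#' `epsilon < ln(L) / L`; genomes with more mutational targets therefore
#' require a smaller per-substitution incompatibility probability.
#'
#' @param model A [landscape_model()] with `big_l >= 2`.
#' @return Logical.
#' @export
snowball_condition <- function(model) {
  stopifnot(inherits(model, "landscape_model"))
  if (model$big_l < 2)
    stop("the snowball condition needs `big_l` >= 2", call. = FALSE)
  model$epsilon < log(model$big_l) / model$big_l
}

#' Probability that two populations can still interbreed
#'
#' With every substitution independently incompatible with probability
#' `epsilon`, a path of `d` substitutions avoids every hole -- and the
#' populations remain interfertile -- with probability `(1 - epsilon)^d`.
#'
#' @param d Substitutions separating the populations (vectorized, >= 0).
#' @param epsilon Per-substitution incompatibility probability.
#' @return Probability vector.
#' @export
interbreed_probability <- function(d, epsilon) {
  if (any(d < 0)) stop("`d` must be >= 0", call. = FALSE)
  (1 - epsilon)^d
}

#' Distribution of the substitution count at which RI completes
#'
#' Under the simplest model -- any single incompatible substitution causes
#' complete reproductive isolation -- the index `k` of the isolating
#' substitution is geometric: `P(k) = (1 - epsilon)^(k-1) epsilon`, with mean
#' `1 / epsilon` substitutions.
#'
#' @param epsilon Per-substitution incompatibility probability in (0, 1).
#' @return List of class `"ri_distribution"` with `pmf(k)`, `cdf(k)`,
#'   `mean`, and `sample(n)` (draws using R's global random stream).
#' @examples
#' d <- ri_substitution_distribution(0.02)
#' d$mean # 50 substitutions on average
#' @export
ri_substitution_distribution <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 1)
    stop("`epsilon` must lie strictly inside (0, 1)", call. = FALSE)
  structure(list(
    epsilon = epsilon,
    pmf = function(k) ifelse(k >= 1 & k == round(k),
                             (1 - epsilon)^(k - 1) * epsilon, 0),
    cdf = function(k) 1 - (1 - epsilon)^floor(pmax(k, 0)),
    mean = 1 / epsilon,
    sample = function(n) stats::rgeom(n, epsilon) + 1L
  ), class = "ri_distribution")
}

#' @export
print.ri_distribution <- function(x, ...) {
  cat(sprintf(
    "Geometric RI waiting distribution: epsilon = %g, mean %g substitutions\n",
    x$epsilon, x$mean))
  invisible(x)
}

#' Expected time to complete reproductive isolation
#'
#' The expected number of substitutions to reach RI is `1 / epsilon`; dividing
#' by the per-generation substitution rate of the diverging pair converts it
#' to generations. Because the neutral substitution rate tracks the mutation
#' rate, lineages with higher mutation rates are expected to reach RI sooner.
#'
#' @param epsilon Per-substitution incompatibility probability.
#' @param substitution_rate Substitutions per generation accumulating between
#'   the pair (> 0).
#' @return Expected generations to complete RI.
#' @examples
#' expected_time_to_ri(0.01, 1e-3) # 100000 generations
#' @export
expected_time_to_ri <- function(epsilon, substitution_rate) {
  if (!is.numeric(substitution_rate) || length(substitution_rate) != 1L ||
      substitution_rate <= 0)
    stop("`substitution_rate` must be a single positive rate", call. = FALSE)
  (1 / epsilon) / substitution_rate
}

#' Fit epsilon and the accumulation exponent from incompatibility counts
#'
#' Regresses observed incompatibility counts against divergence by fitting the
#' power law `count = a d^b`. The exponent `b` measures how much faster than
#' linear incompatibilities accumulate (1 for paired incompatibilities, 2 for
#' a full snowball); `epsilon` is recovered from the prefactor `a` under the
#' declared accumulation model (`a = epsilon` for pairwise-linear,
#' `a = epsilon / 2` for snowball, since `d (d - 1) / 2 ~ d^2 / 2`).
#'
#' @param table Data frame with columns `d` (substitutions, >= 1) and `count`
#'   (observed incompatibilities, >= 0).
#' @param accumulation Model used to convert the prefactor into an epsilon
#'   estimate.
#' @param engine `"log_ls"` (default): least squares on
#'   `log(count) ~ log(d)`, dropping zero counts; `"poisson"`: a Poisson
#'   regression with log link, `count ~ log(d)`, which keeps zero counts.
#' @return List with `epsilon_hat`, `exponent_hat`, `prefactor_hat`, `n_rows`
#'   (rows used in the fit) and `engine`.
#' @export
fit_epsilon_and_exponent <- function(table,
                                     accumulation = c("pairwise_linear",
                                                      "snowball_quadratic"),
                                     engine = c("log_ls", "poisson")) {
  accumulation <- match.arg(accumulation)
  engine <- match.arg(engine)
  if (!all(c("d", "count") %in% names(table)))
    stop("`table` needs columns `d` and `count`", call. = FALSE)
  tab <- table[table$d >= 1 & !is.na(table$count) & table$count >= 0, ,
               drop = FALSE]
  if (all(tab$count == 0))
    stop("all incompatibility counts are zero; nothing to fit", call. = FALSE)
  if (engine == "log_ls") {
    pos <- tab[tab$count > 0, , drop = FALSE]
    if (nrow(pos) < 3)
      stop("need at least 3 rows with positive counts", call. = FALSE)
    fit <- stats::lm(log(count) ~ log(d), data = pos)
    a <- exp(unname(stats::coef(fit)[1]))
    b <- unname(stats::coef(fit)[2])
    n_used <- nrow(pos)
  } else {
    if (nrow(tab) < 3)
      stop("need at least 3 rows", call. = FALSE)
    fit <- stats::glm(count ~ log(d), family = stats::poisson(), data = tab)
    a <- exp(unname(stats::coef(fit)[1]))
    b <- unname(stats::coef(fit)[2])
    n_used <- nrow(tab)
  }
  eps <- if (accumulation == "pairwise_linear") a else 2 * a
  list(epsilon_hat = eps, exponent_hat = b, prefactor_hat = a,
       n_rows = n_used, engine = engine)
}

#' Synthetic incompatibility-vs-divergence tables
#'
#' Generates `(d, count)` tables from a landscape model, either noiseless
#' (expected counts) or with Poisson noise around the expectation, for
#' exercising [fit_epsilon_and_exponent()].
#'
#' Counts come either from the exact pair-count expectation of
#' [incompatibility_count()] (`form = "pairs"`, the default) or from the
#' asymptotic power law that [fit_epsilon_and_exponent()] estimates
#' (`form = "power_law"`: `epsilon d` for pairwise-linear, `epsilon d^2 / 2`
#' for snowball). The power-law form is the one to use for exact
#' parameter-recovery checks, since `d (d - 1) / 2` is not itself a pure
#' power of `d` at small divergence.
#'
#' @param model A [landscape_model()].
#' @param d Vector of divergences.
#' @param noise `"none"` or `"poisson"`.
#' @param seed Optional integer seed (Poisson noise only).
#' @param form `"pairs"` or `"power_law"` (see above).
#' @return Data frame with columns `d` and `count`.
#' @export
make_incompatibility_table <- function(model, d = 10:100,
                                       noise = c("none", "poisson"),
                                       seed = NULL,
                                       form = c("pairs", "power_law")) {
  noise <- match.arg(noise)
  form <- match.arg(form)
  mu <- if (form == "pairs") incompatibility_count(d, model)
        else switch(model$accumulation,
                    pairwise_linear = model$epsilon * d,
                    snowball_quadratic = model$epsilon * d^2 / 2)
  count <- if (noise == "none") mu else {
    if (!is.null(seed)) set.seed(seed)
    stats::rpois(length(mu), mu)
  }
  data.frame(d = d, count = count)
}
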