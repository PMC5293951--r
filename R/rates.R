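#' Substitution rate predicted from a fixation probability
#'
#' Over long periods the substitution rate is the rate of input of new
#' mutations times their fixation probability, `2 Ne u P_fix`, with `Ne` the
#' effective size at the mutation's origin. For a neutral mutation starting
#' from one copy (`P_fix = 1/(2N)`) this reduces to `u Ne / N`, so the neutral
#' substitution rate equals the mutation rate whenever `Ne = N`, regardless of
#' demographic history.
#'
#' @param u Mutation rate per site per generation (> 0).
#' @param profile A [demography_profile()] (supplies the origin-time `Ne`).
#' @param p A `fixation_estimate` from [fixation_probability()].
#' @return A list of class `"rate_prediction"` with `mutation_rate`,
#'   `substitution_rate` and `log_ratio = ln(substitution_rate / u)` (`NA`
#'   when the substitution rate is 0).
#' @export
substitution_rate <- function(u, profile, p) {
  stopifnot(inherits(profile, "demography_profile"),
            inherits(p, "fixation_estimate"))
  if (!is.numeric(u) || length(u) != 1L || u <= 0)
    stop("`u` must be a single positive mutation rate", call. = FALSE)
  rate <- 2 * ne_initial(profile) * u * p$p_fix
  structure(
    list(mutation_rate = u, substitution_rate = rate,
         log_ratio = if (rate > 0) log(rate / u) else NA_real_),
    class = "rate_prediction"
  )
}

#' @export
print.rate_prediction <- function(x, ...) {
  cat(sprintf("Substitution rate: %.6g (u = %.6g, ln(rate/u) = %s)\n",
              x$substitution_rate, x$mutation_rate,
              ifelse(is.na(x$log_ratio), "undefined",
                     sprintf("%.4f", x$log_ratio))))
  invisible(x)
}

ratio_of_pfix <- function(s_num, s_den, profile, n_replicates, seed) {
  seeds <- if (is.null(seed)) list(NULL, NULL) else as.list(derive_seeds(seed, 2))
  num <- fixation_probability(s_num, profile, n_replicates = n_replicates,
                              seed = seeds[[1]])
  den <- fixation_probability(s_den, profile, n_replicates = n_replicates,
                              seed = seeds[[2]])
  num$p_fix / den$p_fix
}

#' dN/dS predicted from fixation probabilities
#'
#' Ratio of the fixation probability of a slightly deleterious mutation
#' (`s = -0.001`, standing in for non-synonymous changes) to that of a neutral
#' mutation (`s = 0`, synonymous changes), both starting from a single new
#' copy under the same demographic profile. Constant-size profiles use the
#' closed form; changing profiles use the Monte-Carlo fixation formula.
#'
#' @param profile A [demography_profile()].
#' @param n_replicates Monte-Carlo replicates (changing profiles only).
#' @param seed Optional integer seed.
#' @param s_deleterious Selection coefficient of the non-synonymous class.
#' @return A single ratio in `(0, 1]` for negative `s_deleterious`.
#' @export
dnds_ratio <- function(profile, n_replicates = 500000L, seed = NULL,
                       s_deleterious = -0.001) {
  ratio_of_pfix(s_deleterious, 0, profile, n_replicates, seed)
}

#' Kr/Kc predicted from fixation probabilities
#'
#' Ratio of the fixation probability of a deleterious mutation (`s = -0.01`,
#' radical amino-acid changes) to that of a slightly deleterious one
#' (`s = -0.001`, conservative changes). Declines faster with effective
#' population size than [dnds_ratio()] because the numerator class is under
#' stronger purifying selection.
#'
#' @inheritParams dnds_ratio
#' @param s_radical,s_conservative Selection coefficients of the two classes.
#' @return A single ratio in `(0, 1]`.
#' @export
krkc_ratio <- function(profile, n_replicates = 500000L, seed = NULL,
                       s_radical = -0.01, s_conservative = -0.001) {
  ratio_of_pfix(s_radical, s_conservative, profile, n_replicates, seed)
}

#' Standard demographic scenarios
#'
#' The five scenarios used throughout: constant size; growth to 1.9 times the
#' initial size over 20 (fast) or 200 (slow) generations; decline to 0.1 times
#' the initial size over 20 or 200 generations.
#'
#' @param n0 Initial census size.
#' @param ne_over_n Ne/N ratio passed through to each profile.
#' @return Named list of [demography_profile()] objects.
#' @export
standard_scenarios <- function(n0, ne_over_n = 1) {
  list(
    constant     = demography_profile(n0, 1.0, 0,   ne_over_n = ne_over_n),
    fast_growth  = demography_profile(n0, 1.9, 20,  ne_over_n = ne_over_n),
    slow_growth  = demography_profile(n0, 1.9, 200, ne_over_n = ne_over_n),
    fast_decline = demography_profile(n0, 0.1, 20,  ne_over_n = ne_over_n),
    slow_decline = demography_profile(n0, 0.1, 200, ne_over_n = ne_over_n)
  )
}

#' Substitution-rate grid across demography, population size and selection
#'
#' Evaluates the fixation-probability formula over a grid of demographic
#' scenarios, initial effective sizes and selection coefficients, and tabulates
#' the log substitution-rate-to-mutation-rate ratio together with the dN/dS
#' and Kr/Kc predictions for each scenario-by-size cell. Each cell gets its
#' own seed derived from `seed` (see [derive_seeds()]), so cells are
#' independently reproducible.
#'
#' @param ne_values Initial census/effective sizes to sweep.
#' @param scenarios Named list of scenario constructors; by default the five
#'   [standard_scenarios()] (functions of `n0` are also accepted).
#' @param s_values Selection coefficients; default neutral, beneficial
#'   (+0.001), slightly deleterious (-0.001) and deleterious (-0.01).
#' @param n_replicates Monte-Carlo replicates per cell with changing size.
#' @param seed Master seed.
#' @return A data frame with columns `scenario`, `ne`, `ne_final`, `s`,
#'   `p_fix`, `se`, `log_ratio`, `log_ratio_se`, `dnds`, `krkc` (the two
#'   ratios are repeated on every row of their cell).
#' @export
substitution_rate_grid <- function(ne_values = c(500, 1000, 5000),
                                   scenarios = NULL,
                                   s_values = c(0, 0.001, -0.001, -0.01),
                                   n_replicates = 500000L, seed = 1L) {
  if (is.null(scenarios)) {
    nms <- names(standard_scenarios(100))
    scenarios <- stats::setNames(lapply(nms, function(nm) {
      force(nm)
      function(n0) standard_scenarios(n0)[[nm]]
    }), nms)
  }
  if (is.null(names(scenarios)) || any(names(scenarios) == ""))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  cells <- expand.grid(scenario = names(scenarios), ne = ne_values,
                       stringsAsFactors = FALSE)
  cell_seeds <- derive_seeds(seed, nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    maker <- scenarios[[cells$scenario[i]]]
    prof <- if (is.function(maker)) maker(cells$ne[i]) else maker
    s_seeds <- derive_seeds(cell_seeds[i], length(s_values))
    est <- lapply(seq_along(s_values), function(k)
      fixation_probability(s_values[k], prof, n_replicates = n_replicates,
                           seed = s_seeds[k]))
    p_fix <- vapply(est, `[[`, numeric(1), "p_fix")
    se <- vapply(est, `[[`, numeric(1), "std_error")
    log_ratio <- ifelse(p_fix > 0, log(2 * ne_initial(prof) * p_fix), NA_real_)
    log_ratio_se <- ifelse(p_fix > 0, se / p_fix, NA_real_)
    pick <- function(sv) if (sv %in% s_values) p_fix[match(sv, s_values)] else NA_real_
    dnds <- pick(-0.001) / pick(0)
    krkc <- pick(-0.01) / pick(-0.001)
    rows[[i]] <- data.frame(
      scenario = cells$scenario[i], ne = cells$ne[i],
      ne_final = ne_final(prof), s = s_values, p_fix = p_fix, se = se,
      log_ratio = log_ratio, log_ratio_se = log_ratio_se,
      dnds = dnds, krkc = krkc, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
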