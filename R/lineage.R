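#' Parameters of the lineage diversification simulator
#'
#' Bundles the three waiting times that govern diversification: `t_i`, the
#' expected time between population-isolating events; `t_s`, the expected
#' time for two isolated populations to come back into secondary contact; and
#' `t_r`, the expected time for an isolated pair to accumulate enough
#' incompatibilities to reach complete reproductive isolation (RI). Instead of
#' a fixed `t_r`, the RI time can be coupled to molecular evolution: the
#' number of substitutions to RI is drawn from the geometric distribution of
#' [ri_substitution_distribution()] and divided by the neutral per-pair
#' substitution rate (the mutation rate `u`), so that faster-mutating
#' lineages reach RI sooner.
#'
#' @param t_i Expected waiting time between isolating events (generations).
#' @param t_s Expected waiting time to secondary contact after a split.
#' @param t_r Expected time to complete RI; ignored when `coupling` is given.
#' @param coupling Optional list `list(epsilon = , u = )`: RI time is drawn
#'   as `k / u` with `k` geometric with success probability `epsilon`.
#' @param timing_mode `"exponential"` (waiting times exponentially distributed
#'   with the stated means; default) or `"fixed"` (deterministic waits).
#' @param contact_outcomes Named numeric vector of probabilities
#'   `c(reinforce = , extinct_one = , extinct_both = )` applied when contact
#'   occurs before RI is complete; the remainder is the probability that the
#'   pair fuses back into a single lineage.
#' @param total_time Length of the simulation (generations).
#' @param max_lineages Cap on concurrently extant lineages; reaching it sets
#'   the `truncated` flag on the history rather than raising an error.
#' @return An object of class `"regime_parameters"`.
#' @examples
#' regime_parameters(t_i = 100, t_s = 500, t_r = 200, total_time = 1000)
#' @export
regime_parameters <- function(t_i, t_s, t_r = NULL, coupling = NULL,
                              timing_mode = c("exponential", "fixed"),
                              contact_outcomes = c(reinforce = 0.5,
                                                   extinct_one = 0.25,
                                                   extinct_both = 0.05),
                              total_time, max_lineages = 1024L) {
  timing_mode <- match.arg(timing_mode)
  if (t_i <= 0 || t_s <= 0) stop("`t_i` and `t_s` must be > 0", call. = FALSE)
  if (is.null(coupling)) {
    if (is.null(t_r) || t_r <= 0)
      stop("supply a positive `t_r` or a `coupling` spec", call. = FALSE)
  } else {
    if (!all(c("epsilon", "u") %in% names(coupling)) ||
        coupling$epsilon <= 0 || coupling$epsilon >= 1 || coupling$u <= 0)
      stop("`coupling` needs epsilon in (0,1) and u > 0", call. = FALSE)
  }
  req <- c("reinforce", "extinct_one", "extinct_both")
  if (!all(req %in% names(contact_outcomes)))
    stop("`contact_outcomes` needs names reinforce, extinct_one, extinct_both",
         call. = FALSE)
  co <- contact_outcomes[req]
  if (any(co < 0) || sum(co) > 1)
    stop("contact outcome probabilities must be in [0,1] with sum <= 1",
         call. = FALSE)
  if (total_time <= 0) stop("`total_time` must be > 0", call. = FALSE)
  if (max_lineages < 2) stop("`max_lineages` must be >= 2", call. = FALSE)
  structure(
    list(t_i = t_i, t_s = t_s, t_r = t_r, coupling = coupling,
         timing_mode = timing_mode, contact_outcomes = co,
         total_time = total_time, max_lineages = as.integer(max_lineages)),
    class = "regime_parameters"
  )
}

#' @export
print.regime_parameters <- function(x, ...) {
  tr <- if (is.null(x$coupling)) sprintf("%g", x$t_r)
        else sprintf("coupled (epsilon = %g, u = %g; mean %g)",
                     x$coupling$epsilon, x$coupling$u,
                     1 / (x$coupling$epsilon * x$coupling$u))
  cat(sprintf("Regime: T_I = %g, T_S = %g, T_R = %s, %s timing, %g generations\n",
              x$t_i, x$t_s, tr, x$timing_mode, x$total_time))
  invisible(x)
}

expected_tr <- function(params) {
  if (is.null(params$coupling)) params$t_r
  else 1 / (params$coupling$epsilon * params$coupling$u)
}

#' Classify the diversification regime from the three waiting times
#'
#' The relative magnitudes of the waiting times to isolation (`t_i`),
#' secondary contact (`t_s`) and complete RI (`t_r`) determine what a
#' reconstructed phylogeny records:
#' \describe{
#'   \item{`isolation_completes_ri`}{`t_s >= t_r`: RI completes before contact,
#'     every isolating event yields a species, internodes reflect `t_i`.}
#'   \item{`fusion_latest_split_only`}{`t_r` much larger than `t_s` (ratio at
#'     least `far_factor`) and `t_i >= t_s`: pairs fuse before the next split,
#'     so only the most recent isolating event is visible.}
#'   \item{`chained_isolation`}{`t_r` much larger than `t_s` and `t_i < t_s`:
#'     new splits outpace contact.}
#'   \item{`partial_ri_contact`}{`t_s < t_r < far_factor * t_s`: contact finds
#'     partial RI, and reinforcement or extinction decides the outcome.}
#' }
#' Ties: `t_s = t_r` counts as `isolation_completes_ri`; `t_i = t_s` in the
#' far-contact case counts as `fusion_latest_split_only`.
#'
#' @param t_i,t_s,t_r Waiting times (> 0).
#' @param far_factor Ratio of `t_r` to `t_s` beyond which contact is treated
#'   as happening far before RI; default 10.
#' @return One of the four regime labels.
#' @export
classify_regime <- function(t_i, t_s, t_r, far_factor = 10) {
  if (any(c(t_i, t_s, t_r) <= 0))
    stop("all waiting times must be > 0", call. = FALSE)
  if (t_s >= t_r) return("isolation_completes_ri")
  if (t_r / t_s >= far_factor) {
    if (t_i >= t_s) return("fusion_latest_split_only")
    return("chained_isolation")
  }
  "partial_ri_contact"
}

draw_wait <- function(mean, mode) {
  if (mode == "fixed") mean else stats::rexp(1L, rate = 1 / mean)
}

draw_ri_time <- function(params) {
  if (is.null(params$coupling))
    return(draw_wait(params$t_r, params$timing_mode))
  k <- stats::rgeom(1L, params$coupling$epsilon) + 1
  k / params$coupling$u
}

#' Simulate a lineage diversification history
#'
#' Event-driven simulation starting from a single lineage. Each extant
#' lineage experiences isolating events at expected intervals `t_i`; every
#' split creates a sister pair that is scheduled for secondary contact
#' (expected wait `t_s`) and for completion of RI (expected wait `t_r`, or a
#' coupled draw). If RI completes first, contact has no effect and the pair
#' are distinct species. If contact arrives first, the outcome is sampled
#' from `contact_outcomes`: the pair fuses back into one lineage (divergence
#' is discarded and the clock restarts), reinforcement completes RI on the
#' spot, or one or both populations go extinct through wasted reproduction on
#' unfit hybrids.
#'
#' @param params A [regime_parameters()] object.
#' @param seed Optional integer seed.
#' @return An object of class `"lineage_history"`: a list with `lineages`
#'   (id, parent, birth, death, status), `pairs` (the per-split contact/RI
#'   bookkeeping), `events` (time-ordered log), `total_time` and `truncated`.
#' @examples
#' p <- regime_parameters(t_i = 100, t_s = 500, t_r = 200,
#'                        timing_mode = "fixed", total_time = 450)
#' h <- simulate_history(p, seed = 1)
#' h$events
#' @export
simulate_history <- function(params, seed = NULL) {
  stopifnot(inherits(params, "regime_parameters"))
  if (!is.null(seed)) set.seed(seed)
  tt <- params$total_time

  # lineage state
  lin_parent <- NA_integer_; lin_birth <- 0; lin_death <- NA_real_
  lin_status <- "extant"
  n_lin <- 1L

  # pair state (one record per split)
  pr_a <- integer(); pr_b <- integer(); pr_split <- numeric()
  pr_contact <- numeric(); pr_ri <- numeric()
  pr_resolved <- logical(); pr_ri_done <- logical()

  # event queue: type 1 = isolation(lineage), 2 = contact(pair), 3 = ri(pair)
  ev_time <- numeric(); ev_type <- integer(); ev_key <- integer()
  ev_done <- logical()
  push <- function(time, type, key) {
    ev_time[length(ev_time) + 1L] <<- time
    ev_type[length(ev_type) + 1L] <<- type
    ev_key[length(ev_key) + 1L] <<- key
    ev_done[length(ev_done) + 1L] <<- FALSE
  }

  # log
  log_time <- numeric(); log_type <- character()
  log_l1 <- integer(); log_l2 <- integer()
  log_event <- function(time, type, l1, l2 = NA_integer_) {
    log_time[length(log_time) + 1L] <<- time
    log_type[length(log_type) + 1L] <<- type
    log_l1[length(log_l1) + 1L] <<- l1
    log_l2[length(log_l2) + 1L] <<- l2
  }

  truncated <- FALSE
  push(draw_wait(params$t_i, params$timing_mode), 1L, 1L)

  repeat {
    open <- which(!ev_done & ev_time <= tt)
    if (!length(open)) break
    i <- open[which.min(ev_time[open])]
    ev_done[i] <- TRUE
    t_now <- ev_time[i]; key <- ev_key[i]

    if (ev_type[i] == 1L) {                     # isolating event
      if (lin_status[key] != "extant") next
      if (sum(lin_status == "extant") >= params$max_lineages) {
        truncated <- TRUE
        next
      }
      n_lin <- n_lin + 1L
      child <- n_lin
      lin_parent[child] <- key; lin_birth[child] <- t_now
      lin_death[child] <- NA_real_; lin_status[child] <- "extant"
      log_event(t_now, "isolation", key, child)
      j <- length(pr_a) + 1L
      pr_a[j] <- key; pr_b[j] <- child; pr_split[j] <- t_now
      pr_contact[j] <- t_now + draw_wait(params$t_s, params$timing_mode)
      pr_ri[j] <- t_now + draw_ri_time(params)
      pr_resolved[j] <- FALSE; pr_ri_done[j] <- FALSE
      push(pr_contact[j], 2L, j)
      push(pr_ri[j], 3L, j)
      push(t_now + draw_wait(params$t_i, params$timing_mode), 1L, key)
      push(t_now + draw_wait(params$t_i, params$timing_mode), 1L, child)

    } else if (ev_type[i] == 2L) {              # secondary contact
      if (pr_resolved[key]) next
      a <- pr_a[key]; b <- pr_b[key]
      if (lin_status[a] != "extant" || lin_status[b] != "extant") {
        pr_resolved[key] <- TRUE
        next
      }
      log_event(t_now, "contact", a, b)
      if (pr_ri_done[key]) {                    # distinct species meet: no-op
        pr_resolved[key] <- TRUE
        next
      }
      co <- params$contact_outcomes
      outcome <- sample(c("reinforce", "extinct_one", "extinct_both", "fuse"),
                        1L, prob = c(co, 1 - sum(co)))
      if (outcome == "fuse") {
        lin_status[b] <- "fused"; lin_death[b] <- t_now
        log_event(t_now, "fuse", a, b)
      } else if (outcome == "reinforce") {
        pr_ri_done[key] <- TRUE
        log_event(t_now, "reinforce", a, b)
        log_event(t_now, "ri_complete", a, b)
      } else if (outcome == "extinct_one") {
        victim <- if (stats::runif(1) < 0.5) a else b
        lin_status[victim] <- "extinct"; lin_death[victim] <- t_now
        log_event(t_now, "extinction", victim)
      } else {
        lin_status[a] <- "extinct"; lin_death[a] <- t_now
        lin_status[b] <- "extinct"; lin_death[b] <- t_now
        log_event(t_now, "extinction", a)
        log_event(t_now, "extinction", b)
      }
      pr_resolved[key] <- TRUE

    } else {                                    # RI completion
      if (pr_resolved[key] || pr_ri_done[key]) next
      a <- pr_a[key]; b <- pr_b[key]
      if (lin_status[a] != "extant" || lin_status[b] != "extant") {
        pr_resolved[key] <- TRUE
        next
      }
      pr_ri_done[key] <- TRUE
      pr_resolved[key] <- TRUE                  # later contact is a no-op
      log_event(t_now, "ri_complete", a, b)
    }
  }

  ord <- order(log_time, seq_along(log_time))
  structure(list(
    lineages = data.frame(id = seq_len(n_lin), parent = lin_parent,
                          birth = lin_birth, death = lin_death,
                          status = lin_status, stringsAsFactors = FALSE),
    pairs = data.frame(a = pr_a, b = pr_b, split_time = pr_split,
                       contact_time = pr_contact, ri_time = pr_ri,
                       ri_complete = pr_ri_done),
    events = data.frame(time = log_time[ord], type = log_type[ord],
                        lineage1 = log_l1[ord], lineage2 = log_l2[ord],
                        stringsAsFactors = FALSE),
    total_time = tt, truncated = truncated, params = params
  ), class = "lineage_history")
}

#' @export
print.lineage_history <- function(x, ...) {
  n_extant <- sum(x$lineages$status == "extant")
  cat(sprintf(
    "Lineage history: %d lineages (%d extant) over %g generations, %d events%s\n",
    nrow(x$lineages), n_extant, x$total_time, nrow(x$events),
    if (x$truncated) " [truncated at lineage cap]" else ""))
  invisible(x)
}

#' Number of lineages extant at a given time
#' @param history A `lineage_history`.
#' @param at_time Observation time (defaults to the end of the simulation).
#' @return Integer count.
#' @export
extant_lineages <- function(history, at_time = history$total_time) {
  ln <- history$lineages
  sum(ln$birth < at_time & (is.na(ln$death) | ln$death > at_time))
}
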