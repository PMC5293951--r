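#' Run the substitution-rate grid and write its outputs
#'
#' Validates the configuration, evaluates [substitution_rate_grid()] and
#' writes `grid.tsv` plus a `manifest_grid.tsv` recording the seed and all
#' parameters at full precision. Nothing is written if validation fails.
#'
#' @param config List with optional entries `ne_values`, `s_values`,
#'   `n_replicates` (defaults: 500/1000/5000, the four standard selection
#'   classes, 500000 replicates).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @return Invisibly, the paths written.
#' @export
run_grid <- function(config = list(), out_dir = ".", seed = 1L) {
  ne_values <- config$ne_values %||% c(500, 1000, 5000)
  s_values <- config$s_values %||% c(0, 0.001, -0.001, -0.01)
  n_replicates <- config$n_replicates %||% 500000L
  if (!is.numeric(n_replicates) || n_replicates < 1)
    stop("invalid config: `n_replicates` must be a positive integer",
         call. = FALSE)
  if (!is.numeric(ne_values) || any(ne_values < 2))
    stop("invalid config: `ne_values` must be sizes >= 2", call. = FALSE)
  if (!is.numeric(s_values) || any(s_values <= -1))
    stop("invalid config: `s_values` must all exceed -1", call. = FALSE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- substitution_rate_grid(ne_values = ne_values, s_values = s_values,
                                 n_replicates = as.integer(n_replicates),
                                 seed = seed)
  grid_path <- file.path(out_dir, "grid.tsv")
  write_tsv6(grid, grid_path)
  manifest <- write_manifest(out_dir, "grid",
                             list(seed = seed, n_replicates = n_replicates,
                                  ne_values = ne_values, s_values = s_values))
  invisible(c(grid_path, manifest))
}

#' Run the holey-landscape report and optional epsilon fit
#'
#' Writes `landscape.tsv` with the scalar predictions of the incompatibility
#' model (expected viable paths, snowball condition, mean substitutions and
#' expected generations to RI) and, when `config$table` points to a TSV with
#' columns `d` and `count`, an `epsilon_fit.tsv` with the recovered epsilon
#' and accumulation exponent.
#'
#' @param config List with `epsilon` (required, in (0,1)), and optional
#'   `big_l` (default 1000), `accumulation`, `substitution_rate` (per-pair,
#'   per generation; default `1e-3`), `table` (path to an input TSV).
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
run_landscape <- function(config = list(), out_dir = ".") {
  epsilon <- config$epsilon %||% stop("invalid config: `epsilon` is required",
                                      call. = FALSE)
  big_l <- config$big_l %||% 1000
  accumulation <- config$accumulation %||% "pairwise_linear"
  sub_rate <- config$substitution_rate %||% 1e-3
  model <- landscape_model(big_l, epsilon, accumulation)
  if (sub_rate <= 0)
    stop("invalid config: `substitution_rate` must be > 0", call. = FALSE)
  if (!is.null(config$table) && !file.exists(config$table))
    stop(sprintf("invalid config: input table %s not found", config$table),
         call. = FALSE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  ep <- expected_paths(model)
  report <- data.frame(
    big_l = model$big_l, epsilon = epsilon,
    expected_paths = ep$expected_paths, viable = ep$viable,
    snowball = if (model$big_l >= 2) snowball_condition(model) else NA,
    snowball_threshold = if (model$big_l >= 2) log(model$big_l) / model$big_l
                         else NA_real_,
    mean_substitutions_to_ri = 1 / epsilon,
    substitution_rate = sub_rate,
    expected_generations_to_ri = expected_time_to_ri(epsilon, sub_rate)
  )
  paths <- c(paths, write_tsv6(report, file.path(out_dir, "landscape.tsv")))
  if (!is.null(config$table)) {
    tab <- read_tsv_cols(config$table, c("d", "count"))
    fit <- fit_epsilon_and_exponent(tab, accumulation = accumulation)
    fit_df <- data.frame(epsilon_hat = fit$epsilon_hat,
                         exponent_hat = fit$exponent_hat,
                         n_rows = fit$n_rows)
    paths <- c(paths, write_tsv6(fit_df, file.path(out_dir, "epsilon_fit.tsv")))
  }
  c(paths, write_manifest(out_dir, "landscape",
                          list(epsilon = epsilon, big_l = big_l,
                               accumulation = accumulation,
                               substitution_rate = sub_rate)))
  invisible(paths)
}

#' Run the lineage simulator and write Newick, event-log and summary files
#'
#' Simulates `n_histories` diversification histories under one regime,
#' writing `trees.nwk` (one Newick string per surviving history),
#' `events.tsv` (the event logs with a `history` column) and `summary.tsv`
#' (per-history tip count, crown age and speciation-rate estimate). When
#' `config$u_values` is supplied the run is a mutation-rate sweep via
#' [sweep_mutation_rate()], and `sweep.tsv` is written instead.
#'
#' @param config List with `t_i`, `t_s`, `total_time` (required), and
#'   optional `t_r`, `coupling` (list with `epsilon`, `u`), `timing_mode`,
#'   `contact_outcomes`, `max_lineages`, `n_histories` (default 100),
#'   `u_values` + `epsilon` (sweep mode).
#' @param out_dir Output directory.
#' @param seed Master seed; history `j` uses the `j`-th derived seed.
#' @return Invisibly, the paths written.
#' @export
run_lineages <- function(config = list(), out_dir = ".", seed = 1L) {
  for (f in c("t_i", "t_s", "total_time"))
    if (is.null(config[[f]]))
      stop(sprintf("invalid config: `%s` is required", f), call. = FALSE)
  sweep_mode <- !is.null(config$u_values)
  coupling <- config$coupling
  if (!is.null(coupling))
    coupling <- list(epsilon = as.numeric(coupling$epsilon),
                     u = as.numeric(coupling$u))
  params <- regime_parameters(
    t_i = num_field(config, "t_i"), t_s = num_field(config, "t_s"),
    t_r = num_field(config, "t_r") %||% (if (sweep_mode) 1 else NULL),
    coupling = coupling,
    timing_mode = config$timing_mode %||% "exponential",
    contact_outcomes = num_field(config, "contact_outcomes") %||%
      c(reinforce = 0.5, extinct_one = 0.25, extinct_both = 0.05),
    total_time = num_field(config, "total_time"),
    max_lineages = num_field(config, "max_lineages") %||% 1024L
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (sweep_mode) {
    if (is.null(config$epsilon))
      stop("invalid config: sweep mode needs `epsilon`", call. = FALSE)
    sweep <- sweep_mutation_rate(num_field(config, "u_values"),
                                 num_field(config, "epsilon"), params,
                                 n_histories = num_field(config, "n_histories") %||% 500L,
                                 seed = seed)
    path <- write_tsv6(sweep, file.path(out_dir, "sweep.tsv"))
    return(invisible(c(path, write_manifest(out_dir, "lineages",
                                            c(config, list(seed = seed))))))
  }

  n_histories <- config$n_histories %||% 100L
  seeds <- derive_seeds(seed, n_histories)
  newick <- character(); ev_rows <- vector("list", n_histories)
  summaries <- vector("list", n_histories)
  for (j in seq_len(n_histories)) {
    h <- simulate_history(params, seed = seeds[j])
    if (nrow(h$events))
      ev_rows[[j]] <- cbind(history = j, h$events)
    tr <- suppressMessages(reconstruct_tree(h))
    if (is.null(tr)) next
    nt <- length(tr$tip.label)
    newick <- c(newick, ape::write.tree(tr))
    est <- if (nt >= 2) diversification_estimate(tr)
           else list(lambda = 0, n_tips = 1L, crown_age = NA_real_)
    summaries[[j]] <- data.frame(history = j, n_tips = est$n_tips,
                                 crown_age = est$crown_age,
                                 lambda = est$lambda,
                                 truncated = h$truncated)
  }
  paths <- character()
  nwk_path <- file.path(out_dir, "trees.nwk")
  writeLines(newick, nwk_path)
  paths <- c(paths, nwk_path)
  ev <- do.call(rbind, ev_rows)
  if (is.null(ev))
    ev <- data.frame(history = integer(), time = numeric(),
                     type = character(), lineage1 = integer(),
                     lineage2 = integer())
  paths <- c(paths, write_tsv6(ev, file.path(out_dir, "events.tsv")))
  sm <- do.call(rbind, summaries)
  if (is.null(sm))
    sm <- data.frame(history = integer(), n_tips = integer(),
                     crown_age = numeric(), lambda = numeric(),
                     truncated = logical())
  paths <- c(paths, write_tsv6(sm, file.path(out_dir, "summary.tsv")))
  c(paths, write_manifest(out_dir, "lineages", c(config, list(seed = seed))))
  invisible(paths)
}

#' Generate synthetic input fixtures
#'
#' Reproducible synthetic inputs for exercising the pipelines without any
#' external data: incompatibility-vs-divergence tables under the pairwise or
#' snowball accumulation model, or a suite of canned regime configurations
#' (one YAML-like TSV per regime).
#'
#' @param kind `"pairwise_table"`, `"snowball_table"` or `"regime_suite"`.
#' @param params List: for the tables, `epsilon` (default 0.02), `d`
#'   (default `10:100`), `noise` (`"none"` or `"poisson"`), `big_l`
#'   (default 1000); ignored for `regime_suite`.
#' @param seed Integer seed (used by Poisson noise).
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(kind = c("pairwise_table", "snowball_table",
                                       "regime_suite"),
                              params = list(), seed = 1L, out_dir = ".") {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (kind %in% c("pairwise_table", "snowball_table")) {
    accumulation <- if (kind == "pairwise_table") "pairwise_linear"
                    else "snowball_quadratic"
    model <- landscape_model(params$big_l %||% 1000,
                             params$epsilon %||% 0.02, accumulation)
    tab <- make_incompatibility_table(model, d = params$d %||% 10:100,
                                      noise = params$noise %||% "none",
                                      seed = seed)
    return(invisible(write_tsv6(tab, file.path(out_dir,
                                               paste0(kind, ".tsv")))))
  }
  regimes <- data.frame(
    regime = c("isolation_completes_ri", "fusion_latest_split_only",
               "chained_isolation", "partial_ri_contact"),
    t_i = c(100, 300, 30, 100),
    t_s = c(500, 50, 50, 100),
    t_r = c(200, 5000, 5000, 500),
    total_time = c(1000, 1030, 1000, 1000)
  )
  invisible(write_tsv6(regimes, file.path(out_dir, "regime_suite.tsv")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce a config entry to numeric (YAML readers hand back strings for
# notations like 1.0e6); NULL passes through, non-numeric text errors
num_field <- function(config, name) {
  v <- config[[name]]
  if (is.null(v)) return(NULL)
  out <- suppressWarnings(as.numeric(unlist(v)))
  if (any(is.na(out)))
    stop(sprintf("invalid config: `%s` must be numeric", name), call. = FALSE)
  names(out) <- names(unlist(v))
  out
}

write_manifest <- function(out_dir, name, params) {
  flat <- lapply(params, function(v) paste(format(v, digits = 17),
                                           collapse = ","))
  keep <- vapply(flat, function(v) length(v) == 1L, logical(1))
  df <- data.frame(key = names(flat)[keep],
                   value = unlist(flat[keep], use.names = FALSE))
  path <- file.path(out_dir, paste0("manifest_", name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  path
}
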