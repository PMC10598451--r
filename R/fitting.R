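#' Annealing configuration for (B, J) inference
#'
#' Controls the simulated-annealing search used by [anneal_fit()]. Defaults:
#' bounds wide enough to bracket every value seen in practice
#' (`B` in `[-2, 2]`, `J` in `[0, 2]`), a budget of 500 objective
#' evaluations, geometric cooling from `t_init` to `t_final`, Gaussian
#' proposals whose scale shrinks geometrically from `step_init` to
#' `step_final` (reflected at the bounds), and one replicate simulation per
#' objective evaluation — the ensemble spread of the summary indices is
#' small, so averaging over replicate simulations buys little at the cost of
#' proportionally fewer search moves.
#'
#' @param b_bounds,j_bounds Length-2 numeric search bounds.
#' @param n_iter Objective evaluations per annealing run.
#' @param t_init,t_final Initial and final temperature of the acceptance
#'   rule (objective-scale units).
#' @param step_init,step_final Initial and final proposal standard
#'   deviation (parameter units, applied to both B and J).
#' @param reps_per_eval Replicate simulations averaged per objective
#'   evaluation.
#' @param init Optional numeric `c(B, J)` starting point; default `NULL`
#'   draws a uniform point in the bounds, so ensemble replicates start from
#'   scattered positions.
#' @return An object of class `anneal_config`.
#' @export
anneal_config <- function(b_bounds = c(-2, 2), j_bounds = c(0, 2),
                          n_iter = 500, t_init = 0.1, t_final = 1e-3,
                          step_init = 0.3, step_final = 0.02,
                          reps_per_eval = 1, init = NULL) {
  stopifnot(length(b_bounds) == 2, length(j_bounds) == 2,
            all(is.finite(c(b_bounds, j_bounds))))
  if (b_bounds[1] > b_bounds[2] || j_bounds[1] > j_bounds[2]) {
    stop("bounds must be ordered (lower <= upper)", call. = FALSE)
  }
  if (n_iter < 1) stop("`n_iter` must be positive", call. = FALSE)
  stopifnot(t_init > 0, t_final > 0, step_init > 0, step_final > 0,
            reps_per_eval >= 1)
  if (!is.null(init)) {
    stopifnot(length(init) == 2)
    if (init[1] < b_bounds[1] || init[1] > b_bounds[2] ||
        init[2] < j_bounds[1] || init[2] > j_bounds[2]) {
      stop("`init` must lie inside the bounds", call. = FALSE)
    }
  }
  structure(list(b_bounds = b_bounds, j_bounds = j_bounds,
                 n_iter = as.integer(n_iter), t_init = t_init, t_final = t_final,
                 step_init = step_init, step_final = step_final,
                 reps_per_eval = as.integer(reps_per_eval), init = init),
            class = "anneal_config")
}

#' Fitting objective: distance between simulated and target summaries
#'
#' Simulates the transition from `initial` under `(b, j)` for `n_steps`
#' Glauber steps and returns the Euclidean distance between the `(m, c1)`
#' summary of the simulated end pattern and the target summary, averaged
#' over `reps` replicate simulations. Always non-negative; zero only when
#' composition and texture both match exactly.
#'
#' @param b,j Candidate parameter values.
#' @param initial The observed [landscape] at the start of the transition.
#' @param target The observed end pattern: a [landscape], a
#'   [pattern_summary()] row, or a numeric `(m, c1)` pair.
#' @param n_steps Dynamic steps for the transition (see
#'   [steps_for_transition()]).
#' @param q Noise-suppression constant held fixed during fitting.
#' @param reps Replicate simulations to average.
#' @return A non-negative number.
#' @export
fit_objective <- function(b, j, initial, target, n_steps, q = 100, reps = 1) {
  initial <- as_landscape(initial)
  tgt <- as_summary_pair(target)
  vals <- vapply(seq_len(reps), function(i) {
    fin <- simulate_landscape(initial, ising_params(b, j, q), n_steps)
    sqrt((composition_imbalance(fin) - tgt[["m"]])^2 +
           (texture_index(fin) - tgt[["c1"]])^2)
  }, numeric(1))
  mean(vals)
}

reflect_into <- function(x, lo, hi) {
  if (lo == hi) return(lo)
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  if (y < 0) y <- y + 2 * width
  lo + ifelse(y <= width, y, 2 * width - y)
}

#' Simulated-annealing fit of (B, J) for one transition
#'
#' Minimizes [fit_objective()] over the bounded `(B, J)` plane by simulated
#' annealing with geometric cooling: at evaluation `k` of `n_iter` the
#' temperature is `t_init * (t_final / t_init)^((k-1)/(n_iter-1))` and the
#' Gaussian proposal scale shrinks on the same schedule. Worse moves are
#' accepted with probability `exp(-increase / temperature)`; the best point
#' seen is tracked and returned, so exhausting the budget is not an error.
#' The objective is stochastic (each evaluation runs a fresh simulation);
#' near the optimum the search therefore behaves as a shrinking random walk
#' around the minimum, which is why fits are replicated and combined by
#' [ensemble_fit()].
#'
#' @inheritParams fit_objective
#' @param initial,target As in [fit_objective()].
#' @param config An [anneal_config()].
#' @param seed Optional integer; runs with the same seed, inputs and config
#'   are identical.
#' @return A one-row tibble with columns `B`, `J`, `objective`, `n_eval`.
#' @export
anneal_fit <- function(initial, target, n_steps, q = 100,
                       config = anneal_config(), seed = NULL) {
  stopifnot(inherits(config, "anneal_config"))
  initial <- as_landscape(initial)
  tgt <- as_summary_pair(target)
  run <- function() {
    lb <- config$b_bounds; lj <- config$j_bounds
    cur <- if (is.null(config$init)) {
      c(runif(1, lb[1], lb[2]), runif(1, lj[1], lj[2]))
    } else {
      as.numeric(config$init)
    }
    cur_val <- fit_objective(cur[1], cur[2], initial, tgt, n_steps, q,
                             config$reps_per_eval)
    best <- cur; best_val <- cur_val
    n_iter <- config$n_iter
    for (k in seq_len(max(n_iter - 1, 0))) {
      frac <- if (n_iter > 2) (k - 1) / (n_iter - 2) else 1
      temp <- config$t_init * (config$t_final / config$t_init)^frac
      step <- config$step_init * (config$step_final / config$step_init)^frac
      prop <- c(reflect_into(cur[1] + rnorm(1, 0, step), lb[1], lb[2]),
                reflect_into(cur[2] + rnorm(1, 0, step), lj[1], lj[2]))
      prop_val <- fit_objective(prop[1], prop[2], initial, tgt, n_steps, q,
                                config$reps_per_eval)
      if (prop_val <= cur_val || runif(1) < exp(-(prop_val - cur_val) / temp)) {
        cur <- prop; cur_val <- prop_val
      }
      if (prop_val < best_val) {
        best <- prop; best_val <- prop_val
      }
    }
    tibble::tibble(B = best[1], J = best[2], objective = best_val,
                   n_eval = n_iter)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Ensemble inference of (B, J) with modal selection
#'
#' Because the dynamics are stochastic, a single annealing run gives a noisy
#' parameter estimate. `ensemble_fit()` repeats [anneal_fit()]
#' `n_replicates` times (default 200) with independent child seeds spawned
#' from `seed`, bins the replicate `(B, J)` pairs into a 2-D histogram (bin
#' widths 0.02 in B and 0.05 in J, matching the precision at which the
#' parameters are reported), and selects the centroid of the pairs in the
#' most populated bin. Ties between equally populated bins are broken by the
#' lower mean objective, then by the lower J.
#'
#' @inheritParams anneal_fit
#' @param n_replicates Number of annealing replicates (`>= 1`).
#' @param bin_b,bin_j Histogram bin widths for mode selection.
#' @param seed Optional master seed; results are bit-reproducible given the
#'   same seed.
#' @return An object of class `ensemble_fit`: a list with `selected` (one-row
#'   tibble `B`, `J`, `objective`, `peak_count`), `replicates` (tibble of all
#'   runs), `histogram` (tibble of bin counts), and the call settings.
#' @export
ensemble_fit <- function(initial, target, n_steps, q = 100,
                         config = anneal_config(), n_replicates = 200,
                         bin_b = 0.02, bin_j = 0.05, seed = NULL) {
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  initial <- as_landscape(initial)
  tgt <- as_summary_pair(target)
  child_seeds <- if (is.null(seed)) {
    sample.int(.Machine$integer.max, n_replicates)
  } else {
    withr::with_seed(seed, sample.int(.Machine$integer.max, n_replicates))
  }
  reps <- purrr::map2(seq_len(n_replicates), child_seeds, function(i, s) {
    fit <- anneal_fit(initial, tgt, n_steps, q, config, seed = s)
    dplyr::bind_cols(tibble::tibble(replicate = i, seed = s), fit)
  })
  replicates <- dplyr::bind_rows(reps)

  binned <- dplyr::mutate(replicates,
                          bin_B = floor(.data$B / bin_b),
                          bin_J = floor(.data$J / bin_j))
  histogram <- binned |>
    dplyr::group_by(.data$bin_B, .data$bin_J) |>
    dplyr::summarise(count = dplyr::n(),
                     mean_objective = mean(.data$objective),
                     B = mean(.data$B), J = mean(.data$J),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$mean_objective, .data$J)
  peak <- histogram[1, ]
  members <- dplyr::filter(binned, .data$bin_B == peak$bin_B,
                           .data$bin_J == peak$bin_J)
  selected <- tibble::tibble(
    B = mean(members$B), J = mean(members$J),
    objective = mean(members$objective), peak_count = nrow(members)
  )
  structure(list(selected = selected, replicates = replicates,
                 histogram = histogram, n_steps = n_steps, q = q,
                 config = config, bin_b = bin_b, bin_j = bin_j, seed = seed),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("<ensemble_fit> ", nrow(x$replicates), " replicates; selected B = ",
      round(x$selected$B, 4), ", J = ", round(x$selected$J, 4),
      " (peak bin holds ", x$selected$peak_count, " replicates)\n", sep = "")
  invisible(x)
}

#' Replicate-level results of an ensemble fit
#'
#' @param x An `ensemble_fit`.
#' @param ... Unused.
#' @return The replicates tibble (`replicate`, `seed`, `B`, `J`,
#'   `objective`, `n_eval`).
#' @export
tidy.ensemble_fit <- function(x, ...) x$replicates

#' One-row summary of an ensemble fit
#'
#' @param x An `ensemble_fit`.
#' @param ... Unused.
#' @return A one-row tibble: selected `B` and `J`, mean objective in the
#'   peak bin, peak bin occupancy, replicate count, and the ensemble
#'   standard deviations of B and J.
#' @export
glance.ensemble_fit <- function(x, ...) {
  dplyr::bind_cols(
    x$selected,
    tibble::tibble(n_replicates = nrow(x$replicates),
                   sd_B = stats::sd(x$replicates$B),
                   sd_J = stats::sd(x$replicates$J))
  )
}

#' Plot the replicate ensemble of an (B, J) fit
#'
#' @param object An `ensemble_fit`.
#' @param ... Unused.
#' @return A ggplot: replicate pairs with the selected mode marked.
#' @export
autoplot.ensemble_fit <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$B, y = .data$J)) +
    ggplot2::geom_bin2d(binwidth = c(object$bin_b, object$bin_j)) +
    ggplot2::geom_point(data = object$selected, colour = "red", shape = 4,
                        size = 3, stroke = 1.5) +
    ggplot2::labs(fill = "replicates") +
    ggplot2::theme_minimal()
}

#' Response surface of the dynamics over a (B, J) grid
#'
#' For every grid cell, runs `reps_per_cell` simulations of the transition
#' and records the ensemble mean and standard deviation of the simulated
#' `m` and `c1`, and the distance between the mean summary and the target.
#' The composition index responds mainly to B and the texture index mainly
#' to J, so the distance surface typically shows a single well-defined
#' minimum near the generating parameters.
#'
#' @inheritParams fit_objective
#' @param b_grid,j_grid Numeric vectors of grid values.
#' @param reps_per_cell Simulations per cell (`>= 2` for standard
#'   deviations).
#' @param seed Optional master seed.
#' @return A tibble of class `response_surface` with one row per grid cell:
#'   `B`, `J`, `m_mean`, `m_sd`, `c1_mean`, `c1_sd`, `distance`.
#' @export
response_surface <- function(initial, target, n_steps, b_grid, j_grid,
                             reps_per_cell = 2, q = 100, seed = NULL) {
  if (length(b_grid) < 1 || length(j_grid) < 1) {
    stop("`b_grid` and `j_grid` must be non-empty", call. = FALSE)
  }
  initial <- as_landscape(initial)
  tgt <- as_summary_pair(target)
  grid <- expand.grid(B = b_grid, J = j_grid)
  run <- function() {
    purrr::pmap(grid, function(B, J) {
      sims <- purrr::map(seq_len(reps_per_cell), function(i) {
        fin <- simulate_landscape(initial, ising_params(B, J, q), n_steps)
        c(m = composition_imbalance(fin), c1 = texture_index(fin))
      })
      ms <- purrr::map_dbl(sims, "m")
      c1s <- purrr::map_dbl(sims, "c1")
      tibble::tibble(
        B = B, J = J,
        m_mean = mean(ms), m_sd = stats::sd(ms),
        c1_mean = mean(c1s), c1_sd = stats::sd(c1s),
        distance = sqrt((mean(ms) - tgt[["m"]])^2 + (mean(c1s) - tgt[["c1"]])^2)
      )
    }) |> dplyr::bind_rows()
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("response_surface", class(out))
  out
}

#' One parameter-recovery trial on a self-generated transition
#'
#' The package's headline integration check: generate a coarse-textured
#' initial landscape, evolve it for one transition under known `(B*, J*)`,
#' then infer the parameters back from the (initial, final) pair with
#' [ensemble_fit()] and report the recovery errors.
#'
#' The initial pattern is equilibrated with plain Glauber dynamics
#' (`Q = 0`, `B = 0`) at the generating coupling: burning in with the
#' suppression term on would drain the focus category (isolated focus cells
#' die but can never be recreated), collapsing the pattern toward uniform
#' background and degrading identifiability. The transition itself is
#' simulated and fitted with the suppression term active, as in production
#' use.
#'
#' @param B,J Generating (ground-truth) parameter values.
#' @param d Landscape side; the default 100 keeps a full trial in the tens
#'   of seconds.
#' @param dt_years Transition duration; steps are `dt_years * d^2` (one
#'   sweep per year).
#' @param burn_in_sweeps Burn-in length for the initial pattern, in sweeps.
#' @param n_replicates Annealing replicates in the ensemble.
#' @param config An [anneal_config()].
#' @param q Noise-suppression constant for the transition and the fit.
#' @param seed Optional master seed for the whole trial.
#' @return A one-row tibble: `truth_B`, `truth_J`, `est_B`, `est_J`,
#'   `error_B`, `error_J`, `n_steps`, `peak_count`.
#' @export
recovery_trial <- function(B, J, d = 100, dt_years = 2, burn_in_sweeps = 100,
                           n_replicates = 50, config = anneal_config(),
                           q = 100, seed = NULL) {
  seeds <- if (is.null(seed)) {
    sample.int(.Machine$integer.max, 3)
  } else {
    withr::with_seed(seed, sample.int(.Machine$integer.max, 3))
  }
  n_steps <- steps_for_transition(dt_years, steps_per_year = d * d)
  init <- equilibrated_landscape(d, ising_params(0, J, Q = 0),
                                 burn_in_sweeps * d * d, seed = seeds[1])
  target <- simulate_landscape(init, ising_params(B, J, q), n_steps,
                               seed = seeds[2])
  ef <- ensemble_fit(init, pattern_summary(target), n_steps, q = q,
                     config = config, n_replicates = n_replicates,
                     seed = seeds[3])
  tibble::tibble(
    truth_B = B, truth_J = J,
    est_B = ef$selected$B, est_J = ef$selected$J,
    error_B = ef$selected$B - B, error_J = ef$selected$J - J,
    n_steps = n_steps, peak_count = ef$selected$peak_count
  )
}

#' Plot a response surface
#'
#' @param object A [response_surface()] tibble.
#' @param value Which surface to show: the distance to the target or the
#'   mean simulated `m` or `c1`.
#' @param ... Unused.
#' @return A ggplot tile map over the (B, J) grid.
#' @export
autoplot.response_surface <- function(object,
                                      value = c("distance", "m_mean", "c1_mean"),
                                      ...) {
  value <- match.arg(value)
  best <- object[which.min(object$distance), ]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$B, y = .data$J,
                                       fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = best, colour = "red", shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal()
}
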