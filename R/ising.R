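#' Sum of the four torus neighbours of a cell
#'
#' Returns \eqn{S_k = x_{up} + x_{down} + x_{left} + x_{right}} with periodic
#' (torus) wrap at the edges. Because each neighbour is `+1` or `-1`, the sum
#' takes one of the five values `{-4, -2, 0, 2, 4}`.
#'
#' @param x A [landscape].
#' @param row,col 1-based cell indices (row 1 is the top of the grid).
#' @return An integer in `{-4, -2, 0, 2, 4}`.
#' @export
neighbour_sum <- function(x, row, col) {
  x <- as_landscape(x)
  d <- nrow(x)
  if (row < 1 || row > d || col < 1 || col > d) {
    stop("cell index (", row, ", ", col, ") out of range for side ", d, call. = FALSE)
  }
  up <- if (row == 1) d else row - 1L
  dn <- if (row == d) 1L else row + 1L
  lf <- if (col == 1) d else col - 1L
  rt <- if (col == d) 1L else col + 1L
  x[up, col] + x[dn, col] + x[row, lf] + x[row, rt]
}

# sum of x_k * x_l over the 2n unordered torus neighbour pairs
torus_pair_sum <- function(x) {
  d <- nrow(x)
  right <- x[, c(seq_len(d)[-1], 1L), drop = FALSE]
  down <- x[c(seq_len(d)[-1], 1L), , drop = FALSE]
  sum(x * right) + sum(x * down)
}

#' Total configuration energy
#'
#' The dimensionless energy of a pattern \eqn{\omega}:
#' \deqn{E(\omega) = -J \sum_{k \sim \ell} x_k x_\ell - B \sum_k x_k,}
#' where the first sum runs over each unordered nearest-neighbour pair on the
#' torus exactly once (`2n` pairs for `n` cells). The noise-suppression
#' constant `Q` plays no role in the total energy; it only modifies the
#' energy *change* of one specific move (see [delta_energy()]).
#'
#' @inheritParams neighbour_sum
#' @param params An [ising_params] object.
#' @return A single dimensionless number.
#' @export
total_energy <- function(x, params) {
  x <- as_landscape(x)
  params <- as_params(params)
  -params$J * torus_pair_sum(x) - params$B * sum(x)
}

#' Energy change of an attempted single-cell flip
#'
#' For a flip of cell `k` from \eqn{x^{bf}} to \eqn{x^{af} = -x^{bf}}:
#' \deqn{\Delta E_k = -(x^{af} - x^{bf})(J S_k + B) + Q_{applied},}
#' where \eqn{S_k} is [neighbour_sum()] and \eqn{Q_{applied} = Q} if and only
#' if the cell is background (\eqn{x^{bf} = -1}) *and* all four neighbours are
#' background (\eqn{S_k = -4}); otherwise \eqn{Q_{applied} = 0}. The rule is
#' deliberately asymmetric: a focus cell inside an all-focus neighbourhood is
#' never penalized.
#'
#' @inheritParams total_energy
#' @param row,col 1-based indices of the cell whose flip is attempted.
#' @return The dimensionless energy change \eqn{\Delta E_k}.
#' @export
delta_energy <- function(x, row, col, params) {
  x <- as_landscape(x)
  params <- as_params(params)
  s <- neighbour_sum(x, row, col)
  xbf <- x[row, col]
  de <- 2 * xbf * (params$J * s + params$B)
  if (xbf == -1L && s == -4L) de <- de + params$Q
  de
}

#' Glauber flip probability
#'
#' \deqn{P(x_k \to -x_k) = \frac{1}{1 + e^{\Delta E_k}}.}
#' Equals 0.5 at \eqn{\Delta E = 0}, approaches 1 for strongly favourable
#' moves and 0 for strongly unfavourable ones. Computed via the logistic
#' function on the numerically stable branch, so it neither overflows nor
#' returns NaN for very large `|delta_e|`.
#'
#' @param delta_e Energy change(s); vectorized.
#' @return Probabilities in `(0, 1)`.
#' @examples
#' flip_probability(0)      # 0.5
#' flip_probability(log(3)) # 0.25
#' @export
flip_probability <- function(delta_e) {
  stats::plogis(-delta_e)
}

#' Run single-flip Glauber dynamics
#'
#' One dynamic step selects a cell uniformly at random and flips it with
#' probability [flip_probability()] of its [delta_energy()]. `n_steps` such
#' attempted flips are applied in sequence; the grid is periodic, so edges
#' behave like interior cells. `glauber_step()` performs exactly one attempt.
#'
#' The trajectory is driven by R's random number generator: call
#' `set.seed()` (or pass `seed`) for reproducible runs.
#'
#' @inheritParams total_energy
#' @param n_steps Number of attempted flips, `>= 0`.
#' @param seed Optional integer; if given, the run uses this seed and leaves
#'   the caller's RNG state untouched.
#' @return The final [landscape]; the input is not modified.
#' @examples
#' l <- random_landscape(20, 0.5, seed = 1)
#' l2 <- simulate_landscape(l, ising_params(B = 0.1, J = 0.4), 400, seed = 2)
#' @export
simulate_landscape <- function(x, params, n_steps, seed = NULL) {
  x <- as_landscape(x)
  params <- as_params(params)
  if (length(n_steps) != 1 || is.na(n_steps) || n_steps < 0) {
    stop("`n_steps` must be a single non-negative number", call. = FALSE)
  }
  run <- function() glauber_run_cpp(x, params$B, params$J, params$Q, n_steps)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(out, class = c("landscape", "matrix", "array"))
}

#' @rdname simulate_landscape
#' @export
glauber_step <- function(x, params, seed = NULL) {
  simulate_landscape(x, params, 1, seed = seed)
}

#' Real-time duration of one dynamic step
#'
#' If a transition spanning `duration_years` is simulated with `n_steps`
#' attempted flips, each step represents
#' `duration_years * 8760 / n_steps` hours (a 365-day year). For example,
#' 3 years simulated with 30 000 steps gives 0.876 h per step.
#'
#' @param duration_years Positive duration in years.
#' @param n_steps Positive number of dynamic steps.
#' @return Hours per dynamic step.
#' @examples
#' step_duration(3, 30000) # 0.876
#' @export
step_duration <- function(duration_years, n_steps) {
  if (any(duration_years <= 0) || any(n_steps <= 0)) {
    stop("duration and step count must be positive", call. = FALSE)
  }
  duration_years * 365 * 24 / n_steps
}

#' Number of dynamic steps for a transition
#'
#' The step count is proportional to the transition duration. Give either a
#' per-year rate (`steps_per_year`; the convention used for full-size sites
#' is `n` steps per year where `n` is the cell count, so each cell gets one
#' flip opportunity per year on average) or a fixed per-step duration in
#' hours (`step_hours`), under a 365-day (8760 h) year. The result is rounded
#' to the nearest integer; a transition that rounds to zero steps is an
#' error.
#'
#' @param duration_years Positive duration of the transition in years.
#' @param steps_per_year Steps per simulated year.
#' @param step_hours Alternative: duration of one step in hours.
#' @return Positive integer step count.
#' @examples
#' steps_for_transition(2, step_hours = 0.876) # 20000
#' steps_for_transition(1, steps_per_year = 62500) # one sweep of a 250x250 site
#' @export
steps_for_transition <- function(duration_years, steps_per_year = NULL,
                                 step_hours = NULL) {
  if (any(duration_years <= 0)) stop("duration must be positive", call. = FALSE)
  if (is.null(steps_per_year) == is.null(step_hours)) {
    stop("give exactly one of `steps_per_year` or `step_hours`", call. = FALSE)
  }
  if (!is.null(step_hours)) {
    if (step_hours <= 0) stop("`step_hours` must be positive", call. = FALSE)
    steps_per_year <- 365 * 24 / step_hours
  }
  if (steps_per_year <= 0) stop("`steps_per_year` must be positive", call. = FALSE)
  n <- round(duration_years * steps_per_year)
  if (any(n < 1)) stop("transition duration too short: zero steps", call. = FALSE)
  as.integer(n)
}

#' Step schedule for a series of observation years
#'
#' Expands a strictly increasing vector of observation years into the
#' per-transition durations and step counts.
#'
#' @param observation_years Strictly increasing numeric vector, length >= 2.
#' @inheritParams steps_for_transition
#' @return A tibble with columns `year_from`, `year_to`, `duration_years`,
#'   `n_steps`.
#' @examples
#' schedule_steps(c(2001, 2004, 2006, 2008, 2011, 2013, 2016, 2019),
#'                step_hours = 0.876)
#' @export
schedule_steps <- function(observation_years, steps_per_year = NULL,
                           step_hours = NULL) {
  if (length(observation_years) < 2 || any(diff(observation_years) <= 0)) {
    stop("`observation_years` must be strictly increasing with length >= 2",
         call. = FALSE)
  }
  dur <- diff(observation_years)
  tibble::tibble(
    year_from = head(observation_years, -1),
    year_to = observation_years[-1],
    duration_years = dur,
    n_steps = steps_for_transition(dur, steps_per_year = steps_per_year,
                                   step_hours = step_hours)
  )
}
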