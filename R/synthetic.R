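#' Random binary landscape with an exact focus fraction
#'
#' Places exactly `round(f * d^2)` focus cells uniformly at random. Such
#' i.i.d. patterns have texture index near 0 (fine texture) and serve as the
#' spatial null.
#'
#' @param d Side length (`>= 2`).
#' @param f Focus fraction in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A [landscape].
#' @export
random_landscape <- function(d, f = 0.5, seed = NULL) {
  if (length(d) != 1 || d < 2) stop("`d` must be a single integer >= 2", call. = FALSE)
  if (f < 0 || f > 1) stop("`f` must be in [0, 1]", call. = FALSE)
  d <- as.integer(d)
  n <- d * d
  k <- round(f * n)
  draw <- function() {
    s <- rep(-1L, n)
    if (k > 0) s[sample.int(n, k)] <- 1L
    landscape(matrix(s, d, d))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Equilibrated (coarse-textured) starting landscape
#'
#' Evolves a random half-and-half landscape under the given parameters for a
#' burn-in period, producing patchy, spatially autocorrelated patterns like
#' those of observed land mosaics. With `J` above roughly 0.44 the dynamics
#' coarsen the pattern into growing domains, so longer burn-ins give coarser
#' texture.
#'
#' @param d Side length.
#' @param params An [ising_params] used during burn-in.
#' @param burn_in_steps Number of attempted flips (`>= 0`). A useful unit is
#'   sweeps: one sweep is `d^2` steps.
#' @param seed Optional integer seed.
#' @return A [landscape].
#' @export
equilibrated_landscape <- function(d, params, burn_in_steps, seed = NULL) {
  if (burn_in_steps < 0) stop("`burn_in_steps` must be >= 0", call. = FALSE)
  gen <- function() {
    l0 <- random_landscape(d, 0.5)
    simulate_landscape(l0, params, burn_in_steps)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Forward-simulate a multi-transition series with known ground truth
#'
#' Starting from `initial`, each transition `i` evolves the previous
#' landscape for `round(dt_years[i] * steps_per_year)` Glauber steps under
#' its own `(B_i, J_i)`. The generating parameters are stored alongside the
#' landscapes so inference can be validated by parameter recovery.
#'
#' @param initial A [landscape] (the observation at the first time point).
#' @param truth A data frame with one row per transition and columns `B`,
#'   `J`, `dt_years`.
#' @param steps_per_year Steps per simulated year; default `NULL` means `n`
#'   (the cell count), the convention under which each cell has one flip
#'   opportunity per year on average.
#' @param q Noise-suppression constant used throughout. Default 100.
#' @param seed Optional master seed; the series is bit-reproducible given
#'   the same initial landscape, truth table, and seed.
#' @return An object of class `landscape_series`: a list with `landscapes`
#'   (length `nrow(truth) + 1`), `truth` (tibble with an added `n_steps`
#'   column), `steps_per_year`, `q`, `seed`.
#' @examples
#' init <- random_landscape(30, 0.5, seed = 1)
#' s <- generate_series(init, data.frame(B = 0.2, J = 0.4, dt_years = 2), seed = 2)
#' length(s$landscapes)
#' @export
generate_series <- function(initial, truth, steps_per_year = NULL, q = 100,
                            seed = NULL) {
  initial <- as_landscape(initial)
  truth <- tibble::as_tibble(truth)
  if (nrow(truth) < 1 || !all(c("B", "J", "dt_years") %in% names(truth))) {
    stop("`truth` needs columns B, J, dt_years and at least one row", call. = FALSE)
  }
  if (any(truth$dt_years <= 0)) stop("all `dt_years` must be positive", call. = FALSE)
  if (is.null(steps_per_year)) steps_per_year <- length(initial)
  truth$n_steps <- steps_for_transition(truth$dt_years, steps_per_year = steps_per_year)
  run <- function() {
    landscapes <- vector("list", nrow(truth) + 1)
    landscapes[[1]] <- initial
    for (i in seq_len(nrow(truth))) {
      landscapes[[i + 1]] <- simulate_landscape(
        landscapes[[i]], ising_params(truth$B[i], truth$J[i], q), truth$n_steps[i])
    }
    landscapes
  }
  landscapes <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(landscapes = landscapes, truth = truth,
                 steps_per_year = steps_per_year, q = q, seed = seed),
            class = "landscape_series")
}

#' @export
print.landscape_series <- function(x, ...) {
  cat("<landscape_series> ", length(x$landscapes), " landscapes, ",
      nrow(x$truth), " transitions, side ", nrow(x$landscapes[[1]]), "\n", sep = "")
  invisible(x)
}

#' Per-observation summaries of a generated series
#'
#' @param x A `landscape_series`.
#' @param ... Unused.
#' @return A tibble with one row per landscape in the series (`index`,
#'   `focus_count`, `m`, `c1`).
#' @export
tidy.landscape_series <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(index = seq_along(x$landscapes)),
    metric_table(x$landscapes)
  )
}

#' Write a generated series to disk with a JSON manifest
#'
#' Landscapes are written as numbered rasters plus a `manifest.json`
#' recording the truth table, steps per year, noise constant and seed.
#'
#' @param series A `landscape_series`.
#' @param dir Output directory (created if needed).
#' @param format Raster format passed to [write_landscape()].
#' @return The manifest path, invisibly.
#' @export
write_series <- function(series, dir, format = "ascii_grid") {
  stopifnot(inherits(series, "landscape_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "geotiff") "tif" else "asc"
  paths <- character(length(series$landscapes))
  for (i in seq_along(series$landscapes)) {
    paths[i] <- file.path(dir, sprintf("landscape_%02d.%s", i - 1, ext))
    write_landscape(series$landscapes[[i]], paths[i], format = format)
  }
  manifest <- list(
    files = basename(paths),
    truth = series$truth,
    steps_per_year = series$steps_per_year,
    q = series$q,
    seed = series$seed
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(mpath)
}
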