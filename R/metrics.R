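#' Composition imbalance index
#'
#' \eqn{m = 2f - 1}, where `f` is the fraction of focus cells. Ranges from
#' -1 (all background) to +1 (all focus); 0 means an even split.
#'
#' @param x A [landscape].
#' @return A number in `[-1, 1]`.
#' @export
composition_imbalance <- function(x) {
  2 * focus_fraction(as_landscape(x)) - 1
}

#' Lag-one texture index
#'
#' A normalized lag-one spatial autocorrelation of the cell states,
#' \deqn{C(1) = \frac{\bar p - m^2}{1 - m^2},}
#' where \eqn{\bar p} is the mean of \eqn{x_k x_\ell} over all `2n`
#' torus-wrapped horizontal and vertical neighbour pairs and `m` is
#' [composition_imbalance()]. Spatially independent (fine-textured) patterns
#' score near 0, coherent single-phase (coarse) patterns near 1. Values below
#' 0 (anti-correlation, e.g. a checkerboard) are reported as computed, not
#' clipped; [pattern_summary()] flags them.
#'
#' A uniform pattern (`m = +1` or `-1`) makes the denominator vanish; it is
#' defined as `C(1) = 1` (a single-phase pattern is maximally coarse) and
#' flagged as degenerate in [pattern_summary()].
#'
#' @param x A [landscape].
#' @param raw If `TRUE`, return the raw pair-product mean \eqn{\bar p}
#'   instead of the normalized index (useful for sensitivity checks).
#' @return A single number; the normalized index lies in `[-1, 1]`.
#' @export
texture_index <- function(x, raw = FALSE) {
  x <- as_landscape(x)
  pbar <- torus_pair_sum(x) / (2 * length(x))
  if (raw) return(pbar)
  m <- composition_imbalance(x)
  if (abs(m) == 1) return(1)
  (pbar - m^2) / (1 - m^2)
}

#' Summarize a landscape's composition and texture
#'
#' The index pair `(m, c1)` used as the fitting target, plus bookkeeping
#' columns: `c1_raw` (unnormalized pair-product mean), `degenerate` (`TRUE`
#' for uniform patterns, where `c1` is defined as 1 by convention) and
#' `c1_in_range` (`FALSE` when `c1` falls outside the nominal `[0, 1]` range,
#' e.g. for anti-correlated patterns).
#'
#' @param x A [landscape].
#' @return A one-row tibble with columns `n`, `focus_count`, `f`, `m`, `c1`,
#'   `c1_raw`, `degenerate`, `c1_in_range`.
#' @export
pattern_summary <- function(x) {
  x <- as_landscape(x)
  fc <- focus_count(x)
  m <- 2 * fc / length(x) - 1
  c1 <- texture_index(x)
  tibble::tibble(
    n = length(x),
    focus_count = fc,
    f = fc / length(x),
    m = m,
    c1 = c1,
    c1_raw = texture_index(x, raw = TRUE),
    degenerate = abs(m) == 1,
    c1_in_range = c1 >= 0 && c1 <= 1
  )
}

# Accept a landscape, a pattern_summary()-style data frame, or a numeric
# (m, c1) pair, and return c(m, c1).
as_summary_pair <- function(x) {
  if (is_landscape(x) || (is.matrix(x) && !is.data.frame(x))) {
    s <- pattern_summary(as_landscape(x))
    return(c(m = s$m, c1 = s$c1))
  }
  if (is.data.frame(x)) {
    if (!all(c("m", "c1") %in% names(x)) || nrow(x) < 1) {
      stop("summary data frame must have columns `m` and `c1`", call. = FALSE)
    }
    return(c(m = x$m[1], c1 = x$c1[1]))
  }
  if (is.numeric(x) && length(x) == 2) return(c(m = x[[1]], c1 = x[[2]]))
  stop("cannot interpret `", deparse(substitute(x)), "` as a pattern summary",
       call. = FALSE)
}

#' Euclidean distance between two pattern summaries
#'
#' The fitting criterion: the Euclidean distance between the `(m, c1)` pairs
#' of two patterns,
#' \eqn{\sqrt{(\Delta m)^2 + (\Delta c_1)^2}}. Zero iff both composition and
#' texture agree.
#'
#' @param a,b Landscapes, [pattern_summary()] rows, or numeric `(m, c1)`
#'   pairs.
#' @return A non-negative number.
#' @examples
#' summary_distance(c(0, 0), c(0.3, 0.4)) # 0.5
#' @export
summary_distance <- function(a, b) {
  pa <- as_summary_pair(a)
  pb <- as_summary_pair(b)
  sqrt(sum((pa - pb)^2))
}

#' Cell-level prediction scores of a simulated pattern
#'
#' Treats the simulation as a prediction of the observed pattern and scores
#' it from the 2x2 confusion matrix with focus as the positive class:
#' accuracy `(tp + tn) / n`, recall `tp / (tp + fn)` (probability that an
#' observed focus cell is also focus in the simulation) and precision
#' `tp / (tp + fp)` (probability that a simulated focus cell is also focus in
#' the observation). Ratios with a zero denominator are reported as `NA` and
#' explained in the `note` column rather than silently coerced to 0.
#'
#' @param observed,simulated Landscapes of equal dimensions.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `recall`, `precision`, `note`.
#' @export
prediction_scores <- function(observed, simulated) {
  observed <- as_landscape(observed)
  simulated <- as_landscape(simulated)
  if (!all(dim(observed) == dim(simulated))) {
    stop("observed and simulated landscapes must have identical dimensions",
         call. = FALSE)
  }
  tp <- sum(observed == 1L & simulated == 1L)
  fp <- sum(observed == -1L & simulated == 1L)
  fn <- sum(observed == 1L & simulated == -1L)
  tn <- sum(observed == -1L & simulated == -1L)
  n <- length(observed)
  notes <- character(0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  if (tp + fn == 0) notes <- c(notes, "no focus cells in observed: recall undefined")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  if (tp + fp == 0) notes <- c(notes, "no focus cells in simulated: precision undefined")
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = (tp + tn) / n,
    recall = recall,
    precision = precision,
    note = paste(notes, collapse = "; ")
  )
}

#' Per-pattern metric table for a series of landscapes
#'
#' Convenience wrapper producing one row per landscape (optionally scored
#' against a matched observed series), in the shape used for CSV export.
#'
#' @param landscapes A list of [landscape]s.
#' @param years Optional numeric vector of observation years (same length).
#' @param observed Optional list of observed landscapes to score against.
#' @return A tibble with one row per landscape.
#' @export
metric_table <- function(landscapes, years = NULL, observed = NULL) {
  stopifnot(is.list(landscapes))
  if (!is.null(years)) stopifnot(length(years) == length(landscapes))
  rows <- purrr::imap(landscapes, function(l, i) {
    s <- pattern_summary(l)[, c("focus_count", "m", "c1")]
    if (!is.null(years)) s <- dplyr::bind_cols(tibble::tibble(year = years[[i]]), s)
    if (!is.null(observed)) {
      sc <- prediction_scores(observed[[i]], l)[, c("accuracy", "recall", "precision")]
      s <- dplyr::bind_cols(s, sc)
    }
    s
  })
  dplyr::bind_rows(rows)
}
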