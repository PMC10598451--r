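#' Binary landscape grids
#'
#' A landscape is a square integer matrix whose cells are `+1` (the focus
#' land-cover category under study) or `-1` (the background, i.e. everything
#' else). The dynamics treat the grid as a torus: opposite edges are glued,
#' so every cell has exactly four nearest neighbours (up, down, left, right).
#'
#' `landscape()` validates and classes a matrix; `as_landscape()` additionally
#' accepts `{0,1}` encodings (0 is recoded to -1), which is how landscapes are
#' stored on disk.
#'
#' @param states An integer (or numeric) square matrix over `{-1, +1}`.
#' @return An object of class `landscape`: an integer matrix over `{-1, +1}`.
#' @examples
#' l <- landscape(matrix(c(1, -1, -1, 1), 2, 2))
#' focus_count(l)
#' @export
landscape <- function(states) {
  if (!is.matrix(states)) stop("`states` must be a matrix", call. = FALSE)
  if (nrow(states) != ncol(states)) {
    stop("landscape must be square (got ", nrow(states), " x ", ncol(states), ")",
         call. = FALSE)
  }
  if (nrow(states) < 2) stop("landscape side must be at least 2", call. = FALSE)
  m <- matrix(as.integer(states), nrow(states), ncol(states))
  if (!all(m == 1L | m == -1L)) {
    stop("all cells must be -1 or +1; use as_landscape() for {0,1} input",
         call. = FALSE)
  }
  structure(m, class = c("landscape", "matrix", "array"))
}

#' @rdname landscape
#' @param x Object to coerce or test.
#' @export
as_landscape <- function(x) {
  if (is_landscape(x)) return(x)
  if (!is.matrix(x)) stop("cannot coerce ", class(x)[1], " to landscape", call. = FALSE)
  v <- unique(as.vector(x))
  if (all(v %in% c(0, 1))) x[] <- ifelse(x == 0, -1L, 1L)
  landscape(x)
}

#' @rdname landscape
#' @export
is_landscape <- function(x) inherits(x, "landscape")

#' @export
print.landscape <- function(x, ...) {
  d <- nrow(x)
  cat("<landscape> ", d, " x ", d, " torus, ", focus_count(x), "/", d * d,
      " focus cells (f = ", signif(focus_fraction(x), 4), ")\n", sep = "")
  invisible(x)
}

#' Focus-cell count and fraction
#'
#' @param x A [landscape].
#' @return `focus_count()` the number of `+1` cells; `focus_fraction()` the
#'   fraction `f` of focus cells, in `[0, 1]`.
#' @export
focus_count <- function(x) {
  x <- as_landscape(x)
  sum(x == 1L)
}

#' @rdname focus_count
#' @export
focus_fraction <- function(x) focus_count(x) / length(as_landscape(x))

#' Model parameters of the kinetic Ising dynamics
#'
#' Bundles the three dimensionless constants of the dynamics: the external
#' force `B` (positive values favour the focus category, negative the
#' background), the neighbour coupling `J` (propensity of neighbouring cells
#' to share a category, i.e. spatial autocorrelation), and the
#' noise-suppression constant `Q`. Temperature is not a separate parameter:
#' it is absorbed into the scale of `B` and `J`.
#'
#' `Q` is added to the energy change only when a background cell whose four
#' neighbours are all background attempts to flip to focus; a large `Q`
#' (default 100) makes that probability negligible, suppressing
#' salt-and-pepper noise in the focus category. `Q = 0` recovers plain
#' Glauber dynamics.
#'
#' @param B External-force strength (finite).
#' @param J Neighbour-coupling strength (finite).
#' @param Q Noise-suppression constant, `>= 0`. Default 100.
#' @return An object of class `ising_params` (a named list).
#' @examples
#' ising_params(B = 0.16, J = 0.5)
#' @export
ising_params <- function(B, J, Q = 100) {
  stopifnot(is.numeric(B), length(B) == 1, is.finite(B),
            is.numeric(J), length(J) == 1, is.finite(J),
            is.numeric(Q), length(Q) == 1, is.finite(Q))
  if (Q < 0) stop("Q must be non-negative", call. = FALSE)
  structure(list(B = as.numeric(B), J = as.numeric(J), Q = as.numeric(Q)),
            class = "ising_params")
}

#' @export
print.ising_params <- function(x, ...) {
  cat("<ising_params> B =", x$B, " J =", x$J, " Q =", x$Q, "\n")
  invisible(x)
}

as_params <- function(params) {
  if (inherits(params, "ising_params")) return(params)
  if (is.list(params) && all(c("B", "J") %in% names(params))) {
    return(ising_params(params$B, params$J, if (is.null(params$Q)) 100 else params$Q))
  }
  stop("`params` must be an ising_params object", call. = FALSE)
}

#' Plot a landscape
#'
#' Focus cells are drawn green and background cells yellow.
#'
#' @param object A [landscape].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.landscape <- function(object, ...) {
  d <- nrow(object)
  df <- tibble::tibble(
    row = rep(seq_len(d), times = d),
    col = rep(seq_len(d), each = d),
    state = factor(as.vector(object), levels = c(-1, 1),
                   labels = c("background", "focus"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(background = "#f2e442", focus = "#1a9641"),
                               drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' @export
plot.landscape <- function(x, ...) print(autoplot(x, ...))
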