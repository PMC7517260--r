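# Tidiers and plot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a spectral result
#'
#' One row per eigenpair: `mode` (0-based, so the stationary/ground mode is
#' mode 0), `value` (real part; the eigenvalue or energy depending on the
#' estimated operator) and `imag`.
#'
#' @param x A `koop_spectrum`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.koop_spectrum <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$values) - 1L,
                 value = Re(x$values), imag = Im(x$values))
}

#' Glance at a spectral result
#'
#' @param x A `koop_spectrum`.
#' @param ... Unused.
#' @return One-row tibble with fit metadata (sample size, retained rank,
#'   ridge, operator and kernel description).
#' @export
glance.koop_spectrum <- function(x, ...) {
  tibble::tibble(
    n = x$n, rank = x$rank, epsilon = x$epsilon, operator = x$operator,
    kernel_family = if (!is.null(x$kernel)) x$kernel$family else NA_character_,
    kernel_bandwidth = if (!is.null(x$kernel) &&
                           x$kernel$family == "gaussian") {
      x$kernel$params$bandwidth
    } else {
      NA_real_
    })
}

#' Augment query points with eigenfunction values
#'
#' @param x A `koop_spectrum`.
#' @param newdata Query points; default the training points.
#' @param ... Unused.
#' @return Tibble of point coordinates plus `phi1..phiK` (real parts).
#' @export
augment.koop_spectrum <- function(x, newdata = NULL, ...) {
  pts <- if (is.null(newdata)) x$points else as_points(newdata, x$kernel$d)
  phi <- Re(evaluate_eigenfunctions(x, pts))
  out <- tibble::as_tibble(as.data.frame(pts))
  names(out) <- paste0("x", seq_len(ncol(pts)))
  for (j in seq_len(ncol(phi))) out[[paste0("phi", j)]] <- phi[, j]
  out
}

#' Tidy a metastable decomposition
#'
#' @param x A `koop_metastable`.
#' @param ... Unused.
#' @return Eigenvalue tibble of the underlying spectrum with a `dominant`
#'   flag.
#' @export
tidy.koop_metastable <- function(x, ...) {
  out <- tidy(x$spectrum)
  out$dominant <- out$mode < x$n_dominant
  out
}

#' @rdname tidy.koop_metastable
#' @export
glance.koop_metastable <- function(x, ...) {
  tibble::tibble(n_sets = x$n_sets, n_dominant = x$n_dominant,
                 n = x$spectrum$n, seed = x$seed)
}

#' Plot an eigenvalue spectrum
#'
#' @param object A `koop_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.koop_spectrum <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mode, yend = 0),
                          linewidth = 0.3) +
    ggplot2::labs(x = "mode", y = "eigenvalue",
                  title = sprintf("Estimated spectrum (%s)", object$operator)) +
    ggplot2::theme_minimal()
}

#' Plot a metastable decomposition
#'
#' Scatter of the first two state coordinates coloured by cluster.
#'
#' @param object A `koop_metastable`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.koop_metastable <- function(object, ...) {
  df <- object$assignments
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x1, y = .data$x2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(title = sprintf("%d metastable sets", object$n_sets)) +
    ggplot2::theme_minimal()
}

#' Plot an embedding
#'
#' Scatter of the first two embedding coordinates.
#'
#' @param object A `koop_embedding`.
#' @param colour Optional vector used to colour the points (e.g. a latent
#'   coordinate when validating against synthetic data).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.koop_embedding <- function(object, colour = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 2) stop_config("need at least two coordinates to plot.")
  df$..colour <- if (is.null(colour)) "sample" else colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$phi1, y = .data$phi2))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_point(size = 0.6, alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$..colour),
                            size = 0.6, alpha = 0.7) +
      ggplot2::labs(colour = "latent")
  }
  p + ggplot2::labs(x = "coordinate 1", y = "coordinate 2",
                    title = "Operator-spectral embedding") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
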