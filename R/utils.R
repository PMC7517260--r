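# Shared plumbing: condition classes, point-matrix coercion, seeded RNG.

stop_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "koop_config_error")
}
stop_parse <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "koop_parse_error")
}
stop_numerical <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "koop_numerical_error")
}

#' Coerce data to a point matrix
#'
#' Accepts a numeric matrix, a numeric vector (interpreted as one-dimensional
#' samples), a data frame, or a trajectory/sampler tibble. For data frames,
#' columns named `x1, x2, ...` are used if present (so sampler output carrying
#' latent validation columns such as `angle`/`height` is handled transparently);
#' otherwise all numeric columns are taken.
#'
#' @param data Samples in any of the accepted forms.
#' @param d Optional expected dimension (checked if given).
#' @return `M x d` numeric matrix.
#' @export
as_points <- function(data, d = NULL) {
  if (is.data.frame(data)) {
    xcols <- grep("^x[0-9]+$", names(data), value = TRUE)
    if (length(xcols) > 0) {
      data <- as.matrix(data[xcols])
    } else {
      num <- vapply(data, is.numeric, logical(1))
      data <- as.matrix(data[num])
    }
  } else if (is.numeric(data) && is.null(dim(data))) {
    data <- matrix(data, ncol = if (is.null(d)) 1L else d)
  }
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_config("points must be a numeric matrix, vector or data frame.")
  }
  if (nrow(data) < 1L) stop_config("empty point set.")
  if (!all(is.finite(data))) stop_config("points contain non-finite values.")
  if (!is.null(d) && ncol(data) != d) {
    stop_config(sprintf("points have dimension %d, expected %d.",
                        ncol(data), d))
  }
  unname(data)
}

# Evaluate a coefficient field rowwise on an M x d matrix.
# Builtin model fields are vectorized (matrix in -> matrix/vector out);
# plain user functions of a single d-vector are applied row by row.
eval_field <- function(f, x, value = c("vector", "scalar", "matrix"),
                       vectorized = FALSE) {
  value <- match.arg(value)
  m <- nrow(x); d <- ncol(x)
  if (vectorized) {
    out <- f(x)
    return(switch(value,
      scalar = as.numeric(out),
      vector = matrix(as.numeric(out), m, d),
      matrix = out))
  }
  switch(value,
    scalar = vapply(seq_len(m), function(i) as.numeric(f(x[i, ])), numeric(1)),
    vector = t(vapply(seq_len(m), function(i) as.numeric(f(x[i, ])),
                      numeric(d))),
    matrix = {
      out <- array(0, c(m, d, d))
      for (i in seq_len(m)) out[i, , ] <- f(x[i, ])
      out
    })
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L) {
    stop_config("`seed` must be a single integer or NULL.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
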