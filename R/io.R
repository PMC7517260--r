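# Delimited-text formats, run configuration, and the pipeline dispatcher
# behind the command-line interface. All files are tab-separated with
# '#'-prefixed header comments carrying metadata, written in full double
# precision.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Read a point table
#'
#' Reads an `M x d` numeric array from a tab-separated file. Leading lines
#' starting with `#` are treated as metadata and returned as an attribute;
#' ragged rows or non-numeric cells raise a parse error naming the line.
#'
#' @param path File path.
#' @return Numeric matrix with attribute `metadata` (character vector of
#'   comment lines, stripped of the `# ` prefix).
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  meta <- sub("^\\s*#\\s?", "", lines[is_comment])
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) == 0) stop_parse("empty input file: %s", path)
  rows <- strsplit(trimws(lines[body_idx]), "[\t ]+")
  width <- length(rows[[1]])
  out <- matrix(NA_real_, length(rows), width)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != width) {
      stop_parse("ragged row at line %d of %s (%d fields, expected %d).",
                 body_idx[i], path, length(rows[[i]]), width)
    }
    vals <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(vals)) {
      stop_parse("non-numeric value at line %d of %s.", body_idx[i], path)
    }
    out[i, ] <- vals
  }
  attr(out, "metadata") <- meta
  out
}

#' Write a point table
#'
#' @param points Matrix or data frame of samples.
#' @param path Output path.
#' @param metadata Optional character vector written as `#` header lines.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, metadata = NULL) {
  x <- as_points(points)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in metadata) writeLines(paste0("# ", m), con)
  utils::write.table(
    matrix(fmt_num(x), nrow(x), ncol(x)), con, sep = "\t",
    row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a spectral result
#'
#' Writes the eigenvalues as a TSV with columns `index`, `real`, `imag`, and
#' the coefficient vectors plus training points to sibling
#' `<stem>_coefficients.tsv` / `<stem>_points.tsv` files (kernel parameters in
#' the header comments) so eigenfunctions can be re-evaluated later with
#' [read_spectrum()].
#'
#' @param spectrum A `koop_spectrum`.
#' @param path Path of the eigenvalue TSV.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "koop_spectrum"))
  con <- file(path, "w")
  writeLines(c(sprintf("# operator: %s", spectrum$operator),
               sprintf("# epsilon: %s", fmt_num(spectrum$epsilon)),
               sprintf("# rank: %d", spectrum$rank),
               "index\treal\timag"), con)
  k <- length(spectrum$values)
  if (k > 0) {
    writeLines(sprintf("%d\t%s\t%s", seq_len(k) - 1L,
                       fmt_num(Re(spectrum$values)),
                       fmt_num(Im(spectrum$values))), con)
  }
  close(con)
  stem <- sub("\\.tsv$", "", path)
  if (!is.null(spectrum$points) && !is.null(spectrum$kernel)) {
    u <- spectrum$coefficients
    umat <- cbind(Re(u), Im(u))
    colnames(umat) <- NULL
    kern <- spectrum$kernel
    kmeta <- c(sprintf("kernel.family: %s", kern$family),
               switch(kern$family,
                 gaussian = sprintf("kernel.bandwidth: %s",
                                    fmt_num(kern$params$bandwidth)),
                 polynomial = sprintf("kernel.degree: %d kernel.offset: %s",
                                      kern$params$degree,
                                      fmt_num(kern$params$offset))),
               sprintf("kernel.d: %d", kern$d),
               sprintf("n_eig: %d", k),
               sprintf("operator: %s", spectrum$operator),
               sprintf("epsilon: %s", fmt_num(spectrum$epsilon)),
               sprintf("rank: %d", spectrum$rank))
    if (k > 0) {
      write_points(umat, paste0(stem, "_coefficients.tsv"), metadata = kmeta)
    } else {
      writeLines(paste0("# ", kmeta), paste0(stem, "_coefficients.tsv"))
    }
    write_points(spectrum$points, paste0(stem, "_points.tsv"))
  }
  invisible(path)
}

#' Read a spectral result written by [write_spectrum()]
#'
#' @param path Path of the eigenvalue TSV.
#' @return A `koop_spectrum` whose eigenfunctions evaluate identically to the
#'   stored one.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  operator <- sub("^# operator: ", "", grep("^# operator:", meta, value = TRUE))
  epsilon <- as.numeric(sub("^# epsilon: ", "",
                            grep("^# epsilon:", meta, value = TRUE)))
  rank <- as.integer(sub("^# rank: ", "", grep("^# rank:", meta, value = TRUE)))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  stopifnot(length(body) >= 1)  # header row
  vals <- if (length(body) > 1) {
    rows <- do.call(rbind, strsplit(body[-1], "\t"))
    complex(real = as.numeric(rows[, 2]), imaginary = as.numeric(rows[, 3]))
  } else {
    complex(0)
  }
  stem <- sub("\\.tsv$", "", path)
  cpath <- paste0(stem, "_coefficients.tsv")
  ppath <- paste0(stem, "_points.tsv")
  if (!file.exists(cpath) || !file.exists(ppath)) {
    stop_parse("sidecar files for %s are missing.", path)
  }
  clines <- readLines(cpath, warn = FALSE)
  kmeta <- sub("^\\s*#\\s?", "", grep("^\\s*#", clines, value = TRUE))
  cm <- if (length(vals) > 0) read_points(cpath) else NULL
  getv <- function(key) {
    hit <- grep(paste0("^", key, ": "), kmeta, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  d <- as.integer(getv("kernel.d"))
  kern <- switch(getv("kernel.family"),
    gaussian = gaussian_kernel(as.numeric(getv("kernel.bandwidth")), d),
    polynomial = {
      deg_off <- getv("kernel.degree")
      parts <- strsplit(deg_off, " kernel.offset: ")[[1]]
      polynomial_kernel(as.integer(parts[1]), as.numeric(parts[2]), d)
    },
    stop_parse("unknown kernel family in %s.", cpath))
  k <- length(vals)
  pts <- read_points(ppath)
  u <- if (k > 0) {
    cm[, seq_len(k), drop = FALSE] + 1i * cm[, k + seq_len(k), drop = FALSE]
  } else {
    matrix(0, nrow(pts), 0)
  }
  if (k > 0 && max(abs(Im(u))) == 0 && max(abs(Im(vals))) == 0) {
    u <- Re(u); vals <- Re(vals)
  } else if (k == 0) {
    vals <- Re(vals)
  }
  structure(list(values = vals, coefficients = u, points = unname(pts[, ]),
                 kernel = kern, operator = operator, epsilon = epsilon,
                 rank = rank, n = nrow(pts)),
            class = "koop_spectrum")
}

# -- run configuration -------------------------------------------------------

config_defaults <- function() {
  list(
    kernel = list(family = "gaussian", bandwidth = 1, degree = 2, offset = 1),
    solver = list(epsilon = NULL, n_eig = 10, rank_tol = 1e-10,
                  symmetric = FALSE),
    system = list(model = "qho", beta = 1, alpha = 1, hbar = 1, mass = 1,
                  omega = 1),
    sampling = list(m = 1000, seed = 1, dt = 1e-3, burn_in = 10000,
                    stride = 100, n_steps = NULL, x0 = NULL,
                    region = "box", lower = -5, upper = 5, radius = 20,
                    kde_bandwidth = 0.22, n_coords = 2, n_sets = NULL,
                    method = "reversible"),
    output = list(dir = ".", prefix = "koop")
  )
}

#' Read a run configuration
#'
#' YAML file with sections `kernel`, `solver`, `system`, `sampling`, `output`.
#' Every field has a default; unknown sections or keys are rejected with the
#' offending key named.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return Nested list of configuration values (class `koop_config`).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: %s", path)
    user <- tryCatch(yaml::read_yaml(path),
                     error = function(e) stop_parse(
                       "could not parse config %s: %s", path,
                       conditionMessage(e)))
    if (!is.list(user)) stop_parse("config %s is not a mapping.", path)
    for (section in names(user)) {
      if (!section %in% names(cfg)) {
        stop_config("unknown config section `%s`.", section)
      }
      for (key in names(user[[section]])) {
        if (!key %in% names(cfg[[section]])) {
          stop_config("unknown config key `%s.%s`.", section, key)
        }
        cfg[[section]][[key]] <- user[[section]][[key]]
      }
    }
  }
  structure(cfg, class = "koop_config")
}

config_kernel <- function(cfg, d) {
  k <- cfg$kernel
  switch(k$family,
    gaussian = gaussian_kernel(k$bandwidth, d),
    polynomial = polynomial_kernel(k$degree, k$offset, d),
    stop_config("invalid kernel family `%s`.", k$family))
}

config_model <- function(cfg) {
  s <- cfg$system
  switch(s$model,
    ou = ou_model(alpha = s$alpha, beta = s$beta),
    quadruple_well = quadruple_well_model(beta = s$beta),
    qho = qho_model(hbar = s$hbar, mass = s$mass, omega = s$omega),
    hydrogen = hydrogen_model(),
    stop_config("unknown system model `%s`.", s$model))
}

config_points <- function(cfg, d) {
  s <- cfg$sampling
  if (identical(s$region, "ball")) {
    sample_uniform_ball(s$radius, s$m, d, seed = s$seed)
  } else {
    sample_uniform_box(s$lower, s$upper, s$m, d = d, seed = s$seed)
  }
}

config_trajectory <- function(cfg, model) {
  s <- cfg$sampling
  n_steps <- s$n_steps %||% (s$burn_in + s$m * s$stride)
  x0 <- s$x0 %||% rep(1, model$d)
  euler_maruyama(model, x0 = x0, n_steps = n_steps, dt = s$dt,
                 burn_in = s$burn_in, stride = s$stride, seed = s$seed)
}

#' Run a pipeline from a configuration
#'
#' Realizes the four algorithmic steps -- choose a kernel, assemble the Gram
#' matrices, solve the eigenvalue problem, evaluate eigenfunctions -- for one
#' of the commands `simulate`, `metastable`, `schrodinger`,
#' `schrodinger-sde`, `manifold`, or `spectrum-eval`, writing TSV outputs
#' under the configured output directory. Runs are fully determined by the
#' configuration (all stochastic stages consume the configured seed).
#'
#' @param config A `koop_config` from [read_run_config()].
#' @param command Command name.
#' @param eval_points For `spectrum-eval`: path of a point table at which to
#'   re-evaluate a stored spectrum.
#' @param spectrum_path For `spectrum-eval`: path of the stored spectrum.
#' @return Character vector of files written, invisibly.
#' @export
run_pipeline <- function(config, command, eval_points = NULL,
                         spectrum_path = NULL) {
  stopifnot(inherits(config, "koop_config"))
  dir.create(config$output$dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$output$dir,
                                  paste0(config$output$prefix, "_", name))
  sv <- config$solver
  written <- character(0)
  log_line <- function(...) message(sprintf(...))
  if (command == "simulate") {
    model <- config_model(config)
    if (!inherits(model, "koop_sde")) {
      stop_config("`simulate` needs a drift-diffusion model.")
    }
    traj <- config_trajectory(config, model)
    f <- out("trajectory.tsv")
    write_points(as_points(traj), f, metadata = c(
      sprintf("model: %s", attr(traj, "model_name")),
      sprintf("dt: %s stride: %d burn_in: %d seed: %s",
              fmt_num(attr(traj, "dt")), attr(traj, "stride"),
              attr(traj, "burn_in"),
              paste(attr(traj, "seed") %||% "none"))))
    return(invisible(f))
  }
  if (command == "metastable") {
    model <- config_model(config)
    log_line("[1/4] kernel + trajectory (model %s)", model$name)
    traj <- config_trajectory(config, model)
    kern <- config_kernel(config, model$d)
    log_line("[2/4] assembling Gram matrices for %d samples", nrow(traj))
    dec <- metastable_analysis(traj, kernel = kern, n_eig = sv$n_eig,
                               n_sets = config$sampling$n_sets,
                               epsilon = sv$epsilon, rank_tol = sv$rank_tol,
                               seed = config$sampling$seed)
    log_line("[3/4] solved: %d dominant modes", dec$n_dominant)
    f1 <- out("eigenvalues.tsv"); write_spectrum(dec$spectrum, f1)
    f2 <- out("labels.tsv")
    utils::write.table(dec$assignments, f2, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    log_line("[4/4] wrote %s, %s", f1, f2)
    return(invisible(c(f1, f2)))
  }
  if (command == "schrodinger") {
    model <- config_model(config)
    if (!inherits(model, "koop_schrodinger")) {
      stop_config("`schrodinger` needs a Schrodinger model (qho or hydrogen).")
    }
    pts <- config_points(config, model$d)
    kern <- config_kernel(config, model$d)
    spec <- schrodinger_direct(pts, model, kernel = kern, n_eig = sv$n_eig,
                               epsilon = sv$epsilon, rank_tol = sv$rank_tol)
    f1 <- out("eigenvalues.tsv"); write_spectrum(spec, f1)
    f2 <- out("eigenfunctions.tsv")
    utils::write.table(augment(spec), f2, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(c(f1, f2)))
  }
  if (command == "schrodinger-sde") {
    s <- config$system
    gs <- switch(s$model,
      qho = qho_ground_state(hbar = s$hbar, mass = s$mass, omega = s$omega),
      hydrogen = hydrogen_ground_state(),
      stop_config("`schrodinger-sde` supports models qho and hydrogen."))
    pts <- config_points(config, gs$d)
    kern <- config_kernel(config, gs$d)
    wf <- schrodinger_via_sde(gs, pts, kernel = kern, hbar = s$hbar,
                              mass = s$mass, n_eig = sv$n_eig,
                              epsilon = sv$epsilon, rank_tol = sv$rank_tol)
    f1 <- out("eigenvalues.tsv")
    spec_e <- wf$spectrum
    spec_e$values <- wf$energies
    write_spectrum(spec_e, f1)
    return(invisible(f1))
  }
  if (command == "manifold") {
    s <- config$sampling
    pts <- swiss_roll_sample(s$m, seed = s$seed)
    x <- as_points(pts)
    # bandwidth 0 requests the nearest-neighbour heuristic
    kern <- if (identical(config$kernel$family, "gaussian") &&
                config$kernel$bandwidth == 0) NULL else {
      config_kernel(config, ncol(x))
    }
    emb <- manifold_embedding(x, kernel = kern, n_coords = s$n_coords,
                              method = s$method,
                              kde_bandwidth = s$kde_bandwidth,
                              epsilon = sv$epsilon)
    f <- out("embedding.tsv")
    utils::write.table(cbind(pts, emb$coordinates), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    return(invisible(f))
  }
  if (command == "spectrum-eval") {
    if (is.null(eval_points) || is.null(spectrum_path)) {
      stop_config("`spectrum-eval` needs `spectrum_path` and `eval_points`.")
    }
    spec <- read_spectrum(spectrum_path)
    q <- read_points(eval_points)
    vals <- Re(evaluate_eigenfunctions(spec, q))
    f <- out("eigenfunction_values.tsv")
    write_points(cbind(q[, ], vals), f,
                 metadata = sprintf("columns: %d point coords then %d eigenfunctions",
                                    ncol(q), ncol(vals)))
    return(invisible(f))
  }
  stop_config("unknown command `%s`.", command)
}
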