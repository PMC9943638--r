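config_param_keys <- c("mu", "sigma", "r", "N_pop", "n_targets", "beta",
                       "pi_cost", "gamma", "m", "omega", "lam", "T_horizon",
                       "threshold", "grid_lo", "grid_hi", "grid_n")
config_run_keys <- c("experiment", "seed", "out_dir", "fraction", "tol",
                     "window", "max_steps", "init", "rates", "rate",
                     "v_values", "e_panels", "v_grid", "k_steps")

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file holding any subset of the model
#' parameters (see [model_params]; omitted keys take the documented
#' defaults) plus run settings: \code{experiment}, \code{seed},
#' \code{out_dir}, convergence controls (\code{fraction}, \code{tol},
#' \code{window}, \code{max_steps}, \code{init}) and experiment grids
#' (\code{rates}, \code{rate}, \code{v_values}, \code{e_panels},
#' \code{v_grid}, \code{k_steps}). Unknown keys are rejected, and the
#' parameter invariants (including the unprofitable-exploitation
#' constraint) are enforced before any computation.
#'
#' @param path path to a YAML file; an empty file yields all defaults.
#' @return An object of class \code{violence_config}: list with
#'   \code{params} (a [model_params]) and \code{run} (the run settings).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_config(raw)
}

as_config <- function(raw) {
  stopifnot(is.list(raw))
  unknown <- setdiff(names(raw), c(config_param_keys, config_run_keys))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  params <- do.call(model_params, raw[intersect(names(raw), config_param_keys)])
  run <- raw[intersect(names(raw), config_run_keys)]
  if (is.null(run$seed)) run$seed <- 1L
  if (!is.null(run$experiment))
    run$experiment <- match.arg(run$experiment,
      c("policy-map", "equilibrium", "hysteresis", "vector-field", "incentive"))
  structure(list(params = params, run = run), class = "violence_config")
}

#' Write a configuration back to YAML
#'
#' Round-trips with [load_config]: writing and re-loading yields an
#' identical configuration.
#'
#' @param config a \code{violence_config}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "violence_config"))
  p <- unclass(config$params)
  yaml::write_yaml(c(p[config_param_keys], config$run), path, precision = 15)
  invisible(path)
}

#' @export
print.violence_config <- function(x, ...) {
  cat("run configuration\n")
  if (length(x$run) > 0) utils::str(x$run, no.list = TRUE, give.head = FALSE)
  print(x$params)
  invisible(x)
}

#' Write a reproducibility manifest
#'
#' Records the configuration hash, seed and package version alongside a
#' run's outputs, enough to re-run the deterministic stages bit-for-bit.
#'
#' @param config a \code{violence_config}.
#' @param dir output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$run$seed,
    package_version = as.character(utils::packageVersion("desperation")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Deterministic test fixtures
#'
#' Writes small deterministic inputs used by the test-suite and examples:
#' \describe{
#' \item{tiny_population}{a 10-agent population CSV with known strategy
#'   counts and resource signs;}
#' \item{policy_toy}{a 5-point resource-grid toy configuration (YAML) for
#'   the dynamic-programming enumeration oracle;}
#' \item{sweep_toy}{a 3-rate sweep configuration (YAML).}
#' }
#'
#' @param kind fixture kind.
#' @param seed integer seed (fixtures are fully deterministic given it).
#' @param dir output directory.
#' @return Path of the written fixture file.
#' @export
make_fixture <- function(kind = c("tiny_population", "policy_toy", "sweep_toy"),
                         seed = 1, dir = tempdir()) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(kind, ".", if (kind == "tiny_population") "csv" else "yaml"))
  if (kind == "tiny_population") {
    rng <- local_rng(seed)
    res <- round(stats::rnorm(10, 5, 10), 3)
    res[1:4] <- -abs(res[1:4]); res[5:10] <- abs(res[5:10])
    rng$restore()
    df <- data.frame(resources = res,
                     strategies = c(rep("exploit", 3), rep("violent", 2),
                                    rep("submissive", 5)))
    utils::write.csv(df, path, row.names = FALSE)
  } else if (kind == "policy_toy") {
    yaml::write_yaml(list(mu = 5, sigma = 4, r = 0.5, N_pop = 10,
                          n_targets = 2, T_horizon = 2, grid_lo = -8,
                          grid_hi = 12, grid_n = 5, seed = seed), path)
  } else {
    yaml::write_yaml(list(experiment = "hysteresis", seed = seed,
                          rates = c(0.005, 0.015, 0.03), N_pop = 2000,
                          max_steps = 200), path)
  }
  path
}

#' Read a population fixture
#'
#' @param path CSV with columns \code{resources}, \code{strategies}.
#' @param seed seed recorded on the object.
#' @return A \code{violence_population}.
#' @export
read_population <- function(path, seed = NA_integer_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("resources", "strategies") %in% names(df)),
            all(df$strategies %in% STRATEGIES))
  structure(list(resources = df$resources, strategies = df$strategies,
                 seed = seed), class = "violence_population")
}
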