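# YAML configuration for (spec, params) pairs.  Blocks: spec, means, phi,
# dynamics, theta, psi; alternatively `fixture: <name>` selects a registered
# scenario.

#' Read and write model configurations
#'
#' A configuration file is YAML with blocks `spec` (fields of [lcs_spec()]),
#' `means` (`mu0`, `mua`), `phi` (matrix as list of rows), `dynamics`
#' (`beta`, optionally `gamma`), `theta` and optionally `psi`.  A file
#' containing only `fixture: <name>` resolves to the registered scenario of
#' that name.  `read_config()` returns a validated `(spec, params)` pair or
#' fails with a precise error.
#'
#' @param path YAML file path.
#' @return `read_config()`: list with `spec` and `params`;
#'   `write_config()`: `path`, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  config_to_model(cfg)
}

config_to_model <- function(cfg) {
  if (!is.null(cfg$fixture)) {
    reg <- fixture_registry()
    if (!cfg$fixture %in% names(reg))
      stop(sprintf("unknown fixture '%s'", cfg$fixture), call. = FALSE)
    return(reg[[cfg$fixture]])
  }
  for (block in c("spec", "means", "phi", "dynamics", "theta"))
    if (is.null(cfg[[block]]))
      stop(sprintf("config is missing the '%s' block", block), call. = FALSE)
  sp <- cfg$spec
  args <- list(n_processes = sp$n_processes %||% 1L,
               stochastic = sp$stochastic %||% FALSE,
               n_occasions = sp$n_occasions %||% 5L,
               time_lag = sp$time_lag %||% 1)
  if ((args$n_processes %||% 1L) == 2L) {
    if (!is.null(sp$free_couplings))
      args$free_couplings <- as.logical(unlist(sp$free_couplings))
    if (!is.null(sp$error_covariance))
      args$error_covariance <- sp$error_covariance
    if (!is.null(sp$innovation_covariance))
      args$innovation_covariance <- sp$innovation_covariance
  }
  spec <- do.call(lcs_spec, args)
  as_mat <- function(x, name) {
    if (is.list(x)) x <- do.call(rbind, lapply(x, unlist))
    as_square_matrix(x, name)
  }
  params <- lcs_params(
    mu0 = unlist(cfg$means$mu0), mua = unlist(cfg$means$mua),
    phi = as_mat(cfg$phi, "phi"),
    beta = unlist(cfg$dynamics$beta),
    gamma = if (!is.null(cfg$dynamics$gamma)) unlist(cfg$dynamics$gamma),
    theta = as_mat(cfg$theta, "theta"),
    psi = if (!is.null(cfg$psi)) as_mat(cfg$psi, "psi"))
  params <- validate_params(spec, params)
  list(spec = spec, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_config
#' @param spec an [lcs_spec()].
#' @param params an [lcs_params()].
#' @export
write_config <- function(spec, params, path) {
  validate_params(spec, params)
  mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  cfg <- list(
    spec = Filter(Negate(is.null),
                  list(n_processes = spec$n_processes,
                       stochastic = spec$stochastic,
                       n_occasions = spec$n_occasions,
                       time_lag = spec$time_lag,
                       free_couplings = spec$free_couplings,
                       error_covariance = if (spec$n_processes == 2L)
                         spec$error_covariance,
                       innovation_covariance = if (spec$innovation_covariance)
                         TRUE)),
    means = list(mu0 = as.list(params$mu0), mua = as.list(params$mua)),
    phi = mat_rows(params$phi),
    dynamics = Filter(Negate(is.null),
                      list(beta = as.list(params$beta),
                           gamma = if (!is.null(params$gamma))
                             as.list(params$gamma))),
    theta = mat_rows(params$theta))
  if (!is.null(params$psi)) cfg$psi <- mat_rows(params$psi)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
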