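#' Specify the structure of a latent change score model
#'
#' A model specification records the structural choices of an LCS model:
#' how many coupled processes, whether latent innovations are present
#' (stochastic variant), the number of equally spaced measurement occasions,
#' and which bivariate blocks are free.
#'
#' @param n_processes 1 (univariate dual LCS) or 2 (bivariate, coupled).
#' @param stochastic logical; if `TRUE`, latent changes carry Gaussian
#'   innovations whose effect persists through the dynamics.
#' @param n_occasions number of measurement occasions `T` (at least 3);
#'   occasions are indexed `0 ... T-1`.
#' @param time_lag positive spacing between adjacent occasions (default 1).
#' @param free_couplings length-2 logical `(gamma_x free, gamma_y free)`;
#'   bivariate only.  A coupling that is not free is fixed at 0.
#' @param error_covariance logical; estimate a within-occasion
#'   measurement-error covariance between the two processes (bivariate only,
#'   default `TRUE`).
#' @param innovation_covariance logical; estimate a within-change innovation
#'   covariance (stochastic bivariate only, default `TRUE`).
#'
#' @return An object of class `"lcs_spec"`.
#' @seealso [count_free_parameters()], [lcs_params()]
#' @examples
#' lcs_spec(1, n_occasions = 5)                     # 7-parameter dual LCS
#' lcs_spec(2, stochastic = TRUE, n_occasions = 5)  # 24-parameter stochastic
#' @export
lcs_spec <- function(n_processes = 1L, stochastic = FALSE, n_occasions = 5L,
                     time_lag = 1, free_couplings = c(TRUE, TRUE),
                     error_covariance = TRUE, innovation_covariance = TRUE) {
  n_processes <- as.integer(n_processes)
  n_occasions <- as.integer(n_occasions)
  if (!n_processes %in% c(1L, 2L))
    stop("'n_processes' must be 1 or 2", call. = FALSE)
  if (n_occasions < 3L)
    stop("'n_occasions' must be at least 3", call. = FALSE)
  if (!is.numeric(time_lag) || length(time_lag) != 1L || time_lag <= 0)
    stop("'time_lag' must be a positive scalar", call. = FALSE)
  if (n_processes == 1L) {
    # bivariate-only flags are rejected when supplied explicitly
    if (!missing(free_couplings))
      stop("'free_couplings' applies to bivariate models only", call. = FALSE)
    if (!missing(error_covariance))
      stop("'error_covariance' applies to bivariate models only",
           call. = FALSE)
    if (!missing(innovation_covariance))
      stop("'innovation_covariance' applies to bivariate models only",
           call. = FALSE)
    free_couplings <- NULL
    error_covariance <- FALSE
    innovation_covariance <- FALSE
  } else {
    free_couplings <- as.logical(free_couplings)
    if (length(free_couplings) != 2L || anyNA(free_couplings))
      stop("'free_couplings' must be two logicals (gamma_x, gamma_y)",
           call. = FALSE)
  }
  if (!stochastic) innovation_covariance <- FALSE
  structure(
    list(n_processes = n_processes,
         stochastic = isTRUE(stochastic),
         n_occasions = n_occasions,
         time_lag = time_lag,
         free_couplings = free_couplings,
         error_covariance = isTRUE(error_covariance) && n_processes == 2L,
         innovation_covariance = isTRUE(innovation_covariance) &&
           n_processes == 2L && isTRUE(stochastic)),
    class = "lcs_spec")
}

process_names <- function(spec) {
  if (spec$n_processes == 1L) "y" else c("x", "y")
}

#' @export
print.lcs_spec <- function(x, ...) {
  kind <- if (x$n_processes == 1L) "Univariate dual" else "Bivariate coupled"
  if (x$stochastic) kind <- paste(kind, "stochastic")
  cat(sprintf("%s LCS specification\n", kind))
  cat(sprintf("  occasions: %d (lag %g), free parameters: %d\n",
              x$n_occasions, x$time_lag, count_free_parameters(x)))
  if (x$n_processes == 2L) {
    cat(sprintf("  couplings free: gamma_x=%s gamma_y=%s; error covariance: %s\n",
                x$free_couplings[1], x$free_couplings[2], x$error_covariance))
    if (x$stochastic)
      cat(sprintf("  innovation covariance: %s\n", x$innovation_covariance))
  }
  invisible(x)
}

#' Count the freely estimated parameters of an LCS specification
#'
#' Sums the free parameters over the model blocks: process means (initial
#' level and additive component), the random-effect covariance `phi`, the
#' dynamics (self-feedbacks and any free couplings), the measurement-error
#' covariance `theta`, and (stochastic models) the innovation covariance
#' `psi`.  The loading of the additive component on each change is fixed to 1
#' and never counted.  The count does not depend on the number of occasions.
#'
#' @param spec an [lcs_spec()] object.
#' @return integer count.
#' @examples
#' count_free_parameters(lcs_spec(1))                       # 7
#' count_free_parameters(lcs_spec(2, stochastic = TRUE))    # 24
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "lcs_spec"))
  p <- spec$n_processes
  k <- 2L * p                          # means of initial levels + additives
  k <- k + (2L * p) * (2L * p + 1L) / 2L   # distinct phi entries
  k <- k + p                           # self-feedbacks
  if (p == 2L) k <- k + sum(spec$free_couplings)
  k <- k + p                           # error variances
  if (p == 2L && spec$error_covariance) k <- k + 1L
  if (spec$stochastic) {
    k <- k + p                         # innovation variances
    if (p == 2L && spec$innovation_covariance) k <- k + 1L
  }
  as.integer(k)
}
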