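#' Lognormal response-time model
#'
#' Under a solution attempt (`xi = 1`) the log response time of person
#' \eqn{i} on item \eqn{j} is normal with mean \eqn{\beta_j - \tau_i}
#' (time intensity minus person speed) and variance \eqn{1/\kappa_j^2};
#' under a rapid guess (`xi = 0`) it is normal with mean \eqn{\beta_0}
#' and variance \eqn{1/\kappa_0^2}, common to all persons and items.
#'
#' `logdensity_rt()` returns the log-density of the *observed* response
#' time in seconds (i.e. the lognormal density including the 1/rt
#' change-of-variable term).  All likelihood computations in the package
#' — mixture responsibilities and DIC deviances alike — use this single
#' observed-scale convention.
#'
#' @param rt observed response time in seconds, > 0; vectorized.
#' @param tau person speed (log-seconds offset).
#' @param beta item time intensity (mean log-seconds for the population).
#' @param kappa item time discrimination, > 0; the log-RT standard
#'   deviation is `1/kappa`.
#' @param xi behaviour indicator (1 = solution attempt, 0 = rapid guess).
#' @param beta0,kappa0 rapid-guessing state time intensity and
#'   discrimination.
#' @return `logdensity_rt`: log-density of `rt`; `mean_log_rt`: the mean
#'   of log RT under the indicated behaviour state.
#' @examples
#' logdensity_rt(exp(2.5), tau = 0.5, beta = 3, kappa = 2, xi = 1)
#' mean_log_rt(tau = 0.5, beta = 3, xi = 0, beta0 = 2)  # 2
#' @export
logdensity_rt <- function(rt, tau, beta, kappa, xi = 1,
                          beta0 = NULL, kappa0 = NULL) {
  if (any(rt <= 0)) stop("rt must be positive")
  if (any(kappa <= 0)) stop("kappa must be positive")
  if (!all(xi %in% c(0, 1))) stop("xi must be 0 or 1")
  if (any(xi == 0)) {
    if (is.null(beta0) || is.null(kappa0)) {
      stop("beta0 and kappa0 are required when xi = 0")
    }
    if (any(kappa0 <= 0)) stop("kappa0 must be positive")
  }
  meanlog <- ifelse(xi == 1, beta - tau,
                    if (is.null(beta0)) NA_real_ else beta0)
  sdlog <- ifelse(xi == 1, 1 / kappa,
                  if (is.null(kappa0)) NA_real_ else 1 / kappa0)
  stats::dlnorm(rt, meanlog = meanlog, sdlog = sdlog, log = TRUE)
}

#' @rdname logdensity_rt
#' @export
mean_log_rt <- function(tau, beta, xi = 1, beta0 = NULL) {
  if (!all(xi %in% c(0, 1))) stop("xi must be 0 or 1")
  if (any(xi == 0) && is.null(beta0)) stop("beta0 required when xi = 0")
  ifelse(xi == 1, beta - tau, if (is.null(beta0)) NA_real_ else beta0)
}
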