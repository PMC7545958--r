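#' Specify a simulation design
#'
#' Bundles everything needed to generate a synthetic joint
#' response/response-time dataset: the Q-matrix, sample size, base model
#' form, the solution-attempt probabilities, and the generating
#' distributions for every parameter family.
#'
#' Defaults reproduce the standard high-quality-test design used by the
#' package's recovery studies: guessing \eqn{g_j \sim U(0.05, 0.3)} and
#' slipping \eqn{s_j \sim U(0.05, 0.2)} (item discrimination indices
#' supported on (0.5, 0.9)); time intensity \eqn{\beta_j \sim U(2, 4)}
#' and discrimination \eqn{\kappa_j \sim U(0.15, 2)}; rapid-guessing
#' state fixed at \eqn{\beta_0 = 2}, \eqn{\kappa_0 = 1.6}; person speed
#' \eqn{\tau_i \sim N(0, 0.3^2)}; attributes dichotomized at 0.253
#' (\eqn{z_{0.6}}) from an equicorrelated multivariate normal with mean
#' 0.5 and correlation 0.5, giving about 60% mastery per attribute.
#'
#' @param qmatrix a [validate_qmatrix()] object.
#' @param n_persons number of test-takers I.
#' @param model base response model, `"DINA"` or `"DINO"`.
#' @param pi_j solution-attempt probability per item (length J or scalar);
#'   `1 - pi_j` is the rapid-guessing rate.  All ones disables rapid
#'   guessing.
#' @param g_range,s_range uniform bounds for guessing and slipping.
#' @param beta_range,kappa_range uniform bounds for item time intensity
#'   and time discrimination.
#' @param beta0,kappa0 rapid-guessing state time intensity/discrimination.
#' @param sigma_tau person-speed standard deviation.
#' @param attr_mu,attr_rho,attr_cutoff latent attribute model: mean of
#'   the underlying normal, equicorrelation, and dichotomization cutoff.
#' @return an object of class `"sim_design"`.
#' @seealso [study1_design()], [simulate_dataset()]
#' @export
sim_design <- function(qmatrix, n_persons = 1000L,
                       model = c("DINA", "DINO"),
                       pi_j = 1,
                       g_range = c(0.05, 0.3), s_range = c(0.05, 0.2),
                       beta_range = c(2, 4), kappa_range = c(0.15, 2),
                       beta0 = 2, kappa0 = 1.6,
                       sigma_tau = 0.3,
                       attr_mu = 0.5, attr_rho = 0.5, attr_cutoff = 0.253) {
  model <- match.arg(model)
  Q <- validate_qmatrix(qmatrix)
  J <- nrow(Q)
  if (length(pi_j) == 1L) pi_j <- rep(pi_j, J)
  stopifnot(length(pi_j) == J, all(pi_j > 0 & pi_j <= 1))
  chk_range <- function(r, lo = 0, hi = 1, name) {
    if (length(r) != 2L || r[1L] >= r[2L] || r[1L] < lo || r[2L] > hi) {
      stop(name, " must be an increasing pair within [", lo, ", ", hi, "]")
    }
  }
  chk_range(g_range, 0, 1, "g_range")
  chk_range(s_range, 0, 1, "s_range")
  chk_range(beta_range, -Inf, Inf, "beta_range")
  chk_range(kappa_range, 0, Inf, "kappa_range")
  stopifnot(sigma_tau > 0, kappa0 > 0,
            attr_rho >= 0, attr_rho < 1)
  structure(list(qmatrix = Q, n_persons = as.integer(n_persons),
                 model = model, pi_j = pi_j, rg_enabled = any(pi_j < 1),
                 g_range = g_range, s_range = s_range,
                 beta_range = beta_range, kappa_range = kappa_range,
                 beta0 = beta0, kappa0 = kappa0, sigma_tau = sigma_tau,
                 attr_mu = attr_mu, attr_rho = attr_rho,
                 attr_cutoff = attr_cutoff),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("sim_design: %s, I = %d, J = %d, K = %d, RG %s\n",
              x$model, x$n_persons, nrow(x$qmatrix), ncol(x$qmatrix),
              if (x$rg_enabled)
                sprintf("enabled (mean 1-pi = %.3f)", mean(1 - x$pi_j))
              else "disabled"))
  invisible(x)
}

#' Standard recovery-study designs
#'
#' `study1_design()` returns the canonical non-compensatory (DINA)
#' recovery design: the 30 x 5 [sim_qmatrix()], 1,000 persons, and the
#' default generating distributions of [sim_design()].  In the
#' rapid-guessing condition the per-item solution-attempt probabilities
#' follow the design table's pattern, alternating blocks of
#' \eqn{\pi_j = 0.9} and \eqn{\pi_j = 0.8} (RG rates 0.1 and 0.2):
#' items 1-5, 11-15, 21-25 at 0.9 and items 6-10, 16-20, 26-30 at 0.8.
#' `rg_level = "0.2"` shifts the whole pattern down by 0.1 (blocks 0.8 /
#' 0.7); `"none"` disables rapid guessing (all \eqn{\pi_j = 1}).
#' `pi_pattern = "homogeneous"` replaces the blocked pattern with a
#' constant \eqn{\pi_j} equal to `1 -` the numeric level.
#'
#' `study2_design()` is identical except the response process is the
#' compensatory DINO model.
#'
#' @param rg_level `"0.1"`, `"0.2"` or `"none"` (numeric 0.1 / 0.2
#'   accepted).
#' @param pi_pattern `"table"` (blocked 0.9/0.8 pattern) or
#'   `"homogeneous"`.
#' @param n_persons number of simulated test-takers.
#' @return a [sim_design()] object.
#' @export
study1_design <- function(rg_level = c("0.1", "0.2", "none"),
                          pi_pattern = c("table", "homogeneous"),
                          n_persons = 1000L) {
  rg_level <- match.arg(as.character(rg_level), c("0.1", "0.2", "none"))
  pi_pattern <- match.arg(pi_pattern)
  base_pattern <- rep(rep(c(0.9, 0.8), each = 5), times = 3)
  pi_j <- switch(rg_level,
    "0.1"  = if (pi_pattern == "table") base_pattern else rep(0.9, 30),
    "0.2"  = if (pi_pattern == "table") base_pattern - 0.1 else rep(0.8, 30),
    "none" = rep(1, 30))
  sim_design(sim_qmatrix(), n_persons = n_persons, model = "DINA",
             pi_j = pi_j)
}

#' @rdname study1_design
#' @export
study2_design <- function(rg_level = c("0.1", "0.2", "none"),
                          pi_pattern = c("table", "homogeneous"),
                          n_persons = 1000L) {
  d <- study1_design(rg_level, pi_pattern, n_persons)
  d$model <- "DINO"
  d
}

#' Simulate correlated binary attribute profiles
#'
#' Draws I latent vectors from an equicorrelated multivariate normal
#' (unit variances, off-diagonal `rho`, mean `mu`) and dichotomizes at
#' `cutoff`: attribute k is mastered iff the k-th latent value exceeds
#' the cutoff.  With `mu = 0.5`, `rho = 0.5`, `cutoff = 0.253`
#' (\eqn{z_{0.6}}) each attribute is mastered by about 60% of persons.
#'
#' @param I number of persons.
#' @param K number of attributes.
#' @param mu latent mean (scalar).
#' @param rho equicorrelation in \[0, 1).
#' @param cutoff dichotomization threshold.
#' @return I x K integer matrix of 0/1 profiles.
#' @export
simulate_attributes <- function(I, K, mu = 0.5, rho = 0.5, cutoff = 0.253) {
  stopifnot(I >= 1, K >= 1, rho >= 0, rho < 1)
  # equicorrelated MVN via one shared + one idiosyncratic standard normal
  shared <- stats::rnorm(I)
  z <- sqrt(rho) * matrix(shared, I, K) +
    sqrt(1 - rho) * matrix(stats::rnorm(I * K), I, K)
  a <- (mu + z > cutoff)
  storage.mode(a) <- "integer"
  a
}

#' Simulate a joint response / response-time dataset
#'
#' Draws item parameters from the design's generating distributions,
#' person attributes and speeds, behaviour indicators
#' \eqn{\xi_{ij} \sim Bernoulli(\pi_j)}, then responses from the base
#' CDM (rapid-guess cells succeed at the guessing rate) and response
#' times from the two-state lognormal model.  The returned dataset
#' carries the complete generating truth for recovery evaluation.
#'
#' @param design a [sim_design()] object.
#' @param seed integer seed; the dataset is bit-reproducible given the
#'   seed.
#' @return an object of class `"rtcdm_data"`: list with `Y` (I x J
#'   integer), `RT` (I x J positive seconds), `qmatrix`, `model`, and
#'   `truth` (list: `alpha`, `tau`, `xi`, `g`, `s`, `beta`, `kappa`,
#'   `pi_j`, `beta0`, `kappa0`).
#' @export
simulate_dataset <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  if (!missing(seed)) set.seed(as.integer(seed))
  Q <- design$qmatrix
  I <- design$n_persons
  J <- nrow(Q)
  K <- ncol(Q)

  g <- stats::runif(J, design$g_range[1], design$g_range[2])
  s <- stats::runif(J, design$s_range[1], design$s_range[2])
  beta <- stats::runif(J, design$beta_range[1], design$beta_range[2])
  kappa <- stats::runif(J, design$kappa_range[1], design$kappa_range[2])

  alpha <- simulate_attributes(I, K, design$attr_mu, design$attr_rho,
                               design$attr_cutoff)
  tau <- stats::rnorm(I, 0, design$sigma_tau)
  xi <- matrix(stats::rbinom(I * J, 1L, rep(design$pi_j, each = I)), I, J)

  # mastery indicator per person-item under the base model
  M <- mastery_from_alpha(alpha, Q, design$model)
  p_solution <- M * rep(1 - s, each = I) + (1 - M) * rep(g, each = I)
  p <- xi * p_solution + (1 - xi) * rep(g, each = I)
  Y <- matrix(stats::rbinom(I * J, 1L, p), I, J)

  meanlog <- xi * (rep(beta, each = I) - tau) + (1 - xi) * design$beta0
  sdlog <- xi / rep(kappa, each = I) + (1 - xi) / design$kappa0
  RT <- matrix(stats::rlnorm(I * J, meanlog, sdlog), I, J)

  structure(list(
    Y = Y, RT = RT, qmatrix = Q, model = design$model,
    truth = list(alpha = alpha, tau = tau, xi = xi,
                 g = g, s = s, beta = beta, kappa = kappa,
                 pi_j = design$pi_j, beta0 = design$beta0,
                 kappa0 = design$kappa0, sigma_tau = design$sigma_tau)),
    class = "rtcdm_data")
}

# per-person mastery indicator matrix (I x J) given profiles
mastery_from_alpha <- function(alpha, qmatrix, model = c("DINA", "DINO")) {
  model <- match.arg(model)
  Q <- unclass(qmatrix)
  hits <- alpha %*% t(Q)
  m <- if (model == "DINA") {
    sweep(hits, 2L, rowSums(Q), `>=`)
  } else {
    hits >= 1
  }
  storage.mode(m) <- "integer"
  m
}

#' Assemble a dataset from observed matrices
#'
#' Wraps observed response and response-time matrices (e.g. read from
#' file) into the container expected by [fit_rtcdm()].  The design is
#' complete-data: missing cells are rejected, not imputed.
#'
#' @param Y I x J binary response matrix.
#' @param RT I x J positive response-time matrix, seconds.
#' @param qmatrix a [validate_qmatrix()] object (or coercible matrix).
#' @param model base model form the data are believed to follow
#'   (`"DINA"` or `"DINO"`); stored as a label only.
#' @return an `"rtcdm_data"` object without a truth block.
#' @export
rtcdm_data <- function(Y, RT, qmatrix, model = c("DINA", "DINO")) {
  model <- match.arg(model)
  Q <- validate_qmatrix(qmatrix)
  Y <- as.matrix(Y); RT <- as.matrix(RT)
  if (!identical(dim(Y), dim(RT))) {
    stop(sprintf("dimension mismatch: Y is %dx%d but RT is %dx%d",
                 nrow(Y), ncol(Y), nrow(RT), ncol(RT)))
  }
  if (ncol(Y) != nrow(Q)) {
    stop(sprintf("dimension mismatch: Y has %d items but Q-matrix has %d",
                 ncol(Y), nrow(Q)))
  }
  if (anyNA(Y) || anyNA(RT)) stop("missing cells are not supported")
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  if (any(RT <= 0)) stop("all response times must be positive")
  storage.mode(Y) <- "integer"
  structure(list(Y = Y, RT = RT, qmatrix = Q, model = model, truth = NULL),
            class = "rtcdm_data")
}

#' @export
print.rtcdm_data <- function(x, ...) {
  cat(sprintf("rtcdm_data: %d persons x %d items, %d attributes (%s)%s\n",
              nrow(x$Y), ncol(x$Y), ncol(x$qmatrix), x$model,
              if (is.null(x$truth)) "" else ", with simulation truth"))
  invisible(x)
}
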