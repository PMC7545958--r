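#' Item response functions: G-DINA, DINA, DINO and rapid-guessing forms
#'
#' Success probabilities for one person-item pair.  `p_correct_gdina()`
#' evaluates the saturated G-DINA model with identity link,
#' \deqn{P(\alpha^*) = \delta_0 + \sum_k \delta_k \alpha_k +
#'   \sum_{k<k'} \delta_{kk'} \alpha_k \alpha_{k'} + \dots +
#'   \delta_{12\dots K^*} \prod_k \alpha_k,}
#' where the delta vector is indexed over all subsets of the item's
#' required attributes.  `p_correct_dina()` and `p_correct_dino()` are the
#' two-parameter special cases: DINA gives \eqn{1 - s} only when *all*
#' required attributes are mastered (else \eqn{g}); DINO gives
#' \eqn{1 - s'} when *at least one* is mastered (else \eqn{g'}).
#'
#' `p_correct_rg()` is the rapid-guessing mixture form: when the latent
#' behaviour indicator `xi = 1` (solution attempt) it equals the base
#' function; when `xi = 0` (rapid guess) the mastery terms drop and the
#' probability is the baseline `delta_star` (by default tied to the
#' guessing parameter \eqn{\delta_0}, i.e. a rapid guess succeeds at the
#' same rate as random guessing without the required attributes).
#'
#' @param alpha binary attribute profile of length K (or already-reduced
#'   profile of length \eqn{K^*} when `qrow` is `NULL`).
#' @param qrow binary Q-matrix row for the item; `NULL` means `alpha` is
#'   already reduced.
#' @param delta numeric delta vector of length \eqn{2^{K^*}}, ordered by
#'   subsets of the required attributes in [latent_classes()] bit order
#'   (element 1 is the intercept \eqn{\delta_0}, element `2^(k-1)+1` the
#'   main effect of required attribute k, ..., last element the highest
#'   interaction).
#' @param g,s guessing and slipping parameters in (0, 1) with
#'   \eqn{g < 1 - s}.
#' @return success probability in \[0, 1\].
#' @examples
#' p_correct_dina(c(1, 1, 0), g = 0.2, s = 0.1, qrow = c(1, 1, 0))  # 0.9
#' p_correct_gdina(c(1, 1), delta = c(0.1, 0.3, 0.2, 0.3))          # 0.9
#' @name irf
NULL

reduce_alpha <- function(alpha, qrow) {
  if (is.null(qrow)) return(alpha)
  stopifnot(length(alpha) == length(qrow))
  alpha[qrow == 1]
}

check_prob_pair <- function(g, s, label = c("g", "s")) {
  if (!(g > 0 && g < 1)) stop(sprintf("%s must lie in (0, 1)", label[1L]))
  if (!(s > 0 && s < 1)) stop(sprintf("%s must lie in (0, 1)", label[2L]))
  if (!(g < 1 - s)) {
    stop(sprintf("monotonicity violated: %s >= 1 - %s (IDI <= 0)",
                 label[1L], label[2L]))
  }
  invisible(TRUE)
}

#' @rdname irf
#' @export
p_correct_gdina <- function(alpha, delta, qrow = NULL) {
  a <- reduce_alpha(alpha, qrow)
  ks <- length(a)
  if (length(delta) != 2^ks) {
    stop("delta must have length 2^K* = ", 2^ks)
  }
  subsets <- latent_classes_or_scalar(ks)
  # a subset contributes iff every attribute in it is mastered
  active <- subsets %*% (1 - a) == 0
  p <- sum(delta[active])
  if (p < -1e-12 || p > 1 + 1e-12) {
    stop("delta vector yields probability outside [0, 1]: ", format(p))
  }
  min(max(p, 0), 1)
}

# latent_classes() extended to K* = 0 (single-item edge: unused in valid
# Q-matrices but keeps the subset enumeration total)
latent_classes_or_scalar <- function(K) {
  if (K == 0L) matrix(0L, 1L, 0L) else latent_classes(K)
}

#' Validate a G-DINA delta vector
#'
#' Checks, eagerly at construction time, that every reduced profile's
#' success probability lies in \[0, 1\].
#'
#' @inheritParams irf
#' @return `delta`, invisibly, if valid; otherwise an error.
#' @export
validate_delta <- function(delta) {
  ks <- as.integer(round(log2(length(delta))))
  if (2^ks != length(delta)) stop("delta length must be a power of 2")
  profiles <- latent_classes_or_scalar(ks)
  for (r in seq_len(nrow(profiles))) {
    p_correct_gdina(profiles[r, ], delta)  # errors if outside [0, 1]
  }
  invisible(delta)
}

#' @rdname irf
#' @export
p_correct_dina <- function(alpha, g, s, qrow = NULL) {
  check_prob_pair(g, s)
  a <- reduce_alpha(alpha, qrow)
  if (all(a == 1)) 1 - s else g
}

#' @rdname irf
#' @export
p_correct_dino <- function(alpha, g, s, qrow = NULL) {
  check_prob_pair(g, s, c("g'", "s'"))
  a <- reduce_alpha(alpha, qrow)
  if (any(a == 1)) 1 - s else g
}

#' DINA / DINO as constrained G-DINA delta vectors
#'
#' The DINA model keeps only the intercept and the highest-order
#' interaction (\eqn{\delta_0 = g}, \eqn{\delta_{12\dots K^*} = 1-s-g});
#' the DINO model sets all main effects and interactions to a common
#' magnitude \eqn{d = 1-s'-g'} with alternating sign by interaction
#' order, \eqn{\delta_S = (-1)^{|S|+1} d}.
#'
#' @inheritParams irf
#' @param Kstar number of required attributes for the item.
#' @return delta vector of length `2^Kstar`.
#' @export
delta_dina <- function(g, s, Kstar) {
  check_prob_pair(g, s)
  d <- numeric(2^Kstar)
  d[1L] <- g
  d[2^Kstar] <- 1 - s - g
  d
}

#' @rdname delta_dina
#' @export
delta_dino <- function(g, s, Kstar) {
  check_prob_pair(g, s, c("g'", "s'"))
  sizes <- rowSums(latent_classes_or_scalar(Kstar))
  d <- ifelse(sizes == 0, g, (-1)^(sizes + 1) * (1 - s - g))
  as.numeric(d)
}

#' @rdname irf
#' @param xi behaviour indicator: 1 = solution attempt, 0 = rapid guess.
#' @param model base model form, `"DINA"`, `"DINO"` or `"GDINA"`.
#' @param delta_star success probability of a rapid guess; defaults to
#'   the base model's intercept (`g` for DINA/DINO, `delta[1]` for
#'   G-DINA).
#' @export
p_correct_rg <- function(alpha, xi, model = c("DINA", "DINO", "GDINA"),
                         g = NULL, s = NULL, delta = NULL, qrow = NULL,
                         delta_star = NULL) {
  model <- match.arg(model)
  if (!xi %in% c(0, 1)) stop("xi must be 0 or 1")
  if (xi == 1) {
    return(switch(model,
                  DINA  = p_correct_dina(alpha, g, s, qrow),
                  DINO  = p_correct_dino(alpha, g, s, qrow),
                  GDINA = p_correct_gdina(alpha, delta, qrow)))
  }
  if (is.null(delta_star)) {
    delta_star <- if (model == "GDINA") delta[1L] else g
  }
  if (!(delta_star > 0 && delta_star < 1)) stop("delta_star must lie in (0, 1)")
  delta_star
}

#' Item discrimination index
#'
#' \eqn{IDI = 1 - s - g}: the gap between the success probability with
#' and without the requisite attributes.  Larger values indicate a more
#' informative item.
#'
#' @inheritParams irf
#' @return numeric IDI value(s); vectorized.
#' @export
idi <- function(g, s) {
  stopifnot(all(g > 0 & g < 1), all(s > 0 & s < 1))
  1 - s - g
}
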