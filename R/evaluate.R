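#' Recovery metrics: bias, RMSE, speed reliability
#'
#' Given estimates of the same quantity across replications,
#' `bias()` is the mean signed error \eqn{\sum_r (\hat\nu_r - \nu)/r}
#' and `rmse()` the root mean squared error
#' \eqn{\sqrt{\sum_r (\hat\nu_r - \nu)^2 / r}}.
#' `reliability()` is the squared Pearson correlation between true and
#' estimated person speeds.
#'
#' @param estimates numeric vector of estimates across replications.
#' @param truth true value (scalar, or vector matching `estimates` when
#'   the truth differs per replication).
#' @return scalar metric.
#' @examples
#' bias(c(0.6, 0.7), 0.5)   # 0.15
#' rmse(c(0.4, 0.6), 0.5)   # 0.1
#' @export
bias <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("empty estimate vector")
  mean(estimates - truth)
}

#' @rdname bias
#' @export
rmse <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("empty estimate vector")
  sqrt(mean((estimates - truth)^2))
}

#' @rdname bias
#' @param tau_hat,tau estimated and true person speeds (length >= 3,
#'   non-constant).
#' @export
reliability <- function(tau_hat, tau) {
  stopifnot(length(tau_hat) == length(tau), length(tau) >= 3)
  if (stats::sd(tau_hat) == 0 || stats::sd(tau) == 0) {
    stop("zero-variance speed vector")
  }
  stats::cor(tau_hat, tau)^2
}

#' Attribute classification
#'
#' `classify_attributes()` dichotomizes posterior mastery probabilities
#' at a threshold; a probability exactly at the threshold classifies as
#' mastery (ties go to 1).  `classification_accuracy()` is the mean
#' cell-wise agreement between estimated and true binary attribute
#' matrices (equivalently the accuracy per attribute averaged over
#' attributes).
#'
#' @param posterior_probs I x K matrix of posterior mastery
#'   probabilities.
#' @param threshold classification threshold, default 0.5.
#' @return `classify_attributes`: binary I x K matrix.
#' @export
classify_attributes <- function(posterior_probs, threshold = 0.5) {
  p <- as.matrix(posterior_probs)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  m <- (p >= threshold)
  storage.mode(m) <- "integer"
  m
}

#' @rdname classify_attributes
#' @param est,truth binary matrices of identical dimension.
#' @return `classification_accuracy`: scalar in \[0, 1\].
#' @export
classification_accuracy <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!identical(dim(est), dim(truth))) stop("shape mismatch")
  mean(est == truth)
}

#' Cohen's kappa for two binary classifications
#'
#' Chance-corrected agreement \eqn{(p_o - p_e)/(1 - p_e)} with
#' marginal-product expected agreement.  When both raters are constant
#' and identical, agreement is perfect but chance-undefined; the value
#' is defined as 1 with a warning.
#'
#' @param a,b binary vectors of equal length.
#' @return scalar kappa.
#' @export
cohens_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), all(a %in% c(0, 1)), all(b %in% c(0, 1)))
  po <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) {
    warning("both classifications constant; kappa undefined, returning 1")
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Replicated parameter-recovery study
#'
#' Simulates `n_reps` datasets from `design`, fits each requested model,
#' and aggregates recovery metrics: per-item and per-family bias and
#' RMSE of the item parameters, attribute classification accuracy
#' (cell-wise, with whole-pattern accuracy as a secondary column), and
#' person-speed reliability.  Item parameters are redrawn each
#' replication from the design's generating distributions; each
#' replication's seed derives deterministically from `seed`.
#'
#' @param design a [sim_design()] object.
#' @param models character subset of `c("rg", "base")`: `"rg"` fits the
#'   rapid-guessing mixture, `"base"` the model without it.
#' @param n_reps number of replications.
#' @param seed master seed.
#' @param chain a [chain_config()]; deviance storage is off by default
#'   here to bound memory across replications.
#' @param priors an [rtcdm_priors()] list.
#' @param progress print one line per replication.
#' @return object of class `"recovery_report"`: list with `summary`
#'   (per model x family bias/RMSE data frame), `person` (per model
#'   accuracy/reliability means), `per_item` (item-level bias/RMSE),
#'   `per_rep` (replication-level metrics) and `n_reps`.
#' @export
run_recovery <- function(design, models = c("rg", "base"), n_reps = 10L,
                         seed = 1L,
                         chain = chain_config(store_deviance = FALSE),
                         priors = rtcdm_priors(), progress = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  models <- match.arg(models, c("rg", "base"), several.ok = TRUE)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  families <- c("g", "s", "beta", "kappa", "pi")
  per_rep <- list()
  per_item_err <- list()  # model -> family -> reps x J error matrix

  for (r in seq_len(n_reps)) {
    dat <- simulate_dataset(design, seed = rep_seeds[r])
    for (mod in models) {
      fit <- tryCatch(
        fit_rtcdm(dat, model = design$model, rg = (mod == "rg"),
                  priors = priors, chain = chain, seed = rep_seeds[r] %% 100000L + r),
        error = function(e) e)
      if (inherits(fit, "error")) {
        per_rep[[length(per_rep) + 1L]] <- data.frame(
          rep = r, model = mod, accuracy = NA_real_,
          pattern_accuracy = NA_real_, reliability = NA_real_,
          error = conditionMessage(fit))
        next
      }
      est <- coef(fit)
      alpha_hat <- classify_attributes(fit$alpha_prob)
      acc <- classification_accuracy(alpha_hat, dat$truth$alpha)
      pat <- mean(rowSums(alpha_hat != dat$truth$alpha) == 0L)
      rel <- reliability(fit$tau_mean, dat$truth$tau)
      per_rep[[length(per_rep) + 1L]] <- data.frame(
        rep = r, model = mod, accuracy = acc, pattern_accuracy = pat,
        reliability = rel, error = NA_character_)
      for (f in families) {
        if (is.null(est[[f]])) next
        truth_f <- switch(f, pi = dat$truth$pi_j, dat$truth[[f]])
        err <- est[[f]] - truth_f
        key <- paste(mod, f, sep = ".")
        per_item_err[[key]] <- rbind(per_item_err[[key]], err)
      }
    }
    if (progress) {
      message(sprintf("replication %d/%d done", r, n_reps))
    }
  }

  per_rep <- do.call(rbind, per_rep)
  summ <- list(); per_item <- list()
  for (key in names(per_item_err)) {
    err <- per_item_err[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    item_bias <- colMeans(err)
    item_rmse <- sqrt(colMeans(err^2))
    per_item[[length(per_item) + 1L]] <- data.frame(
      model = parts[1L], family = parts[2L],
      item = seq_along(item_bias), bias = item_bias, rmse = item_rmse)
    summ[[length(summ) + 1L]] <- data.frame(
      model = parts[1L], family = parts[2L],
      bias = mean(item_bias), rmse = mean(item_rmse))
  }
  person <- stats::aggregate(
    per_rep[, c("accuracy", "pattern_accuracy", "reliability")],
    by = list(model = per_rep$model), FUN = mean, na.rm = TRUE)

  structure(list(summary = do.call(rbind, summ),
                 person = person,
                 per_item = do.call(rbind, per_item),
                 per_rep = per_rep, n_reps = n_reps,
                 design = design),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: %d replications, %s design (I = %d)\n",
              x$n_reps, x$design$model, x$design$n_persons))
  cat("\nPerson-side metrics:\n")
  print(x$person, row.names = FALSE)
  cat("\nItem-parameter recovery (family means):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
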