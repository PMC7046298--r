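# S3 methods for the elongation_abc fit object.

#' @export
print.elongation_abc <- function(x, ...) {
  cat("Transcription elongation MCMC-ABC fit\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\n%d chain(s) x %d iterations (burn-in %.0f%%, thin %d): %d retained samples\n",
              x$chains, x$iterations, 100 * x$burnin, x$thin, nrow(x$trace)))
  cat(sprintf("epsilon = %g; overall acceptance %.1f%%\n",
              x$epsilon, 100 * x$acceptance_rate))
  cat("\nPosterior model probabilities:\n")
  print(round(x$model_probs, 3))
  invisible(x)
}

#' Point estimates from an MCMC-ABC fit
#'
#' Geometric-median point estimates of the active parameters, conditional on
#' the maximum a posteriori model (or a given model).
#'
#' @param object an `elongation_abc` fit.
#' @param model model index to condition on (default: highest posterior
#'   probability).
#' @param ... unused.
#' @return named numeric vector of active-parameter estimates; the model
#'   index is attached as attribute `"model"`.
#' @export
coef.elongation_abc <- function(object, model = NULL, ...) {
  probs <- object$model_probs
  if (is.null(model)) model <- as.integer(names(probs)[which.max(probs)])
  sub <- object$trace[object$trace$model == model, , drop = FALSE]
  if (!nrow(sub)) stop("no posterior samples for model ", model)
  act <- active_params(model)
  est <- geometric_median(as.matrix(sub[, act, drop = FALSE]))
  names(est) <- act
  attr(est, "model") <- model
  est
}

#' Posterior-predictive mean velocities
#'
#' @param object an `elongation_abc` fit.
#' @param newdata data frame with `force_pN` and `ntp_spec` (default: the
#'   fitted conditions).
#' @param n_draws posterior draws used.
#' @param type `"mean"` for the predictive mean per condition, `"draws"` for
#'   the full draw-level table.
#' @param seed seed for draw selection and simulation.
#' @param ... unused.
#' @return data frame (see `type`).
#' @export
predict.elongation_abc <- function(object, newdata = NULL, n_draws = 30L,
                                   type = c("mean", "draws"), seed = 1L, ...) {
  type <- match.arg(type)
  pp <- posterior_predictive(object, conditions = newdata, n_draws = n_draws,
                             seed = seed)
  if (type == "draws") return(pp)
  agg <- aggregate(velocity_bp_s ~ force_pN + ntp_spec, data = pp, FUN = mean)
  names(agg)[names(agg) == "velocity_bp_s"] <- "velocity_mean"
  sdv <- aggregate(velocity_bp_s ~ force_pN + ntp_spec, data = pp, FUN = sd)
  agg$velocity_sd <- sdv$velocity_bp_s
  agg
}

#' @export
residuals.elongation_abc <- function(object, n_draws = 30L, seed = 1L, ...) {
  pred <- predict(object, n_draws = n_draws, seed = seed)
  key <- paste(object$data$force_pN, object$data$ntp_spec)
  pkey <- paste(pred$force_pN, pred$ntp_spec)
  object$data$velocity_bp_s - pred$velocity_mean[match(key, pkey)]
}

#' Simulate datasets from the posterior
#'
#' Each simulation draws one chain state from the posterior trace and
#' generates a full synthetic dataset at the fitted conditions (posterior
#' predictive replicate datasets).
#'
#' @param object an `elongation_abc` fit.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` data frames shaped like the fitted dataset.
#' @export
simulate.elongation_abc <- function(object, nsim = 1L, seed = 1L, ...) {
  pp <- posterior_predictive(object, n_draws = nsim, seed = seed)
  lapply(split(pp, pp$draw), function(d) {
    data.frame(force_pN = d$force_pN, ntp_spec = d$ntp_spec,
               velocity_bp_s = d$velocity_bp_s, stringsAsFactors = FALSE)
  })
}

#' Plot observed and posterior-predictive velocities
#'
#' Velocity against applied force, one panel point-cloud per NTP condition:
#' open black circles are the observed mean velocities, coloured dots are
#' posterior-predictive simulations.
#'
#' @param x an `elongation_abc` fit.
#' @param n_draws posterior draws to overlay.
#' @param seed seed for the predictive draws.
#' @param ... passed to [plot()].
#' @return invisibly, the predictive draw table.
#' @export
plot.elongation_abc <- function(x, n_draws = 30L, seed = 1L, ...) {
  pp <- posterior_predictive(x, n_draws = n_draws, seed = seed)
  specs <- unique(x$data$ntp_spec)
  cols <- setNames(grDevices::hcl.colors(max(3L, length(specs)), "Dark 3")[seq_along(specs)],
                   specs)
  rng_y <- range(c(x$data$velocity_bp_s, pp$velocity_bp_s))
  plot(x$data$force_pN, x$data$velocity_bp_s, pch = 1, cex = 1.3,
       xlab = "applied force (pN)", ylab = "mean velocity (bp/s)",
       ylim = rng_y, ...)
  points(jitter(pp$force_pN, amount = 0.3), pp$velocity_bp_s, pch = 16,
         cex = 0.5, col = cols[pp$ntp_spec])
  points(x$data$force_pN, x$data$velocity_bp_s, pch = 1, cex = 1.3)
  legend("topleft", legend = c("observed", paste("[NTP]", specs)),
         pch = c(1, rep(16, length(specs))),
         col = c("black", cols), bty = "n", cex = 0.8)
  invisible(pp)
}
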