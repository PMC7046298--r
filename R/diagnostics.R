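# Convergence diagnostics and posterior summaries.

#' Effective sample size of an MCMC series
#'
#' Autocorrelation-time ESS: `n / (1 + 2 sum rho_k)` with the
#' autocorrelation sum truncated by the initial-positive-sequence rule (the
#' sum stops before the first pair `rho_{2k} + rho_{2k+1}` that is not
#' positive).
#'
#' @param x numeric series of length >= 10.
#' @return scalar ESS.
#' @examples
#' set.seed(1); effective_sample_size(rnorm(1000))
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10L) stop("series too short for an ESS estimate (need >= 10)")
  if (var(x) == 0) stop("ESS undefined for a constant series")
  rho <- as.numeric(acf(x, lag.max = n - 1L, plot = FALSE,
                        demean = TRUE)$acf)[-1L]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  n / (1 + 2 * s)
}

#' Potential scale reduction factor (R-hat)
#'
#' Classic Gelman-Rubin diagnostic across chains: the square root of the
#' weighted within- plus between-chain variance over the within-chain
#' variance.  Chains are truncated to a common length.
#'
#' @param chains list of (>= 2) numeric series.
#' @return scalar R-hat (about 1 at convergence).
#' @export
gelman_rhat <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("R-hat requires at least two chains")
  n <- min(lengths(chains))
  if (n < 2L) stop("chains too short for R-hat")
  xs <- vapply(chains, function(ch) ch[seq_len(n)], numeric(n))
  m <- ncol(xs)
  means <- colMeans(xs)
  W <- mean(apply(xs, 2L, var))
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Highest posterior density interval
#'
#' Narrowest contiguous interval containing at least `mass` of the samples
#' (`ceiling(mass * n)` order statistics).
#'
#' @param x numeric samples (length >= 20 recommended).
#' @param mass probability mass (default 0.95).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, mass = 0.95) {
  stopifnot(mass > 0, mass <= 1)
  xs <- sort(x)
  n <- length(xs)
  k <- min(n, ceiling(mass * n))
  if (k == n) return(c(lower = xs[1L], upper = xs[n]))
  widths <- xs[k:n] - xs[1:(n - k + 1L)]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + k - 1L])
}

#' Geometric median of multivariate samples
#'
#' The point minimising the summed Euclidean distances to the samples,
#' computed by iterative reweighting (Weiszfeld) to a relative tolerance of
#' 1e-8.  Dimensions are standardised by their median and MAD before
#' minimisation (the parameters carry mixed units) and the result is mapped
#' back.
#'
#' @param x numeric matrix (samples in rows) or vector (1-D: the coordinate
#'   median).
#' @param tol relative convergence tolerance.
#' @param standardize standardise dimensions first (default TRUE)?
#' @return numeric vector, one entry per column.
#' @export
geometric_median <- function(x, tol = 1e-8, standardize = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  if (nrow(x) == 1L) return(drop(x[1L, ]))
  if (ncol(x) == 1L) return(median(x[, 1L]))
  ctr <- apply(x, 2L, median)
  scl <- apply(x, 2L, mad)
  scl[scl == 0 | !is.finite(scl)] <- apply(x, 2L, sd)[scl == 0 | !is.finite(scl)]
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- if (standardize) sweep(sweep(x, 2L, ctr), 2L, scl, "/") else x
  m <- colMeans(z)
  for (iter in seq_len(1000L)) {
    d <- sqrt(rowSums(sweep(z, 2L, m)^2))
    at_point <- d < 1e-12
    if (any(at_point)) d[at_point] <- 1e-12
    w <- 1 / d
    m_new <- colSums(z * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) <= tol * (1 + sqrt(sum(m^2)))) {
      m <- m_new; break
    }
    m <- m_new
  }
  if (standardize) m * scl + ctr else m
}

#' Posterior summary of an MCMC-ABC fit
#'
#' Mirrors the standard report of this analysis: posterior model
#' probabilities, the 95% credible set of models, and, conditional on each
#' model in the credible set, per-parameter effective sample size, R-hat
#' across chains, 95% HPD interval and the geometric-median point estimate
#' (computed jointly over that model's active parameters).  Convergence
#' flags follow the usual rules (ESS > 100, R-hat < 1.1).
#'
#' @param object an `elongation_abc` fit.
#' @param mass credible-set mass (default 0.95).
#' @param ... unused.
#' @return object of class `summary.elongation_abc`: list with
#'   `model_probs`, `credible_set`, and `parameters` (data frame with one
#'   row per model x active parameter).
#' @export
summary.elongation_abc <- function(object, mass = 0.95, ...) {
  trace <- object$trace
  probs <- posterior_model_probabilities(trace)
  cs <- credible_set(probs, mass)
  space <- model_space()
  rows <- list()
  for (m in cs) {
    sub <- trace[trace$model == m, , drop = FALSE]
    act <- active_params(m, space)
    gm <- geometric_median(as.matrix(sub[, act, drop = FALSE]))
    names(gm) <- act
    for (p in act) {
      x <- sub[[p]]
      ess <- tryCatch(effective_sample_size(x), error = function(e) NA_real_)
      by_chain <- split(x, sub$chain)
      rh <- if (length(by_chain) >= 2L && min(lengths(by_chain)) >= 2L)
        tryCatch(gelman_rhat(by_chain), error = function(e) NA_real_)
      else NA_real_
      hpd <- hpd_interval(x, mass)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, parameter = p, n = length(x),
        estimate = gm[[p]], hpd_lower = hpd[["lower"]],
        hpd_upper = hpd[["upper"]], ess = ess, rhat = rh,
        converged = !is.na(ess) && ess > 100 &&
                    (is.na(rh) || rh < 1.1),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(model_probs = probs, credible_set = cs,
                 parameters = do.call(rbind, rows),
                 epsilon = object$epsilon,
                 acceptance_rate = object$acceptance_rate,
                 n_samples = nrow(trace), chains = object$chains),
            class = "summary.elongation_abc")
}

#' @export
print.summary.elongation_abc <- function(x, ...) {
  cat("MCMC-ABC posterior summary\n")
  cat(sprintf("  %d retained samples from %d chain(s); epsilon = %g; acceptance %.1f%%\n",
              x$n_samples, x$chains, x$epsilon, 100 * x$acceptance_rate))
  cat("\nPosterior model probabilities:\n")
  print(round(x$model_probs, 3))
  cat("\n95% credible set: model(s)", paste(x$credible_set, collapse = ", "),
      "\n\nConditional parameter summaries:\n")
  if (!is.null(x$parameters)) {
    df <- x$parameters
    df$estimate <- signif(df$estimate, 3)
    df$hpd_lower <- signif(df$hpd_lower, 3)
    df$hpd_upper <- signif(df$hpd_upper, 3)
    df$ess <- round(df$ess)
    df$rhat <- round(df$rhat, 3)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
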