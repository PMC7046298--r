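# Prior distributions for Bayesian inference, per enzyme profile.
#
# Rates and equilibrium constants carry lognormal priors (parameterised in
# log space); Gibbs energy terms carry normal priors; the transition-state
# displacement delta1 is uniform on (0, delta).  The model indicator prior
# gives translocation-equilibrium models (which never use delta1) twice the
# mass of the others.

#' Prior specification for an enzyme profile
#'
#' Default priors for the three polymerases studied with this model family.
#' `rnap` (E. coli RNAP) and `polII` (S. cerevisiae pol II) share a profile;
#' `t7` (bacteriophage T7 pol) differs in the catalysis rate, the
#' posttranslocated offset and the translocation barrier:
#'
#' * `k_cat`: Lognormal(3.454, 0.587) for RNAP/pol II (central 95% interval
#'   10-100 1/s); Lognormal(4.585, 0.457) for T7 (40-240 1/s).
#' * `K_D`: Lognormal(1.844, 1.762) (0.2-200 uM).
#' * `k_bind`: Lognormal(-1.498, 1.585) (0.01-5 1/uM/s).
#' * `dG_t1`: Normal(0, 1.55) kB*T for RNAP/pol II; Normal(-3.3, 1.55) for T7.
#' * `dG_tdag`: Normal(5.5, 0.97) kB*T for RNAP/pol II (99% interval 3-8);
#'   Normal(2.5, 1.36) for T7 (-1 to 6).
#' * `delta1`: Uniform(0, 3.4) Angstrom.
#'
#' The default ABC threshold `epsilon` shipped with each profile (2.39 RNAP,
#' 0.705 pol II, 4.63 T7) is tied to the distance definition used when those
#' values were calibrated and should be re-chosen for other datasets.
#'
#' @param enzyme `"rnap"`, `"polII"` or `"t7"`.
#' @return object of class `prior_spec`: per-parameter descriptors (each a
#'   list with `dist` in `lognormal`/`normal`/`uniform` and parameters
#'   `p1`, `p2`), `model_mass` (length-12 vector), `enzyme` and `epsilon`.
#' @examples
#' enzyme_priors("t7")$k_cat
#' @export
enzyme_priors <- function(enzyme = c("rnap", "polII", "t7")) {
  enzyme <- match.arg(enzyme)
  t7 <- enzyme == "t7"
  pr <- function(dist, p1, p2) list(dist = dist, p1 = p1, p2 = p2)
  masses <- model_space()$prior_mass
  structure(list(
    k_cat   = if (t7) pr("lognormal", 4.585, 0.457) else pr("lognormal", 3.454, 0.587),
    K_D     = pr("lognormal", 1.844, 1.762),
    k_bind  = pr("lognormal", -1.498, 1.585),
    dG_t1   = if (t7) pr("normal", -3.3, 1.55) else pr("normal", 0, 1.55),
    delta1  = pr("uniform", 0, 3.4),
    dG_tdag = if (t7) pr("normal", 2.5, 1.36) else pr("normal", 5.5, 0.97),
    model_mass = setNames(masses, as.character(model_space()$model)),
    enzyme = enzyme,
    epsilon = c(rnap = 2.39, polII = 0.705, t7 = 4.63)[[enzyme]]),
    class = "prior_spec")
}

#' Central prior interval
#'
#' Central interval of a parameter's prior: `exp(mu +/- z sigma)` for
#' lognormal, `mu +/- z sigma` for normal, the support for uniform.
#'
#' @param prior one per-parameter descriptor from [enzyme_priors()].
#' @param mass central probability mass (default 0.95).
#' @return length-2 numeric vector.
#' @export
prior_interval <- function(prior, mass = 0.95) {
  z <- stats::qnorm(1 - (1 - mass) / 2)
  switch(prior$dist,
         lognormal = exp(prior$p1 + c(-1, 1) * z * prior$p2),
         normal    = prior$p1 + c(-1, 1) * z * prior$p2,
         uniform   = c(prior$p1, prior$p2),
         stop("unknown prior distribution: ", prior$dist))
}

# Internal transformed-space representation: k_cat, K_D, k_bind are handled
# on the log scale (where their priors are normal); dG_t1, delta1, dG_tdag on
# the natural scale.

.log_scale <- c(k_cat = TRUE, K_D = TRUE, k_bind = TRUE,
                dG_t1 = FALSE, delta1 = FALSE, dG_tdag = FALSE)

to_internal <- function(theta) {
  theta <- unlist(theta)
  idx <- .log_scale[names(theta)]
  theta[idx] <- log(theta[idx])
  theta
}

from_internal <- function(phi) {
  phi <- unlist(phi)
  idx <- .log_scale[names(phi)]
  phi[idx] <- exp(phi[idx])
  phi
}

prior_sample_one <- function(prior, n = 1L) {
  # returns values on the INTERNAL scale
  switch(prior$dist,
         lognormal = rnorm(n, prior$p1, prior$p2),
         normal    = rnorm(n, prior$p1, prior$p2),
         uniform   = runif(n, prior$p1, prior$p2))
}

prior_logdens_one <- function(prior, phi) {
  # density on the INTERNAL scale (lognormal variates are normal in log space)
  switch(prior$dist,
         lognormal = dnorm(phi, prior$p1, prior$p2, log = TRUE),
         normal    = dnorm(phi, prior$p1, prior$p2, log = TRUE),
         uniform   = dunif(phi, prior$p1, prior$p2, log = TRUE))
}

prior_sd_internal <- function(prior) {
  switch(prior$dist,
         lognormal = prior$p2,
         normal    = prior$p2,
         uniform   = (prior$p2 - prior$p1) / sqrt(12))
}

sample_prior_params <- function(priors) {
  phi <- vapply(.param_names, function(p) prior_sample_one(priors[[p]]),
                numeric(1))
  from_internal(setNames(phi, .param_names))
}
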