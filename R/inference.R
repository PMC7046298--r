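# MCMC-ABC inference of the model indicator and kinetic parameters from
# force-velocity-[NTP] data.
#
# Marjoram-style ABC-MCMC: a proposal (single-component random walk on one
# active parameter, or a model jump) is accepted only if the chi-squared
# distance between freshly simulated and observed velocities is at or below
# the threshold epsilon AND the Metropolis-Hastings ratio on the prior and
# proposal densities accepts.  The distance is recomputed from new
# simulations at every proposal; the stored distance of the current state is
# never refreshed (noisy ABC-MCMC).

#' Chi-squared distance between simulated and observed velocities
#'
#' Pearson-type discrepancy `X^2 = sum_i (v_sim,i - v_obs,i)^2 / v_obs,i`
#' over the rows of the observed dataset.
#'
#' @param simulated numeric vector of simulated mean velocities, one per
#'   observed row (same order).
#' @param observed numeric vector of observed mean velocities, or a
#'   `velocity_data` data frame with a `velocity_bp_s` column.
#' @return non-negative scalar distance.
#' @examples
#' abc_distance(12, 10)   # 0.4
#' @export
abc_distance <- function(simulated, observed) {
  if (is.data.frame(observed)) observed <- observed$velocity_bp_s
  if (length(simulated) != length(observed))
    stop("simulated and observed velocity vectors differ in length")
  stopifnot(all(observed > 0))
  sum((simulated - observed)^2 / observed)
}

# inclusive threshold rule + MH test, isolated for testability
accept_state <- function(x2, epsilon, log_mh, log_u) {
  is.finite(x2) && x2 <= epsilon && log_u < min(0, log_mh)
}

# observed dataset -> list of per-row (condition, concentration vector)
prepare_rows <- function(data, landscape) {
  lapply(seq_len(nrow(data)), function(i) {
    cond <- tec_condition(force = data$force_pN[i],
                          ntp = parse_ntp_spec(data$ntp_spec[i]))
    list(cond = cond, v_obs = data$velocity_bp_s[i])
  })
}

simulate_dataset_x2 <- function(rows, landscape, model, params, c) {
  v <- vapply(rows, function(r) {
    tryCatch(
      estimate_mean_velocity(landscape, model, params, r$cond, c = c),
      error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(v)) return(Inf)   # simulator failure => proposal rejected
  abc_distance(v, vapply(rows, `[[`, numeric(1), "v_obs"))
}

#' Fit transcription elongation models by MCMC-ABC
#'
#' Jointly samples the model indicator and the kinetic/thermodynamic
#' parameters of the Brownian-ratchet elongation model family from their
#' posterior given observed mean pause-free velocities, using approximate
#' Bayesian computation: each proposal is evaluated by Gillespie-simulating
#' every observed condition on the template (`replicates` transcriptions
#' each) and is accepted only if the chi-squared discrepancy
#' [abc_distance()] is at or below `epsilon` and the Metropolis-Hastings
#' ratio accepts.  The model indicator is treated identically to the
#' continuous parameters: all six parameters are always carried in the chain
#' state, model jumps draw newly activated parameters from their priors, and
#' parameters outside the current model's active set are held at their
#' reference constants when simulating.
#'
#' @param data observed dataset: data frame with columns `force_pN`,
#'   `ntp_spec` (scalar uM or `"A=..;C=..;G=..;U=.."`) and `velocity_bp_s`
#'   (positive), e.g. from [generate_dataset()] or [read_velocity_data()].
#' @param sequence template as a [tec_template()] or precomputed
#'   [energy_landscape()].
#' @param enzyme prior profile: `"rnap"`, `"polII"` or `"t7"`.
#' @param models integer vector of admissible model indices (subset of 1-12).
#' @param epsilon ABC acceptance threshold on the chi-squared distance
#'   (inclusive).  Default: the enzyme profile's shipped threshold.
#' @param chains number of independent chains.
#' @param iterations chain length (states per chain, before burn-in/thinning).
#' @param replicates Gillespie replicates per condition per proposal.
#' @param seed root seed; chain seeds are derived deterministically.
#' @param priors a [enzyme_priors()] object (overrides `enzyme`).
#' @param proposal_scale random-walk standard deviation as a fraction of each
#'   prior's (internal-scale) standard deviation.
#' @param p_model probability that a proposal is a model jump rather than a
#'   parameter perturbation (ignored when only one model is admissible).
#' @param burnin fraction of each chain discarded as burn-in.
#' @param thin keep every `thin`-th state; default aims at ~2000 retained
#'   states per chain (at least 1).
#' @param simulate logical; `FALSE` bypasses the simulator entirely (every
#'   proposal has distance 0), so the chain samples the prior.  Used for
#'   prior-recovery checks.
#' @param init_draws prior draws scored to choose each chain's starting
#'   state.
#' @param max_events per-simulation event cap.
#' @param progress print a line per chain?
#' @return object of class `elongation_abc`: list with `trace` (post burn-in,
#'   thinned data frame: `chain`, `iteration`, `model`, the six parameters,
#'   `X2`), `model_probs`, `acceptance_rate`, `priors`, `epsilon`, `models`,
#'   `data`, `landscape`, `replicates`, `seed`, `call`.  Methods: `print`,
#'   `summary`, `coef`, `predict`, `plot`, `simulate`, `residuals`.
#' @seealso [posterior_model_probabilities()], [credible_set()],
#'   [posterior_predictive()], [summary.elongation_abc()]
#' @export
elongation_abc <- function(data, sequence, enzyme = c("rnap", "polII", "t7"),
                           models = 1:12, epsilon = NULL, chains = 2L,
                           iterations = 2000L, replicates = 2L, seed = 1L,
                           priors = NULL, proposal_scale = 0.5,
                           p_model = 0.25, burnin = 0.1, thin = NULL,
                           simulate = TRUE, init_draws = 100L,
                           max_events = 1e7, progress = FALSE) {
  cl <- match.call()
  if (is.null(priors)) priors <- enzyme_priors(match.arg(enzyme))
  models <- as.integer(models)
  stopifnot(all(models %in% 1:12), length(models) >= 1L,
            chains >= 1L, iterations >= 1L, replicates >= 1L,
            burnin >= 0, burnin < 1)
  if (is.null(epsilon)) epsilon <- priors$epsilon
  stopifnot(epsilon > 0)
  if (!all(c("force_pN", "ntp_spec", "velocity_bp_s") %in% names(data)))
    stop("data must have columns force_pN, ntp_spec, velocity_bp_s")
  if (any(data$velocity_bp_s <= 0)) stop("observed velocities must be > 0")
  landscape <- if (inherits(sequence, "energy_landscape")) sequence
               else energy_landscape(as_template(sequence))
  rows <- prepare_rows(data, landscape)
  space <- model_space()
  mass <- priors$model_mass[as.character(models)]
  mass <- mass / sum(mass)
  if (is.null(thin)) thin <- max(1L, as.integer(floor(iterations / 2000)))

  traces <- vector("list", chains)
  acc_n <- 0L; prop_n <- 0L
  for (ch in seq_len(chains)) {
    res <- run_one_chain(chain_id = ch, seed = derive_seed(seed, ch),
                         rows = rows, landscape = landscape, space = space,
                         models = models, mass = mass, priors = priors,
                         epsilon = epsilon, iterations = iterations,
                         replicates = replicates,
                         proposal_scale = proposal_scale, p_model = p_model,
                         simulate = simulate, init_draws = init_draws,
                         max_events = max_events)
    traces[[ch]] <- res$trace
    acc_n <- acc_n + res$accepted; prop_n <- prop_n + res$proposed
    if (progress)
      message(sprintf("chain %d/%d: acceptance %.1f%%", ch, chains,
                      100 * res$accepted / res$proposed))
  }
  full <- do.call(rbind, traces)
  keep <- full$iteration > burnin * iterations &
          (full$iteration %% thin == 0L)
  trace <- full[keep, , drop = FALSE]
  rownames(trace) <- NULL
  out <- structure(list(
    trace = trace, model_probs = posterior_model_probabilities(trace),
    acceptance_rate = acc_n / prop_n,
    priors = priors, epsilon = epsilon, models = models,
    data = data, landscape = landscape, replicates = replicates,
    burnin = burnin, thin = thin, iterations = iterations,
    chains = chains, seed = seed, simulate = simulate, call = cl),
    class = "elongation_abc")
  out
}

run_one_chain <- function(chain_id, seed, rows, landscape, space, models,
                          mass, priors, epsilon, iterations, replicates,
                          proposal_scale, p_model, simulate, init_draws,
                          max_events) {
  set.seed(seed)
  n_par <- length(.param_names)
  prop_sd <- vapply(.param_names,
                    function(p) proposal_scale * prior_sd_internal(priors[[p]]),
                    numeric(1))
  x2_of <- function(model, params) {
    if (!simulate) return(0)
    simulate_dataset_x2(rows, landscape, model,
                        structure(as.list(params), class = "parameter_set"),
                        replicates)
  }
  draw_model <- function() models[sample.int(length(models), 1L, prob = mass)]
  # initial state: best of init_draws prior draws
  best <- NULL
  for (i in seq_len(max(1L, init_draws))) {
    m <- draw_model()
    th <- sample_prior_params(priors)
    x2 <- x2_of(m, th)
    if (is.null(best) || x2 < best$x2) best <- list(model = m, theta = th, x2 = x2)
  }
  cur <- best
  # threshold annealing during burn-in: start from the initial distance and
  # tighten linearly to epsilon over the first 10% of the chain (states from
  # that phase are discarded as burn-in anyway)
  anneal_len <- max(1L, as.integer(0.1 * iterations))
  eps_path <- function(it) {
    if (it >= anneal_len || cur0_x2 <= epsilon) return(epsilon)
    cur0_x2 + (epsilon - cur0_x2) * it / anneal_len
  }
  cur0_x2 <- max(cur$x2, epsilon)

  model_rec <- integer(iterations)
  x2_rec <- numeric(iterations)
  par_rec <- matrix(NA_real_, nrow = iterations, ncol = length(.param_names),
                    dimnames = list(NULL, .param_names))
  accepted <- 0L
  logdens_active <- function(model, theta) {
    act <- active_params(model, space)
    phi <- to_internal(theta)
    sum(vapply(act, function(p) prior_logdens_one(priors[[p]], phi[[p]]),
               numeric(1)))
  }
  for (it in seq_len(iterations)) {
    eps_t <- eps_path(it)
    do_model_move <- length(models) > 1L && runif(1) < p_model
    if (do_model_move) {
      others <- setdiff(models, cur$model)
      m_new <- others[sample.int(length(others), 1L)]
      th_new <- cur$theta
      newly <- setdiff(active_params(m_new, space),
                       active_params(cur$model, space))
      for (p in newly) {
        phi <- prior_sample_one(priors[[p]])
        th_new[[p]] <- if (.log_scale[[p]]) exp(phi) else phi
      }
      # uniform jump among admissible models, birth values from the prior:
      # proposal terms for newly activated / deactivated parameters cancel
      # against their prior factors, leaving the model-prior ratio
      log_mh <- log(mass[[as.character(m_new)]]) -
                log(mass[[as.character(cur$model)]])
    } else {
      m_new <- cur$model
      act <- active_params(cur$model, space)
      p <- if (length(act) == 1L) act else sample(act, 1L)
      phi <- to_internal(cur$theta)
      phi[[p]] <- phi[[p]] + rnorm(1, 0, prop_sd[[p]])
      if (p == "delta1") {   # reflect at the uniform support bounds
        lo <- priors$delta1$p1; hi <- priors$delta1$p2
        w <- hi - lo
        y <- (phi[[p]] - lo) %% (2 * w)
        phi[[p]] <- lo + ifelse(y > w, 2 * w - y, y)
      }
      th_new <- from_internal(phi)
      log_mh <- logdens_active(m_new, th_new) -
                logdens_active(cur$model, cur$theta)
    }
    prop_ok <- !is.na(log_mh) && log_mh > -Inf
    x2_new <- if (prop_ok) x2_of(m_new, th_new) else Inf
    if (accept_state(x2_new, eps_t, log_mh, log(runif(1)))) {
      cur <- list(model = m_new, theta = th_new, x2 = x2_new)
      accepted <- accepted + 1L
    }
    model_rec[it] <- cur$model
    par_rec[it, ] <- cur$theta[.param_names]
    x2_rec[it] <- cur$x2
  }
  trace <- data.frame(chain = chain_id, iteration = seq_len(iterations),
                      model = model_rec, par_rec, X2 = x2_rec)
  list(trace = trace, accepted = accepted, proposed = iterations)
}

#' Posterior model probabilities
#'
#' Relative frequencies of the model indicator in the (combined,
#' post-burn-in) trace.
#'
#' @param trace a trace data frame with a `model` column, or an
#'   `elongation_abc` fit.
#' @return named numeric vector summing to 1, ordered by model index.
#' @export
posterior_model_probabilities <- function(trace) {
  if (inherits(trace, "elongation_abc")) trace <- trace$trace
  if (!nrow(trace)) stop("empty posterior trace")
  tab <- table(factor(trace$model, levels = sort(unique(trace$model))))
  p <- as.numeric(tab) / sum(tab)
  setNames(p, names(tab))
}

#' Credible set of models
#'
#' Smallest set of models, taken in order of decreasing posterior
#' probability, whose cumulative probability reaches `mass`.
#'
#' @param x model probabilities (named vector), a trace data frame, or an
#'   `elongation_abc` fit.
#' @param mass target cumulative probability (default 0.95).
#' @return integer vector of model indices.
#' @export
credible_set <- function(x, mass = 0.95) {
  probs <- if (is.numeric(x) && !is.null(names(x))) x
           else posterior_model_probabilities(x)
  o <- order(probs, decreasing = TRUE)
  k <- which(cumsum(probs[o]) >= mass - 1e-12)[1L]
  sort(as.integer(names(probs)[o[seq_len(k)]]))
}

#' Posterior-predictive velocity simulation
#'
#' Draws chain states uniformly from the posterior trace and Gillespie-
#' simulates every requested condition under each draw, giving the posterior
#' predictive distribution of mean velocities.
#'
#' @param object an `elongation_abc` fit.
#' @param conditions data frame with `force_pN` and `ntp_spec` (default: the
#'   fitted dataset's conditions).
#' @param n_draws number of posterior draws (default 30).
#' @param seed integer seed.
#' @param replicates Gillespie replicates per condition (default: as fitted).
#' @return data frame with columns `draw`, `model`, `force_pN`, `ntp_spec`,
#'   `velocity_bp_s`.
#' @export
posterior_predictive <- function(object, conditions = NULL, n_draws = 30L,
                                 seed = 1L, replicates = NULL) {
  stopifnot(inherits(object, "elongation_abc"))
  trace <- object$trace
  if (!nrow(trace)) stop("empty posterior trace")
  if (is.null(conditions)) conditions <- object$data
  if (is.null(replicates)) replicates <- object$replicates
  set.seed(seed)
  picks <- sample.int(nrow(trace), n_draws, replace = TRUE)
  out <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    st <- trace[picks[d], ]
    params <- structure(as.list(st[.param_names]), class = "parameter_set")
    v <- vapply(seq_len(nrow(conditions)), function(i) {
      cond <- tec_condition(force = conditions$force_pN[i],
                            ntp = parse_ntp_spec(conditions$ntp_spec[i]))
      estimate_mean_velocity(object$landscape, st$model, params, cond,
                             c = replicates)
    }, numeric(1))
    out[[d]] <- data.frame(draw = d, model = st$model,
                           force_pN = conditions$force_pN,
                           ntp_spec = conditions$ntp_spec,
                           velocity_bp_s = v, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
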