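# Gillespie simulation of full-template transcription and the
# master-equation (mean first-passage time) velocity oracle.

derive_seed <- function(root, index) {
  # deterministic per-replicate stream; keep below 2^31 - 1
  as.integer((as.double(root) * 48271 + as.double(index) * 1299709) %% 2147483647)
}

#' Simulate one transcription of the template
#'
#' Exact (Gillespie) stochastic simulation of the elongation pathway from the
#' initial state `S(l0, 0)` to completion at `S(L, 0)`, under the partial
#' equilibrium approximations of the chosen model (coalesced states carry
#' occupancy-weighted outbound rates).  Waiting times are exponential in the
#' total propensity and reactions are selected proportionally to their rates.
#' Deterministic given `seed`.
#'
#' @param sequence a [tec_template()] or an [energy_landscape()] (passing a
#'   precomputed landscape avoids recomputing the energetics).
#' @param model model index 1-12 (see [model_space()]).
#' @param params a [parameter_set()].
#' @param cond a [tec_condition()].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param max_events safety cap on the number of reaction events.
#' @param trajectory record the event trajectory (time, l, t)?
#' @return object of class `sim_result`: list with `nucleotides_added`,
#'   `elapsed_time` (s), `mean_velocity` (bp/s; `NaN` on a degenerate
#'   template with `L = l0`), `events`, `seed`, and optionally `trajectory`.
#' @examples
#' tpl <- random_template(100, seed = 1)
#' simulate_transcription(tpl, model = 1, parameter_set(), tec_condition(),
#'                        seed = 42)
#' @export
simulate_transcription <- function(sequence, model, params, cond,
                                   seed = NULL, max_events = 1e8,
                                   trajectory = FALSE) {
  landscape <- if (inherits(sequence, "energy_landscape")) sequence
               else energy_landscape(as_template(sequence))
  sr <- site_rates(model, params, cond, landscape)
  if (!is.null(seed)) set.seed(seed)
  if (sr$n == 0L) {
    return(structure(list(nucleotides_added = 0L, elapsed_time = 0,
                          mean_velocity = NaN, events = 0, seed = seed),
                     class = "sim_result"))
  }
  res <- run_gillespie(sr, landscape$geometry$l0, max_events, trajectory)
  out <- list(nucleotides_added = sr$n, elapsed_time = res$time,
              mean_velocity = sr$n / res$time, events = res$events,
              seed = seed)
  if (trajectory) out$trajectory <- res$trajectory
  structure(out, class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", x$nucleotides_added, " nt in ",
      signif(x$elapsed_time, 4), " s  (", signif(x$mean_velocity, 4),
      " bp/s, ", x$events, " events)\n", sep = "")
  invisible(x)
}

#' Mean elongation velocity across replicate simulations
#'
#' Runs `c` independent Gillespie transcriptions of the full template and
#' returns the arithmetic mean of the per-replicate mean velocities
#' (each replicate's velocity is its nucleotides added divided by its elapsed
#' time; the estimator is the mean of those means, not total distance over
#' total time).  Replicate seeds are derived deterministically from `seed`,
#' so the result is independent of execution order.
#'
#' @inheritParams simulate_transcription
#' @param c number of replicate simulations (>= 1).
#' @param details return per-replicate velocities as an attribute?
#' @return mean velocity (bp/s); with `details = TRUE`, attribute
#'   `"replicates"` holds the per-replicate velocities.
#' @export
estimate_mean_velocity <- function(sequence, model, params, cond, c = 1L,
                                   seed = NULL, max_events = 1e8,
                                   details = FALSE) {
  stopifnot(c >= 1L)
  landscape <- if (inherits(sequence, "energy_landscape")) sequence
               else energy_landscape(as_template(sequence))
  sr <- site_rates(model, params, cond, landscape)   # shared across replicates
  l0 <- landscape$geometry$l0
  v <- vapply(seq_len(c), function(i) {
    if (!is.null(seed)) set.seed(derive_seed(seed, i))
    if (sr$n == 0L) return(NaN)
    res <- run_gillespie(sr, l0, max_events, FALSE)
    sr$n / res$time
  }, numeric(1))
  out <- mean(v)
  if (details) attr(out, "replicates") <- v
  out
}

# low-level dispatch into the C++ kernel; raises on stall / event cap
run_gillespie <- function(sr, l0, max_events, trajectory) {
  res <- gillespie_core(sr$variant,
                        r0   = sr$r0    %||% numeric(0),
                        kf   = sr$k_fwd %||% numeric(0),
                        kb   = sr$k_bck %||% numeric(0),
                        bind = sr$bind  %||% numeric(0),
                        rb   = sr$r_bck %||% numeric(0),
                        rc   = sr$r_cat %||% numeric(0),
                        k_rel = sr$k_rel, k_cat = sr$k_cat,
                        max_events = max_events,
                        keep_trajectory = trajectory, l0 = l0)
  if (res$stalled)
    stop("stalled simulation: a state with zero total propensity was reached ",
         "before the template was copied (is an NTP concentration zero?)")
  if (res$capped)
    stop("simulation exceeded max_events = ", format(max_events))
  res
}

#' Master-equation velocity on a template
#'
#' Exact expected velocity of the elongation pathway, used as an independent
#' oracle for the stochastic simulator.  Two estimands are available:
#'
#' * `"first_passage"` (default): `(L - l0) / E[T]`, where the expected
#'   completion time `E[T]` is the sum over sites of the closed-form mean
#'   first-passage time from the (coalesced) pretranslocated state at site
#'   `l` to that at `l + 1`.
#' * `"replicate_mean"`: `(L - l0) * E[1/T]`, the expectation of the
#'   per-replicate mean velocity that [estimate_mean_velocity()] reports.
#'   On short templates this exceeds the first-passage velocity (Jensen's
#'   inequality; the gap shrinks like 1/L).  It is evaluated exactly from
#'   the per-site phase-type Laplace transforms via
#'   `E[1/T] = integral_0^inf prod_l L_l(s) ds`.
#'
#' Both are computed from the same per-site propensities the simulator uses,
#' but through independent mathematics (no sampling).  Intended for short
#' templates.
#'
#' @inheritParams simulate_transcription
#' @param estimator which expectation to return (see above).
#' @return expected velocity (bp/s).
#' @examples
#' tpl <- random_template(100, seed = 1)
#' master_equation_velocity(tpl, model = 1, parameter_set(), tec_condition())
#' @export
master_equation_velocity <- function(sequence, model, params, cond,
                                     estimator = c("first_passage",
                                                   "replicate_mean")) {
  estimator <- match.arg(estimator)
  landscape <- if (inherits(sequence, "energy_landscape")) sequence
               else energy_landscape(as_template(sequence))
  sr <- site_rates(model, params, cond, landscape)
  if (sr$n == 0L) return(NaN)
  tt <- site_passage_times(sr)
  if (any(!is.finite(tt)))
    stop("infinite expected passage time (zero propensity at some site)")
  if (estimator == "first_passage") return(sr$n / sum(tt))
  sr$n * expected_inverse_time(sr)
}

# log Laplace transform of the site-passage-time distribution at s >= 0,
# vectorised over sites; each site is a small phase-type distribution
site_log_laplace <- function(sr, s) {
  geometric_cycle <- function(lA, q) {
    # passage = geometric number of cycles with per-cycle LT exp(lA) and
    # success probability q:  L = q A / (1 - (1-q) A)
    log(q) + lA - log1p(-(1 - q) * exp(lA))
  }
  switch(as.character(sr$variant),
    "0" = log(sr$r0) - log(sr$r0 + s),
    "1" = {
      rk <- sr$k_rel + sr$k_cat
      lA <- log(sr$bind) - log(sr$bind + s) + log(rk) - log(rk + s)
      geometric_cycle(lA, sr$k_cat / rk)
    },
    "2" = {
      tot <- sr$r_bck + sr$r_cat
      lA <- log(sr$k_fwd) - log(sr$k_fwd + s) + log(tot) - log(tot + s)
      geometric_cycle(lA, sr$r_cat / tot)
    },
    "3" = {
      # absorption from pre through {pre, post, bound} with catalysis exit:
      # L(s) = e1' (sI - Q)^{-1} a, solved per site (3 x 3)
      vapply(seq_len(sr$n), function(i) {
        a <- sr$k_fwd[i]; b <- sr$k_bck[i]; cc <- sr$bind[i]
        r <- sr$k_rel; k <- sr$k_cat
        Q <- rbind(c(-a, a, 0), c(b, -(b + cc), cc), c(0, r, -(r + k)))
        x <- solve(diag(3) * s - Q, c(0, 0, k))
        log(x[1L])
      }, numeric(1))
    })
}

# E[1/T] where T is the independent sum of the per-site passage times:
# E[1/T] = integral_0^Inf E[exp(-sT)] ds = integral prod_l L_l(s) ds
expected_inverse_time <- function(sr) {
  f <- function(s) {
    vapply(s, function(si) exp(sum(site_log_laplace(sr, si))), numeric(1))
  }
  ET <- sum(site_passage_times(sr))      # sets the decay scale of the MGF
  # substitute s = u / E[T] so the integrand is approximately exp(-u)
  g <- function(u) f(u / ET) / ET
  stats::integrate(g, 0, Inf, rel.tol = 1e-9, abs.tol = 0,
                   subdivisions = 400L)$value
}

# mean first-passage times per site, by variant (closed forms)
site_passage_times <- function(sr) {
  switch(as.character(sr$variant),
    "0" = 1 / sr$r0,
    "1" = (sr$k_rel + sr$k_cat + sr$bind) / (sr$bind * sr$k_cat),
    "2" = (sr$k_fwd + sr$r_bck + sr$r_cat) / (sr$k_fwd * sr$r_cat),
    "3" = 1 / sr$k_fwd + 1 / sr$k_cat +
          (sr$k_rel + sr$k_cat) / (sr$bind * sr$k_cat) *
            (1 + sr$k_bck / sr$k_fwd))
}
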