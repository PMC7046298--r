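# The 12-model space and all reaction propensities.
#
# Every model shares the same three-step nucleotide addition cycle
# (translocation, NTP binding, catalysis); models differ in whether
# translocation and/or NTP binding are treated as partial equilibria, and in
# whether the posttranslocated-state offset dG_t1 and the transition-state
# displacement delta1 are estimated or held at their reference constants
# (0 kBT and delta/2 respectively).

.param_names <- c("k_cat", "K_D", "k_bind", "dG_t1", "delta1", "dG_tdag")

#' Kinetic/thermodynamic parameter set
#'
#' The six parameters of the fully kinetic elongation model.  Simpler models
#' use subsets; inactive entries are carried at their reference values.
#' The NTP release rate is implied, `k_rel = K_D * k_bind`, and never stored.
#'
#' @param k_cat catalysis rate (1/s).
#' @param K_D NTP dissociation constant `k_rel / k_bind` (uM).
#' @param k_bind NTP binding rate (1/uM/s).
#' @param dG_t1 posttranslocated-state energy offset (kB*T); reference 0.
#' @param delta1 displacement to the translocation transition state
#'   (Angstrom), in `(0, delta)`; reference `delta / 2`.
#' @param dG_tdag sequence-independent translocation barrier baseline (kB*T),
#'   interpretable only jointly with the pre-exponential factor.
#' @param delta basepair rise (Angstrom), used only to default `delta1`.
#' @return a named list of class `parameter_set`.
#' @examples
#' parameter_set(k_cat = 24.7, K_D = 15.6)
#' @export
parameter_set <- function(k_cat = 30, K_D = 20, k_bind = 0.25,
                          dG_t1 = 0, delta1 = delta / 2, dG_tdag = 5.5,
                          delta = 3.4) {
  stopifnot(k_cat > 0, K_D > 0, k_bind > 0, delta1 > 0, delta1 < delta)
  structure(list(k_cat = k_cat, K_D = K_D, k_bind = k_bind, dG_t1 = dG_t1,
                 delta1 = delta1, dG_tdag = dG_tdag),
            class = "parameter_set")
}

#' The hierarchical space of 12 elongation models
#'
#' Enumerates the model family: translocation equilibrium or kinetic, NTP
#' binding equilibrium or kinetic, and, where meaningful, whether `dG_t1` and
#' `delta1` are estimated.  Translocation-equilibrium models never use
#' `delta1` or `dG_tdag`.  Models 1, 2, 4, 5, 11 and 12 are pinned by the
#' model descriptions (1: both equilibria, two parameters; 2: + kinetic
#' binding; 4: both equilibria + `dG_t1`; 5: translocation equilibrium,
#' kinetic binding, `dG_t1`; 11: binding equilibrium, kinetic translocation,
#' `dG_t1`, `delta1`; 12: all six); 3 is the three-parameter
#' kinetic-translocation base and 8 its `dG_t1` extension; the remaining
#' indices follow the canonical assignment 6 = `{delta1}`, 7 = `{k_bind}`,
#' 9 = `{k_bind, dG_t1}`, 10 = `{k_bind, delta1}` (additions on top of
#' model 3).
#'
#' @return data frame with one row per model: `model`, `transl_eq`,
#'   `bind_eq`, `uses_dG_t1`, `uses_delta1`, `k` (number of estimated
#'   parameters), `params` (comma-separated active parameters) and
#'   `prior_mass` (2/16 for translocation-equilibrium models, 1/16 else).
#' @examples
#' model_space()
#' @export
model_space <- function() {
  if (!is.null(.ratchet_env$model_space)) return(.ratchet_env$model_space)
  def <- list(
    #          transl_eq bind_eq dG_t1 delta1
    `1`  = c(TRUE,  TRUE,  FALSE, FALSE),
    `2`  = c(TRUE,  FALSE, FALSE, FALSE),
    `3`  = c(FALSE, TRUE,  FALSE, FALSE),
    `4`  = c(TRUE,  TRUE,  TRUE,  FALSE),
    `5`  = c(TRUE,  FALSE, TRUE,  FALSE),
    `6`  = c(FALSE, TRUE,  FALSE, TRUE),
    `7`  = c(FALSE, FALSE, FALSE, FALSE),
    `8`  = c(FALSE, TRUE,  TRUE,  FALSE),
    `9`  = c(FALSE, FALSE, TRUE,  FALSE),
    `10` = c(FALSE, FALSE, FALSE, TRUE),
    `11` = c(FALSE, TRUE,  TRUE,  TRUE),
    `12` = c(FALSE, FALSE, TRUE,  TRUE))
  m <- do.call(rbind, def)
  transl_eq <- m[, 1]; bind_eq <- m[, 2]
  uses_dG_t1 <- m[, 3]; uses_delta1 <- m[, 4]
  act <- lapply(seq_len(12L), function(i) {
    p <- c("k_cat", "K_D")
    if (!bind_eq[i]) p <- c(p, "k_bind")
    if (uses_dG_t1[i]) p <- c(p, "dG_t1")
    if (uses_delta1[i]) p <- c(p, "delta1")
    if (!transl_eq[i]) p <- c(p, "dG_tdag")
    p
  })
  out <- data.frame(model = seq_len(12L), transl_eq = transl_eq,
                    bind_eq = bind_eq,
                    uses_dG_t1 = uses_dG_t1, uses_delta1 = uses_delta1,
                    k = lengths(act),
                    params = vapply(act, paste, "", collapse = ","),
                    prior_mass = ifelse(transl_eq, 2 / 16, 1 / 16),
                    row.names = NULL)
  .ratchet_env$model_space <- out
  out
}

active_params <- function(model, space = model_space()) {
  strsplit(space$params[space$model == model], ",", fixed = TRUE)[[1L]]
}

#' Single-parameter-augmentation network over the model space
#'
#' Two models are neighbours if one is obtained from the other by activating
#' exactly one additional parameter.  The network is validated: every edge
#' must differ by exactly one parameter, the adjacency is symmetric and has
#' no self-edges.
#'
#' @param space the model space data frame (default [model_space()]).
#' @return a named list mapping each model index to the integer vector of its
#'   neighbours.
#' @examples
#' model_network()[["12"]]   # the three 5-parameter models
#' @export
model_network <- function(space = model_space()) {
  sets <- lapply(space$model, active_params, space = space)
  n <- nrow(space)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (j in seq_len(n)) {
      if (i == j) next
      d <- length(union(sets[[i]], sets[[j]])) - length(intersect(sets[[i]], sets[[j]]))
      if (d == 1L) nb <- c(nb, space$model[j])
    }
    adj[[i]] <- nb
  }
  names(adj) <- as.character(space$model)
  # validation: symmetry, no self edges
  for (i in seq_len(n)) {
    if (space$model[i] %in% adj[[i]]) stop("model network has a self-edge")
    for (j in adj[[i]]) {
      if (!(space$model[i] %in% adj[[as.character(j)]]))
        stop("model network adjacency is not symmetric")
    }
  }
  adj
}

#' Experimental condition
#'
#' Applied force and NTP concentrations under which elongation proceeds.
#' Assisting loads are positive, hindering loads negative.  A scalar NTP
#' concentration is broadcast to all four nucleotides.
#'
#' @param force applied force (pN); assisting > 0.
#' @param ntp either a single concentration (uM) broadcast to A, C, G, U, or
#'   a named vector/list with entries `A`, `C`, `G`, `U`.
#' @param temperature absolute temperature (K); fixed at 310 in this model.
#' @param prefactor pre-exponential factor A of the translocation rates
#'   (1/s); held constant at 1e6.
#' @return a list of class `tec_condition` with `force`, `ntp` (named length-4
#'   vector), `temperature`, `prefactor`.
#' @examples
#' tec_condition(force = 7, ntp = c(A = 5, C = 2.5, G = 10, U = 10))
#' @export
tec_condition <- function(force = 0, ntp = 1000, temperature = 310,
                          prefactor = 1e6) {
  ntp <- unlist(ntp)
  if (length(ntp) == 1L && is.null(names(ntp))) {
    ntp <- setNames(rep(as.numeric(ntp), 4L), c("A", "C", "G", "U"))
  } else {
    if (!all(c("A", "C", "G", "U") %in% names(ntp)))
      stop("per-base NTP concentrations must name A, C, G and U")
    ntp <- ntp[c("A", "C", "G", "U")]
  }
  stopifnot(all(is.finite(ntp)), all(ntp >= 0), temperature > 0, prefactor > 0)
  structure(list(force = as.numeric(force), ntp = ntp,
                 temperature = temperature, prefactor = prefactor),
            class = "tec_condition")
}

# substitute reference constants for parameters the model does not estimate
effective_params <- function(params, model, space = model_space(),
                             delta = 3.4) {
  row <- space[space$model == model, ]
  if (!nrow(row)) stop("unknown model index: ", model)
  p <- params
  if (!row$uses_dG_t1) p$dG_t1 <- 0
  if (!row$uses_delta1) p$delta1 <- delta / 2
  p
}

#' Force-dependent translocation rates
#'
#' Arrhenius-type rates over the sequence-dependent barrier: the forward rate
#' from the pretranslocated state and the backward rate from the
#' posttranslocated state, with the applied force acting through the
#' displacements `delta1` and `delta - delta1` (1 pN.Angstrom = 1e-22 J).
#' The barrier is `dG_tdag + dG_T^bp(l)`; the posttranslocated state is
#' offset by `dG_t1`.
#'
#' @param params a [parameter_set()] (reference constants are substituted for
#'   parameters outside `model`'s active set).
#' @param cond a [tec_condition()].
#' @param landscape an [energy_landscape()].
#' @param l sites at which to evaluate (default: all landscape sites).
#' @param model model index used to decide which parameters are active
#'   (default 12, all active).
#' @return list with numeric vectors `k_fwd` and `k_bck` (1/s).
#' @examples
#' ls <- energy_landscape(random_template(60, seed = 2))
#' r <- translocation_rates(parameter_set(), tec_condition(force = 5), ls)
#' @export
translocation_rates <- function(params, cond, landscape, l = NULL,
                                model = 12L) {
  geom <- landscape$geometry
  p <- effective_params(params, model, delta = geom$delta)
  idx <- if (is.null(l)) seq_along(landscape$l) else match(l, landscape$l)
  if (anyNA(idx)) stop("site(s) outside landscape: ",
                       paste(l[is.na(idx)], collapse = ", "))
  fscale <- pnA_per_kBT(cond$temperature)
  dGdag <- p$dG_tdag + landscape$dG_T[idx]
  if (any(!is.finite(dGdag))) stop("non-finite transition-state energies")
  k_fwd <- cond$prefactor *
    exp(-(dGdag - landscape$dG_pre[idx] - cond$force * p$delta1 / fscale))
  k_bck <- cond$prefactor *
    exp(-(dGdag - (landscape$dG_post[idx] + p$dG_t1) +
            cond$force * (geom$delta - p$delta1) / fscale))
  list(k_fwd = k_fwd, k_bck = k_bck)
}

#' Translocation equilibrium constant
#'
#' `K_tau(l) = p(pre) / p(post)` at zero force, from the basepairing energies
#' of the two states and the posttranslocated offset `dG_t1`.  Under an
#' applied force the posttranslocated side gains the Boltzmann factor
#' `exp(+F delta / kBT)`, so the force-dependent ratio is
#' `K_tau(l) * exp(-F delta / kBT)`; set `with_force = TRUE` to include it.
#'
#' @inheritParams translocation_rates
#' @param with_force include the force tilt (default FALSE: bare `K_tau`).
#' @return numeric vector of equilibrium constants.
#' @export
translocation_equilibrium <- function(params, landscape, l = NULL,
                                      cond = tec_condition(), model = 12L,
                                      with_force = FALSE) {
  geom <- landscape$geometry
  p <- effective_params(params, model, delta = geom$delta)
  idx <- if (is.null(l)) seq_along(landscape$l) else match(l, landscape$l)
  if (anyNA(idx)) stop("site(s) outside landscape")
  ktau <- exp(-(landscape$dG_pre[idx] - landscape$dG_post[idx] - p$dG_t1))
  if (with_force) {
    ktau <- ktau * exp(-cond$force * geom$delta / pnA_per_kBT(cond$temperature))
  }
  ktau
}

#' Closed-form mean velocity of the doubly-equilibrated model
#'
#' Deterministic pause-free velocity for the model in which both
#' translocation and NTP binding are at equilibrium, on a homogeneous
#' template with a single translocation equilibrium constant:
#' `v = k_cat / (1 + (K_D/[NTP]) (1 + K_tau exp(-F delta / kBT)))`.
#'
#' @param k_cat catalysis rate (1/s).
#' @param K_D NTP dissociation constant (uM).
#' @param K_tau translocation equilibrium constant (dimensionless).
#' @param force applied force (pN).
#' @param ntp NTP concentration (uM); 0 gives velocity 0.
#' @param delta basepair rise (Angstrom).
#' @param temperature kelvin.
#' @return velocity in bp/s (vectorised over its arguments).
#' @examples
#' analytic_velocity(24.7, 15.6, K_tau = 1, force = 0, ntp = 31.2)  # 12.35
#' @export
analytic_velocity <- function(k_cat, K_D, K_tau, force, ntp, delta = 3.4,
                              temperature = 310) {
  ifelse(ntp <= 0, 0,
         k_cat / (1 + (K_D / ntp) *
                    (1 + K_tau * exp(-force * delta / pnA_per_kBT(temperature)))))
}

#' Sequence-averaged translocation equilibrium constant
#'
#' Geometric mean over all sites of the backward/forward rate ratio at zero
#' force: `exp` of the arithmetic mean of `log(k_bck(l)/k_fwd(l))`, which by
#' detailed balance equals the geometric mean of `K_tau(l)` and is
#' independent of `dG_tdag` and `delta1`.
#'
#' @param landscape an [energy_landscape()] (or a template, which is
#'   converted with default geometry/tables).
#' @param params a [parameter_set()]; only `dG_t1` enters.
#' @return scalar geometric-mean equilibrium constant.
#' @export
sequence_averaged_Ktau <- function(landscape, params = parameter_set()) {
  if (!inherits(landscape, "energy_landscape"))
    landscape <- energy_landscape(as_template(landscape))
  exp(mean(log(translocation_equilibrium(params, landscape))))
}

# NTP concentration seen at each site (the NTP complementary to the next
# template position, i.e. matching the coding base at l + 1)
site_ntp <- function(landscape, cond) {
  unname(cond$ntp[landscape$next_base])
}

# Per-site effective propensity arrays for the four equilibrium variants.
# variant codes: 0 both equilibria; 1 translocation eq + kinetic binding;
# 2 kinetic translocation + binding eq; 3 fully kinetic.
model_variant <- function(model, space = model_space()) {
  row <- space[space$model == model, ]
  if (!nrow(row)) stop("unknown model index: ", model)
  if (row$transl_eq && row$bind_eq) 0L
  else if (row$transl_eq) 1L
  else if (row$bind_eq) 2L
  else 3L
}

site_rates <- function(model, params, cond, landscape,
                       space = model_space()) {
  variant <- model_variant(model, space)
  geom <- landscape$geometry
  p <- effective_params(params, model, space, delta = geom$delta)
  conc <- site_ntp(landscape, cond)
  fscale <- pnA_per_kBT(cond$temperature)
  out <- list(variant = variant, n = length(landscape$l),
              k_cat = p$k_cat, k_rel = p$K_D * p$k_bind)
  if (variant %in% c(0L, 1L)) {
    ktauF <- translocation_equilibrium(p, landscape, cond = cond,
                                       model = model, with_force = TRUE)
    if (variant == 0L) {
      out$r0 <- ifelse(conc <= 0, 0,
                       p$k_cat / (1 + (p$K_D / conc) * (1 + ktauF)))
    } else {
      out$bind <- p$k_bind * conc / (1 + ktauF)   # post occupancy scaling
    }
  } else {
    tr <- translocation_rates(p, cond, landscape, model = model)
    out$k_fwd <- tr$k_fwd; out$k_bck <- tr$k_bck
    if (variant == 2L) {
      f <- conc / (conc + p$K_D)
      out$r_bck <- tr$k_bck * (1 - f)   # coalesced post: unbound fraction
      out$r_cat <- p$k_cat * f          # coalesced post: bound fraction
    } else {
      out$bind <- p$k_bind * conc
    }
  }
  out
}

#' Reaction propensities leaving a TEC state
#'
#' Enumerates the outgoing reactions of a single state under a given model,
#' after coalescing any states subject to a partial equilibrium
#' approximation.  Backtracking and hypertranslocation successors are never
#' emitted.
#'
#' @param state list with `l` (mRNA length), `t` (register 0/1) and `bound`
#'   (logical; kinetic-binding models only).  Under a translocation
#'   equilibrium `t` is ignored for the coalesced state (use `t = 1`).
#' @param model model index (1-12).
#' @inheritParams translocation_rates
#' @return data frame with columns `reaction`, `rate` (1/s), `next_l`,
#'   `next_t`, `next_bound`.
#' @examples
#' ls <- energy_landscape(random_template(60, seed = 3))
#' propensity_table(list(l = 30, t = 0, bound = FALSE), model = 12,
#'                  parameter_set(), tec_condition(ntp = 100), ls)
#' @export
propensity_table <- function(state, model, params, cond, landscape) {
  check_state(list(length = landscape$L), state$l, state$t %||% 0L,
              landscape$geometry)
  bound <- isTRUE(state$bound)
  if (bound && state$t == 0)
    stop("an NTP-bound state must be posttranslocated")
  sr <- site_rates(model, params, cond, landscape)
  i <- match(state$l, landscape$l)
  if (is.na(i)) stop("state beyond the last elongation site")
  l <- state$l
  row <- function(reaction, rate, next_l, next_t, next_bound = FALSE) {
    data.frame(reaction = reaction, rate = rate, next_l = next_l,
               next_t = next_t, next_bound = next_bound,
               stringsAsFactors = FALSE)
  }
  tab <- switch(as.character(sr$variant),
    "0" = row("catalysis (coalesced)", sr$r0[i], l + 1L, 0L),
    "1" = if (!bound) {
      row("NTP binding (coalesced pre/post)", sr$bind[i], l, 1L, TRUE)
    } else {
      rbind(row("NTP release", sr$k_rel, l, 1L, FALSE),
            row("catalysis", sr$k_cat, l + 1L, 0L))
    },
    "2" = if (state$t == 0L) {
      row("forward translocation", sr$k_fwd[i], l, 1L)
    } else {
      rbind(row("backward translocation (coalesced post)", sr$r_bck[i], l, 0L),
            row("catalysis (coalesced post)", sr$r_cat[i], l + 1L, 0L))
    },
    "3" = if (state$t == 0L) {
      row("forward translocation", sr$k_fwd[i], l, 1L)
    } else if (!bound) {
      rbind(row("backward translocation", sr$k_bck[i], l, 0L),
            row("NTP binding", sr$bind[i], l, 1L, TRUE))
    } else {
      rbind(row("NTP release", sr$k_rel, l, 1L, FALSE),
            row("catalysis", sr$k_cat, l + 1L, 0L))
    })
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
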