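# Synthetic templates and force-velocity-[NTP] datasets with known ground
# truth, emulating the designs of the published optical-trapping experiments
# the elongation models are fitted to.

#' Random template sequence
#'
#' Generates an iid random coding-strand sequence with a given GC fraction
#' (`P(G) = P(C) = gc/2`).
#'
#' @param L sequence length (nt); must be at least `l0` of the geometry.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param id sequence identifier.
#' @return a [tec_template()].
#' @examples
#' random_template(50, gc = 0, seed = 1)   # A/T only
#' @export
random_template <- function(L, gc = 0.5, seed = NULL, id = NULL) {
  stopifnot(gc >= 0, gc <= 1, L >= 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- sample(c("A", "T", "G", "C"), size = L, replace = TRUE,
                  prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  tec_template(paste(bases, collapse = ""),
               id = id %||% sprintf("synthetic_L%d_gc%g", L, gc))
}

#' Built-in experimental designs
#'
#' Three synthetic designs emulating the published single-molecule datasets
#' the elongation models are fitted against:
#'
#' * `"abbondanzieri_like"` (E. coli RNAP): force sweep from hindering to
#'   assisting loads at saturating NTP (1 mM each) and at the limiting
#'   equimolar-substitute mix `[ATP] = 5, [CTP] = 2.5, [GTP] = 10,
#'   [UTP] = 10` uM.
#' * `"schweikhard_like"` (yeast pol II): NTP titration at fixed assisting
#'   and hindering forces.
#' * `"thomen_like"` (T7 pol): force sweeps at two NTP concentrations.
#'
#' @return named list of design data frames with columns `force_pN` and
#'   `ntp_spec` (scalar uM or `"A=..;C=..;G=..;U=.."`).
#' @export
builtin_designs <- function() {
  ntp_eq <- "A=5;C=2.5;G=10;U=10"
  forces6 <- c(-10, -5, 0, 10, 20, 30)
  list(
    abbondanzieri_like = data.frame(
      force_pN = rep(forces6, 2L),
      ntp_spec = rep(c("1000", ntp_eq), each = length(forces6)),
      stringsAsFactors = FALSE),
    schweikhard_like = data.frame(
      force_pN = rep(c(-7, 10), each = 6L),
      ntp_spec = as.character(rep(c(10, 25, 50, 100, 250, 1000), 2L)),
      stringsAsFactors = FALSE),
    thomen_like = data.frame(
      force_pN = rep(c(-15, -10, -5, 0, 5, 10, 15), 2L),
      ntp_spec = as.character(rep(c(100, 1000), each = 7L)),
      stringsAsFactors = FALSE))
}

#' Ground truth for a synthetic experiment
#'
#' @param model generating model index (1-12).
#' @param params generating [parameter_set()].
#' @param template a [tec_template()] (default: 500 nt, GC 0.5).
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   measurement noise on each mean velocity (default 0.05).
#' @param replicates Gillespie replicates per design cell.
#' @param seed root seed for template-independent dataset generation.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(model = 11L, params = parameter_set(),
                         template = random_template(500, gc = 0.5, seed = 101L),
                         noise_cv = 0.05, replicates = 8L, seed = 1L) {
  stopifnot(model %in% 1:12, noise_cv >= 0, replicates >= 1)
  structure(list(model = as.integer(model), params = params,
                 template = template, noise_cv = noise_cv,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate a synthetic observed dataset
#'
#' For every cell of the design, simulates the mean pause-free velocity under
#' the ground-truth model (averaging `replicates` Gillespie transcriptions of
#' the full template) and adds multiplicative Gaussian noise with standard
#' deviation `noise_cv * velocity`.  Deterministic given the truth's seed.
#'
#' @param truth a [ground_truth()].
#' @param design a design data frame (`force_pN`, `ntp_spec`), e.g. one of
#'   [builtin_designs()].
#' @return data frame of class `velocity_data` with columns `force_pN`,
#'   `ntp_spec`, `velocity_bp_s`; the truth is attached as attribute
#'   `"ground_truth"`.
#' @examples
#' \donttest{
#' gt <- ground_truth(model = 4, params = parameter_set(k_cat = 25, K_D = 16))
#' d <- generate_dataset(gt, builtin_designs()$abbondanzieri_like)
#' }
#' @export
generate_dataset <- function(truth, design) {
  stopifnot(inherits(truth, "ground_truth"),
            all(c("force_pN", "ntp_spec") %in% names(design)),
            nrow(design) >= 1L)
  landscape <- energy_landscape(truth$template)
  v <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    cond <- tec_condition(force = design$force_pN[i],
                          ntp = parse_ntp_spec(design$ntp_spec[i]))
    v[i] <- estimate_mean_velocity(landscape, truth$model, truth$params,
                                   cond, c = truth$replicates,
                                   seed = derive_seed(truth$seed, i))
  }
  if (truth$noise_cv > 0) {
    set.seed(derive_seed(truth$seed, 0L))
    v <- v * (1 + truth$noise_cv * rnorm(length(v)))
  }
  out <- data.frame(force_pN = design$force_pN, ntp_spec = design$ntp_spec,
                    velocity_bp_s = v, stringsAsFactors = FALSE)
  class(out) <- c("velocity_data", "data.frame")
  attr(out, "ground_truth") <- truth
  out
}
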