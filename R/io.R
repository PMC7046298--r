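# File formats: FASTA templates, TSV datasets and traces, YAML run configs.
# Units are fixed: pN, uM, bp/s, kB*T, Angstrom.

#' Parse / format an NTP specification
#'
#' An `ntp_spec` is either a single concentration in uM (broadcast to all
#' four NTPs) or a per-base string `"A=5;C=2.5;G=10;U=10"`.
#'
#' @param spec character or numeric scalar.
#' @return named numeric vector with entries A, C, G, U.
#' @examples
#' parse_ntp_spec("A=5;C=2.5;G=10;U=10")
#' parse_ntp_spec(1000)
#' @export
parse_ntp_spec <- function(spec) {
  if (is.numeric(spec)) return(setNames(rep(spec, 4L), c("A", "C", "G", "U")))
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- gsub(" ", "", spec)
  if (!grepl("=", spec, fixed = TRUE)) {
    val <- suppressWarnings(as.numeric(spec))
    if (is.na(val)) stop("cannot parse ntp_spec: ", spec)
    return(setNames(rep(val, 4L), c("A", "C", "G", "U")))
  }
  parts <- strsplit(spec, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bases <- toupper(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, "", 2L)))
  if (anyNA(vals) || !setequal(bases, c("A", "C", "G", "U")))
    stop("cannot parse ntp_spec: ", spec,
         " (expected \"A=..;C=..;G=..;U=..\")")
  setNames(vals[match(c("A", "C", "G", "U"), bases)], c("A", "C", "G", "U"))
}

#' @rdname parse_ntp_spec
#' @param ntp named numeric vector (A, C, G, U).
#' @export
format_ntp_spec <- function(ntp) {
  ntp <- parse_ntp_spec(if (is.character(ntp)) ntp else {
    if (length(unique(ntp)) == 1L) unname(ntp[1L]) else
      paste(paste0(names(ntp), "=", ntp), collapse = ";")
  })
  if (length(unique(ntp)) == 1L) as.character(ntp[[1L]])
  else paste(paste0(c("A", "C", "G", "U"), "=", ntp), collapse = ";")
}

#' Read a template sequence from FASTA
#'
#' Reads the first (or a named) record, uppercases it, maps U to T with a
#' warning, and validates the alphabet (non-ACGT characters are rejected
#' with their positions).
#'
#' @param path FASTA file path.
#' @param id record identifier to select; default: first record.
#' @return a [tec_template()].
#' @export
read_template_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  if (!length(recs)) stop("no FASTA records in ", path)
  rec <- if (is.null(id)) recs[[1L]] else {
    if (!id %in% names(recs)) stop("no record named '", id, "' in ", path)
    recs[[id]]
  }
  tec_template(as.character(rec),
               id = if (is.null(id)) names(recs)[1L] else id)
}

#' Write a template to FASTA
#' @param template a [tec_template()].
#' @param path output path.
#' @param width line width.
#' @return invisibly, `path`.
#' @export
write_template_fasta <- function(template, path, width = 70L) {
  template <- as_template(template)
  chunks <- substring(template$seq,
                      seq(1L, template$length, by = width),
                      pmin(seq(1L, template$length, by = width) + width - 1L,
                           template$length))
  writeLines(c(paste0(">", template$id), chunks), path)
  invisible(path)
}

#' Read / write an observed velocity dataset
#'
#' TSV with required columns `force_pN`, `ntp_spec`, `velocity_bp_s`.
#' Malformed rows are reported with their line numbers.
#'
#' @param path TSV file path.
#' @return data frame of class `velocity_data`.
#' @export
read_velocity_data <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = "character", comment.char = "#")
  need <- c("force_pN", "ntp_spec", "velocity_bp_s")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  for (col in c("force_pN", "velocity_bp_s")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v)) stop("non-numeric ", col, " at line(s): ",
                       paste(which(is.na(v)) + 1L, collapse = ", "))
    d[[col]] <- v
  }
  for (i in seq_len(nrow(d))) {
    tryCatch(parse_ntp_spec(d$ntp_spec[i]),
             error = function(e) stop("bad ntp_spec at line ", i + 1L, ": ",
                                      d$ntp_spec[i]))
  }
  if (any(d$velocity_bp_s <= 0))
    stop("velocities must be positive (line(s) ",
         paste(which(d$velocity_bp_s <= 0) + 1L, collapse = ", "), ")")
  class(d) <- c("velocity_data", "data.frame")
  d
}

#' @rdname read_velocity_data
#' @param data velocity dataset data frame.
#' @export
write_velocity_data <- function(data, path) {
  stopifnot(all(c("force_pN", "ntp_spec", "velocity_bp_s") %in% names(data)))
  write.table(data[, c("force_pN", "ntp_spec", "velocity_bp_s")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a posterior trace
#'
#' TSV with columns `chain`, `iteration`, `model`, the six parameters
#' (`k_cat`, `K_D`, `k_bind`, `dG_t1`, `delta1`, `dG_tdag`) and `X2`.
#'
#' @param trace trace data frame (e.g. `fit$trace`).
#' @param path TSV file path.
#' @export
write_trace <- function(trace, path) {
  cols <- c("chain", "iteration", "model", .param_names, "X2")
  stopifnot(all(cols %in% names(trace)))
  write.table(trace[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.table(path, header = TRUE, sep = "\t")
  cols <- c("chain", "iteration", "model", .param_names, "X2")
  miss <- setdiff(cols, names(d))
  if (length(miss)) stop("missing trace column(s): ",
                         paste(miss, collapse = ", "))
  d
}

#' Read / write a run configuration (YAML)
#'
#' A run configuration holds the enzyme profile and ABC settings
#' (`enzyme`, `epsilon`, `chains`, `iterations`, `replicates`, `seed`,
#' `models`, optional `proposal_scale`, `p_model`, `burnin`, `thin`).
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("enzyme", "epsilon", "chains", "iterations", "replicates",
             "seed", "models", "proposal_scale", "p_model", "burnin", "thin")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(cfg$enzyme) && !cfg$enzyme %in% c("rnap", "polII", "t7"))
    stop("enzyme must be one of rnap, polII, t7")
  cfg
}

#' @rdname read_run_config
#' @param config named list of settings.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write / read ground truth (YAML sidecar)
#' @param truth a [ground_truth()].
#' @param path YAML path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  yaml::write_yaml(list(
    model = truth$model, params = unclass(truth$params),
    template = list(id = truth$template$id, seq = truth$template$seq),
    noise_cv = truth$noise_cv, replicates = truth$replicates,
    seed = truth$seed), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  y <- yaml::read_yaml(path)
  ground_truth(model = y$model,
               params = do.call(parameter_set, y$params),
               template = tec_template(y$template$seq, id = y$template$id),
               noise_cv = y$noise_cv, replicates = y$replicates,
               seed = y$seed)
}
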