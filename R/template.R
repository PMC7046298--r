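# Template sequences and TEC geometry.

#' Create a template (coding-strand) sequence
#'
#' The stored strand is the coding (non-template) DNA strand written 5'->3',
#' so the nascent mRNA has the same sequence with U in place of T, and the
#' template strand is its reverse complement.  All downstream energetics and
#' kinetics are derived views of this single strand.
#'
#' @param seq a single character string, or character vector of single bases,
#'   over the alphabet A, C, G, T (case-insensitive; U is mapped to T).
#' @param id sequence identifier.
#' @return an object of class `tec_template`: a list with elements `id`,
#'   `seq` (uppercase string) and `length`.
#' @examples
#' tec_template("ACGTACGTACGTACGT")
#' @export
tec_template <- function(seq, id = "template") {
  if (length(seq) > 1L) seq <- paste(seq, collapse = "")
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("U", seq, fixed = TRUE)) {
    warning("template contains U; mapping U -> T (coding strand stored as DNA)")
    seq <- gsub("U", "T", seq, fixed = TRUE)
  }
  bad <- gregexpr("[^ACGT]", seq)[[1L]]
  if (bad[1L] != -1L) {
    stop("template contains non-ACGT characters at position(s): ",
         paste(head(bad, 10L), collapse = ", "))
  }
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "tec_template")
}

#' @export
print.tec_template <- function(x, ...) {
  cat("<tec_template> ", x$id, ": ", x$length, " nt\n", sep = "")
  show <- if (x$length > 60L) paste0(substr(x$seq, 1L, 57L), "...") else x$seq
  cat("  ", show, "\n", sep = "")
  invisible(x)
}

#' @export
as.character.tec_template <- function(x, ...) x$seq

#' @export
length.tec_template <- function(x) x$length

as_template <- function(x) {
  if (inherits(x, "tec_template")) x else tec_template(x)
}

#' Geometry of the transcription elongation complex
#'
#' Fixed structural parameters of the TEC: the DNA/mRNA hybrid length `h`,
#' the numbers of unpaired template bases upstream (`beta1`) and downstream
#' (`beta2`) of the hybrid within the transcription bubble, and the rise per
#' basepair `delta` (Angstrom).  The transcription bubble spans
#' `beta1 + h + beta2` template bases; transcription starts with an mRNA of
#' length `l0 = beta1 + h + 2`.
#'
#' @param h hybrid length in basepairs (default 9).
#' @param beta1 upstream unpaired template bases (default 2).
#' @param beta2 downstream unpaired template bases (default 1).
#' @param delta inter-basepair distance in Angstrom (default 3.4).
#' @return an object of class `tec_geometry` with derived fields
#'   `bubble` and `l0`.
#' @examples
#' tec_geometry()  # h = 9, beta1 = 2, beta2 = 1: bubble 12, l0 = 13
#' @export
tec_geometry <- function(h = 9L, beta1 = 2L, beta2 = 1L, delta = 3.4) {
  stopifnot(h >= 2, beta1 >= 1, beta2 >= 1, delta > 0)
  structure(list(h = as.integer(h), beta1 = as.integer(beta1),
                 beta2 = as.integer(beta2), delta = delta,
                 bubble = as.integer(beta1 + h + beta2),
                 l0 = as.integer(beta1 + h + 2L)),
            class = "tec_geometry")
}

#' @export
print.tec_geometry <- function(x, ...) {
  cat("<tec_geometry> h =", x$h, " beta1 =", x$beta1, " beta2 =", x$beta2,
      " delta =", x$delta, "A  (bubble =", x$bubble, "nt, l0 =", x$l0, ")\n")
  invisible(x)
}
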