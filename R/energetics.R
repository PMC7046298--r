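# Sequence-dependent basepairing energetics of TEC states.
#
# A state S(l, t) of the elongation complex is described by the mRNA length l
# and the translocation register t (0 = pretranslocated, 1 = posttranslocated;
# backtracked t < 0 and hypertranslocated t > 1 states are outside the model).
# Coding-strand coordinates are 1-based; at register t the hybrid pairs
# template positions [l - h + 1 + t, l] (h - t basepairs) and the bubble spans
# [l - h + 1 - beta1 + t, l + beta2 + t] (always beta1 + h + beta2 bases).

.ratchet_env <- new.env(parent = emptyenv())

#' Nearest-neighbour energy tables
#'
#' Loads the shipped nearest-neighbour tables: SantaLucia's unified DNA/DNA
#' doublet Gibbs energies for the duplex DNA flanking the transcription
#' bubble, Sugimoto's DNA/RNA doublet energies for the DNA/mRNA hybrid, and a
#' single-nucleotide dangling-end set applied at the exposed hybrid termini.
#' All values are standard Gibbs energies at 37 C in kcal/mol; the elongation
#' model converts them to kB*T at 310 K without temperature correction.
#'
#' @param dna,hybrid,dangling optional paths to replacement TSV files in the
#'   same format as the shipped ones (`doublet`, `dG_kcal_mol`, and for the
#'   dangling set an `end` column with values `5p`/`3p`).
#' @return a list of class `nn_tables` with named-numeric components `dna`
#'   and `hybrid` (names are the 16 doublets), `dangling` (names
#'   `"<doublet>_<end>"`), and `provenance`.
#' @examples
#' tabs <- nn_tables()
#' tabs$dna[["GC"]]
#' @export
nn_tables <- function(dna = NULL, hybrid = NULL, dangling = NULL) {
  default <- is.null(dna) && is.null(hybrid) && is.null(dangling)
  if (default && !is.null(.ratchet_env$nn_tables)) return(.ratchet_env$nn_tables)
  path <- function(x, f) if (is.null(x)) system.file("extdata", f, package = "ratchet") else x
  read_doublets <- function(p) {
    d <- read.table(p, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
    stopifnot(all(c("doublet", "dG_kcal_mol") %in% names(d)))
    v <- setNames(d$dG_kcal_mol, d$doublet)
    miss <- setdiff(all_doublets(), names(v))
    if (length(miss)) stop("doublet table incomplete; missing: ", paste(miss, collapse = ", "))
    if (any(!is.finite(v))) stop("non-finite doublet energies")
    v
  }
  dang <- read.table(path(dangling, "nn_dangling_ends.tsv"), header = TRUE,
                     sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("doublet", "end", "dG_kcal_mol") %in% names(dang)),
            all(dang$end %in% c("5p", "3p")))
  out <- structure(list(
    dna      = read_doublets(path(dna, "nn_dna_dna_santalucia1998.tsv")),
    hybrid   = read_doublets(path(hybrid, "nn_dna_rna_sugimoto1995.tsv")),
    dangling = setNames(dang$dG_kcal_mol, paste0(dang$doublet, "_", dang$end)),
    provenance = c(dna = "DNA/DNA SantaLucia", hybrid = "DNA/RNA Sugimoto",
                   dangling = "DNA dangling ends, nearest-neighbour 37C")),
    class = "nn_tables")
  if (default) .ratchet_env$nn_tables <- out
  out
}

all_doublets <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(b, b, paste0))
}

#' Uniform nearest-neighbour tables
#'
#' Replaces every doublet (and optionally dangling-end) energy by a single
#' constant.  Useful as a sequence-independence control: with uniform tables
#' the energy landscape, and hence every rate, is identical at every site.
#'
#' @param dna,hybrid,dangling constant energies in kcal/mol.
#' @return an `nn_tables` object.
#' @export
uniform_nn_tables <- function(dna = -1, hybrid = -1, dangling = -0.5) {
  d <- all_doublets()
  structure(list(
    dna      = setNames(rep(dna, 16L), d),
    hybrid   = setNames(rep(hybrid, 16L), d),
    dangling = setNames(rep(dangling, 32L), paste0(rep(d, 2L), "_", rep(c("5p", "3p"), each = 16L))),
    provenance = c(dna = "uniform", hybrid = "uniform", dangling = "uniform")),
    class = "nn_tables")
}

# State coordinate helpers ---------------------------------------------------

state_coords <- function(l, t, geom) {
  h <- geom$h; b1 <- geom$beta1; b2 <- geom$beta2
  list(
    hybrid_from  = l - h + 1L + t,   # first hybrid-paired template position
    hybrid_to    = l,
    bubble_from  = l - h + 1L - b1 + t,
    bubble_to    = l + b2 + t,
    # fixed window (independent of t) for gene doublet bookkeeping, so that
    # the layouts of S(l,0), S(l,1) and T(l,0) are directly comparable
    win_from     = l - h - b1 - 3L,
    win_to       = l + b2 + 4L
  )
}

check_state <- function(sequence, l, t, geom) {
  L <- sequence$length
  if (L < geom$l0) stop("template shorter than l0 = ", geom$l0)
  if (length(l) != 1L || l < geom$l0 || l > L)
    stop("mRNA length l = ", l, " outside [l0, L] = [", geom$l0, ", ", L, "]")
  if (!(length(t) == 1L && t %in% c(0L, 1L)))
    stop("translocation register t must be 0 or 1 ",
         "(backtracked and hypertranslocated states are not modelled)")
  invisible(TRUE)
}

# doublets (start positions i, meaning the pair of positions i, i+1) fully
# inside the closed (paired) DNA runs of the window, i.e. outside the bubble
gene_doublet_starts <- function(co, L, bubble_from = co$bubble_from,
                                bubble_to = co$bubble_to) {
  up_from <- max(1L, co$win_from); up_to <- bubble_from - 1L
  dn_from <- bubble_to + 1L;       dn_to <- min(L, co$win_to)
  c(if (up_to - up_from >= 1L) seq.int(up_from, up_to - 1L),
    if (dn_to - dn_from >= 1L) seq.int(dn_from, dn_to - 1L))
}

#' Basepair layout of a TEC state
#'
#' Enumerates the basepair doublets and dangling ends of state `S(l, t)`:
#' the closed dsDNA doublets flanking the transcription bubble (within a fixed
#' window around the complex, truncated at the sequence ends), the DNA/mRNA
#' hybrid doublets, and one dangling-end descriptor per exposed hybrid
#' terminus.  Doublets are identified by the coding-strand position of their
#' first base.
#'
#' @param sequence a [tec_template()] (or string coercible to one).
#' @param l mRNA length, in `[l0, L]`.
#' @param t translocation register, 0 (pre) or 1 (post).
#' @param geometry a [tec_geometry()].
#' @return an object of class `bp_layout`: list with integer vectors
#'   `gene_doublets` and `hybrid_doublets` (doublet start positions), a
#'   data frame `dangling` (`pos`, `end`), and the hybrid basepair positions
#'   `hybrid_bp`.
#' @examples
#' tpl <- random_template(60, seed = 1)
#' lay <- basepair_layout(tpl, l = 30, t = 0)
#' length(lay$hybrid_bp)   # 9 hybrid basepairs in the pretranslocated state
#' @export
basepair_layout <- function(sequence, l, t, geometry = tec_geometry()) {
  sequence <- as_template(sequence)
  check_state(sequence, l, t, geometry)
  l <- as.integer(l); t <- as.integer(t)
  co <- state_coords(l, t, geometry)
  L <- sequence$length
  hyb_bp <- seq.int(co$hybrid_from, co$hybrid_to)
  hyb_d  <- if (length(hyb_bp) >= 2L) hyb_bp[-length(hyb_bp)] else integer(0)
  dang <- data.frame(pos = integer(0), end = character(0),
                     stringsAsFactors = FALSE)
  if (co$hybrid_from - 1L >= 1L)               # template base 5' of the hybrid
    dang <- rbind(dang, data.frame(pos = co$hybrid_from - 1L, end = "5p"))
  if (co$hybrid_to + 1L <= L)                  # active-site template base
    dang <- rbind(dang, data.frame(pos = co$hybrid_to, end = "3p"))
  structure(list(
    l = l, t = t,
    gene_doublets   = gene_doublet_starts(co, L),
    hybrid_doublets = hyb_d,
    hybrid_bp       = hyb_bp,
    dangling        = dang),
    class = "bp_layout")
}

transition_layout <- function(sequence, l, geometry = tec_geometry()) {
  # basepairs present in both S(l,0) and S(l,1): hybrid of the post state,
  # DNA closed outside the union of the two bubbles
  sequence <- as_template(sequence)
  check_state(sequence, l, 0L, geometry)
  check_state(sequence, l, 1L, geometry)
  l <- as.integer(l)
  co0 <- state_coords(l, 0L, geometry)
  co1 <- state_coords(l, 1L, geometry)
  L <- sequence$length
  hyb_bp <- seq.int(co1$hybrid_from, co1$hybrid_to)
  dang <- data.frame(pos = integer(0), end = character(0),
                     stringsAsFactors = FALSE)
  if (co1$hybrid_from - 1L >= 1L)
    dang <- rbind(dang, data.frame(pos = co1$hybrid_from - 1L, end = "5p"))
  if (co1$hybrid_to + 1L <= L)
    dang <- rbind(dang, data.frame(pos = co1$hybrid_to, end = "3p"))
  structure(list(
    l = l, t = NA_integer_,
    gene_doublets   = gene_doublet_starts(co0, L,
                                          bubble_from = co0$bubble_from,
                                          bubble_to   = co1$bubble_to),
    hybrid_doublets = if (length(hyb_bp) >= 2L) hyb_bp[-length(hyb_bp)] else integer(0),
    hybrid_bp       = hyb_bp,
    dangling        = dang),
    class = "bp_layout")
}

#' @export
print.bp_layout <- function(x, ...) {
  cat("<bp_layout> S(", x$l, ", ", x$t, "): ",
      length(x$hybrid_bp), " hybrid bp, ",
      length(x$gene_doublets), " gene doublets, ",
      nrow(x$dangling), " dangling end(s)\n", sep = "")
  invisible(x)
}

#' Standard Gibbs basepairing energy of a layout
#'
#' Purely additive nearest-neighbour sum: DNA/DNA doublets of the closed gene
#' duplex, DNA/RNA doublets of the hybrid, and dangling-end terms at the
#' hybrid termini, converted from kcal/mol (37 C tables) to kB*T at `T_K`.
#'
#' @param layout a `bp_layout` from [basepair_layout()].
#' @param sequence the template the layout refers to.
#' @param tables an [nn_tables()] list.
#' @param use_dangling include the dangling-end terms (default TRUE).
#' @param T_K temperature for the kcal/mol -> kB*T conversion.
#' @return energy in kB*T (scalar).
#' @export
gibbs_basepairing <- function(layout, sequence, tables = nn_tables(),
                              use_dangling = TRUE, T_K = 310) {
  sequence <- as_template(sequence)
  doublet_at <- function(i) {
    if (!length(i)) return(character(0))
    substring(sequence$seq, i, i + 1L)
  }
  lookup <- function(tab, keys, what) {
    if (!length(keys)) return(0)
    v <- tab[keys]
    if (any(is.na(v))) stop("doublet missing from ", what, " table: ",
                            paste(unique(keys[is.na(v)]), collapse = ", "))
    sum(v)
  }
  e <- lookup(tables$dna,    doublet_at(layout$gene_doublets),   "DNA/DNA") +
       lookup(tables$hybrid, doublet_at(layout$hybrid_doublets), "DNA/RNA")
  if (use_dangling && nrow(layout$dangling)) {
    keys <- paste0(doublet_at(layout$dangling$pos), "_", layout$dangling$end)
    e <- e + lookup(tables$dangling, keys, "dangling-end")
  }
  kcal_per_mol_to_kBT(e, T_K = T_K)
}

#' Basepairing energy of the translocation transition state
#'
#' The transition state `T(l, t)` between `S(l, t)` and `S(l, t + 1)` retains
#' exactly the basepairs present in both flanking states (the intersection of
#' their basepair sets); its basepairing energy is the nearest-neighbour sum
#' over that intersection.  Only `t = 0` is a valid elongation transition.
#'
#' @inheritParams basepair_layout
#' @inheritParams gibbs_basepairing
#' @param t register of the lower flanking state; must be 0.
#' @return energy in kB*T (scalar).
#' @export
transition_state_basepairing <- function(sequence, l, t = 0L,
                                         geometry = tec_geometry(),
                                         tables = nn_tables(),
                                         use_dangling = TRUE, T_K = 310) {
  if (!(length(t) == 1L && t == 0L))
    stop("only the pre -> post transition (t = 0) exists in this state space")
  gibbs_basepairing(transition_layout(sequence, l, geometry), sequence,
                    tables = tables, use_dangling = use_dangling, T_K = T_K)
}

#' Sequence-dependent energy landscape of a template
#'
#' Precomputes, for every elongation site `l` in `[l0, L - 1]`, the standard
#' Gibbs basepairing energies of the pretranslocated state `S(l, 0)`, the
#' posttranslocated state `S(l, 1)` and the translocation transition state
#' `T(l, 0)`, in kB*T, together with the identity of the next template base
#' (which selects the NTP that can bind at that site).  All translocation
#' rates and equilibrium constants are cheap functions of these arrays, so
#' the landscape is computed once per template and reused across simulations.
#'
#' @inheritParams basepair_layout
#' @inheritParams gibbs_basepairing
#' @return object of class `energy_landscape`: list with `l` (sites),
#'   `dG_pre`, `dG_post`, `dG_T` (kB*T), `next_base` (mRNA alphabet, i.e. the
#'   NTP consumed by catalysis at each site), `geometry`, `template_id`, `L`.
#' @examples
#' tpl <- random_template(120, seed = 4)
#' ls <- energy_landscape(tpl)
#' head(ls$dG_post - ls$dG_pre)   # cost of losing one hybrid basepair
#' @export
energy_landscape <- function(sequence, geometry = tec_geometry(),
                             tables = nn_tables(), use_dangling = TRUE,
                             T_K = 310) {
  sequence <- as_template(sequence)
  L <- sequence$length
  l0 <- geometry$l0
  if (L < l0) stop("template shorter than l0 = ", l0)
  sites <- if (L > l0) seq.int(l0, L - 1L) else integer(0)
  pre <- post <- tst <- numeric(length(sites))
  for (k in seq_along(sites)) {
    l <- sites[k]
    pre[k]  <- gibbs_basepairing(basepair_layout(sequence, l, 0L, geometry),
                                 sequence, tables, use_dangling, T_K)
    post[k] <- gibbs_basepairing(basepair_layout(sequence, l, 1L, geometry),
                                 sequence, tables, use_dangling, T_K)
    tst[k]  <- transition_state_basepairing(sequence, l, 0L, geometry,
                                            tables, use_dangling, T_K)
  }
  nb <- if (length(sites)) substring(sequence$seq, sites + 1L, sites + 1L)
        else character(0)
  nb[nb == "T"] <- "U"
  structure(list(l = sites, dG_pre = pre, dG_post = post, dG_T = tst,
                 next_base = nb, geometry = geometry,
                 template_id = sequence$id, L = L, T_K = T_K),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat("<energy_landscape> ", x$template_id, ": ", length(x$l),
      " sites, T = ", x$T_K, " K\n", sep = "")
  if (length(x$l)) {
    cat("  l = ", min(x$l), "..", max(x$l),
        "; mean dG_post - dG_pre = ",
        signif(mean(x$dG_post - x$dG_pre), 4), " kBT\n", sep = "")
  }
  invisible(x)
}
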