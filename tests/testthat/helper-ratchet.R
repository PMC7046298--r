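# Shared fixtures, built in code.

# a homogeneous (flat) energy landscape: every site identical, so the
# sequence-homogeneous closed forms apply exactly
flat_landscape <- function(n_sites, dG_pre = 0, dG_post = 0, dG_T = 0,
                           next_base = "U", geometry = tec_geometry()) {
  l0 <- geometry$l0
  structure(list(
    l = seq.int(l0, l0 + n_sites - 1L),
    dG_pre = rep(dG_pre, n_sites),
    dG_post = rep(dG_post, n_sites),
    dG_T = rep(dG_T, n_sites),
    next_base = rep(next_base, n_sites),
    geometry = geometry, template_id = "flat", L = l0 + n_sites,
    T_K = 310), class = "energy_landscape")
}

# standard small test objects
test_template <- function(L = 120, seed = 1, gc = 0.5) {
  random_template(L, gc = gc, seed = seed)
}

# Monte Carlo standard error of a replicate mean
mc_se <- function(v) sd(v) / sqrt(length(v))
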