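# Model space, translocation rates, equilibrium constants, propensities.

test_that("the model space has the pinned structure", {
  sp <- model_space()
  expect_equal(nrow(sp), 12L)
  expect_equal(sp$k[sp$model == 1], 2L)
  expect_equal(sp$k[sp$model == 12], 6L)
  # translocation-equilibrium models never use delta1 or dG_tdag
  te <- sp$model[sp$transl_eq]
  expect_setequal(te, c(1, 2, 4, 5))
  for (m in te) {
    act <- ratchet:::active_params(m, sp)
    expect_false(any(c("delta1", "dG_tdag") %in% act))
  }
  # pinned descriptions
  expect_setequal(ratchet:::active_params(1), c("k_cat", "K_D"))
  expect_setequal(ratchet:::active_params(2), c("k_cat", "K_D", "k_bind"))
  expect_setequal(ratchet:::active_params(4), c("k_cat", "K_D", "dG_t1"))
  expect_setequal(ratchet:::active_params(5),
                  c("k_cat", "K_D", "k_bind", "dG_t1"))
  expect_setequal(ratchet:::active_params(11),
                  c("k_cat", "K_D", "dG_t1", "delta1", "dG_tdag"))
  expect_setequal(ratchet:::active_params(12),
                  c("k_cat", "K_D", "k_bind", "dG_t1", "delta1", "dG_tdag"))
  # prior masses: doubled for translocation-equilibrium models, sum 1
  expect_equal(sum(sp$prior_mass), 1)
  expect_true(all(sp$prior_mass[sp$transl_eq] == 2 / 16))
  expect_true(all(sp$prior_mass[!sp$transl_eq] == 1 / 16))
})

test_that("the model network is a single-parameter-augmentation graph", {
  net <- model_network()
  sp <- model_space()
  # no self edges, symmetric (validated inside), every edge differs by one
  for (i in names(net)) {
    for (j in net[[i]]) {
      a <- ratchet:::active_params(as.integer(i), sp)
      b <- ratchet:::active_params(j, sp)
      expect_equal(length(union(a, b)) - length(intersect(a, b)), 1L)
    }
  }
  expect_true(length(net[["1"]]) >= 2)            # at least +k_bind, +dG_t1
  expect_true(all(c(2, 4) %in% net[["1"]]))
  expect_setequal(net[["12"]], c(9, 10, 11))      # the 5-parameter models
})

test_that("translocation rates follow the Arrhenius form with force", {
  # flat landscape where the barrier equals the pretranslocated energy:
  # at F = 0 and dG_tdag = 0 the forward rate equals the prefactor A
  ls <- flat_landscape(5, dG_pre = 2, dG_post = 2, dG_T = 2)
  p <- parameter_set(dG_tdag = 0, dG_t1 = 0, delta1 = 1.7)
  r0 <- translocation_rates(p, tec_condition(force = 0), ls)
  expect_equal(r0$k_fwd, rep(1e6, 5), tolerance = 1e-12)
  # raising the barrier baseline by 1 kBT scales both rates by exp(-1)
  p1 <- parameter_set(dG_tdag = 1, dG_t1 = 0, delta1 = 1.7)
  r1 <- translocation_rates(p1, tec_condition(force = 0), ls)
  expect_equal(r1$k_fwd / r0$k_fwd, rep(exp(-1), 5), tolerance = 1e-12)
  expect_equal(r1$k_bck / r0$k_bck, rep(exp(-1), 5), tolerance = 1e-12)
  # F * delta1 = kBT at F = 12.588 pN, delta1 = 3.4 A (1 pN.A = 1e-22 J)
  pf <- parameter_set(dG_tdag = 0, delta1 = 3.4 - 1e-12)
  rf <- translocation_rates(pf, tec_condition(force = 12.588), ls)
  rb <- translocation_rates(pf, tec_condition(force = 0), ls)
  expect_equal(rf$k_fwd / rb$k_fwd, rep(exp(1), 5), tolerance = 1e-4)
})

test_that("detailed balance links rates and equilibrium constant at any force", {
  ls <- energy_landscape(test_template(80, seed = 21))
  for (f in c(-12, 0, 17)) {
    for (pars in list(parameter_set(dG_t1 = -2.5, delta1 = 3.1, dG_tdag = 4),
                      parameter_set(dG_t1 = 1.2, delta1 = 0.4, dG_tdag = 7))) {
      cond <- tec_condition(force = f)
      r <- translocation_rates(pars, cond, ls)
      kt <- translocation_equilibrium(pars, ls)
      fd <- f * 3.4 / ratchet:::pnA_per_kBT(310)
      # k_fwd / k_bck = exp(F delta / kBT) / K_tau, independent of barrier terms
      expect_equal(r$k_fwd / r$k_bck, exp(fd) / kt, tolerance = 1e-10)
    }
  }
})

test_that("translocation equilibrium constant evaluates the state energies", {
  ls <- flat_landscape(4, dG_pre = 1, dG_post = 1)
  p0 <- parameter_set(dG_t1 = 0)
  expect_equal(translocation_equilibrium(p0, ls), rep(1, 4))
  # dG_pre - dG_post = -1 and dG_t1 = -2: K_tau = exp(-(-1 - (-2))) = exp(-1)
  ls2 <- flat_landscape(4, dG_pre = 0, dG_post = 1)
  p2 <- parameter_set(dG_t1 = -2)
  expect_equal(translocation_equilibrium(p2, ls2), rep(exp(-1), 4),
               tolerance = 1e-12)
})

test_that("the closed-form velocity behaves like Michaelis-Menten in force", {
  # quoted historical fit: k_cat = 24.7 1/s, K_D = 15.6 uM
  expect_equal(analytic_velocity(24.7, 15.6, K_tau = 1, force = 0, ntp = 31.2),
               12.35, tolerance = 1e-10)
  expect_equal(analytic_velocity(24.7, 15.6, 1, 0, ntp = 0), 0)
  # saturating NTP: v -> k_cat; infinite assisting force: force term vanishes
  expect_equal(analytic_velocity(24.7, 15.6, 1, 0, ntp = 1e12), 24.7,
               tolerance = 1e-6)
  expect_equal(analytic_velocity(24.7, 15.6, 5, force = 1e6, ntp = 31.2),
               24.7 / (1 + 15.6 / 31.2), tolerance = 1e-9)
  # strictly increasing in F and [NTP], always below k_cat
  f <- seq(-10, 30, by = 5); n <- c(1, 5, 20, 100, 500, 2000)
  v_f <- analytic_velocity(24.7, 15.6, 1, f, 50)
  v_n <- analytic_velocity(24.7, 15.6, 1, 5, n)
  expect_true(all(diff(v_f) > 0))
  expect_true(all(diff(v_n) > 0))
  expect_true(all(c(v_f, v_n) < 24.7))
})

test_that("propensity tables implement the coalesced state reductions", {
  ls <- energy_landscape(test_template(80, seed = 22))
  p <- parameter_set(k_cat = 50, K_D = 10, k_bind = 0.5)
  cond <- tec_condition(force = 0, ntp = 10)
  # fully kinetic pretranslocated state: only forward translocation
  tab <- propensity_table(list(l = 40, t = 0, bound = FALSE), 12, p, cond, ls)
  expect_equal(nrow(tab), 1L)
  expect_match(tab$reaction, "forward")
  expect_equal(tab$next_t, 1L)
  # binding-equilibrium coalesced post state: occupancy [NTP]/([NTP]+K_D)
  tab11 <- propensity_table(list(l = 40, t = 1, bound = FALSE), 11, p, cond, ls)
  cat_rate <- tab11$rate[grepl("catalysis", tab11$reaction)]
  expect_equal(cat_rate, 25, tolerance = 1e-12)   # 50 * 10/(10+10)
  # zero NTP: binding (or coalesced catalysis) propensity vanishes
  cond0 <- tec_condition(force = 0, ntp = 0)
  tab0 <- propensity_table(list(l = 40, t = 1, bound = FALSE), 12, p, cond0, ls)
  expect_equal(tab0$rate[grepl("binding", tab0$reaction)], 0)
  tab0e <- propensity_table(list(l = 40, t = 1, bound = FALSE), 1, p, cond0, ls)
  expect_equal(tab0e$rate, 0)
  # no backtracking/hypertranslocation successors ever
  for (m in c(1, 2, 3, 11, 12)) {
    for (st in list(list(l = 40, t = 0, bound = FALSE),
                    list(l = 40, t = 1, bound = FALSE),
                    list(l = 40, t = 1, bound = TRUE))) {
      tt <- propensity_table(st, m, p, cond, ls)
      expect_true(all(tt$next_t %in% c(0L, 1L)))
      expect_true(all((tt$next_l - st$l) %in% c(0L, 1L)))
    }
  }
  # an NTP-bound state must be posttranslocated
  expect_error(propensity_table(list(l = 40, t = 0, bound = TRUE), 12, p,
                                cond, ls), "posttranslocated")
})

test_that("binding-equilibrium coalescing conserves outbound flux", {
  ls <- energy_landscape(test_template(80, seed = 23))
  p <- parameter_set(k_cat = 40, K_D = 25, k_bind = 0.8)
  cond <- tec_condition(force = 4, ntp = 60)
  # occupancy-weighted outbound rates of the kinetic model's post + bound
  # states must equal the coalesced model's outbound rates
  f <- 60 / (60 + 25)
  tabK <- propensity_table(list(l = 30, t = 1, bound = FALSE), 12, p, cond, ls)
  tabB <- propensity_table(list(l = 30, t = 1, bound = TRUE), 12, p, cond, ls)
  tabC <- propensity_table(list(l = 30, t = 1, bound = FALSE), 11, p, cond, ls)
  k_bck <- tabK$rate[grepl("backward", tabK$reaction)]
  k_cat <- tabB$rate[grepl("catalysis", tabB$reaction)]
  expect_equal(tabC$rate[grepl("backward", tabC$reaction)],
               (1 - f) * k_bck, tolerance = 1e-12)
  expect_equal(tabC$rate[grepl("catalysis", tabC$reaction)],
               f * k_cat, tolerance = 1e-12)
})

test_that("larger models collapse exactly onto their submodels", {
  # setting dG_t1 = 0 and delta1 = delta/2 in model 12 reproduces model 7;
  # in model 11 reproduces model 3 (nesting of the network)
  ls <- energy_landscape(test_template(90, seed = 24))
  cond <- tec_condition(force = 9, ntp = 80)
  p_free <- parameter_set(k_cat = 35, K_D = 12, k_bind = 0.6,
                          dG_t1 = 0, delta1 = 1.7, dG_tdag = 5)
  for (pair in list(c(12, 7), c(11, 3), c(5, 2), c(4, 1))) {
    v_big <- master_equation_velocity(ls, pair[1], p_free, cond)
    v_sub <- master_equation_velocity(ls, pair[2], p_free, cond)
    expect_equal(v_big, v_sub, tolerance = 1e-12)
  }
})

test_that("sequence-averaged K_tau is the geometric mean of site ratios", {
  # homogeneous landscape: equals the common site value
  ls <- flat_landscape(20, dG_pre = 0.7, dG_post = 1.2)
  p <- parameter_set(dG_t1 = -0.3)
  expect_equal(sequence_averaged_Ktau(ls, p),
               exp(-(0.7 - 1.2 - (-0.3))), tolerance = 1e-12)
  # two-site landscape with ratios {e, 1/e}: geometric mean 1
  ls2 <- flat_landscape(2)
  ls2$dG_pre <- c(1, -1); ls2$dG_post <- c(0, 0)
  expect_equal(sequence_averaged_Ktau(ls2, parameter_set(dG_t1 = 0)), 1,
               tolerance = 1e-12)
  # shifting dG_t1 by D multiplies the average by exp(D)
  ls3 <- energy_landscape(test_template(100, seed = 25))
  k0 <- sequence_averaged_Ktau(ls3, parameter_set(dG_t1 = -1))
  k1 <- sequence_averaged_Ktau(ls3, parameter_set(dG_t1 = -1 + 0.8))
  expect_equal(k1 / k0, exp(0.8), tolerance = 1e-10)
  # and equals the geometric mean of k_bck/k_fwd at zero force
  r <- translocation_rates(parameter_set(dG_t1 = -1), tec_condition(0), ls3)
  expect_equal(k0, exp(mean(log(r$k_bck / r$k_fwd))), tolerance = 1e-10)
})
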