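# Gillespie simulation and the master-equation first-passage oracle.

test_that("a degenerate template (L = l0) yields an empty transcription", {
  geom <- tec_geometry()
  tpl <- test_template(geom$l0, seed = 31)
  res <- simulate_transcription(tpl, 1, parameter_set(), tec_condition(),
                                seed = 1)
  expect_identical(res$nucleotides_added, 0L)
  expect_identical(res$elapsed_time, 0)
  expect_true(is.nan(res$mean_velocity))
})

test_that("simulation is deterministic given the seed", {
  ls <- energy_landscape(test_template(80, seed = 32))
  p <- parameter_set()
  cond <- tec_condition(force = 3, ntp = 50)
  for (m in c(1, 2, 3, 12)) {
    a <- simulate_transcription(ls, m, p, cond, seed = 99, trajectory = TRUE)
    b <- simulate_transcription(ls, m, p, cond, seed = 99, trajectory = TRUE)
    expect_identical(a$trajectory, b$trajectory)
    expect_identical(a$elapsed_time, b$elapsed_time)
  }
  # and the replicate-mean estimator is reproducible too
  v1 <- estimate_mean_velocity(ls, 12, p, cond, c = 5, seed = 4)
  v2 <- estimate_mean_velocity(ls, 12, p, cond, c = 5, seed = 4)
  expect_identical(v1, v2)
})

test_that("a homogeneous single-rate chain transcribes at its rate", {
  # flat landscape, both equilibria, saturating NTP, K_tau irrelevant:
  # per-nucleotide rate k_cat = 10 1/s over 200 nt
  ls <- flat_landscape(200)
  p <- parameter_set(k_cat = 10, K_D = 1e-9)
  cond <- tec_condition(force = 0, ntp = 1e9)
  v <- estimate_mean_velocity(ls, 1, p, cond, c = 200, seed = 5,
                              details = TRUE)
  reps <- attr(v, "replicates")
  expect_equal(as.numeric(v), 10, tolerance = 3 * mc_se(reps) / 10)
  # waiting times: each site is one exponential event with mean 1/rate,
  # so mean elapsed time is (sites / rate) within sampling error
  times <- 200 / reps
  expect_equal(mean(times), 20, tolerance = 3 * mc_se(times) / 20)
})

test_that("the replicate-mean estimator averages per-replicate velocities", {
  ls <- energy_landscape(test_template(60, seed = 33))
  p <- parameter_set()
  cond <- tec_condition()
  v1 <- estimate_mean_velocity(ls, 1, p, cond, c = 1, seed = 8)
  s1 <- simulate_transcription(ls, 1, p, cond,
                               seed = ratchet:::derive_seed(8, 1))
  expect_identical(as.numeric(v1), s1$mean_velocity)
  # variance decreases roughly like 1/c
  vars <- sapply(c(1, 4, 16), function(cc) {
    var(replicate(40, estimate_mean_velocity(ls, 1, p, cond, c = cc)))
  })
  expect_true(vars[3] < vars[1] / 4)   # loose: 16x replication, >4x shrinkage
  # published replicate counts are legal configuration
  for (cc in c(32, 10, 3)) {
    expect_silent(estimate_mean_velocity(ls, 1, p, cond, c = cc, seed = 1))
  }
})

test_that("master-equation passage times match hand-derived closed forms", {
  # binding-equilibrium variant: (k_fwd + k_bck_eff + k_cat_eff) /
  # (k_fwd * k_cat_eff) = (2 + 1 + 1) / (2 * 1) = 2 s per nucleotide
  sr <- list(variant = 2L, n = 3L, k_fwd = rep(2, 3), r_bck = rep(1, 3),
             r_cat = rep(1, 3), k_rel = 0, k_cat = 0)
  expect_equal(ratchet:::site_passage_times(sr), rep(2, 3))
  # both equilibria at K_tau = 1, [NTP] = K_D: velocity k_cat / 3
  ls <- flat_landscape(50)
  p <- parameter_set(k_cat = 30, K_D = 100)
  v <- master_equation_velocity(ls, 1, p, tec_condition(force = 0, ntp = 100))
  expect_equal(v, 30 / 3, tolerance = 1e-12)
  # fully kinetic closed form against a 3-state linear-system oracle
  a <- 7; b <- 3; cbind_ <- 4; r <- 2; k <- 5
  A <- rbind(c(-a, a, 0), c(b, -(b + cbind_), cbind_), c(0, r, -(r + k)))
  t_oracle <- solve(A, rep(-1, 3))[1L]   # mean absorption time from pre
  sr3 <- list(variant = 3L, n = 1L, k_fwd = a, k_bck = b, bind = cbind_,
              k_rel = r, k_cat = k)
  expect_equal(ratchet:::site_passage_times(sr3), t_oracle, tolerance = 1e-12)
})

test_that("Gillespie agrees with the master equation on all four variants", {
  tpl <- test_template(100, seed = 34)
  ls <- energy_landscape(tpl)
  p <- parameter_set(k_cat = 30, K_D = 15, k_bind = 0.4, dG_t1 = -1,
                     delta1 = 2.0, dG_tdag = 5)
  cond <- tec_condition(force = 6, ntp = 40)
  n <- length(ls$l)
  for (m in c(1, 2, 3, 12)) {   # one model per equilibrium variant
    v <- estimate_mean_velocity(ls, m, p, cond, c = 50, seed = 6,
                                details = TRUE)
    # the replicate-mean velocity matches its Laplace-transform expectation
    v_or <- master_equation_velocity(ls, m, p, cond,
                                     estimator = "replicate_mean")
    se <- mc_se(attr(v, "replicates"))
    expect_true(abs(v - v_or) < 3 * se + 1e-9,
                label = sprintf("model %d: |%g - %g| < 3SE=%g", m, v, v_or,
                                3 * se))
    # and the mean completion time matches the summed first-passage times
    times <- n / attr(v, "replicates")
    ET <- n / master_equation_velocity(ls, m, p, cond)
    expect_true(abs(mean(times) - ET) < 3 * mc_se(times) + 1e-9,
                label = sprintf("model %d completion time", m))
  }
})

test_that("velocity is sequence-independent under uniform tables", {
  u <- uniform_nn_tables()
  cond <- tec_condition(force = 2, ntp = 30)
  p <- parameter_set()
  ls_a <- energy_landscape(test_template(70, seed = 35), tables = u)
  ls_b <- energy_landscape(test_template(70, seed = 36), tables = u)
  # relabelling bases changes nothing when all doublets share one energy
  # (boundary truncation affects both landscapes identically)
  expect_equal(ls_a$dG_pre, ls_b$dG_pre, tolerance = 1e-12)
  for (m in c(1, 12)) {
    expect_equal(master_equation_velocity(ls_a, m, p, cond),
                 master_equation_velocity(ls_b, m, p, cond),
                 tolerance = 1e-12)
  }
})

test_that("stalled and runaway simulations raise errors", {
  ls <- flat_landscape(10)
  p <- parameter_set()
  expect_error(simulate_transcription(ls, 1, p, tec_condition(ntp = 0),
                                      seed = 1), "stalled")
  expect_error(simulate_transcription(ls, 12, p, tec_condition(ntp = 100),
                                      seed = 1, max_events = 3), "max_events")
  expect_error(master_equation_velocity(ls, 1, p, tec_condition(ntp = 0)),
               "infinite")
})
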