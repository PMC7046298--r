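# Distance, ABC acceptance rule, chain mechanics, posterior summaries.

test_that("the chi-squared distance matches its definition", {
  expect_identical(abc_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(abc_distance(12, 10), 0.4)                 # (2)^2 / 10
  expect_equal(abc_distance(c(12, 7), c(10, 7)), 0.4)     # matched row adds 0
  expect_error(abc_distance(1:3, 1:2), "length")
})

test_that("the acceptance rule is inclusive at the threshold", {
  acc <- ratchet:::accept_state
  expect_true(acc(x2 = 2, epsilon = 2, log_mh = 0, log_u = -0.1))  # X2 == eps
  expect_false(acc(x2 = 2 + 1e-12, epsilon = 2, log_mh = 0, log_u = -0.1))
  expect_false(acc(x2 = 0, epsilon = 2, log_mh = -Inf, log_u = -0.1))
  expect_false(acc(x2 = Inf, epsilon = Inf, log_mh = 0, log_u = -0.1))
})

test_that("priors match the published table and proposals respect support", {
  pr <- enzyme_priors("rnap")
  expect_equal(pr$k_cat[c("p1", "p2")], list(p1 = 3.454, p2 = 0.587))
  expect_equal(pr$dG_t1[c("p1", "p2")], list(p1 = 0, p2 = 1.55))
  prt <- enzyme_priors("t7")
  expect_equal(prt$dG_t1$p1, -3.3)
  expect_equal(prt$dG_tdag[c("p1", "p2")], list(p1 = 2.5, p2 = 1.36))
  # delta1 outside (0, delta) has zero prior density -> proposal rejected
  expect_identical(ratchet:::prior_logdens_one(pr$delta1, -0.1), -Inf)
  expect_identical(ratchet:::prior_logdens_one(pr$delta1, 3.5), -Inf)
})

test_that("chains are reproducible and combinable in any order", {
  ls <- energy_landscape(test_template(60, seed = 41))
  d <- data.frame(force_pN = c(0, 10, 20), ntp_spec = "200",
                  velocity_bp_s = c(8, 9, 10))
  fit1 <- elongation_abc(d, ls, enzyme = "rnap", models = c(1, 4),
                         epsilon = 50, chains = 2, iterations = 120,
                         replicates = 1, seed = 17, init_draws = 5)
  fit2 <- elongation_abc(d, ls, enzyme = "rnap", models = c(1, 4),
                         epsilon = 50, chains = 2, iterations = 120,
                         replicates = 1, seed = 17, init_draws = 5)
  expect_identical(fit1$trace, fit2$trace)
  # model probabilities do not depend on chain interleaving order
  tr <- fit1$trace
  perm <- tr[order(tr$iteration, tr$chain), ]
  expect_equal(posterior_model_probabilities(tr),
               posterior_model_probabilities(perm))
})

test_that("tightening epsilon cannot raise the acceptance rate", {
  ls <- energy_landscape(test_template(60, seed = 42))
  d <- data.frame(force_pN = c(0, 10, 20), ntp_spec = "200",
                  velocity_bp_s = c(8, 9, 10))
  rates <- sapply(c(0.2, 5, 1e6), function(eps) {
    elongation_abc(d, ls, enzyme = "rnap", models = 1, epsilon = eps,
                   chains = 1, iterations = 150, replicates = 1,
                   seed = 3, init_draws = 5)$acceptance_rate
  })
  expect_true(rates[1] <= rates[2] + 1e-12)
  expect_true(rates[2] <= rates[3] + 1e-12)
})

test_that("posterior model probabilities and credible sets behave", {
  tr <- data.frame(model = rep(11L, 50))
  expect_identical(posterior_model_probabilities(tr), c("11" = 1))
  expect_identical(credible_set(tr), 11L)
  probs <- c("11" = 0.81, "12" = 0.19)
  expect_setequal(credible_set(probs, 0.95), c(11L, 12L))
  expect_identical(credible_set(c("5" = 0.96, "2" = 0.04), 0.95), 5L)
  tr2 <- data.frame(model = c(rep(1L, 3), rep(4L, 7)))
  expect_equal(sum(posterior_model_probabilities(tr2)), 1)
  expect_error(posterior_model_probabilities(data.frame(model = integer(0))),
               "empty")
})

test_that("posterior predictive collapses onto a degenerate trace", {
  ls <- energy_landscape(test_template(60, seed = 43))
  p <- parameter_set(k_cat = 20, K_D = 10)
  st <- c(p$k_cat, p$K_D, p$k_bind, p$dG_t1, p$delta1, p$dG_tdag)
  trace <- data.frame(chain = 1L, iteration = 1L, model = 1L,
                      k_cat = p$k_cat, K_D = p$K_D, k_bind = p$k_bind,
                      dG_t1 = p$dG_t1, delta1 = p$delta1,
                      dG_tdag = p$dG_tdag, X2 = 0)
  fit <- structure(list(trace = trace, landscape = ls, replicates = 2,
                        data = data.frame(force_pN = 0, ntp_spec = "100",
                                          velocity_bp_s = 10)),
                   class = "elongation_abc")
  pp <- posterior_predictive(fit, n_draws = 6, seed = 2)
  expect_equal(nrow(pp), 6L)
  expect_true(all(pp$model == 1L))
  # all draws carry identical parameters: velocities differ only by
  # simulation noise around the same mean
  v_ref <- master_equation_velocity(ls, 1, p, tec_condition(0, 100),
                                    estimator = "replicate_mean")
  expect_true(all(abs(pp$velocity_bp_s - v_ref) / v_ref < 0.5))
  # predictive mean approaches the plug-in estimate as draws accumulate
  pp2 <- posterior_predictive(fit, n_draws = 40, seed = 3)
  expect_equal(mean(pp2$velocity_bp_s), v_ref, tolerance = 0.05)
})

test_that("a bypassed simulator with one model samples that model only", {
  ls <- energy_landscape(test_template(60, seed = 44))
  d <- data.frame(force_pN = 0, ntp_spec = "100", velocity_bp_s = 10)
  fit <- elongation_abc(d, ls, enzyme = "t7", models = 5, epsilon = 1,
                        chains = 1, iterations = 300, replicates = 1,
                        seed = 21, simulate = FALSE, init_draws = 1)
  expect_identical(unique(fit$trace$model), 5L)
  expect_identical(names(posterior_model_probabilities(fit)), "5")
  # non-empty posterior with all parameters inside prior support
  expect_true(all(fit$trace$delta1 > 0 & fit$trace$delta1 < 3.4))
  expect_true(all(fit$trace$k_cat > 0))
})
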