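test_that("closed-form profiles satisfy the initial condition and mass balance", {
  m <- two_step_model(0.05, 0.012, c0 = 0.8)
  p0 <- two_step_profile(0, m)
  expect_equal(unlist(p0[1, c("API", "Inter", "Prod")]),
               c(API = 0.8, Inter = 0, Prod = 0))
  t <- seq(0, 150, by = 0.5)
  p <- two_step_profile(t, m)
  expect_equal(p$API + p$Inter + p$Prod, rep(0.8, length(t)))
  expect_true(all(diff(p$API) < 0))
  expect_true(all(diff(p$Prod) >= 0))
  expect_true(all(p$API >= 0 & p$Inter >= 0 & p$Prod >= 0))
  expect_error(two_step_profile(-1, m), "non-negative")
})

test_that("the confluent k1 = k2 case uses the exact limiting form", {
  # k1 t = 1 at the intermediate maximum: cInter = exp(-1)
  p <- two_step_profile(100, two_step_model(0.01, 0.01))
  expect_equal(p$Inter, exp(-1), tolerance = 1e-12)
  # continuity across the switch
  t <- seq(0, 120, by = 1)
  for (eps in c(1e-8, -1e-8)) {
    near <- two_step_profile(t, two_step_model(0.01, 0.01 * (1 + eps)))
    conf <- two_step_profile(t, two_step_model(0.01, 0.01))
    expect_lt(max(abs(near$Inter - conf$Inter)), 1e-6)
  }
  # both zero rate constants: nothing ever reacts
  frozen <- two_step_profile(c(0, 50), two_step_model(0, 0))
  expect_equal(frozen$API, c(1, 1))
})

test_that("profiles agree with a numerical ODE integrator", {
  t <- c(0, 7, 33.3, 79, 120)
  for (k1 in c(0.001, 0.022, 0.1)) {
    for (k2 in c(0.001, 0.003, 0.1)) {
      cf <- as.matrix(two_step_profile(t, two_step_model(k1, k2))[, -1])
      ode <- ode_two_step(t, k1, k2)
      expect_lt(max(abs(cf - ode)), 1e-8)
    }
  }
  # the first degradation stage is nearly over after 79 months at the
  # tablet-scale first-stage rate
  p79 <- two_step_profile(79, two_step_model(0.022, 0.003))
  expect_equal(p79$API, 0.176, tolerance = 5e-3)
})

test_that("rate-constant estimation is exact on noiseless profiles", {
  t <- seq(0, 120, length.out = 24)
  conc <- two_step_profile(t, two_step_model(0.05, 0.01))[, -1]
  fit <- fit_rate_constants(conc, t)
  expect_equal(fit$k1, 0.05, tolerance = 1e-6)
  expect_equal(fit$k2, 0.01, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  # a frozen second stage is detected as k2 ~ 0
  conc0 <- two_step_profile(t, two_step_model(0.04, 0))[, -1]
  expect_lt(fit_rate_constants(conc0, t)$k2, 1e-4)

  expect_error(fit_rate_constants(conc, t[1:3]), "length")
  expect_error(fit_rate_constants(conc * NA, t), "finite")
  expect_error(fit_rate_constants(conc[1:2, ], t[c(1, 1)]), "distinct")
})

test_that("rate constants are recovered from noisy concentrations", {
  t <- seq(0, 120, length.out = 36)
  truth <- as.matrix(two_step_profile(t, two_step_model(0.023, 0.01))[, -1])
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    noisy <- truth + matrix(rnorm(length(truth), sd = 0.01), nrow = nrow(truth))
    fit <- fit_rate_constants(noisy, t)
    c(abs(fit$k1 / 0.023 - 1), abs(fit$k2 / 0.01 - 1))
  })
  expect_true(all(errs < 0.10))
})

test_that("estimation error shrinks as concentration noise shrinks", {
  t <- seq(0, 120, length.out = 36)
  truth <- as.matrix(two_step_profile(t, two_step_model(0.023, 0.01))[, -1])
  err_at <- function(sd) {
    mean(sapply(1:5, function(s) {
      set.seed(100 + s)
      noisy <- truth + matrix(rnorm(length(truth), sd = sd), nrow = nrow(truth))
      fit <- fit_rate_constants(noisy, t)
      abs(fit$k1 / 0.023 - 1) + abs(fit$k2 / 0.01 - 1)
    }))
  }
  e <- c(err_at(0), err_at(0.01), err_at(0.05))
  expect_true(e[1] <= e[2] && e[2] <= e[3])
  expect_lt(e[1], 1e-6)
})

test_that("joint fits honour the shared-k1 hypothesis and nesting", {
  t_tab <- rep(c(0, 9, 18, 76, 79), 2)
  t_sub <- seq(0, 120, length.out = 12)
  c_tab <- two_step_profile(t_tab, two_step_model(0.022, 0.003))[, -1]
  c_sub <- two_step_profile(t_sub, two_step_model(0.022, 0.003))[, -1]
  joint <- fit_joint(c_tab, t_tab, c_sub, t_sub)
  split <- fit_joint(c_tab, t_tab, c_sub, t_sub, share_k1 = FALSE)
  # identical generating constants: shared and split fits agree
  expect_equal(joint$k1, split$k1, tolerance = 1e-3)
  expect_equal(joint$k21, joint$k22, tolerance = 1e-3)
  # nesting: pooling everything cannot beat the split model
  expect_gte(joint$rss_shared_all + 1e-12, joint$rss_split)
  expect_gte(joint$rss + 1e-12, joint$rss_split)

  set.seed(5)
  noisy_tab <- as.matrix(two_step_profile(t_tab, two_step_model(0.022, 0.003))[, -1]) +
    matrix(rnorm(3 * length(t_tab), sd = 0.01), ncol = 3)
  noisy_sub <- as.matrix(two_step_profile(t_sub, two_step_model(0.022, 0.007))[, -1]) +
    matrix(rnorm(3 * length(t_sub), sd = 0.01), ncol = 3)
  jn <- fit_joint(noisy_tab, t_tab, noisy_sub, t_sub)
  expect_lt(abs(jn$k1 / 0.022 - 1), 0.10)
  expect_lt(abs(jn$k21 / 0.003 - 1), 0.10)
  expect_lt(abs(jn$k22 / 0.007 - 1), 0.10)
  expect_gte(jn$rss + 1e-12, jn$rss_split)
})

test_that("time-point adjustment recovers jittered ages and nests the plain fit", {
  t_true <- seq(0, 120, length.out = 24)
  conc <- two_step_profile(t_true, two_step_model(0.023, 0.01))[, -1]

  # exact nominal ages: the penalty keeps the optimum at nominal
  fit0 <- adjust_time_points(conc, t_true, bound_months = 6)
  expect_equal(fit0$adjusted_times, t_true, tolerance = 1e-4)
  expect_equal(fit0$k1, 0.023, tolerance = 1e-4)

  # bound 0 reduces exactly to the plain fit
  plain <- fit_rate_constants(conc, t_true)
  bound0 <- adjust_time_points(conc, t_true, bound_months = 0)
  expect_identical(bound0$k1, plain$k1)
  expect_identical(bound0$k2, plain$k2)

  # jittered nominal ages, noiseless concentrations
  set.seed(11)
  nominal <- pmax(0, t_true + runif(24, -6, 6))
  fitj <- adjust_time_points(conc, nominal, bound_months = 6)
  expect_lt(abs(fitj$k1 / 0.023 - 1), 0.02)
  expect_lt(abs(fitj$k2 / 0.01 - 1), 0.02)
  expect_true(all(abs(fitj$adjusted_times - nominal) <= 6 + 1e-8))
})

test_that("kinetic fits expose tidy, glance and augment views", {
  t <- seq(0, 100, length.out = 12)
  conc <- two_step_profile(t, two_step_model(0.03, 0.005))[, -1]
  fit <- fit_rate_constants(conc, t)
  td <- tidy(fit)
  expect_identical(td$term, c("k1", "k2"))
  expect_equal(td$estimate, c(fit$k1, fit$k2))
  gl <- glance(fit)
  expect_equal(gl$n, 12)
  aug <- augment(fit)
  expect_equal(nrow(aug), 36)
  expect_lt(max(abs(aug$observed - aug$fitted)), 1e-6)
})
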