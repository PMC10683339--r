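test_that("iq and miq main-effect fits coincide on exact stage-2 data", {
  tr <- noiseless_trial(20)
  s2 <- fit_stage2(tr, spec2_z1())
  fi <- fit_main_effect(tr, s2, spec1_z1(), "iq")
  fm <- fit_main_effect(tr, s2, spec1_z1(), "miq")
  expect_equal(fi$coef, fm$coef, tolerance = 1e-8)
})

test_that("the miq response strips the received arm's contrast from the outcome", {
  s2 <- fit_stage2(noiseless_trial(), spec2_z1()) # contrast t = 3 - z1
  tr <- tibble::tibble(z1 = 0, a1 = c(1, -1), z2 = 0, rerandomized = TRUE,
                       a2 = 1, y = 10)
  # response for both subjects is 10 - (+1) * 3 = 7: an intercept-only check
  fit <- fit_main_effect(tr, s2, model_spec(1), "miq")
  expect_equal(unname(fit$coef), c(7, 0), tolerance = 1e-10)
})

test_that("the g regression recovers the contrast's conditional scale", {
  # exact linear contrast: zero residual scale, all-zero pool
  tr <- noiseless_trial(20)
  tr$z2 <- tr$z1 # contrast 3 - z1 is linear in the stage-1 design
  s2 <- fit_stage2(tr, spec2_z1())
  gn <- fit_g(tr, s2, spec1_z1(), "normal")
  ge <- fit_g(tr, s2, spec1_z1(), "empirical")
  expect_equal(gn$sigma, 0, tolerance = 1e-8)
  expect_equal(ge$residual_pool, rep(0, 20), tolerance = 1e-8)

  # contrast t = z2 = z1 + e with e ~ N(0, 4): sigma-hat near 2
  n <- 20000
  base <- sim_trial(n, c1 = 0, c2 = 0, seed = 21)
  tr2 <- base
  tr2$y <- tr2$a2 * tr2$z2 # exact fit: beta1 = (0, 1) on effect = z2
  s2b <- fit_stage2(tr2, model_spec(2, effect = "z2"))
  gb <- fit_g(tr2, s2b, spec1_z1(), "normal")
  expect_equal(gb$sigma, 2, tolerance = 3 / sqrt(2 * n) * 2)
  # OLS residual pool with an intercept averages to zero
  gb_e <- fit_g(tr2, s2b, spec1_z1(), "empirical")
  expect_equal(mean(gb_e$residual_pool), 0, tolerance = 1e-10)
})

test_that("the folded-normal mean dominates |mu|, increases with sigma", {
  expect_equal(folded_normal_mean(0, 1), sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(folded_normal_mean(-3, 0), 3)
  grid <- expand.grid(mu = seq(-4, 4, by = 0.5), sigma = c(0.2, 1, 2, 5))
  ev <- folded_normal_mean(grid$mu, grid$sigma)
  expect_true(all(ev >= abs(grid$mu)))
  for (mu in c(-2, 0, 1.3)) {
    expect_true(all(diff(folded_normal_mean(mu, seq(0, 5, by = 0.25))) >= -1e-12))
  }
})

test_that("a degenerate empirical pool reduces the expected |contrast| to |mu|", {
  tr <- noiseless_trial(20)
  tr$z2 <- tr$z1
  s2 <- fit_stage2(tr, spec2_z1())
  ge <- fit_g(tr, s2, spec1_z1(), "empirical")
  ge$residual_pool <- rep(0, 20)
  d <- build_design(tr, spec1_z1(), a = 1)
  mu <- drop(d$full %*% ge$mu_coef)
  expect_equal(expected_abs(ge, tr, 1), abs(mu))
})

test_that("the interactive Q-function composes m-hat and the expected |contrast|", {
  tr <- noiseless_trial(20)
  s2 <- fit_stage2(tr, spec2_z1())
  m <- fit_main_effect(tr, s2, spec1_z1(), "miq")
  g <- fit_g(tr, s2, spec1_z1(), "normal")
  # degenerate g at 0: Q1 equals the main-effect prediction
  g0 <- g
  g0$mu_coef[] <- 0
  g0$sigma <- 0
  d <- build_design(tr, spec1_z1(), a = -1)
  expect_equal(q1_interactive(m, g0, tr, -1), drop(d$full %*% m$coef))
  # standard-normal g: constant offset sqrt(2/pi)
  g1 <- g0
  g1$sigma <- 1
  expect_equal(q1_interactive(m, g1, tr, -1),
               drop(d$full %*% m$coef) - sqrt(2 / pi))
})

test_that("normal and empirical expected |contrast| match a sampling oracle", {
  tr <- sim_trial(300, c1 = 2, c2 = 2, seed = 17)
  s2 <- fit_stage2(tr, model_spec(2, main = c("z1", "a1", "z2"),
                                  effect = c("z1", "a1", "z2")))
  gn <- fit_g(tr, s2, spec1_z1(), "normal")
  sub <- tr[1:5, ]
  ea <- expected_abs(gn, sub, 1)
  d <- build_design(sub, spec1_z1(), a = 1)
  mu <- drop(d$full %*% gn$mu_coef)
  withr::with_seed(99, z <- rnorm(2e6))
  mc <- vapply(mu, function(m) mean(abs(m + gn$sigma * z)), numeric(1))
  expect_equal(ea, mc, tolerance = 5e-3)

  ge <- fit_g(tr, s2, spec1_z1(), "empirical")
  eae <- expected_abs(ge, sub, 1)
  de <- build_design(sub, spec1_z1(), a = 1)
  mue <- drop(de$full %*% ge$mu_coef)
  oracle <- vapply(mue, function(m) mean(abs(m + ge$residual_pool)), numeric(1))
  expect_equal(eae, oracle, tolerance = 1e-12)
})

test_that("interactive stage-1 rules agree with enumeration across random fits", {
  set.seed(1)
  for (s in 1:20) {
    tr <- sim_trial(80, c1 = runif(1, -2, 4), c2 = runif(1, 0, 3), seed = 500 + s)
    fit <- fit_dtr(tr, method = sample(c("IQ", "mIQ"), 1),
                   g_kind = sample(c("normal", "empirical"), 1))
    q_m <- q1_value(fit, tr, -1)
    q_p <- q1_value(fit, tr, +1)
    expect_equal(rule_stage1(fit, tr), ifelse(q_p < q_m, 1, -1))
  }
})

test_that("iq and miq agree when the stage-2 model is saturated and noiseless", {
  tr <- noiseless_trial(24)
  fi <- fit_dtr(tr, method = "IQ")
  fm <- fit_dtr(tr, method = "mIQ")
  expect_equal(q1_value(fi, tr, tr$a1), q1_value(fm, tr, tr$a1),
               tolerance = 1e-8)
})

test_that("the g regression can include or exclude non-re-randomized rows", {
  tr <- tailored_trial(24)
  s2 <- fit_stage2(tr, spec2_z1())
  g_rer <- fit_g(tr, s2, spec1_z1(), "empirical", g_rows = "rerandomized")
  g_all <- fit_g(tr, s2, spec1_z1(), "empirical", g_rows = "all")
  expect_length(g_rer$residual_pool, sum(tr$rerandomized))
  expect_length(g_all$residual_pool, nrow(tr))
})
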