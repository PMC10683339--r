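test_that("noiseless stage-2 data are recovered exactly", {
  tr <- noiseless_trial()
  fit <- fit_stage2(tr, spec2_z1())
  expect_equal(unname(fit$beta0), c(1, 2), tolerance = 1e-10)
  expect_equal(unname(fit$beta1), c(3, -1), tolerance = 1e-10)
  expect_equal(fit$resid_sd, 0, tolerance = 1e-8)
  expect_equal(fit$n_fit, nrow(tr))
})

test_that("the stage-2 fit uses re-randomized subjects only", {
  tr <- tailored_trial(16)
  fit <- fit_stage2(tr, spec2_z1())
  expect_equal(fit$n_fit, sum(tr$rerandomized))
  expect_equal(unname(fit$beta0), c(1, 2), tolerance = 1e-10)
  expect_error(fit_stage2(tr[tr$rerandomized, ][1:4, ], spec2_z1()),
               "re-randomized subjects")
})

test_that("the contrast equals an independent row-wise computation", {
  tr <- sim_trial(40, c1 = 1, c2 = 2, seed = 3)
  fit <- fit_stage2(tr, model_spec(2, main = c("z1", "a1", "z2"),
                                   effect = c("z1", "a1", "z2")))
  tt <- stage2_contrast(fit, tr)
  byrow <- vapply(seq_len(nrow(tr)), function(i) {
    sum(c(1, tr$z1[i], tr$a1[i], tr$z2[i]) * fit$beta1)
  }, numeric(1))
  expect_equal(tt, byrow, tolerance = 1e-12)
  # zero effect block gives an identically zero contrast
  fit0 <- fit
  fit0$beta1[] <- 0
  expect_equal(stage2_contrast(fit0, tr), rep(0, nrow(tr)))
})

test_that("the optimal-arm rule follows the sgn convention, ties to -1", {
  expect_equal(rule_from_contrast(c(2.5, -0.1, 0)), c(-1, 1, -1))
})

test_that("stage rules agree with exhaustive two-arm enumeration", {
  tr <- sim_trial(60, c1 = 2, c2 = 2, seed = 8)
  for (m in c("Q", "mQ", "IQ", "mIQ")) {
    fit <- fit_dtr(tr, method = m)
    enum <- ifelse(q1_value(fit, tr, +1) < q1_value(fit, tr, -1), 1, -1)
    expect_equal(rule_stage1(fit, tr), enum)
    # stage 2: the rule minimizes a2 * contrast over the two codes
    tt <- stage2_contrast(fit$stage2, tr)
    enum2 <- ifelse((+1) * tt < (-1) * tt, 1, -1)
    expect_equal(rule_from_contrast(tt), enum2)
  }
})

test_that("pseudo-outcomes implement regret adjustment per the two-arm enumeration", {
  # subjects with known contrasts t = 3 - z1 under the noiseless fit
  fit <- fit_stage2(noiseless_trial(), spec2_z1())
  tr <- tibble::tibble(z1 = c(5, 1), a1 = c(1, -1), z2 = 0,
                       rerandomized = TRUE, a2 = c(1, 1), y = 10)
  tt <- stage2_contrast(fit, tr)
  expect_equal(tt, c(-2, 2), tolerance = 1e-10)

  mq <- pseudo_outcome(fit, tr, "mQ")
  # independent oracle: regret = min_{a2} a2*t - A2*t, enumerated
  regret <- pmin(tt, -tt) - tr$a2 * tt
  expect_equal(mq, tr$y + regret, tolerance = 1e-10)
  # t = -2 with A2 = +1: already optimal, regret 0
  expect_equal(mq[1], 10)
  # t = +2 with A2 = +1: regret -4 applied on top of -|t|... outcome 6
  expect_equal(mq[2], 10 - 2 - 2)

  # Q replaces the outcome by the fitted optimum
  q <- pseudo_outcome(fit, tr, "Q")
  m0 <- 1 + 2 * tr$z1
  expect_equal(q, m0 - abs(tt), tolerance = 1e-10)
})

test_that("regret is nonpositive with equality iff the optimal arm was taken", {
  tr <- sim_trial(200, c1 = 1, c2 = 2, seed = 12)
  fit <- fit_stage2(tr, model_spec(2, main = c("z1", "a1", "z2"),
                                   effect = c("z1", "a1", "z2")))
  adj <- pseudo_outcome(fit, tr, "mQ") - tr$y
  expect_true(all(adj <= 1e-12))
  took_opt <- tr$a2 == rule_from_contrast(stage2_contrast(fit, tr))
  expect_equal(abs(adj) < 1e-12, took_opt)
})

test_that("non-re-randomized subjects keep their observed outcome", {
  tr <- tailored_trial(16)
  fit <- fit_stage2(tr, spec2_z1())
  for (m in c("Q", "mQ")) {
    ps <- pseudo_outcome(fit, tr, m)
    expect_equal(ps[!tr$rerandomized], tr$y[!tr$rerandomized])
  }
})

test_that("stage-1 fit recovers an exactly linear pseudo-outcome", {
  tr <- noiseless_trial(10)
  pseudo <- 2 - 3 * tr$z1 + tr$a1 * (0.5 + 1.5 * tr$z1)
  fit <- fit_stage1(pseudo, tr, spec1_z1())
  expect_equal(unname(fit$beta0), c(2, -3), tolerance = 1e-10)
  expect_equal(unname(fit$beta1), c(0.5, 1.5), tolerance = 1e-10)
  expect_equal(fit$resid_sd, 0, tolerance = 1e-8)

  # 6-row instance against the explicit normal equations
  tr6 <- tibble::tibble(z1 = c(-2.1, -0.4, 0.8, 1.6, -1.2, 0.1),
                        a1 = c(-1, 1, -1, 1, 1, -1),
                        rerandomized = TRUE)
  ps6 <- c(4.2, 1.1, -0.3, 2.2, 0.9, 1.4)
  d <- build_design(tr6, spec1_z1())
  oracle <- unname(drop(solve(t(d$full) %*% d$full, t(d$full) %*% ps6)))
  f6 <- fit_stage1(ps6, tr6, spec1_z1())
  expect_equal(unname(c(f6$beta0, f6$beta1)), oracle, tolerance = 1e-10)
})

test_that("Q and mQ coincide when the stage-2 fit is exact", {
  tr <- noiseless_trial(20)
  fq <- fit_dtr(tr, method = "Q")
  fm <- fit_dtr(tr, method = "mQ")
  expect_equal(fq$stage1$beta0, fm$stage1$beta0, tolerance = 1e-8)
  expect_equal(fq$stage1$beta1, fm$stage1$beta1, tolerance = 1e-8)
})

test_that("stage-2 rules are invariant to positive rescaling of the effect block", {
  tr <- sim_trial(50, c1 = 0, c2 = 1, seed = 6)
  fit <- fit_stage2(tr, model_spec(2, main = c("z1", "a1", "z2"),
                                   effect = c("z1", "a1", "z2")))
  scaled <- fit
  scaled$beta1 <- 7.3 * fit$beta1
  expect_equal(rule_from_contrast(stage2_contrast(scaled, tr)),
               rule_from_contrast(stage2_contrast(fit, tr)))
})

test_that("fitted regimes tidy, summarize, predict and serialize", {
  tr <- sim_trial(120, c1 = 2, c2 = 1, seed = 13)
  fit <- fit_dtr(tr, method = "mIQ")
  td <- tidy(fit)
  expect_true(all(c("stage", "component", "term", "estimate") %in% names(td)))
  expect_equal(sum(td$component == "q2"), 8L)
  gl <- glance(fit)
  expect_equal(gl$method, "mIQ")
  expect_equal(gl$n_stage2, 120L)

  pr <- predict(fit, tr)
  expect_setequal(unique(pr$d1), c(-1, 1))
  expect_true(all(pr$d2 %in% c(-1, 1)))

  js <- jsonlite::fromJSON(write_dtr_json(fit))
  expect_equal(js$method, "mIQ")
  expect_equal(js$g$kind, "normal")
  expect_length(js$stage2$beta1, 4L)

  fq <- fit_dtr(tr, method = "Q")
  jq <- jsonlite::fromJSON(write_dtr_json(fq))
  expect_length(jq$stage1$beta0, 2L)
})
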