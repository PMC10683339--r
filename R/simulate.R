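# Deterministic substream seeds: one master seed spawns named streams so the
# population draw and each replicate use independent, order-insensitive seeds.
# Lehmer-style mixing kept below 2^31 (R integers are 32-bit).
substream_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) + 11) %% 2147483647
  }
  as.integer(s) + 1L
}

scenario_key <- function(c1, c2) c(round(c1 * 1000), round(c2 * 1000))

# Generative truth: the main-effect and treatment-contrast surfaces.
truth_main <- function(z1, a1, z2, c1) {
  3 - z1 + 0.1 * a1 - 0.1 * z2 + c1 * z1 * a1
}
truth_contrast <- function(z1, a1, z2) {
  -6 - 4 * z1 + 5 * a1 - 0.2 * z2
}

#' Simulate a two-stage SMART with heterogeneous effects at both stages
#'
#' Generates `n` trajectories from the study's generative law:
#' \eqn{Z_1 \sim N(-2, 1)}, \eqn{Z_2 = Z_1 + \phi}, \eqn{\phi \sim N(0, 4)},
#' \eqn{A_1, A_2} balanced on \eqn{\{-1, +1\}}, and
#' \deqn{Y = 3 - Z_1 + 0.1 A_1 - 0.1 Z_2 + c_1 Z_1 A_1
#'   + c_2 A_2 (-6 - 4 Z_1 + 5 A_1 - 0.2 Z_2) + \varepsilon,}
#' \eqn{\varepsilon \sim N(0, 1)}, smaller \eqn{Y} preferred. `c1` scales
#' the stage-1 treatment-by-covariate interaction (the term a conventional
#' stage-2 main-effect model omits); `c2` scales the stage-2
#' treatment-effect heterogeneity. All subjects are re-randomized (no
#' embedded tailoring in this design).
#'
#' @param n Sample size.
#' @param c1,c2 Heterogeneity scales for stages 1 and 2.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A trajectory tibble with columns `id`, `z1`, `a1`, `z2`,
#'   `rerandomized`, `a2`, `y`.
#' @examples
#' sim_trial(5, c1 = 0, c2 = 1, seed = 1)
#' @export
sim_trial <- function(n, c1 = 0, c2 = 1, seed = 1) {
  withr::with_seed(seed, {
    z1 <- rnorm(n, mean = -2, sd = 1)
    z2 <- z1 + rnorm(n, mean = 0, sd = 2)
    a1 <- 2 * rbinom(n, 1, 0.5) - 1
    a2 <- 2 * rbinom(n, 1, 0.5) - 1
    eps <- rnorm(n, 0, 1)
  })
  y <- truth_main(z1, a1, z2, c1) + c2 * a2 * truth_contrast(z1, a1, z2) + eps
  tibble(id = seq_len(n), z1 = z1, a1 = as.numeric(a1), z2 = z2,
         rerandomized = TRUE, a2 = as.numeric(a2), y = y)
}

#' Construct the evaluation population with known potential outcomes
#'
#' Draws `N` subjects' covariates from the generative law and tabulates
#' the expected potential outcome \eqn{\mu_i(a_1, a_2)} (noise excluded)
#' under each of the four regimes \eqn{(a_1, a_2) \in \{-1,+1\}^2}. The
#' true optimal rules minimize \eqn{\mu_i} over the four cells,
#' conditional on the subject's realized \eqn{(z_1, z_2)} — so attainable
#' stage-1 accuracy is below 1, since a stage-1 decision cannot see
#' \eqn{z_2}. Ties go to arm `-1`.
#'
#' @param N Population size.
#' @inheritParams sim_trial
#' @return A `dtr_population` tibble with columns `z1`, `z2`,
#'   `mu_mm`, `mu_mp`, `mu_pm`, `mu_pp` (first suffix \eqn{a_1}, second
#'   \eqn{a_2}; `m` = `-1`, `p` = `+1`), `d1_true`, `d2_true`, `v_opt`.
#' @export
sim_population <- function(N, c1 = 0, c2 = 1, seed = 1) {
  withr::with_seed(seed, {
    z1 <- rnorm(N, mean = -2, sd = 1)
    z2 <- z1 + rnorm(N, mean = 0, sd = 2)
  })
  mu_cell <- function(a1, a2) {
    truth_main(z1, a1, z2, c1) + c2 * a2 * truth_contrast(z1, a1, z2)
  }
  mu_mm <- mu_cell(-1, -1)
  mu_mp <- mu_cell(-1, +1)
  mu_pm <- mu_cell(+1, -1)
  mu_pp <- mu_cell(+1, +1)
  best_m <- pmin(mu_mm, mu_mp)
  best_p <- pmin(mu_pm, mu_pp)
  d1_true <- ifelse(best_p < best_m, 1, -1)
  d2_true <- ifelse(d1_true == 1,
                    ifelse(mu_pp < mu_pm, 1, -1),
                    ifelse(mu_mp < mu_mm, 1, -1))
  out <- tibble(z1 = z1, z2 = z2,
                mu_mm = mu_mm, mu_mp = mu_mp, mu_pm = mu_pm, mu_pp = mu_pp,
                d1_true = d1_true, d2_true = d2_true,
                v_opt = pmin(best_m, best_p))
  class(out) <- c("dtr_population", class(out))
  out
}

#' Probability of correctly identified stage-1 rules
#'
#' Fraction of the population whose estimated stage-1 arm matches the true
#' optimal arm.
#'
#' @param d1_hat Estimated stage-1 codes over the population.
#' @param population A [sim_population()] tibble.
#' @return A number in `[0, 1]`.
#' @export
pci <- function(d1_hat, population) {
  stopifnot(length(d1_hat) == nrow(population))
  mean(d1_hat == population$d1_true)
}

#' Bias of the estimated optimal value
#'
#' Population average of \eqn{\hat Q_1(z_{1i}, \hat d_{1i}) - v^{opt}_i}:
#' the learner's own estimate of the outcome achievable under its regime,
#' minus the true optimal value. Outcomes are minimized, so a positive
#' bias means the learner's claimed achievable level sits above (worse
#' than) the true optimum.
#'
#' @param fit A `dtr_fit`.
#' @param population A [sim_population()] tibble.
#' @return A single number.
#' @export
value_bias <- function(fit, population) {
  d1_hat <- rule_stage1(fit, population)
  q1_hat <- q1_value(fit, population, d1_hat)
  mean(q1_hat - population$v_opt)
}

#' Fit and score one learner against the evaluation population
#'
#' @param fit A `dtr_fit`.
#' @param population A [sim_population()] tibble.
#' @return A one-row tibble with `method`, `pci`, `value_bias`.
#' @export
evaluate_dtr <- function(fit, population) {
  d1_hat <- rule_stage1(fit, population)
  q1_hat <- q1_value(fit, population, d1_hat)
  tibble(method = fit$method,
         pci = mean(d1_hat == population$d1_true),
         value_bias = mean(q1_hat - population$v_opt))
}

sim_spec1 <- function() model_spec(1, main = "z1", effect = "z1")
sim_spec2 <- function() {
  model_spec(2, main = c("z1", "a1", "z2"), effect = c("z1", "a1", "z2"))
}

#' Replicated evaluation of the four learners at one scenario
#'
#' Builds one evaluation population for the scenario (shared across
#' replicates and methods; its seed derives deterministically from
#' `(seed, c1, c2)`), then for each replicate draws a fresh trial of size
#' `n`, fits each requested learner with the study's model
#' specifications — stage 2: main and effect blocks `(1, z1, a1, z2)`;
#' stage 1: `(1, z1)` — and records the stage-1 accuracy and value bias
#' against the population. Replicate seeds are independent substreams, so
#' method order cannot change any result.
#'
#' @param c1,c2 Scenario heterogeneity scales.
#' @param n Trial size per replicate.
#' @param N Population size.
#' @param reps Number of replicates.
#' @param seed Master seed.
#' @param methods Learners to fit.
#' @param g_kind Contrast-distribution model for the interactive learners.
#' @param spec1,spec2 Model specifications (defaults: the study's).
#' @return A tibble with one row per replicate and method: `c1`, `c2`,
#'   `rep`, `method`, `pci`, `value_bias`.
#' @export
run_scenario <- function(c1, c2, n = 250, N = 10000, reps = 1000, seed = 1,
                         methods = c("Q", "mQ", "IQ", "mIQ"),
                         g_kind = "normal",
                         spec1 = sim_spec1(), spec2 = sim_spec2()) {
  key <- scenario_key(c1, c2)
  pop <- sim_population(N, c1, c2, seed = substream_seed(seed, 1, key))
  purrr::map_dfr(seq_len(reps), function(r) {
    trial <- sim_trial(n, c1, c2, seed = substream_seed(seed, 2, key, r))
    purrr::map_dfr(methods, function(m) {
      fit <- fit_dtr(trial, spec1 = spec1, spec2 = spec2,
                     method = m, g_kind = g_kind)
      dplyr::bind_cols(tibble(c1 = c1, c2 = c2, rep = r), evaluate_dtr(fit, pop))
    })
  })
}

#' Scenario grid: mean and spread of value bias and stage-1 accuracy
#'
#' Runs [run_scenario()] over the cross of `c1` and `c2` values and
#' aggregates to replicate means and standard deviations — the layout of
#' the simulation study's bias table, one row per scenario and method.
#'
#' @param c1,c2 Vectors of heterogeneity scales to cross.
#' @inheritParams run_scenario
#' @return A `dtr_grid` tibble with columns `c1`, `c2`, `method`,
#'   `bias_mean`, `bias_sd`, `pci_mean`, `pci_sd`, `reps`; attributes
#'   `n`, `N`, `seed`.
#' @examples
#' \donttest{
#' grid <- run_grid(c1 = c(0, 2), c2 = c(1, 3), reps = 20, seed = 1)
#' autoplot(grid)
#' }
#' @export
run_grid <- function(c1 = c(0, 2, 4), c2 = c(1, 2, 3),
                     n = 250, N = 10000, reps = 1000, seed = 1,
                     methods = c("Q", "mQ", "IQ", "mIQ"),
                     g_kind = "normal",
                     spec1 = sim_spec1(), spec2 = sim_spec2()) {
  cells <- tidyr::expand_grid(c1 = c1, c2 = c2)
  out <- purrr::pmap_dfr(cells, function(c1, c2) {
    run_scenario(c1, c2, n = n, N = N, reps = reps, seed = seed,
                 methods = methods, g_kind = g_kind,
                 spec1 = spec1, spec2 = spec2) |>
      dplyr::group_by(.data$c1, .data$c2, .data$method) |>
      dplyr::summarise(
        bias_mean = mean(.data$value_bias),
        bias_sd = stats::sd(.data$value_bias),
        pci_mean = mean(.data$pci),
        pci_sd = stats::sd(.data$pci),
        reps = dplyr::n(),
        .groups = "drop"
      )
  })
  out$method <- factor(out$method, levels = methods)
  out <- dplyr::arrange(out, .data$c1, .data$c2, .data$method)
  attr(out, "n") <- n
  attr(out, "N") <- N
  attr(out, "seed") <- seed
  class(out) <- c("dtr_grid", class(out))
  out
}

#' Omitted-variable-bias oracle for the stage-2 main-effect coefficients
#'
#' When the generative outcome surface contains a stage-1
#' treatment-by-covariate interaction (weight `gamma`, term `omitted`)
#' that the stage-2 model leaves out, the included OLS coefficients are
#' biased by the omitted-variable formula
#' \deqn{\mathrm{bias} = E(X^T X)^{-1}\, E(X^T V)\, \gamma,}
#' with \eqn{X} the full included design and \eqn{V} the omitted columns.
#' The moment matrices are computed by Monte Carlo over `mc_n` draws of
#' the covariate/treatment law (they do not depend on the outcome noise).
#' With `gamma = 0` the bias is exactly zero.
#'
#' @param gamma Weight(s) of the omitted term(s) in the generative truth
#'   (the study's interaction weight is `c1`).
#' @param omitted Character vector of omitted term(s), default `"z1:a1"`.
#' @param spec2 The (misspecified) stage-2 [model_spec()] actually fitted.
#' @param mc_n Monte-Carlo draws for the moment matrices.
#' @param seed Integer seed.
#' @return A tibble with `term` and `bias` for every included coefficient
#'   (main block then treatment block, intercepts first).
#' @examples
#' ovb_oracle(gamma = 2, mc_n = 20000, seed = 1)
#' @export
ovb_oracle <- function(gamma, omitted = "z1:a1", spec2 = sim_spec2(),
                       mc_n = 400000, seed = 1) {
  if (length(gamma) != length(omitted)) {
    abort("one weight per omitted term required")
  }
  draws <- sim_trial(mc_n, c1 = 0, c2 = 0, seed = seed)
  d <- build_design(draws, spec2)
  X <- d$full
  V <- do.call(cbind, lapply(omitted, resolve_term, data = draws))
  M <- crossprod(X) / mc_n
  if (kappa(M) > 1e12) {
    abort("moment matrix E(X'X) is numerically singular")
  }
  b <- (crossprod(X, V) / mc_n) %*% as.numeric(gamma)
  tibble(term = colnames(X), bias = unname(drop(solve(M, b))))
}
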