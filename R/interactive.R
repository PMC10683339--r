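#' Stage-1 main-effect regression for the interactive learners
#'
#' Regresses a main-effect response on the stage-1 design
#' `[M0 | a1 * M1]` over all subjects. The response for a re-randomized
#' subject is, by variant:
#' \describe{
#'   \item{`"iq"`}{the fitted stage-2 main effect
#'     \eqn{\tilde X_{20}^T \hat\beta_{20}} — a consistent estimate of
#'     \eqn{E(Y - A_2 \tilde X_{21}^T \psi_{21} \mid H_2)} only when the
#'     stage-2 main-effect model is correctly specified.}
#'   \item{`"miq"`}{the contrast-stripped outcome \eqn{Y - A_2 \hat t},
#'     which keeps any residual left by a misspecified stage-2 main-effect
#'     model (e.g. an omitted stage-1 treatment interaction) in the
#'     response, where the stage-1 design can absorb it.}
#' }
#' A non-re-randomized subject contributes their observed \eqn{Y} under
#' both variants.
#'
#' @param data Trajectory tibble.
#' @param stage2 A stage-2 `stage_fit`.
#' @param spec1 Stage-1 [model_spec()]; the same design serves the
#'   main-effect and g-location regressions so both are evaluable at
#'   either arm code.
#' @param variant `"iq"` or `"miq"`.
#' @return A `main_effect_fit` (coefficients over the stage-1 design,
#'   variant, rows used).
#' @export
fit_main_effect <- function(data, stage2, spec1, variant = c("miq", "iq")) {
  variant <- match.arg(variant)
  stopifnot(spec1$stage == 1L)
  rr <- data$rerandomized
  resp <- data$y
  if (variant == "miq") {
    tt <- stage2_contrast(stage2, data)
    resp[rr] <- data$y[rr] - data$a2[rr] * tt[rr]
  } else {
    M0 <- term_matrix(data, stage2$spec$main, "main")
    resp[rr] <- drop(M0 %*% stage2$beta0)[rr]
  }
  d <- build_design(data, spec1)
  fit <- ols_fit(d$full, resp)
  structure(list(coef = fit$coef, variant = variant,
                 n_fit = nrow(data), spec1 = spec1),
            class = "main_effect_fit")
}

#' Conditional distribution of the stage-2 contrast given stage-1 history
#'
#' Fits a location(-scale) model for
#' \eqn{g(\tilde X_{21}^T \psi_{21} \mid H_1, A_1)} by regressing the
#' estimated contrast \eqn{\hat t} on the stage-1 design. `"normal"`
#' stores the residual standard deviation \eqn{\hat\sigma} (constant
#' variance); `"empirical"` stores the pool of centered OLS residuals for
#' a location-shift empirical distribution — the nonparametric fallback
#' when the contrast residuals look non-normal.
#'
#' @inheritParams fit_main_effect
#' @param kind `"normal"` or `"empirical"`.
#' @param g_rows `"rerandomized"` (default) restricts the regression rows
#'   to re-randomized subjects — the contrast corrects a stage-2 choice
#'   those subjects actually faced; `"all"` uses every subject's contrast
#'   row (the contrast is a function of the stage-2 history, defined for
#'   all).
#' @return A `g_model` with `mu_coef`, and `sigma` or `residual_pool`.
#' @export
fit_g <- function(data, stage2, spec1, kind = c("normal", "empirical"),
                  g_rows = c("rerandomized", "all")) {
  kind <- match.arg(kind)
  g_rows <- match.arg(g_rows)
  stopifnot(spec1$stage == 1L)
  tt <- stage2_contrast(stage2, data)
  keep <- if (g_rows == "rerandomized") data$rerandomized else rep(TRUE, nrow(data))
  d <- build_design(data[keep, , drop = FALSE], spec1)
  fit <- ols_fit(d$full, tt[keep])
  resid <- tt[keep] - drop(d$full %*% fit$coef)
  structure(list(kind = kind,
                 mu_coef = fit$coef,
                 sigma = if (kind == "normal") fit$resid_sd else NA_real_,
                 residual_pool = if (kind == "empirical") resid else NULL,
                 spec1 = spec1),
            class = "g_model")
}

#' Mean absolute value of a normal variable (folded-normal mean)
#'
#' Closed form for \eqn{E|Z|} with \eqn{Z \sim N(\mu, \sigma^2)}:
#' \deqn{E|Z| = \sigma\sqrt{2/\pi}\,e^{-\mu^2/(2\sigma^2)}
#'   + \mu\{1 - 2\Phi(-\mu/\sigma)\},}
#' degenerating to \eqn{|\mu|} as \eqn{\sigma \to 0}. Vectorized over
#' `mu` and `sigma`.
#'
#' @param mu Mean(s).
#' @param sigma Standard deviation(s), `>= 0`.
#' @return \eqn{E|Z|}, always `>= abs(mu)` (Jensen).
#' @examples
#' folded_normal_mean(0, 1) # sqrt(2/pi)
#' @export
folded_normal_mean <- function(mu, sigma) {
  k <- pmax(length(mu), length(sigma))
  mu <- rep_len(as.numeric(mu), k)
  sigma <- rep_len(as.numeric(sigma), k)
  if (any(sigma < 0)) abort("sigma must be nonnegative")
  out <- abs(mu)
  pos <- sigma > 0
  if (any(pos)) {
    m <- mu[pos]
    s <- sigma[pos]
    out[pos] <- s * sqrt(2 / pi) * exp(-m^2 / (2 * s^2)) +
      m * (1 - 2 * pnorm(-m / s))
  }
  out
}

#' Expected absolute contrast under a fitted g model
#'
#' \eqn{\int |z| \hat g(z \mid h_1, a_1)\,dz} at each subject's stage-1
#' history and a given arm code: the folded-normal closed form for the
#' normal kind, the average \eqn{|\hat\mu + \hat e_j|} over the residual
#' pool for the empirical kind.
#'
#' @param g A `g_model`.
#' @param data Table with the stage-1 covariate columns.
#' @param a1 Arm code(s), scalar or one per row.
#' @return Numeric vector, one value per row.
#' @export
expected_abs <- function(g, data, a1) {
  stopifnot(inherits(g, "g_model"))
  d <- build_design(data, g$spec1, a = a1)
  mu <- drop(d$full %*% g$mu_coef)
  if (g$kind == "normal") {
    folded_normal_mean(mu, g$sigma)
  } else {
    pool <- g$residual_pool
    vapply(mu, function(m) mean(abs(m + pool)), numeric(1))
  }
}

#' Interactive stage-1 Q-function
#'
#' \eqn{\hat Q_1(h_1, a_1) = \hat m(h_1, a_1) - \int |z|\,
#' \hat g(z \mid h_1, a_1)\,dz}: the main-effect prediction minus the
#' expected absolute contrast (the expected benefit of optimal stage-2
#' assignment, since smaller outcomes are preferred).
#'
#' @param m A `main_effect_fit`.
#' @param g A `g_model` fitted with the same stage-1 spec.
#' @param data Table with the stage-1 covariate columns.
#' @param a1 Arm code(s), scalar or one per row.
#' @return Numeric vector of Q-values.
#' @export
q1_interactive <- function(m, g, data, a1) {
  stopifnot(inherits(m, "main_effect_fit"))
  d <- build_design(data, m$spec1, a = a1)
  drop(d$full %*% m$coef) - expected_abs(g, data, a1)
}
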