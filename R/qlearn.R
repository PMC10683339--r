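new_stage_fit <- function(fit, spec, n_fit) {
  p0 <- length(spec$main) + 1L
  p1 <- length(spec$effect) + 1L
  structure(
    list(beta0 = fit$coef[seq_len(p0)],
         beta1 = fit$coef[p0 + seq_len(p1)],
         n_fit = n_fit,
         resid_sd = fit$resid_sd,
         spec = spec),
    class = "stage_fit"
  )
}

#' @export
print.stage_fit <- function(x, ...) {
  cat(sprintf("<stage_fit stage %d> n = %d, residual sd = %.4g\n",
              x$spec$stage, x$n_fit, x$resid_sd))
  cat("  main:  ", paste(sprintf("%s=%.4g", names(x$beta0), x$beta0), collapse = ", "), "\n")
  cat("  effect:", paste(sprintf("%s=%.4g", names(x$beta1), x$beta1), collapse = ", "), "\n")
  invisible(x)
}

#' Fit the stage-2 Q-function
#'
#' OLS regression of the final outcome on `[M0 | a2 * M1]`, restricted to
#' re-randomized subjects: under embedded tailoring the non-re-randomized
#' subjects had no stage-2 choice, so they carry no information about the
#' stage-2 treatment effect.
#'
#' @param data Trajectory tibble.
#' @param spec2 A stage-2 [model_spec()].
#' @return A `stage_fit` with coefficient blocks `beta0` (main,
#'   intercept-first) and `beta1` (treatment, intercept-first).
#' @export
fit_stage2 <- function(data, spec2) {
  stopifnot(spec2$stage == 2L)
  sub <- data[data$rerandomized, , drop = FALSE]
  p <- length(spec2$main) + length(spec2$effect) + 2L
  if (nrow(sub) <= p) {
    abort(sprintf("stage-2 fit needs more than p = %d re-randomized subjects (have %d)",
                  p, nrow(sub)))
  }
  d <- build_design(sub, spec2)
  new_stage_fit(ols_fit(d$full, sub$y), spec2, nrow(sub))
}

#' Stage-2 treatment-effect contrast
#'
#' Evaluates \eqn{\hat t_i = \tilde X_{21,i}^T \hat\beta_{21}} for every
#' subject. The contrast is a function of the stage-2 history (which exists
#' for all subjects, re-randomized or not); its sign decides the optimal
#' stage-2 arm and its absolute value the benefit of optimal assignment.
#'
#' @param fit A stage-2 `stage_fit`.
#' @param data Trajectory tibble (any table containing the effect-term
#'   columns).
#' @return Numeric vector, one contrast per row of `data`.
#' @export
stage2_contrast <- function(fit, data) {
  stopifnot(inherits(fit, "stage_fit"), fit$spec$stage == 2L)
  M1 <- term_matrix(data, fit$spec$effect, "effect")
  drop(M1 %*% fit$beta1)
}

#' Optimal-arm rule from a contrast
#'
#' With arms coded `-1`/`+1` and smaller outcomes preferred, the optimal
#' arm minimizes \eqn{a \cdot t}, i.e. \eqn{d = -\mathrm{sgn}(t)} with the
#' convention \eqn{\mathrm{sgn}(0) = 1} so an exact tie deterministically
#' yields arm `-1`. (Ties are a probability-zero event under the usual
#' regularity condition but must still be decided reproducibly.)
#'
#' @param contrast Numeric vector of treatment-effect contrasts.
#' @return Vector of codes in `{-1, 1}`.
#' @export
rule_from_contrast <- function(contrast) {
  ifelse(contrast < 0, 1, -1)
}

#' Stage-1 pseudo-outcomes for the non-interactive learners
#'
#' Builds the response for the stage-1 regression from the stage-2 fit.
#' For a re-randomized subject:
#' \describe{
#'   \item{`"Q"`}{the fully fitted optimal value
#'     \eqn{\tilde X_{20}^T \hat\beta_{20} - |\hat t|} (standard
#'     Q-learning: the observed outcome is replaced by the model's
#'     prediction under the optimal stage-2 arm).}
#'   \item{`"mQ"`}{the regret-adjusted outcome
#'     \eqn{Y - A_2 \hat t - |\hat t|}: the observed outcome plus the
#'     estimated regret \eqn{\min_{a_2}(a_2 \hat t) - A_2 \hat t \le 0}
#'     of the arm actually received. This retains the stage-2 residual,
#'     so informative residuals from a misspecified stage-2 main-effect
#'     model are not thrown away.}
#' }
#' A non-re-randomized subject keeps \eqn{Y} unchanged under both methods:
#' their single stage-2 continuation is, by design, their optimal one.
#'
#' @param fit A stage-2 `stage_fit`.
#' @param data Trajectory tibble.
#' @param method `"Q"` or `"mQ"`.
#' @return Numeric vector of pseudo-outcomes, one per subject.
#' @export
pseudo_outcome <- function(fit, data, method = c("Q", "mQ")) {
  method <- match.arg(method)
  tt <- stage2_contrast(fit, data)
  rr <- data$rerandomized
  out <- data$y
  if (method == "Q") {
    M0 <- term_matrix(data, fit$spec$main, "main")
    main_hat <- drop(M0 %*% fit$beta0)
    out[rr] <- main_hat[rr] - abs(tt[rr])
  } else {
    out[rr] <- data$y[rr] - data$a2[rr] * tt[rr] - abs(tt[rr])
  }
  out
}

#' Fit the stage-1 Q-function by OLS
#'
#' Regresses a pseudo-outcome on `[M0 | a1 * M1]` over all subjects.
#'
#' @param pseudo Numeric pseudo-outcome, one per subject.
#' @param data Trajectory tibble.
#' @param spec1 A stage-1 [model_spec()].
#' @return A `stage_fit`.
#' @export
fit_stage1 <- function(pseudo, data, spec1) {
  stopifnot(spec1$stage == 1L)
  if (length(pseudo) != nrow(data)) abort("one pseudo-outcome per subject required")
  d <- build_design(data, spec1)
  new_stage_fit(ols_fit(d$full, pseudo), spec1, nrow(data))
}

stage1_contrast <- function(fit, data) {
  stopifnot(inherits(fit, "stage_fit"), fit$spec$stage == 1L)
  M1 <- term_matrix(data, fit$spec$effect, "effect")
  drop(M1 %*% fit$beta1)
}

#' Fit a two-stage dynamic treatment regime
#'
#' Backward-induction estimation of the optimal two-stage regime by one of
#' four learners sharing the same stage-2 OLS fit:
#' \describe{
#'   \item{`"Q"`}{standard Q-learning: stage-1 OLS on the fitted optimal
#'     value \eqn{\tilde X_{20}^T\hat\beta_{20} - |\hat t|}.}
#'   \item{`"mQ"`}{modified Q-learning: stage-1 OLS on the regret-adjusted
#'     outcome \eqn{Y - A_2\hat t - |\hat t|}, which keeps stage-2
#'     residuals in the response.}
#'   \item{`"IQ"`}{interactive Q-learning: a main-effect regression of
#'     \eqn{\tilde X_{20}^T\hat\beta_{20}} on the stage-1 design, plus a
#'     location-scale model for the conditional distribution of the
#'     contrast \eqn{\hat t} given stage-1 history; the stage-1 Q-function
#'     is \eqn{\hat m - E_{\hat g}|Z|}, avoiding the linearity assumption
#'     on \eqn{|\hat t|}.}
#'   \item{`"mIQ"`}{modified interactive Q-learning: as `"IQ"` but the
#'     main-effect response is \eqn{Y - A_2\hat t}, so omitted stage-1
#'     treatment-by-covariate interactions in the stage-2 main-effect
#'     model are absorbed through the residual instead of biasing the
#'     stage-1 fit.}
#' }
#'
#' @param data Trajectory tibble from [as_trial()], [read_trial()] or
#'   [sim_trial()].
#' @param spec1,spec2 Stage-1 and stage-2 [model_spec()]s.
#' @param method One of `"Q"`, `"mQ"`, `"IQ"`, `"mIQ"`.
#' @param g_kind For the interactive learners: `"normal"` (constant-variance
#'   normal contrast distribution; closed-form folded-normal expectation)
#'   or `"empirical"` (location shift with the pooled OLS residuals).
#' @param g_rows Which subjects' contrast rows enter the g regression:
#'   `"rerandomized"` (default) or `"all"`. Irrelevant without embedded
#'   tailoring.
#'
#' @return A `dtr_fit` object; see [tidy.dtr_fit()], [glance.dtr_fit()],
#'   [predict.dtr_fit()].
#' @examples
#' trial <- sim_trial(n = 300, c1 = 2, c2 = 1, seed = 1)
#' fit <- fit_dtr(trial, method = "mIQ")
#' glance(fit)
#' tidy(fit)
#' @export
fit_dtr <- function(data,
                    spec1 = model_spec(1, main = "z1", effect = "z1"),
                    spec2 = model_spec(2, main = c("z1", "a1", "z2"),
                                       effect = c("z1", "a1", "z2")),
                    method = c("Q", "mQ", "IQ", "mIQ"),
                    g_kind = c("normal", "empirical"),
                    g_rows = c("rerandomized", "all")) {
  method <- match.arg(method)
  g_kind <- match.arg(g_kind)
  g_rows <- match.arg(g_rows)
  stage2 <- fit_stage2(data, spec2)
  if (method %in% c("Q", "mQ")) {
    stage1 <- fit_stage1(pseudo_outcome(stage2, data, method), data, spec1)
    out <- list(method = method, stage2 = stage2, stage1 = stage1,
                m_fit = NULL, g_model = NULL, g_kind = "none",
                spec1 = spec1, spec2 = spec2, n = nrow(data))
  } else {
    variant <- if (method == "IQ") "iq" else "miq"
    m_fit <- fit_main_effect(data, stage2, spec1, variant)
    g_model <- fit_g(data, stage2, spec1, kind = g_kind, g_rows = g_rows)
    out <- list(method = method, stage2 = stage2, stage1 = NULL,
                m_fit = m_fit, g_model = g_model, g_kind = g_kind,
                spec1 = spec1, spec2 = spec2, n = nrow(data))
  }
  structure(out, class = "dtr_fit")
}

#' Evaluate the fitted stage-1 Q-function
#'
#' \eqn{\hat Q_1(h_1, a_1)}: for `"Q"`/`"mQ"` the fitted linear form; for
#' `"IQ"`/`"mIQ"` the interactive form \eqn{\hat m(h_1, a_1) -
#' E_{\hat g}|Z|}. Smaller is better.
#'
#' @param fit A `dtr_fit`.
#' @param data Table with the stage-1 covariate columns.
#' @param a1 Stage-1 arm code(s), scalar or one per row.
#' @return Numeric vector of Q-values, one per row.
#' @export
q1_value <- function(fit, data, a1) {
  stopifnot(inherits(fit, "dtr_fit"))
  if (fit$method %in% c("Q", "mQ")) {
    d <- build_design(data, fit$spec1, a = a1)
    drop(d$full %*% c(fit$stage1$beta0, fit$stage1$beta1))
  } else {
    q1_interactive(fit$m_fit, fit$g_model, data, a1)
  }
}

#' Estimated stage-1 decision rule
#'
#' Evaluates \eqn{\hat Q_1} at both arm codes and returns the minimizer
#' per subject; an exact tie yields `-1` (the same convention as
#' [rule_from_contrast()]). For the linear learners this reduces to
#' \eqn{-\mathrm{sgn}(\tilde X_{11}^T \hat\beta_{11})}.
#'
#' @inheritParams q1_value
#' @return Vector of codes in `{-1, 1}`.
#' @export
rule_stage1 <- function(fit, data) {
  stopifnot(inherits(fit, "dtr_fit"))
  if (fit$method %in% c("Q", "mQ")) {
    rule_from_contrast(stage1_contrast(fit$stage1, data))
  } else {
    q_m <- q1_value(fit, data, -1)
    q_p <- q1_value(fit, data, +1)
    ifelse(q_p < q_m, 1, -1)
  }
}

#' Predict optimal arms for new subjects
#'
#' @param object A `dtr_fit`.
#' @param newdata Table of subjects. The stage-1 rule needs the stage-1
#'   covariates; the stage-2 rule additionally needs the stage-2 history
#'   columns (including `a1`) and is returned only when they are present.
#' @param ... Unused.
#' @return A tibble with `id` (if present), `d1`, and `d2` (when
#'   computable).
#' @export
predict.dtr_fit <- function(object, newdata, ...) {
  out <- tibble(d1 = rule_stage1(object, newdata))
  if ("id" %in% names(newdata)) out <- dplyr::bind_cols(tibble(id = newdata$id), out)
  eff_cols <- unique(unlist(strsplit(object$spec2$effect, "[:*]")))
  if (all(trimws(eff_cols) %in% names(newdata))) {
    out$d2 <- rule_from_contrast(stage2_contrast(object$stage2, newdata))
  }
  out
}

#' @export
print.dtr_fit <- function(x, ...) {
  cat(sprintf("<dtr_fit> method %s, n = %d (stage 2: n = %d)\n",
              x$method, x$n, x$stage2$n_fit))
  print(x$stage2)
  if (!is.null(x$stage1)) {
    print(x$stage1)
  } else {
    cat(sprintf("  stage-1 main effect (%s): %s\n", x$m_fit$variant,
                paste(sprintf("%s=%.4g", names(x$m_fit$coef), x$m_fit$coef),
                      collapse = ", ")))
    if (x$g_model$kind == "normal") {
      cat(sprintf("  g: normal, sigma = %.4g\n", x$g_model$sigma))
    } else {
      cat(sprintf("  g: empirical, pool of %d residuals\n",
                  length(x$g_model$residual_pool)))
    }
  }
  invisible(x)
}

#' Tidy a fitted regime's coefficients
#'
#' @param x A `dtr_fit`.
#' @param ... Unused.
#' @return A tibble with columns `stage`, `component`, `block`, `term`,
#'   `estimate`: the stage-2 Q-function blocks, plus either the stage-1
#'   Q-function blocks (Q/mQ) or the stage-1 main-effect and g-location
#'   coefficients (IQ/mIQ).
#' @method tidy dtr_fit
#' @export
tidy.dtr_fit <- function(x, ...) {
  blocks <- list(
    tibble(stage = 2L, component = "q2", block = "main",
           term = names(x$stage2$beta0), estimate = unname(x$stage2$beta0)),
    tibble(stage = 2L, component = "q2", block = "effect",
           term = names(x$stage2$beta1), estimate = unname(x$stage2$beta1))
  )
  if (!is.null(x$stage1)) {
    blocks <- c(blocks, list(
      tibble(stage = 1L, component = "q1", block = "main",
             term = names(x$stage1$beta0), estimate = unname(x$stage1$beta0)),
      tibble(stage = 1L, component = "q1", block = "effect",
             term = names(x$stage1$beta1), estimate = unname(x$stage1$beta1))
    ))
  } else {
    blocks <- c(blocks, list(
      tibble(stage = 1L, component = "main_effect", block = "full",
             term = names(x$m_fit$coef), estimate = unname(x$m_fit$coef)),
      tibble(stage = 1L, component = "g_location", block = "full",
             term = names(x$g_model$mu_coef), estimate = unname(x$g_model$mu_coef))
    ))
  }
  dplyr::bind_rows(blocks)
}

#' One-row summary of a fitted regime
#'
#' @param x A `dtr_fit`.
#' @param ... Unused.
#' @return A tibble with `method`, `n`, `n_stage2`, `resid_sd_stage2`, and
#'   (interactive learners) `g_kind` and `g_sigma`.
#' @method glance dtr_fit
#' @export
glance.dtr_fit <- function(x, ...) {
  tibble(
    method = x$method,
    n = x$n,
    n_stage2 = x$stage2$n_fit,
    resid_sd_stage2 = x$stage2$resid_sd,
    g_kind = x$g_kind,
    g_sigma = if (identical(x$g_kind, "normal")) x$g_model$sigma else NA_real_
  )
}
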