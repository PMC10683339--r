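#' Plot a scenario grid
#'
#' Stage-1 rule accuracy (or value bias) against the stage-2 heterogeneity
#' scale, one line per learner, faceted by the stage-1 heterogeneity scale.
#'
#' @param object A `dtr_grid` from [run_grid()].
#' @param metric `"pci"` or `"bias"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dtr_grid
#' @export
autoplot.dtr_grid <- function(object, metric = c("pci", "bias"), ...) {
  metric <- match.arg(metric)
  ycol <- if (metric == "pci") "pci_mean" else "bias_mean"
  ylab <- if (metric == "pci") {
    "Probability of correctly identified stage-1 rules"
  } else {
    "Bias of the estimated optimal value"
  }
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$c2, y = .data[[ycol]],
    colour = .data$method, shape = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$c1),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Stage-2 heterogeneity scale (c2)", y = ylab,
                  colour = "Method", shape = "Method") +
    ggplot2::theme_bw()
}

#' Format a scenario grid as a bias table
#'
#' One row per `(c1, c2)` scenario, one "mean (SD)" column per learner.
#'
#' @param grid A `dtr_grid`.
#' @param digits Digits for mean and SD.
#' @return A tibble in wide layout.
#' @export
bias_table <- function(grid, digits = 2) {
  grid |>
    dplyr::mutate(cell = sprintf("%.*f (%.*f)", digits, .data$bias_mean,
                                 digits, .data$bias_sd)) |>
    dplyr::select("c1", "c2", "method", "cell") |>
    tidyr::pivot_wider(names_from = "method", values_from = "cell")
}

#' Serialize a fitted regime to JSON
#'
#' Writes the method, model specifications, coefficient blocks, fit sizes,
#' and g-model parameters so a fit can be archived or diffed across runs.
#'
#' @param fit A `dtr_fit`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_dtr_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "dtr_fit"))
  obj <- list(
    method = fit$method,
    n = fit$n,
    spec1 = unclass(fit$spec1),
    spec2 = unclass(fit$spec2),
    stage2 = list(beta0 = as.list(fit$stage2$beta0),
                  beta1 = as.list(fit$stage2$beta1),
                  n_fit = fit$stage2$n_fit,
                  resid_sd = fit$stage2$resid_sd)
  )
  if (!is.null(fit$stage1)) {
    obj$stage1 <- list(beta0 = as.list(fit$stage1$beta0),
                       beta1 = as.list(fit$stage1$beta1),
                       n_fit = fit$stage1$n_fit,
                       resid_sd = fit$stage1$resid_sd)
  } else {
    obj$main_effect <- list(variant = fit$m_fit$variant,
                            coef = as.list(fit$m_fit$coef))
    obj$g <- list(kind = fit$g_model$kind,
                  mu_coef = as.list(fit$g_model$mu_coef),
                  sigma = fit$g_model$sigma,
                  n_residuals = length(fit$g_model$residual_pool))
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(js)
}
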