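#' Declare a stage's Q-function design
#'
#' A Q-function at stage \eqn{j} is linear with a main-effect block and a
#' treatment-effect block,
#' \deqn{Q_j(H_j, A_j) = \tilde X_{j0}^T \beta_{j0} + A_j \tilde X_{j1}^T \beta_{j1},}
#' where both blocks carry an implicit leading intercept. `main` and
#' `effect` list the history columns (or products of columns, written
#' `"z1:a1"`) entering each block; the two lists are independent, so the
#' main-effect block can adjust for earlier-stage treatment interactions
#' that the treatment block omits, and vice versa.
#'
#' @param stage 1 or 2; decides which treatment column (`a1` or `a2`)
#'   multiplies the effect block.
#' @param main Character vector of main-effect terms (may be empty:
#'   intercept-only block).
#' @param effect Character vector of treatment-effect terms (may be empty).
#'
#' @return A `model_spec` object.
#' @examples
#' model_spec(2, main = c("z1", "a1", "z2"), effect = c("z1", "a1", "z2"))
#' model_spec(1, main = "z1", effect = "z1")
#' @export
model_spec <- function(stage, main = character(), effect = character()) {
  stage <- as.integer(stage)
  if (!stage %in% c(1L, 2L)) abort("stage must be 1 or 2")
  structure(list(stage = stage,
                 main = as.character(main),
                 effect = as.character(effect)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec stage %d>\n  main:   1%s\n  effect: 1%s\n",
              x$stage,
              if (length(x$main)) paste0(" + ", paste(x$main, collapse = " + ")) else "",
              if (length(x$effect)) paste0(" + ", paste(x$effect, collapse = " + ")) else ""))
  invisible(x)
}

# A term is a column name or a ':'/'*'-separated product of column names.
resolve_term <- function(data, term) {
  parts <- trimws(strsplit(term, "[:*]")[[1]])
  missing <- setdiff(parts, names(data))
  if (length(missing)) {
    abort(sprintf("term '%s' refers to unknown column(s): %s",
                  term, paste(missing, collapse = ", ")))
  }
  Reduce(`*`, lapply(parts, function(p) as.numeric(data[[p]])))
}

term_matrix <- function(data, terms, label) {
  n <- nrow(data)
  cols <- lapply(terms, resolve_term, data = data)
  m <- cbind(`(Intercept)` = rep(1, n),
             do.call(cbind, c(list(), cols)))
  colnames(m) <- c("(Intercept)", terms)
  m
}

#' Build the stage design matrices
#'
#' Realizes a [model_spec()] against a trajectory table: the main block
#' `M0` (intercept-first), the effect block `M1` (intercept-first), the
#' treatment vector `a`, and the full fitting matrix
#' `[M0 | a * M1]` (each effect column multiplied elementwise by the
#' treatment code). Pure function: identical inputs give identical
#' matrices.
#'
#' @param data Trajectory tibble (see [as_trial()]); must contain every
#'   column a term references, plus the stage's treatment column unless
#'   `a` is supplied.
#' @param spec A [model_spec()].
#' @param a Optional treatment vector overriding `data[[paste0("a", stage)]]`
#'   (used to evaluate a Q-function at a counterfactual arm).
#'
#' @return A list with elements `M0`, `M1`, `a`, `full`.
#' @export
build_design <- function(data, spec, a = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  a_col <- paste0("a", spec$stage)
  if (is.null(a)) {
    if (!a_col %in% names(data)) {
      abort(sprintf("column '%s' not found and no treatment vector supplied", a_col))
    }
    a <- as.numeric(data[[a_col]])
  } else {
    a <- rep_len(as.numeric(a), nrow(data))
  }
  M0 <- term_matrix(data, spec$main, "main")
  M1 <- term_matrix(data, spec$effect, "effect")
  trt <- M1 * a
  colnames(trt) <- paste0(a_col, ":", colnames(M1))
  full <- cbind(M0, trt)
  list(M0 = M0, M1 = M1, a = a, full = full)
}

#' Ordinary least squares with an explicit rank check
#'
#' Minimizes the residual sum of squares; a rank-deficient design is a hard
#' error naming the collinear columns rather than a silent pseudo-inverse,
#' because collinearity in a Q-function design usually signals a
#' misspecified or overfitted block. The residual standard deviation uses
#' the unbiased denominator \eqn{n - p} (defined as 0 when \eqn{n = p}).
#'
#' @param X Numeric matrix, `n >= p`.
#' @param y Numeric response of length `n`.
#' @return List with `coef` (named as `colnames(X)`) and `resid_sd`.
#' @examples
#' ols_fit(cbind(1, 0:1), c(2, 5))
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (n < p) abort(sprintf("need at least as many rows (%d) as columns (%d)", n, p))
  qx <- qr(X)
  if (qx$rank < p) {
    nm <- colnames(X) %||% paste0("V", seq_len(p))
    bad <- nm[qx$pivot[seq(qx$rank + 1L, p)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  coef <- qr.coef(qx, y)
  rss <- sum((y - drop(X %*% coef))^2)
  resid_sd <- if (n > p) sqrt(rss / (n - p)) else 0
  list(coef = setNames(as.numeric(coef), colnames(X)), resid_sd = resid_sd)
}
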