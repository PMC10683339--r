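#' Treatment coding for one randomization stage
#'
#' Maps the arms of a randomized stage to numeric codes such that the coded
#' treatment variable has expectation zero under the design allocation.
#' With balanced two-arm randomization the usual coding is `+1` / `-1`;
#' with a 2:1 allocation the codes `+1` / `-2` restore `E(A) = 0`. Zero
#' expectation of the coded treatment is what separates main-effect and
#' treatment-effect blocks in the Q-function fits.
#'
#' @param labels Character vector of arm names (exactly two arms).
#' @param codes Numeric codes, one per arm.
#' @param allocation Allocation probabilities, one per arm; must sum to 1
#'   and be strictly positive (positivity).
#'
#' @return A `treatment_coding` object (list with `labels`, `codes`,
#'   `allocation`).
#' @examples
#' treatment_coding(c("early", "late"))
#' treatment_coding(c("A", "B"), codes = c(1, -2), allocation = c(2 / 3, 1 / 3))
#' @export
treatment_coding <- function(labels = c("-1", "1"),
                             codes = c(-1, 1),
                             allocation = rep(1 / length(codes), length(codes))) {
  labels <- as.character(labels)
  if (length(labels) != 2L || length(codes) != 2L || length(allocation) != 2L) {
    abort("exactly two arms are supported per stage")
  }
  if (anyDuplicated(labels)) abort("arm labels must be distinct")
  if (any(allocation <= 0)) abort("allocation probabilities must be positive")
  if (abs(sum(allocation) - 1) > 1e-8) abort("allocation probabilities must sum to 1")
  ea <- sum(codes * allocation)
  if (abs(ea) > 1e-8) {
    abort(sprintf(
      "coded treatment has nonzero expectation %.4g under its allocation; pick codes with sum(codes * allocation) == 0",
      ea
    ))
  }
  structure(list(labels = labels, codes = as.numeric(codes),
                 allocation = as.numeric(allocation)),
            class = "treatment_coding")
}

#' @export
print.treatment_coding <- function(x, ...) {
  cat("<treatment_coding> ",
      paste(sprintf("%s = %g (%.3g)", x$labels, x$codes, x$allocation),
            collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

map_arm_codes <- function(x, coding, what, stage) {
  if (is.null(coding)) {
    return(as.numeric(x))
  }
  if (is.numeric(x) && all(x[!is.na(x)] %in% coding$codes)) {
    return(as.numeric(x))
  }
  lab <- as.character(x)
  idx <- match(lab, coding$labels)
  bad <- which(is.na(idx) & !is.na(lab))
  if (length(bad)) {
    abort(sprintf(
      "unknown %s arm label '%s' in row %d (known arms: %s)",
      what, lab[bad[1]], bad[1], paste(coding$labels, collapse = ", ")
    ))
  }
  coding$codes[idx]
}

#' Read two-stage SMART trajectories from a delimited file
#'
#' Reads a CSV of one-row-per-subject trajectories, maps arm labels to
#' numeric codes, and applies the complete-case contract: rows with a
#' missing value in any used column are dropped with a message stating the
#' count. Columns other than the declared roles (covariates) are kept under
#' their original names.
#'
#' The returned tibble has standardized columns `a1`, `a2`, `y` and logical
#' `rerandomized`; `a2` is `NA` for subjects who were not re-randomized
#' (embedded tailoring) and is ignored by all stage-2 fits for those rows.
#'
#' @param path Path to a CSV file with a header row.
#' @param a1_coding,a2_coding [treatment_coding()] objects for the two
#'   stages (defaults: balanced `-1`/`+1`).
#' @param a1,a2,y,rerandomized,id Column names holding the stage-1 arm,
#'   stage-2 arm, final outcome (smaller preferred), re-randomization flag,
#'   and subject identifier. `rerandomized = NULL` declares a design without
#'   embedded tailoring (all subjects re-randomized); `id = NULL`
#'   auto-numbers subjects.
#'
#' @return A tibble of validated trajectories.
#' @export
read_trial <- function(path,
                       a1_coding = treatment_coding(),
                       a2_coding = treatment_coding(),
                       a1 = "a1", a2 = "a2", y = "y",
                       rerandomized = "rerandomized",
                       id = "id") {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_trial(raw,
           a1_coding = a1_coding, a2_coding = a2_coding,
           a1 = a1, a2 = a2, y = y, rerandomized = rerandomized, id = id)
}

#' Validate an in-memory trajectory table
#'
#' Same contract as [read_trial()] but starting from a data frame.
#'
#' @param data A data frame of one-row-per-subject trajectories.
#' @inheritParams read_trial
#' @return A tibble of validated trajectories.
#' @export
as_trial <- function(data,
                     a1_coding = treatment_coding(),
                     a2_coding = treatment_coding(),
                     a1 = "a1", a2 = "a2", y = "y",
                     rerandomized = "rerandomized",
                     id = "id") {
  data <- as_tibble(data)
  need <- c(a1, a2, y)
  if (!is.null(rerandomized) && rerandomized %in% names(data)) {
    need <- c(need, rerandomized)
  }
  missing_cols <- setdiff(c(a1, y), names(data))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }

  out <- data
  if (!is.null(id) && id %in% names(out)) {
    out <- dplyr::rename(out, id = dplyr::all_of(id))
  } else {
    out$id <- seq_len(nrow(out))
  }
  out <- dplyr::rename(out, a1 = dplyr::all_of(a1), y = dplyr::all_of(y))
  if (!is.null(rerandomized) && rerandomized %in% names(out)) {
    out <- dplyr::rename(out, rerandomized = dplyr::all_of(rerandomized))
    out$rerandomized <- as.logical(out$rerandomized)
  } else {
    out$rerandomized <- TRUE
  }
  if (a2 %in% names(out)) {
    out <- dplyr::rename(out, a2 = dplyr::all_of(a2))
  } else if (any(out$rerandomized)) {
    abort("no stage-2 treatment column but re-randomized subjects are present")
  } else {
    out$a2 <- NA_real_
  }

  out$a1 <- map_arm_codes(out$a1, a1_coding, "stage-1", 1L)
  a2_codes <- rep(NA_real_, nrow(out))
  a2_codes[out$rerandomized] <-
    map_arm_codes(out$a2[out$rerandomized], a2_coding, "stage-2", 2L)
  out$a2 <- a2_codes
  out$y <- as.numeric(out$y)

  used <- setdiff(names(out), "a2")
  complete <- stats::complete.cases(out[used]) &
    (!out$rerandomized | !is.na(out$a2))
  dropped <- sum(!complete)
  if (dropped > 0) {
    inform(sprintf("dropped %d row(s) with missing values (complete-case)", dropped))
  }
  out <- out[complete, , drop = FALSE]
  dplyr::relocate(out, "id")
}

#' Write trajectories or rule assignments to CSV
#'
#' @param data A tibble (trajectories or any result table).
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_trial <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}
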