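#' Parametric bootstrap of model parameters
#'
#' Draws replicate parameter vectors from independent normal sampling
#' distributions centred at the point estimates with the reported standard
#' errors. Parameters fixed without error (SE 0) are held constant in every
#' replicate. This propagates estimation uncertainty into simulation-based
#' predictions.
#'
#' @param estimates Named numeric vector of point estimates.
#' @param standard_errors Named numeric vector of SEs, same names as
#'   `estimates`; an `NA` SE for any parameter is an error (the sampling
#'   distribution is unknown), 0 means fixed.
#' @param n_reps Number of replicates, >= 1.
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @param lower,upper Optional named bounds; draws are truncated by
#'   rejection (redrawn) so replicates stay in the admissible range, e.g.
#'   positive ED50.
#' @return Matrix `n_reps x length(estimates)` of class
#'   `parameter_replicates`, one replicate per row.
#' @export
parametric_bootstrap <- function(estimates, standard_errors, n_reps = 1000,
                                 seed = NULL, lower = NULL, upper = NULL) {
  stopifnot(is.numeric(estimates),
            length(estimates) == length(standard_errors), n_reps >= 1)
  standard_errors <- as.numeric(standard_errors)
  if (is.null(names(estimates))) names(estimates) <- paste0("p", seq_along(estimates))
  if (is.null(names(standard_errors))) names(standard_errors) <- names(estimates)
  standard_errors <- standard_errors[names(estimates)]
  if (anyNA(standard_errors))
    stop("missing SE for sampled parameter(s): ",
         paste(names(standard_errors)[is.na(standard_errors)], collapse = ", "),
         call. = FALSE)
  draw <- function() {
    reps <- vapply(seq_along(estimates), function(j) {
      x <- stats::rnorm(n_reps, estimates[j], standard_errors[j])
      lo <- if (!is.null(lower) && names(estimates)[j] %in% names(lower))
        lower[[names(estimates)[j]]] else -Inf
      hi <- if (!is.null(upper) && names(estimates)[j] %in% names(upper))
        upper[[names(estimates)[j]]] else Inf
      bad <- which(x < lo | x > hi)
      while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), estimates[j], standard_errors[j])
        bad <- bad[x[bad] < lo | x[bad] > hi]
      }
      x
    }, numeric(n_reps))
    if (n_reps == 1L) reps <- matrix(reps, nrow = 1L)
    colnames(reps) <- names(estimates)
    reps
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  class(out) <- c("parameter_replicates", class(out))
  out
}

#' Non-parametric bootstrap of a trial dataset
#'
#' Resamples subjects with replacement; every record of a resampled subject
#' is carried along, and each replicate contains exactly as many subjects
#' as the original dataset. Resampled subjects receive fresh ids so a
#' subject drawn twice contributes two independent "patients".
#'
#' @param dataset A long-format trial data.frame with a `subject_id`
#'   column (see [generate_trial()]).
#' @param n_reps Number of replicate datasets.
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return List of `n_reps` data.frames.
#' @export
nonparametric_bootstrap <- function(dataset, n_reps = 1000, seed = NULL) {
  if (is.null(dataset$subject_id) || nrow(dataset) == 0L)
    stop("`dataset` must be non-empty with a subject_id column", call. = FALSE)
  stopifnot(n_reps >= 1)
  ids <- unique(dataset$subject_id)
  rows_of <- split(seq_len(nrow(dataset)), factor(dataset$subject_id, levels = ids))
  draw <- function() {
    lapply(seq_len(n_reps), function(r) {
      pick <- sample(length(ids), length(ids), replace = TRUE)
      idx <- unlist(rows_of[pick], use.names = FALSE)
      out <- dataset[idx, , drop = FALSE]
      out$subject_id <- rep(seq_along(pick), lengths(rows_of)[pick])
      rownames(out) <- NULL
      out
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
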