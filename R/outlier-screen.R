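#' Parametric-simulation outlier screen
#'
#' Data-exploration screen for a continuous response: draw `n_sim` random
#' samples of the observed size from a normal distribution with the
#' observed mean and standard deviation, form a 95% envelope from the
#' simulated values, and flag raw data points falling outside it.
#'
#' Two envelope constructions are available. `"pooled"` (default) takes
#' the 2.5th and 97.5th percentiles of all `n_sim * n` simulated values,
#' which converges to `mean +/- 1.96 sd`; under a true Gaussian about 5%
#' of points are expected outside, so at n = 70 a handful of flags is
#' normal and only genuinely extreme points stand far outside.
#' `"extremes"` instead uses the 2.5th percentile of the per-sample
#' minima and the 97.5th percentile of the per-sample maxima, a wider
#' envelope that flags only points more extreme than almost all simulated
#' samples of the same size.
#'
#' @param values Numeric vector (n >= 3).
#' @param n_sim Number of simulated samples (default 1000).
#' @param level Envelope coverage (default 0.95).
#' @param seed Integer seed; recorded in the report. NULL leaves the RNG
#'   state alone.
#' @param envelope `"pooled"` or `"extremes"`.
#' @return An object of class `outlier_report`: list with `n`, `mean`,
#'   `sd`, `n_sim`, `level`, `envelope` (lower, upper), `method`,
#'   `flagged` (indices into `values`), `seed`.
#' @export
screen_outliers <- function(values, n_sim = 1000, level = 0.95, seed = NULL,
                            envelope = c("pooled", "extremes")) {
  envelope <- match.arg(envelope)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (anyNA(values)) stop("NA values not allowed")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero standard deviation: no outliers can be flagged")
    rep <- list(n = n, mean = m, sd = s, n_sim = n_sim, level = level,
                envelope = c(lower = -Inf, upper = Inf), method = envelope,
                flagged = integer(0), seed = seed)
    class(rep) <- "outlier_report"
    return(rep)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  sims <- matrix(stats::rnorm(n_sim * n, m, s), nrow = n_sim)
  alpha <- (1 - level) / 2
  env <- if (envelope == "pooled") {
    stats::quantile(sims, c(alpha, 1 - alpha), names = FALSE)
  } else {
    c(stats::quantile(apply(sims, 1, min), alpha, names = FALSE),
      stats::quantile(apply(sims, 1, max), 1 - alpha, names = FALSE))
  }
  rep <- list(n = n, mean = m, sd = s, n_sim = n_sim, level = level,
              envelope = c(lower = env[1], upper = env[2]),
              method = envelope,
              flagged = which(values < env[1] | values > env[2]),
              seed = seed)
  class(rep) <- "outlier_report"
  rep
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Parametric-simulation outlier screen (", x$method, " envelope)\n",
      sep = "")
  cat(sprintf("  n = %d, mean = %.4g, sd = %.4g, %d simulated samples\n",
              x$n, x$mean, x$sd, x$n_sim))
  cat(sprintf("  %.0f%% envelope: [%.4g, %.4g]\n", 100 * x$level,
              x$envelope[1], x$envelope[2]))
  cat(sprintf("  %d point(s) flagged\n", length(x$flagged)))
  invisible(x)
}

#' Screen a dataset and return both filtered and full versions
#'
#' Applies [screen_outliers()] to one column of a dataset and removes the
#' flagged rows. Both the filtered and the original data are returned so
#' any analysis can be redone with outliers reincorporated as a
#' robustness check.
#'
#' @param data data.frame.
#' @param response Name of the column to screen.
#' @param ... Passed to [screen_outliers()] (`n_sim`, `level`, `seed`,
#'   `envelope`).
#' @return List with `filtered` (flagged rows removed), `full` (input
#'   unchanged), `report` (the `outlier_report`), `flagged_rows` (the
#'   removed rows).
#' @export
apply_screen <- function(data, response, ...) {
  stopifnot(is.data.frame(data), response %in% names(data))
  report <- screen_outliers(data[[response]], ...)
  keep <- setdiff(seq_len(nrow(data)), report$flagged)
  list(filtered = data[keep, , drop = FALSE],
       full = data,
       report = report,
       flagged_rows = data[report$flagged, , drop = FALSE])
}
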