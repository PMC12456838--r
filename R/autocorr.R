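#' Autocorrelation functions and correlation times of a trajectory
#'
#' Per-neuron normalised autocorrelations (biased estimator, lag-0 value 1),
#' subgroup means, and 1/e correlation times (the first lag at which the
#' autocorrelation falls below `exp(-1)`). Zero-variance neurons get a
#' correlation time of 0 and are flagged.
#'
#' @param traj A [trajectory][integrate_network].
#' @param subgroups Optional factor/vector of length N labelling neuron
#'   subgroups (e.g. GPA vs normal by decay rate); default one group.
#' @param max_lag_time Maximum lag in time units.
#' @param t_min Discard samples before this time (transient removal).
#' @return An `autocorr_summary`: list with `acf_mean` (tibble `lag`,
#'   `subgroup`, `acf`) and `correlation_times` (tibble `neuron`,
#'   `subgroup`, `corr_time`, `zero_variance`).
#' @export
autocorrelation_summary <- function(traj, subgroups = NULL, max_lag_time = 50,
                                    t_min = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  x <- traj$x
  if (!is.null(t_min)) x <- x[traj$times >= t_min, , drop = FALSE]
  N <- ncol(x)
  if (is.null(subgroups)) subgroups <- rep("all", N)
  if (length(subgroups) != N) abort_param("`subgroups` must have length N.")
  lag_max <- min(nrow(x) - 1L, as.integer(round(max_lag_time / traj$dt)))
  lags <- (0:lag_max) * traj$dt

  acfs <- matrix(NA_real_, lag_max + 1L, N)
  zero_var <- logical(N)
  for (i in seq_len(N)) {
    v <- stats::var(x[, i])
    if (!is.finite(v) || v == 0) {
      zero_var[i] <- TRUE
      acfs[, i] <- c(1, rep(0, lag_max))
    } else {
      acfs[, i] <- stats::acf(x[, i], lag.max = lag_max, plot = FALSE,
                              demean = TRUE)$acf[, 1, 1]
    }
  }
  corr_time <- vapply(seq_len(N), function(i) {
    if (zero_var[i]) return(0)
    k <- which(acfs[, i] < exp(-1))[1]
    if (is.na(k)) max_lag_time else lags[k]
  }, numeric(1))

  grp <- as.character(subgroups)
  acf_mean <- dplyr::bind_rows(lapply(unique(grp), function(gname) {
    tibble::tibble(
      lag = lags, subgroup = gname,
      acf = rowMeans(acfs[, grp == gname, drop = FALSE])
    )
  }))
  structure(
    list(
      acf_mean = acf_mean,
      correlation_times = tibble::tibble(
        neuron = seq_len(N), subgroup = grp,
        corr_time = corr_time, zero_variance = zero_var
      )
    ),
    class = "autocorr_summary"
  )
}

#' @export
print.autocorr_summary <- function(x, ...) {
  cat(sprintf("<autocorr_summary: %d neurons, %d subgroups>\n",
              nrow(x$correlation_times), length(unique(x$acf_mean$subgroup))))
  invisible(x)
}
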