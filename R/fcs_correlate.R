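#' Fluorescence intensity trace
#'
#' One or two channels of photon counts per sampling interval.
#'
#' @param counts numeric vector (one channel) or matrix with one column per
#'   channel; counts must be non-negative.
#' @param dt sampling interval, s.
#' @return object of class `fcs_trace` with `counts` (matrix), `dt`,
#'   `duration`.
#' @export
fcs_trace <- function(counts, dt) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1L)
  stopifnot(is.numeric(counts), dt > 0, all(counts >= 0),
            ncol(counts) %in% 1:2)
  structure(list(counts = counts, dt = dt,
                 duration = nrow(counts) * dt),
            class = "fcs_trace")
}

#' @export
print.fcs_trace <- function(x, ...) {
  cat(sprintf("FCS trace: %d channel(s), %d samples at dt = %g s (%.3g s)\n",
              ncol(x$counts), nrow(x$counts), x$dt, x$duration))
  cat(sprintf("  mean counts/sample: %s\n",
              paste(sprintf("%.3g", colMeans(x$counts)), collapse = ", ")))
  invisible(x)
}

#' Quasi-logarithmic lag grid
#'
#' @param dt sampling interval, s.
#' @param max_lag largest lag, s.
#' @param points_per_octave lag-grid density.
#' @return numeric vector of lags, s (multiples of dt, strictly increasing).
#' @export
lag_grid <- function(dt, max_lag, points_per_octave = 8) {
  stopifnot(max_lag >= dt)
  n_max <- floor(max_lag / dt)
  lg <- unique(pmin(n_max, round(2^(seq(0, log2(n_max),
                                        by = 1 / points_per_octave)))))
  sort(unique(lg)) * dt
}

#' Windowed correlation of an intensity trace
#'
#' Local-average correlator: the trace is tiled into non-overlapping windows
#' of length `window`; within each window w the correlator
#' `G_w(tau) = <dF_k(t) dF_l(t+tau)> / (<F_k> <F_l>)` uses window-local
#' means, and the final estimate averages `G_w` over all windows. Windows
#' with zero mean are skipped and counted. The window-local normalization
#' suppresses fluctuations slower than the window (e.g. bulk
#' photobleaching).
#'
#' @param trace an [fcs_trace()].
#' @param window window length Theta, s.
#' @param lags lag grid, s (defaults to a quasi-logarithmic grid up to
#'   `window/5`); lags above `window/5` are rejected.
#' @param channels length-2 integer: channel pair (k, l); `c(1, 1)` gives
#'   the ACF, `c(1, 2)` the CCF.
#' @return object of class `correlation_function` with `lags`, `G`, `se`
#'   (standard error over windows), `n_windows`, `skipped`, `window`.
#' @export
correlate <- function(trace, window, lags = NULL, channels = c(1L, 1L)) {
  stopifnot(inherits(trace, "fcs_trace"), window > 0,
            window <= trace$duration + trace$dt, length(channels) == 2L)
  dt <- trace$dt
  if (is.null(lags)) lags <- lag_grid(dt, window / 5)
  lag_n <- round(lags / dt)
  if (any(lag_n < 1L)) stop("lags must be at least one sampling interval")
  if (any(lags > window / 5 + 1e-12))
    stop("lags must not exceed window/5")
  Fk <- as.numeric(trace$counts[, channels[1]])
  Fl <- as.numeric(trace$counts[, channels[2]])
  N <- length(Fk)
  m <- min(floor(window / dt + 1e-9), N)
  n_win <- N %/% m
  if (n_win < 1L) stop("window longer than the trace")
  starts <- (0:(n_win - 1L)) * m + 1L
  # full-window means
  csFk <- c(0, cumsum(Fk))
  csFl <- c(0, cumsum(Fl))
  mu_k <- (csFk[starts + m] - csFk[starts]) / m
  mu_l <- (csFl[starts + m] - csFl[starts]) / m
  ok <- mu_k > 0 & mu_l > 0
  skipped <- sum(!ok)
  if (!any(ok)) stop("all windows have zero mean intensity")
  G <- se <- numeric(length(lag_n))
  for (q in seq_along(lag_n)) {
    l <- lag_n[q]
    prod <- Fk[1:(N - l)] * Fl[(1 + l):N]
    csP <- c(0, cumsum(prod))
    cnt <- m - l
    ends <- starts + cnt            # cumsum index of last valid t + 1
    P <- (csP[ends] - csP[starts]) / cnt
    A <- (csFk[ends] - csFk[starts]) / cnt
    Bv <- (csFl[ends + l] - csFl[starts + l]) / cnt
    Gw <- (P - mu_k * Bv - mu_l * A + mu_k * mu_l) / (mu_k * mu_l)
    Gw <- Gw[ok]
    G[q] <- mean(Gw)
    se[q] <- if (length(Gw) > 1L) sd(Gw) / sqrt(length(Gw)) else NA_real_
  }
  structure(list(lags = lag_n * dt, G = G, se = se,
                 n_windows = sum(ok), skipped = skipped,
                 window = window, channels = channels, dt = dt),
            class = "correlation_function")
}

#' @export
print.correlation_function <- function(x, ...) {
  kind <- if (x$channels[1] == x$channels[2]) "ACF" else "CCF"
  cat(sprintf("%s: %d lags (%.3g - %.3g s), window %g s, %d window(s)",
              kind, length(x$lags), min(x$lags), max(x$lags), x$window,
              x$n_windows))
  if (x$skipped > 0) cat(sprintf(", %d skipped", x$skipped))
  cat(sprintf("\n  G(min lag) = %.4g\n", x$G[1]))
  invisible(x)
}

#' Write / read a correlation function as TSV
#' @param cf a `correlation_function`.
#' @param path file path.
#' @export
write_correlation <- function(cf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chromodyn correlation: window=%g n_windows=%d",
                     cf$window, cf$n_windows), con)
  write.table(data.frame(lag = cf$lags, G = cf$G, se = cf$se), con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Window-size scan for correlation-time stability
#'
#' Fits the chosen model at every window size and looks for a plateau: the
#' longest run of consecutive window sizes whose fitted characteristic time
#' changes by less than `tol` between neighbours (runs of length >= 2). The
#' smallest window of the longest plateau is selected; without any plateau
#' the trace is flagged invalid and should be discarded.
#'
#' @param trace an [fcs_trace()].
#' @param theta_grid window sizes to scan, s (>= 4 values spanning at least
#'   one decade).
#' @param fit_fun function(cf) returning a fit whose `coef()` contains the
#'   monitored time, or one of `"relaxation"`, `"diffusion"`.
#' @param time_name name of the monitored coefficient (default `tau_1` for
#'   relaxation, `tau_D` for diffusion).
#' @param tol relative change defining the plateau.
#' @param channels channel pair for the correlator.
#' @param ... passed to the fitter.
#' @return object of class `window_scan`: `table` (window, time,
#'   converged), `selected` window (NA when invalid), `valid`, `fit` (the
#'   fit at the selected window).
#' @export
window_scan <- function(trace, theta_grid, fit_fun = "relaxation",
                        time_name = NULL, tol = 0.1, channels = c(1L, 1L),
                        ...) {
  stopifnot(length(theta_grid) >= 4,
            max(theta_grid) / min(theta_grid) >= 10)
  theta_grid <- sort(theta_grid)
  if (is.character(fit_fun)) {
    kind <- match.arg(fit_fun, c("relaxation", "diffusion"))
    if (is.null(time_name))
      time_name <- if (kind == "relaxation") "tau_1" else "tau_D"
    fitter <- if (kind == "relaxation") {
      function(cf, ...) fit_relaxation(cf, ...)
    } else {
      function(cf, ...) fit_diffusion(cf, ...)
    }
  } else {
    fitter <- fit_fun
    if (is.null(time_name)) time_name <- "tau_1"
  }
  times <- rep(NA_real_, length(theta_grid))
  fits <- vector("list", length(theta_grid))
  for (i in seq_along(theta_grid)) {
    fits[i] <- list(tryCatch({
      cf <- correlate(trace, theta_grid[i], channels = channels)
      fitter(cf, ...)
    }, error = function(e) NULL))
    if (!is.null(fits[[i]])) times[i] <- coef(fits[[i]])[[time_name]]
  }
  tab <- data.frame(window = theta_grid, time = times,
                    converged = !is.na(times))
  # longest run of consecutive windows with pairwise change < tol
  best_run <- integer(0)
  run <- if (!is.na(times[1])) 1L else integer(0)
  for (i in seq_along(times)[-1]) {
    contiguous <- length(run) > 0L && !is.na(times[i]) &&
      abs(times[i] - times[run[length(run)]]) /
        abs(times[run[length(run)]]) < tol
    run <- if (contiguous) c(run, i) else if (!is.na(times[i])) i
           else integer(0)
    if (length(run) > length(best_run)) best_run <- run
  }
  valid <- length(best_run) >= 2L
  sel <- if (valid) best_run[1L] else NA_integer_
  structure(list(table = tab,
                 selected = if (valid) theta_grid[sel] else NA_real_,
                 valid = valid,
                 fit = if (valid) fits[[sel]] else NULL),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat("Window-size scan:\n")
  print(x$table, row.names = FALSE)
  if (x$valid) {
    cat(sprintf("  plateau found; selected window %g s\n", x$selected))
  } else {
    cat("  no plateau: trace flagged invalid\n")
  }
  invisible(x)
}
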