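#' Two-state chromatin-binding parameters
#'
#' The sequential binding scheme of a linker histone: free molecules
#' associate with rate `k_on` into a short-lived bound state, from which
#' they either dissociate (`k_off1`) or switch (`k_switch`) into a
#' long-lived state that dissociates with `k_off2`.
#'
#' @param f_free,f_short,f_long steady-state fractions (must sum to 1).
#' @param k_on,k_off1,k_switch,k_off2 rates, 1/s.
#' @return object of class `binding_params`.
#' @export
binding_params <- function(f_free, f_short, f_long, k_on = NA_real_,
                           k_off1 = NA_real_, k_switch = NA_real_,
                           k_off2 = NA_real_) {
  fr <- c(f_free, f_short, f_long)
  stopifnot(all(fr >= 0), abs(sum(fr) - 1) < 1e-9)
  rates <- c(k_on, k_off1, k_switch, k_off2)
  if (any(!is.na(rates) & rates < 0)) stop("rates must be >= 0")
  structure(list(f_free = f_free, f_short = f_short, f_long = f_long,
                 k_on = k_on, k_off1 = k_off1, k_switch = k_switch,
                 k_off2 = k_off2),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat("Sequential two-state binding scheme\n")
  cat(sprintf("  fractions: free %.3g, short %.3g, long %.3g\n",
              x$f_free, x$f_short, x$f_long))
  cat(sprintf("  rates (1/s): k_on %.3g, k_off1 %.3g, k_switch %.3g, k_off2 %.3g\n",
              x$k_on, x$k_off1, x$k_switch, x$k_off2))
  invisible(x)
}

#' Steady-state rate algebra of the sequential scheme
#'
#' From the stationary occupancies of free -> short -> long -> free:
#' `k_switch = f_long k_off2 / f_short` and
#' `k_on = f_short (k_off1 + k_switch) / f_free`.
#'
#' @param f_free,f_short,f_long steady-state fractions (sum 1; any common
#'   scale such as percentages is accepted and normalized).
#' @param k_off1 short-state dissociation rate, 1/s.
#' @param k_off2 long-state dissociation rate, 1/s.
#' @return a [binding_params()] with all rates filled in.
#' @export
steady_state_rates <- function(f_free, f_short, f_long, k_off1, k_off2) {
  tot <- f_free + f_short + f_long
  stopifnot(tot > 0, k_off1 >= 0, k_off2 >= 0)
  f_free <- f_free / tot; f_short <- f_short / tot; f_long <- f_long / tot
  if (f_free <= 0) stop("f_free must be positive")
  if (f_short <= 0) stop("f_short must be positive")
  k_switch <- f_long * k_off2 / f_short
  k_on <- f_short * (k_off1 + k_switch) / f_free
  binding_params(f_free, f_short, f_long, k_on, k_off1, k_switch, k_off2)
}

#' Residence times of the sequential binding scheme
#'
#' `t_short = 1/k_off1`, `t_long = 1/k_off2`, and the mean total bound time
#' per binding event (mean absorption time of short -> (off | long) ->
#' off): `t_mean = 1/(k_off1 + k_switch) +
#' [k_switch/(k_off1 + k_switch)] / k_off2`.
#'
#' @param params a [binding_params()] with `k_off1`, `k_switch`, `k_off2`.
#' @return list with `t_short`, `t_long`, `t_mean`, s.
#' @export
residence_times <- function(params) {
  stopifnot(inherits(params, "binding_params"))
  k1 <- params$k_off1; ks <- params$k_switch; k2 <- params$k_off2
  if (anyNA(c(k1, ks, k2))) stop("all rates must be set")
  if (k1 <= 0 || k2 <= 0) stop("dissociation rates must be positive")
  list(t_short = 1 / k1, t_long = 1 / k2,
       t_mean = 1 / (k1 + ks) + (ks / (k1 + ks)) / k2)
}

# erf via the normal CDF
.erf <- function(x) 2 * pnorm(sqrt(2) * x) - 1

# bounded Levenberg-Marquardt curve fit on the residual interface (robust
# to the degenerate-gradient corner cases of the nls model machinery,
# e.g. exactly noiseless data)
.lm_curve_fit <- function(par, lower, upper, model, y, weights = NULL) {
  sw <- if (is.null(weights)) rep(1, length(y)) else sqrt(weights)
  fit <- minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                            fn = function(p) sw * (y - model(p)),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300))
  list(par = as.list(fit$par), fitted = y - fit$fvec / sw,
       rss = sum(fit$fvec^2), lm = fit)
}

#' Apparent diffusion coefficient from strip-FRAP profile broadening
#'
#' Each post-bleach profile is fitted with a Gaussian depletion
#' `I(x) = 1 - depth * exp(-(x - x0)^2 / (2 sigma^2))`; the squared widths
#' follow `sigma^2(t) = sigma_0^2 + 2 D_app t`, so a linear regression of
#' `sigma^2` on time gives `D_app = slope / 2` with its regression CI.
#'
#' @param series a `frap_profile_series` (see
#'   [simulate_frap()]) or a list with `times` (s), `positions` (um) and
#'   `profiles` (matrix, positions x times, normalized intensity).
#' @param conf_level confidence level of the reported interval.
#' @return object of class `strip_frap_fit`: `D_app` (um^2/s), `ci`,
#'   `sigma2` (fitted squared widths), `lm` (the regression).
#' @export
fit_strip_profiles <- function(series, conf_level = 0.95) {
  stopifnot(length(series$times) >= 5,
            ncol(series$profiles) == length(series$times))
  x <- series$positions
  sigma2 <- apply(series$profiles, 2, function(prof) {
    st <- c(depth = max(0.05, 1 - min(prof)), x0 = x[which.min(prof)],
            sigma = max(diff(range(x)) / 20, 1e-3))
    fit <- tryCatch(
      .lm_curve_fit(st, lower = c(0, min(x), 1e-4),
                    upper = c(2, max(x), diff(range(x))),
                    model = function(p)
                      1 - p[["depth"]] *
                        exp(-(x - p[["x0"]])^2 / (2 * p[["sigma"]]^2)),
                    y = prof),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    fit$par$sigma^2
  })
  keep <- is.finite(sigma2)
  if (sum(keep) < 3) stop("too few profile fits converged")
  reg <- lm(sigma2 ~ times, data = data.frame(times = series$times,
                                              sigma2 = sigma2),
            subset = keep)
  slope <- coef(reg)[["times"]]
  ci <- stats::confint(reg, "times", level = conf_level) / 2
  D <- slope / 2
  warn <- NULL
  if (D < 0) {
    warn <- "negative broadening slope; D_app reported as 0"
    warning(warn)
    D <- 0
  }
  structure(list(D_app = D, ci = as.numeric(ci), sigma2 = sigma2,
                 times = series$times, lm = reg, warning = warn),
            class = "strip_frap_fit")
}

#' @export
print.strip_frap_fit <- function(x, ...) {
  cat(sprintf("Strip-FRAP broadening fit: D_app = %.4g um^2/s (CI %.4g - %.4g)\n",
              x$D_app, x$ci[1], x$ci[2]))
  invisible(x)
}

# integrated strip recovery model shared by generator and fitter
.recovery_model <- function(t, B, f_slow, f_mobile, D_app, k_off2, h,
                            sigma_0) {
  1 - B * (f_slow * exp(-k_off2 * t) +
             f_mobile * .erf(h / sqrt(2 * sigma_0^2 + 4 * D_app * t)))
}

#' Fit the integrated strip-FRAP recovery curve
#'
#' Uncoupled diffusion-and-binding recovery with three populations: a free
#' fraction whose recovery is complete at the first post-bleach point, a
#' mobile fraction recovering by effective diffusion (erf kernel over the
#' bleach half-width), and a slowly dissociating fraction recovering
#' exponentially with `k_off2`:
#' `F(t) = 1 - B [f_slow e^{-k_off2 t} +
#' f_mobile erf(h / sqrt(2 sigma_0^2 + 4 D_app t))]`.
#'
#' @param curve list with `times` (s) and `intensity` (normalized).
#' @param h bleach-region half-width, um.
#' @param sigma_0 initial profile width, um.
#' @param B bleach depth (fraction of fluorophores bleached in the strip),
#'   known from the bleach protocol or the first post-bleach frame. The
#'   depth multiplies both population amplitudes, so fractions are only
#'   identifiable relative to it.
#' @param init optional start values.
#' @return object of class `recovery_fit` with coefficients `f_free`,
#'   `f_mobile`, `f_slow` (normalized fractions), `D_app`, `k_off2`.
#' @export
fit_recovery <- function(curve, h, sigma_0, B = 0.9, init = NULL) {
  t <- curve$times
  F <- curve$intensity
  stopifnot(length(t) == length(F), length(t) >= 6, B > 0)
  start <- c(f_slow = 0.5, f_mobile = 0.4, D_app = 0.01, k_off2 = 0.01)
  if (!is.null(init)) start[names(init)] <- unlist(init)
  fit <- .lm_curve_fit(
    start,
    lower = c(f_slow = 0, f_mobile = 0, D_app = 0, k_off2 = 0),
    upper = c(f_slow = 1, f_mobile = 1, D_app = Inf, k_off2 = Inf),
    model = function(p)
      .recovery_model(t, B, p[["f_slow"]], p[["f_mobile"]],
                      p[["D_app"]], p[["k_off2"]], h, sigma_0),
    y = F)
  cfs <- c(fit$par, list(B = B))
  f_free <- max(0, 1 - cfs$f_slow - cfs$f_mobile)
  structure(list(coefficients = c(list(f_free = f_free), cfs),
                 nls = fit$lm, times = t, intensity = F,
                 fitted = as.numeric(fit$fitted), h = h,
                 sigma_0 = sigma_0),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cfs <- x$coefficients
  cat("Strip-FRAP recovery fit (free + mobile + slow populations)\n")
  cat(sprintf("  f_free = %.3g, f_mobile = %.3g, f_slow = %.3g\n",
              cfs$f_free, cfs$f_mobile, cfs$f_slow))
  cat(sprintf("  D_app = %.4g um^2/s, k_off2 = %.4g 1/s\n",
              cfs$D_app, cfs$k_off2))
  invisible(x)
}

#' @export
coef.recovery_fit <- function(object, ...) object$coefficients

# CP decay model with two bound states under constant focal bleaching k_b:
# bound molecules bleach until dissociation rescues them; the free fraction
# exchanges too fast to bleach appreciably.
.cp_model <- function(t, f_free, f_1, f_2, k_off1, k_off2, k_b) {
  f_free +
    f_1 * (k_off1 / (k_off1 + k_b) +
             (k_b / (k_off1 + k_b)) * exp(-(k_off1 + k_b) * t)) +
    f_2 * (k_off2 / (k_off2 + k_b) +
             (k_b / (k_off2 + k_b)) * exp(-(k_off2 + k_b) * t))
}

#' Fit a continuous-photobleaching (CP) curve
#'
#' Normalized CP decay for a free fraction plus two bound states with
#' dissociation rates `k_off1`, `k_off2` under focal bleach rate `k_b`:
#' each bound state decays toward `k_off/(k_off + k_b)` with rate
#' `k_off + k_b`. States with `k_off >> k_b` are flagged unidentifiable.
#'
#' @param curve list with `times` (s) and `intensity` (normalized to 1 at
#'   t = 0).
#' @param k_b bleach rate, 1/s (known from calibration).
#' @param init optional start values.
#' @return object of class `cp_fit` with fractions and rates.
#' @export
fit_cp <- function(curve, k_b, init = NULL) {
  t <- curve$times
  F <- curve$intensity
  stopifnot(length(t) == length(F), k_b >= 0)
  start <- c(f_free = 0.1, f_1 = 0.3, f_2 = 0.5, k_off1 = 1,
             k_off2 = 0.01)
  if (!is.null(init)) start[names(init)] <- unlist(init)
  fit <- .lm_curve_fit(
    start,
    lower = c(f_free = 0, f_1 = 0, f_2 = 0, k_off1 = 1e-6, k_off2 = 1e-6),
    upper = c(f_free = 1, f_1 = 1, f_2 = 1, k_off1 = Inf, k_off2 = Inf),
    model = function(p)
      .cp_model(t, p[["f_free"]], p[["f_1"]], p[["f_2"]], p[["k_off1"]],
                p[["k_off2"]], k_b),
    y = F)
  cfs <- fit$par
  flags <- character(0)
  if (k_b > 0 && cfs$k_off1 > 20 * k_b)
    flags <- c(flags, "k_off1 >> k_b: fast state barely identifiable")
  if (k_b > 0 && cfs$k_off2 > 20 * k_b)
    flags <- c(flags, "k_off2 >> k_b: slow state barely identifiable")
  structure(list(coefficients = cfs, k_b = k_b, nls = fit$lm, times = t,
                 intensity = F, fitted = as.numeric(fit$fitted),
                 flags = flags),
            class = "cp_fit")
}

#' @export
print.cp_fit <- function(x, ...) {
  cfs <- x$coefficients
  cat(sprintf("CP fit (k_b = %.3g 1/s)\n", x$k_b))
  cat(sprintf("  f_free = %.3g, f_1 = %.3g (k_off1 = %.3g), f_2 = %.3g (k_off2 = %.4g)\n",
              cfs$f_free, cfs$f_1, cfs$k_off1, cfs$f_2, cfs$k_off2))
  for (fl in x$flags) cat("  note:", fl, "\n")
  invisible(x)
}

#' @export
coef.cp_fit <- function(object, ...) object$coefficients

#' Global point-FRAP fit over a bleach-duration series
#'
#' Fits all recovery curves of a bleach-time series simultaneously with a
#' two-exponential recovery whose two dissociation rates are shared across
#' curves while the amplitudes are free per curve:
#' `F_j(t) = 1 - a1_j exp(-k_fast t) - a2_j exp(-k_slow t)`.
#'
#' @param curves list of >= 3 curves, each with `times` and `intensity`.
#' @param init optional start values for `k_fast`, `k_slow`.
#' @return object of class `point_frap_fit`: shared `k_fast`, `k_slow` and
#'   per-curve amplitude matrix.
#' @export
fit_point_frap <- function(curves, init = NULL) {
  if (length(curves) < 3) stop("need at least 3 bleach durations")
  nj <- length(curves)
  t_all <- unlist(lapply(curves, `[[`, "times"))
  F_all <- unlist(lapply(curves, `[[`, "intensity"))
  idx <- rep(seq_len(nj), vapply(curves, function(c) length(c$times),
                                 integer(1)))
  start <- list(k_fast = 1, k_slow = 0.01)
  if (!is.null(init)) start <- modifyList(start, init)
  # profile the linear amplitudes per curve for given rates
  resid_fun <- function(par) {
    k_fast <- exp(par[1]); k_slow <- exp(par[2])
    r <- numeric(0)
    for (j in seq_len(nj)) {
      t <- t_all[idx == j]; F <- F_all[idx == j]
      X <- cbind(exp(-k_fast * t), exp(-k_slow * t))
      a <- tryCatch(qr.solve(crossprod(X), crossprod(X, 1 - F)),
                    error = function(e) c(0, 0))
      r <- c(r, (1 - X %*% a) - F)
    }
    r
  }
  opt <- minpack.lm::nls.lm(par = log(c(start$k_fast, start$k_slow)),
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300))
  k <- sort(exp(opt$par), decreasing = TRUE)
  k_fast <- k[1]; k_slow <- k[2]
  amps <- t(vapply(seq_len(nj), function(j) {
    t <- t_all[idx == j]; F <- F_all[idx == j]
    X <- cbind(exp(-k_fast * t), exp(-k_slow * t))
    as.numeric(qr.solve(crossprod(X), crossprod(X, 1 - F)))
  }, numeric(2)))
  colnames(amps) <- c("a_fast", "a_slow")
  structure(list(k_fast = k_fast, k_slow = k_slow, amplitudes = amps,
                 n_curves = nj, optim = opt),
            class = "point_frap_fit")
}

#' @export
print.point_frap_fit <- function(x, ...) {
  cat(sprintf("Global point-FRAP fit over %d bleach durations\n",
              x$n_curves))
  cat(sprintf("  shared rates: k_fast = %.3g 1/s, k_slow = %.4g 1/s\n",
              x$k_fast, x$k_slow))
  invisible(x)
}

#' @export
coef.point_frap_fit <- function(object, ...)
  list(k_fast = object$k_fast, k_slow = object$k_slow)

#' Read / write two-column recovery or CP curves as TSV
#' @param curve list with `times`, `intensity`.
#' @param path file path.
#' @export
write_curve <- function(curve, path) {
  write.table(data.frame(t = curve$times, F = curve$intensity), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.table(path, header = TRUE)
  list(times = df[[1]], intensity = df[[2]])
}
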