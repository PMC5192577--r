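#' Confocal focus model
#'
#' 3D Gaussian detection volume with lateral 1/e^2 radius `w_0` and axial
#' radius `z_0`; the structure parameter is `kappa = z_0 / w_0`.
#'
#' @param w_0 lateral focal radius, nm.
#' @param z_0 axial focal radius, nm.
#' @return object of class `focus_model`.
#' @export
focus_model <- function(w_0 = 200, z_0 = 1000) {
  stopifnot(w_0 > 0, z_0 > 0)
  if (z_0 < w_0) stop("structure parameter kappa = z_0/w_0 must be >= 1")
  structure(list(w_0 = w_0, z_0 = z_0, kappa = z_0 / w_0),
            class = "focus_model")
}

#' Free (anomalous) diffusion ACF model with blinking
#'
#' Standard confocal FCS autocorrelation of freely diffusing emitters with a
#' fluorescent-protein-like dark state:
#' `G(tau) = (1/N) [1 - Theta_T + Theta_T exp(-tau/tau_T)]
#' [1 + (tau/tau_D)^alpha]^{-1} [1 + kappa^{-2} (tau/tau_D)^alpha]^{-1/2}`.
#'
#' @param tau lag times, s.
#' @param N mean focal occupancy.
#' @param tau_D diffusion correlation time `w_0^2/(4D)`, s.
#' @param alpha anomaly exponent (1 = normal diffusion).
#' @param theta_T dark-state fraction in \[0, 1).
#' @param tau_T dark-state lifetime, s.
#' @param focus a [focus_model()].
#' @return model values at `tau`.
#' @export
diffusion_acf <- function(tau, N = 1, tau_D, alpha = 1, theta_T = 0,
                          tau_T = 1e-4, focus = focus_model()) {
  stopifnot(N > 0, tau_D > 0, alpha > 0, alpha <= 2,
            theta_T >= 0, theta_T < 1, tau_T > 0)
  r <- (tau / tau_D)^alpha
  blink <- 1 - theta_T + theta_T * exp(-tau / tau_T)
  (blink / N) * (1 + r)^-1 * (1 + r / focus$kappa^2)^-0.5
}

# Single-mode relaxation ACF term for an Ornstein-Uhlenbeck mode of
# amplitude a_p (nm^2) and time tau_p observed through a Gaussian focus;
# the diffusion-to-relaxation ratio is closed per mode via the OU mapping
# upsilon_p = 3 w_0^2 / (4 a_p).
.relax_term <- function(tau, tau_p, a_p, w_0, kappa) {
  ups <- 3 * w_0^2 / (4 * a_p)
  u <- (1 - exp(-tau / tau_p)) / ups
  uinf <- 1 / ups
  (1 + u)^-1 * (1 + u / kappa^2)^-0.5 -
    (1 + uinf)^-1 * (1 + uinf / kappa^2)^-0.5
}

#' Polymer-relaxation ACF model
#'
#' Sum over the relaxation modes of a domain: each mode contributes an
#' amplitude-weighted correlation term that decays from a positive value at
#' lag zero to zero, with per-mode diffusion-to-relaxation ratio
#' `upsilon_p = 3 w_0^2 / (4 a_p)` fixed by the Ornstein-Uhlenbeck mapping
#' (per-axis mode variance `a_p/3`).
#'
#' @param tau lag times, s.
#' @param spectrum a [mode_spectrum()].
#' @param focus a [focus_model()].
#' @return dimensionless model values (weighted by `a_p / R_g^2`); scale
#'   freely when fitting.
#' @export
relaxation_acf <- function(tau, spectrum, focus = focus_model()) {
  stopifnot(inherits(spectrum, "mode_spectrum"),
            inherits(focus, "focus_model"))
  out <- numeric(length(tau))
  for (p in seq_len(spectrum$p_max)) {
    out <- out + (spectrum$a_p[p] / spectrum$R_g^2) *
      .relax_term(tau, spectrum$tau_p[p], spectrum$a_p[p],
                  focus$w_0, focus$kappa)
  }
  out
}

.cf_weights <- function(cf) {
  # inverse-variance weights, floored so that a few accidentally tiny
  # window-to-window SE estimates cannot dominate the fit
  w <- 1 / pmax(cf$se, stats::median(cf$se, na.rm = TRUE) / 3)^2
  if (any(!is.finite(w))) w <- rep(1, length(cf$G))
  w
}

# windowed correlators carry a small negative baseline from window-local
# mean estimation; anchor it to the long-lag tail (top octave), which the
# relaxation model predicts to be zero when max lag >> tau_1
.tail_baseline <- function(cf) {
  idx <- cf$lags >= max(cf$lags) / 2
  if (sum(idx) < 3) return(0)
  mean(cf$G[idx])
}

# expected window-normalization bias of the local-average correlator for a
# model curve g(t): subtracting the window mean shifts the estimate by
# approximately -(2/Theta) * int_0^Theta (1 - t/Theta) g(t) dt
.window_bias <- function(model_fun, window) {
  t <- sort(unique(c(0, exp(seq(log(window * 1e-5), log(window),
                                length.out = 300)))))
  g <- model_fun(t)
  f <- (1 - t / window) * g
  (2 / window) * sum(diff(t) * (head(f, -1) + tail(f, -1)) / 2)
}

#' Fit the free-diffusion model to a correlation function
#'
#' Weighted least squares (inverse variance of G across windows; uniform
#' fallback) of the anomalous-diffusion/blinking model. The diffusion
#' coefficient is reported as `D = w_0^2 / (4 tau_D)` in um^2/s.
#'
#' @param cf a `correlation_function`.
#' @param focus a [focus_model()].
#' @param init optional named list of start values (`N`, `tau_D`, `alpha`,
#'   `theta_T`, `tau_T`).
#' @param fit_blinking fit the dark-state term (default FALSE: `theta_T`
#'   fixed at 0).
#' @param fix_alpha fix the anomaly exponent at this value (NULL = free).
#' @return object of class `diffusion_fit` (and `fcs_fit`) with
#'   coefficients, `D` (um^2/s), fitted values and the underlying `nls`
#'   object.
#' @export
fit_diffusion <- function(cf, focus = focus_model(), init = NULL,
                          fit_blinking = FALSE, fix_alpha = NULL) {
  stopifnot(inherits(cf, "correlation_function"))
  tau <- cf$lags
  G <- cf$G
  if (all(!is.finite(G))) stop("correlation function has no finite values")
  w <- .cf_weights(cf)
  g0 <- G[1]
  if (g0 <= 0) g0 <- max(G, 1e-6)
  half_idx <- which(G < g0 / 2)
  tauD0 <- if (length(half_idx)) tau[half_idx[1]] else tau[ceiling(
    length(tau) / 2)]
  start <- list(N = 1 / g0, tau_D = tauD0, alpha = 1)
  if (!is.null(init)) start <- modifyList(start, init)
  df <- data.frame(tau = tau, G = G)
  if (fit_blinking) {
    if (is.null(start$theta_T)) start$theta_T <- 0.1
    if (is.null(start$tau_T)) start$tau_T <- tau[1]
  }
  alpha_free <- is.null(fix_alpha)
  a_expr <- if (alpha_free) quote(alpha) else fix_alpha
  form <- if (fit_blinking) {
    eval(bquote(G ~ diffusion_acf(tau, N, tau_D, .(a_expr), theta_T, tau_T,
                                  focus)))
  } else {
    eval(bquote(G ~ diffusion_acf(tau, N, tau_D, .(a_expr), 0, 1e-4,
                                  focus)))
  }
  environment(form) <- environment()
  if (!alpha_free) start$alpha <- NULL
  lower <- vapply(names(start), function(nm)
    switch(nm, N = 1e-6, tau_D = cf$dt / 100, alpha = 0.2, theta_T = 0,
           tau_T = cf$dt / 100), numeric(1))
  upper <- vapply(names(start), function(nm)
    switch(nm, N = Inf, tau_D = Inf, alpha = 2, theta_T = 0.9999,
           tau_T = Inf), numeric(1))
  fit <- minpack.lm::nlsLM(form, data = df, start = start, weights = w,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))
  cf_out <- as.list(coef(fit))
  if (!alpha_free) cf_out$alpha <- fix_alpha
  if (!fit_blinking) { cf_out$theta_T <- 0; cf_out$tau_T <- NA_real_ }
  cf_out$D <- (focus$w_0 * 1e-3)^2 / (4 * cf_out$tau_D)   # um^2/s
  structure(list(coefficients = cf_out, focus = focus, nls = fit,
                 lags = tau, G = G, fitted = as.numeric(fitted(fit)),
                 rss = sum(w * residuals(fit)^2)),
            class = c("diffusion_fit", "fcs_fit"))
}

#' Fit the composite polymer-relaxation model to a correlation function
#'
#' Composite model: a free-diffusion term (normal diffusion, `alpha = 1`)
#' plus the mode sum of the relaxation model whose mode times and
#' amplitudes follow the conformation's spectral laws, parameterized by the
#' first-mode time `tau_1` alone (the gyration radius follows from `tau_1`
#' through the hydrodynamic relation, and with it all mode amplitudes).
#'
#' @param cf a `correlation_function`.
#' @param topology,solvent conformation tag (as in [mode_spectrum()]).
#' @param focus a [focus_model()].
#' @param env a [physical_environment()].
#' @param include_diffusion include the fast free-diffusion component.
#' @param init optional named list of start values (`A_D`, `tau_D_free`,
#'   `B`, `tau_1`).
#' @param p_max mode truncation (default as in [mode_spectrum()]).
#' @param calib a [chromatin_calibration()] used to report genomic content.
#' @param baseline correction for the windowed correlator's
#'   mean-subtraction bias: `"window"` (default) subtracts the
#'   model-implied bias `(2/Theta) int_0^Theta (1 - t/Theta) G_model dt`
#'   from the model during fitting; `"tail"` instead anchors the data
#'   baseline to the mean of the top lag octave; `"none"` fits raw values.
#' @return object of class `relaxation_fit` (and `fcs_fit`): coefficients
#'   (`tau_1`, amplitudes), derived `R_g` (nm) and `gc_range` (bp), the
#'   fitted spectrum, fitted values and the `nls.lm` object.
#' @export
fit_relaxation <- function(cf, topology = "loop_rosette", solvent = "theta",
                           focus = focus_model(),
                           env = physical_environment(),
                           include_diffusion = TRUE, init = NULL,
                           p_max = NULL, calib = chromatin_calibration(),
                           baseline = c("window", "tail", "none")) {
  stopifnot(inherits(cf, "correlation_function"))
  baseline <- match.arg(baseline)
  tau <- cf$lags
  base <- if (baseline == "tail") .tail_baseline(cf) else 0
  G <- cf$G - base
  w <- .cf_weights(cf)
  law <- .mode_law(topology, solvent)
  model_relax <- function(tau, tau_1) {
    R_g <- (tau_1 * env$kBT / (law$c_tau * env$eta_s))^(1 / 3) * 1e9
    sp <- mode_spectrum(R_g, topology, solvent, env, p_max)
    relaxation_acf(tau, sp, focus)
  }
  g0 <- max(G[1], max(G), 1e-8)
  # slow-component level: G after the fast free-diffusion decay (~5 ms)
  i_slow <- which.min(abs(tau - 5e-3))
  g_slow <- max(G[i_slow], 0.1 * g0)
  model_at <- if (include_diffusion) {
    function(par, tvec)
      par[["A_D"]] * diffusion_acf(tvec, 1, par[["tau_D_free"]], 1, 0,
                                   1e-4, focus) +
      par[["B"]] * model_relax(tvec, par[["tau_1"]])
  } else {
    function(par, tvec) par[["B"]] * model_relax(tvec, par[["tau_1"]])
  }
  model_full <- if (baseline == "window") {
    function(par) model_at(par, tau) -
      .window_bias(function(t) model_at(par, t), cf$window)
  } else {
    function(par) model_at(par, tau)
  }
  # the free-diffusion component models the fast (ms-scale) fraction; its
  # correlation time is capped well below the relaxation regime so the two
  # components cannot trade places
  lower <- if (include_diffusion)
    c(A_D = 0, tau_D_free = cf$dt / 10, B = 0, tau_1 = 10 * cf$dt)
  else c(B = 0, tau_1 = 10 * cf$dt)
  upper <- if (include_diffusion)
    c(A_D = Inf, tau_D_free = 0.01, B = Inf, tau_1 = Inf)
  else c(B = Inf, tau_1 = Inf)
  make_start <- function(tau_1) {
    st <- c(B = g_slow / max(model_relax(5e-3, tau_1), 1e-12),
            tau_1 = tau_1)
    if (include_diffusion)
      st <- c(A_D = max(g0 - g_slow, 0.02 * g0),
              tau_D_free = max(5 * cf$dt, 5e-4), st)
    st[names(lower)]
  }
  starts <- if (!is.null(init)) {
    st <- make_start(if (is.null(init$tau_1)) 0.1 else init$tau_1)
    st[names(init)] <- unlist(init)
    list(st)
  } else {
    lapply(c(0.02, 0.05, 0.1, 0.2, 0.5), make_start)
  }
  sw <- sqrt(w)
  best <- NULL
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = function(par) sw * (G - model_full(par)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300)),
      error = function(e) NULL)
    if (is.null(cand)) next
    rss <- sum(cand$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = cand, rss = rss)
  }
  if (is.null(best)) stop("relaxation fit did not converge from any start")
  fit <- best$fit
  cfs <- as.list(fit$par)
  if (any(unlist(cfs) < 0)) warning("negative amplitude in relaxation fit")
  geom <- rg_from_relaxation(cfs$tau_1, topology, solvent, env, calib)
  spectrum <- mode_spectrum(geom$R_g, topology, solvent, env, p_max)
  if (include_diffusion && is.finite(cfs$tau_D_free) &&
      cfs$tau_1 <= cfs$tau_D_free)
    warning("fitted tau_1 is not slower than the free-diffusion time")
  vc <- tryCatch({
    s2 <- best$rss / (length(G) - length(fit$par))
    s2 * solve(fit$hessian)
  }, error = function(e) NULL)
  structure(list(coefficients = cfs, R_g = geom$R_g,
                 gc_range = geom$gc_range, spectrum = spectrum,
                 topology = topology, solvent = solvent, focus = focus,
                 env = env, nls = fit, lags = tau, G = G,
                 baseline = base,
                 fitted = as.numeric(G - fit$fvec / sw),
                 vcov = vc, rss = best$rss),
            class = c("relaxation_fit", "fcs_fit"))
}

#' @export
coef.fcs_fit <- function(object, ...) object$coefficients

#' @export
fitted.fcs_fit <- function(object, ...) object$fitted

#' @export
residuals.fcs_fit <- function(object, ...) object$G - object$fitted

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("Free-diffusion FCS fit\n")
  cat(sprintf("  N = %.3g, tau_D = %.4g ms, alpha = %.3g, D = %.4g um^2/s\n",
              x$coefficients$N, 1e3 * x$coefficients$tau_D,
              x$coefficients$alpha, x$coefficients$D))
  invisible(x)
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("Polymer-relaxation FCS fit (%s)\n", x$spectrum$tag))
  cat(sprintf("  tau_1 = %.4g ms -> R_g = %.4g nm, gc %.3g - %.3g Mb\n",
              1e3 * x$coefficients$tau_1, x$R_g,
              x$gc_range[1] / 1e6, x$gc_range[2] / 1e6))
  invisible(x)
}

#' @export
predict.relaxation_fit <- function(object, newlags = NULL, ...) {
  if (is.null(newlags)) return(object$fitted)
  cfs <- object$coefficients
  out <- cfs$B * relaxation_acf(newlags, object$spectrum, object$focus)
  if (!is.null(cfs$A_D))
    out <- out + cfs$A_D * diffusion_acf(newlags, 1, cfs$tau_D_free, 1, 0,
                                         1e-4, object$focus)
  out
}

#' Segment MSD implied by a relaxation fit
#'
#' @param fit a `relaxation_fit`.
#' @param times times, s.
#' @return an `msd_curve` from [segment_msd()] on the fitted spectrum.
#' @export
msd_from_fit <- function(fit, times) {
  stopifnot(inherits(fit, "relaxation_fit"))
  segment_msd(fit$spectrum, times)
}
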