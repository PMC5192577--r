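# Synthetic-data generators. Every generator is deterministic under its
# seed and attaches a `truth` attribute holding the ground-truth parameters
# alongside the output, so downstream recovery tests compare against the
# generating values rather than hard-coded numbers.

#' Ground truth attached to a synthetic data set
#' @param x a generator output.
#' @return the `truth` list.
#' @export
generator_truth <- function(x) attr(x, "truth")

#' Write the ground truth of a synthetic data set as a JSON sidecar
#' @param x a generator output.
#' @param path output file.
#' @export
write_truth <- function(x, path) {
  truth <- generator_truth(x)
  truth <- truth[!vapply(truth, is.object, logical(1))]
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# exact OU discretization: x' = phi x + N(0, s^2 (1 - phi^2)),
# phi = exp(-dt/tau), stationary sd s
.ou_path <- function(n, tau, s, dt) {
  phi <- exp(-dt / tau)
  innov <- rnorm(n, sd = s * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = rnorm(1, sd = s)))
}

# two-state telegraph (bright/dark) with dark fraction theta_T and dark
# lifetime tau_T; returns 0/1 vector of length n
.telegraph <- function(n, dt, theta_T, tau_T) {
  if (theta_T <= 0) return(rep(1, n))
  tau_B <- tau_T * (1 - theta_T) / theta_T
  total <- n * dt
  state <- runif(1) > theta_T        # TRUE = bright
  t_acc <- 0
  out <- numeric(0)
  while (t_acc < total) {
    dur <- rexp(1, rate = 1 / if (state) tau_B else tau_T)
    k <- max(1L, round(dur / dt))
    out <- c(out, rep(as.numeric(state), k))
    t_acc <- t_acc + k * dt
    state <- !state
  }
  out[seq_len(n)]
}

.detection <- function(x, y, z, w_0, z_0) {
  exp(-2 * (x^2 + y^2) / w_0^2 - 2 * z^2 / z_0^2)
}

#' Simulate an intensity trace of chromatin-bound emitters
#'
#' Each emitter sits at an anchor drawn uniformly from a box enclosing the
#' focus and fluctuates around it by Ornstein-Uhlenbeck relaxation-mode
#' displacements (per-axis variance `a_p/3`, correlation time `tau_p`;
#' exact discretization). Under the default independent-mode quasi-particle
#' composition each emitter carries a single mode, with mode populations
#' proportional to the amplitudes `a_p`, so that the ensemble
#' autocorrelation is exactly the amplitude-weighted mode sum that the
#' relaxation fitter assumes; `mode_composition = "summed"` instead gives
#' every emitter the sum of all modes (the physically collective picture,
#' whose multi-mode correlator saturates the focal weighting and is no
#' longer an exact mode sum). The detected signal is the Gaussian focal
#' weight times the brightness, with optional blinking, optional slow
#' multiplicative photobleaching, and Poisson shot noise on the counts.
#'
#' @param spectrum a [mode_spectrum()] (ground truth).
#' @param focus a [focus_model()].
#' @param n_emitters number of bound emitters.
#' @param mode_composition `"quasiparticle"` (default) or `"summed"`.
#' @param brightness peak count rate per emitter, counts/s.
#' @param dt sampling interval, s (warned about when `> min(tau_p)/5`).
#' @param duration trace length, s.
#' @param seed RNG seed (mandatory).
#' @param box_halfwidth half-widths (nm) of the anchor box, default
#'   `2 c(w_0, w_0, z_0)`.
#' @param blinking optional list `(theta_T, tau_T)`.
#' @param bleach_tau optional bulk photobleaching time constant, s
#'   (multiplicative exponential envelope).
#' @param shot_noise Poisson counting noise (TRUE) or noiseless signal.
#' @param channels 1 or 2; with 2 channels every emitter is detected in
#'   both channels (independent shot noise), emulating co-moving dual
#'   labels whose fluctuations cross-correlate.
#' @return an [fcs_trace()] with a `truth` attribute.
#' @export
simulate_ou_trace <- function(spectrum, focus = focus_model(),
                              n_emitters = 2000, brightness = 4e3,
                              mode_composition = c("quasiparticle",
                                                   "summed"),
                              dt = NULL, duration = 30, seed,
                              box_halfwidth = NULL, blinking = NULL,
                              bleach_tau = NULL, shot_noise = TRUE,
                              channels = 1L) {
  stopifnot(inherits(spectrum, "mode_spectrum"), !missing(seed))
  mode_composition <- match.arg(mode_composition)
  if (is.null(box_halfwidth))
    box_halfwidth <- 1.5 * c(focus$w_0, focus$w_0, focus$z_0)
  set.seed(seed)
  s_p <- sqrt(spectrum$a_p / 3)
  if (mode_composition == "quasiparticle") {
    # emitters per mode proportional to a_p (largest-remainder rounding)
    frac <- spectrum$a_p / sum(spectrum$a_p)
    n_p <- floor(frac * n_emitters)
    rem <- n_emitters - sum(n_p)
    if (rem > 0) {
      extra <- order(frac * n_emitters - n_p, decreasing = TRUE)[seq_len(rem)]
      n_p[extra] <- n_p[extra] + 1L
    }
    emitter_modes <- rep(seq_len(spectrum$p_max), n_p)
    # sampling only needs to resolve the fastest mode actually present
    tau_fast <- min(spectrum$tau_p[unique(emitter_modes)])
  } else {
    emitter_modes <- NULL
    tau_fast <- min(spectrum$tau_p)
  }
  if (is.null(dt)) dt <- tau_fast / 5
  if (dt > tau_fast / 5 * (1 + 1e-9))
    warning("dt undersamples the fastest occupied mode (dt > tau/5)")
  n <- round(duration / dt)
  tvec <- (seq_len(n) - 1) * dt
  signal <- numeric(n)
  for (e in seq_len(n_emitters)) {
    anchor <- (2 * runif(3) - 1) * box_halfwidth
    if (mode_composition == "quasiparticle") {
      p <- emitter_modes[e]
      x <- anchor[1] + .ou_path(n, spectrum$tau_p[p], s_p[p], dt)
      y <- anchor[2] + .ou_path(n, spectrum$tau_p[p], s_p[p], dt)
      z <- anchor[3] + .ou_path(n, spectrum$tau_p[p], s_p[p], dt)
    } else {
      x <- rep(anchor[1], n); y <- rep(anchor[2], n); z <- rep(anchor[3], n)
      for (p in seq_len(spectrum$p_max)) {
        x <- x + .ou_path(n, spectrum$tau_p[p], s_p[p], dt)
        y <- y + .ou_path(n, spectrum$tau_p[p], s_p[p], dt)
        z <- z + .ou_path(n, spectrum$tau_p[p], s_p[p], dt)
      }
    }
    w <- .detection(x, y, z, focus$w_0, focus$z_0)
    if (!is.null(blinking))
      w <- w * .telegraph(n, dt, blinking$theta_T, blinking$tau_T)
    signal <- signal + w
  }
  signal <- signal * brightness * dt
  if (!is.null(bleach_tau)) signal <- signal * exp(-tvec / bleach_tau)
  counts <- if (shot_noise) rpois(n, signal) else signal
  if (channels == 2L) {
    counts2 <- if (shot_noise) rpois(n, signal) else signal
    counts <- cbind(counts, counts2)
  }
  out <- fcs_trace(counts, dt)
  attr(out, "truth") <- list(scenario = "ou_bound",
                             tau_1 = spectrum$tau_p[1],
                             R_g = spectrum$R_g, tag = spectrum$tag,
                             p_max = spectrum$p_max,
                             mode_composition = mode_composition,
                             n_emitters = n_emitters,
                             brightness = brightness, seed = seed,
                             blinking = blinking, bleach_tau = bleach_tau,
                             spectrum = spectrum)
  out
}

#' Simulate an intensity trace of freely diffusing emitters
#'
#' Emitters execute Gaussian random walks (per-axis step variance
#' `2 D dt`) in a periodic box enclosing the focus; detection as in
#' [simulate_ou_trace()].
#'
#' @param D diffusion coefficient, um^2/s.
#' @param focus a [focus_model()].
#' @param concentration emitters per um^3.
#' @param dt sampling interval, s.
#' @param duration trace length, s.
#' @param seed RNG seed.
#' @param box box dimensions, nm (default `c(1600, 1600, 4000)`).
#' @param brightness peak count rate per emitter, counts/s.
#' @param shot_noise Poisson counting noise.
#' @return an [fcs_trace()] with a `truth` attribute (including the
#'   implied `tau_D`).
#' @export
simulate_diffusion_trace <- function(D, focus = focus_model(),
                                     concentration = 10, dt = 4e-5,
                                     duration = 30, seed,
                                     box = c(1600, 1600, 4000),
                                     brightness = 5e4, shot_noise = TRUE) {
  stopifnot(D > 0, !missing(seed))
  set.seed(seed)
  n <- round(duration / dt)
  vol_um3 <- prod(box) * 1e-9
  n_emitters <- max(1L, round(concentration * vol_um3))
  step_sd <- sqrt(2 * D * 1e6 * dt)       # nm
  signal <- numeric(n)
  for (e in seq_len(n_emitters)) {
    pos0 <- runif(3) * box
    x <- (pos0[1] + cumsum(rnorm(n, sd = step_sd))) %% box[1] - box[1] / 2
    y <- (pos0[2] + cumsum(rnorm(n, sd = step_sd))) %% box[2] - box[2] / 2
    z <- (pos0[3] + cumsum(rnorm(n, sd = step_sd))) %% box[3] - box[3] / 2
    signal <- signal + .detection(x, y, z, focus$w_0, focus$z_0)
  }
  signal <- signal * brightness * dt
  counts <- if (shot_noise) rpois(n, signal) else signal
  out <- fcs_trace(counts, dt)
  attr(out, "truth") <- list(scenario = "free_diffusion", D = D,
                             tau_D = (focus$w_0 * 1e-3)^2 / (4 * D),
                             concentration = concentration,
                             n_emitters = n_emitters, seed = seed)
  out
}

#' Simulate strip- or point-FRAP data
#'
#' Strip FRAP returns a Gaussian-depletion profile series whose squared
#' width grows as `sigma^2(t) = sigma_0^2 + 2 D_app t` (depth shrinking to
#' conserve the depleted area) together with the integrated recovery curve
#' of the free/mobile/slow three-population model; point FRAP returns a
#' bleach-duration series of two-exponential recovery curves sharing the
#' scheme's two dissociation rates. Gaussian noise of `noise_sd` is added.
#'
#' @param kind `"strip"` or `"point"`.
#' @param binding a [binding_params()] (fractions; `k_off1`/`k_off2` used
#'   as the recovery rates).
#' @param D_app apparent diffusion coefficient, um^2/s.
#' @param seed RNG seed.
#' @param times time points, s.
#' @param positions profile positions, um (strip).
#' @param h bleach half-width, um (strip).
#' @param sigma_0 initial profile width, um (strip).
#' @param depth initial bleach depth (strip profiles).
#' @param B bleached amplitude of the integrated recovery.
#' @param bleach_durations bleach durations, s (point).
#' @param noise_sd Gaussian noise SD.
#' @return for `"strip"`: object of class `frap_profile_series` with
#'   `times`, `positions`, `profiles`, `recovery`; for `"point"`: list of
#'   recovery curves. Both carry `truth`.
#' @export
simulate_frap <- function(kind = c("strip", "point"), binding, D_app = 0.01,
                          seed, times = seq(0, 120, by = 2),
                          positions = seq(-5, 5, by = 0.1), h = 1,
                          sigma_0 = 0.5, depth = 0.6, B = 0.9,
                          bleach_durations = c(0.1, 0.3, 1, 3),
                          noise_sd = 0.01) {
  kind <- match.arg(kind)
  stopifnot(inherits(binding, "binding_params"), !missing(seed))
  set.seed(seed)
  if (kind == "strip") {
    sigma2 <- sigma_0^2 + 2 * D_app * times
    profiles <- vapply(seq_along(times), function(i) {
      d_t <- depth * sigma_0 / sqrt(sigma2[i])
      1 - d_t * exp(-positions^2 / (2 * sigma2[i])) +
        rnorm(length(positions), sd = noise_sd)
    }, numeric(length(positions)))
    tot_bound <- binding$f_short + binding$f_long
    recovery <- .recovery_model(times, B, binding$f_long, binding$f_short,
                                D_app, binding$k_off2, h, sigma_0) +
      rnorm(length(times), sd = noise_sd)
    out <- structure(list(times = times, positions = positions,
                          profiles = profiles,
                          recovery = list(times = times,
                                          intensity = recovery),
                          h = h, sigma_0 = sigma_0),
                     class = "frap_profile_series")
    attr(out, "truth") <- list(scenario = "frap_strip", D_app = D_app,
                               sigma_0 = sigma_0, depth = depth, B = B,
                               f_free = binding$f_free,
                               f_mobile = binding$f_short,
                               f_slow = binding$f_long,
                               k_off2 = binding$k_off2, h = h,
                               noise_sd = noise_sd, seed = seed,
                               total_bound = tot_bound)
    return(out)
  }
  # point FRAP: deeper bleach for longer bleach duration
  k_fast <- binding$k_off1
  k_slow <- binding$k_off2
  frac_fast <- binding$f_short / (binding$f_short + binding$f_long)
  curves <- lapply(bleach_durations, function(bd) {
    tot <- (1 - binding$f_free) * (1 - exp(-bd))   # depth grows with bd
    a1 <- tot * frac_fast
    a2 <- tot * (1 - frac_fast)
    list(times = times,
         intensity = 1 - a1 * exp(-k_fast * times) -
           a2 * exp(-k_slow * times) +
           rnorm(length(times), sd = noise_sd),
         bleach_duration = bd)
  })
  attr(curves, "truth") <- list(scenario = "frap_point", k_fast = k_fast,
                                k_slow = k_slow, frac_fast = frac_fast,
                                bleach_durations = bleach_durations,
                                noise_sd = noise_sd, seed = seed)
  curves
}

#' Simulate a continuous-photobleaching curve
#'
#' Two-bound-state CP decay under focal bleach rate `k_b`, normalized to 1
#' at t = 0, with Gaussian noise.
#'
#' @param binding a [binding_params()] (fractions and both dissociation
#'   rates).
#' @param k_b bleach rate, 1/s.
#' @param seed RNG seed.
#' @param times time points, s.
#' @param noise_sd Gaussian noise SD.
#' @return a `cp_curve` list (`times`, `intensity`, `k_b`) with `truth`.
#' @export
simulate_cp <- function(binding, k_b, seed, times = seq(0, 300, by = 0.5),
                        noise_sd = 0.005) {
  stopifnot(inherits(binding, "binding_params"), k_b >= 0, !missing(seed))
  set.seed(seed)
  F <- .cp_model(times, binding$f_free, binding$f_short, binding$f_long,
                 binding$k_off1, binding$k_off2, k_b)
  F <- F + rnorm(length(times), sd = noise_sd)
  F <- F / F[1]
  out <- list(times = times, intensity = F, k_b = k_b)
  class(out) <- "cp_curve"
  attr(out, "truth") <- list(scenario = "cp", f_free = binding$f_free,
                             f_1 = binding$f_short, f_2 = binding$f_long,
                             k_off1 = binding$k_off1,
                             k_off2 = binding$k_off2, k_b = k_b,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a noisy contact map with planted loop bases
#'
#' Runs the lattice Monte Carlo ensemble for a configuration, computes the
#' ensemble contact map, and adds binomial sampling noise (each bin pair
#' observed with `reads_per_bin` trials); `reads_per_bin = Inf` returns the
#' noiseless ensemble map. The planted loop-base coordinates are attached
#' as ground truth.
#'
#' @param config `domain_config` or configuration string.
#' @param n_conformations ensemble size.
#' @param reads_per_bin binomial trials per bin pair (Inf = noiseless).
#' @param seed RNG seed.
#' @param lattice a [lattice_spec()].
#' @param bin_size map bin size, bp.
#' @param ... passed to [sample_ensemble()].
#' @return a [contact_map()] with `truth` (planted loop-base coordinates).
#' @export
simulate_contact_map <- function(config, n_conformations = 50,
                                 reads_per_bin = Inf, seed,
                                 lattice = lattice_spec(), bin_size = 2500,
                                 ...) {
  stopifnot(!missing(seed))
  ens <- sample_ensemble(config, n_conformations, seed = seed,
                         lattice = lattice, ...)
  map <- contact_map_from_ensemble(ens, bin_size = bin_size)
  if (is.finite(reads_per_bin)) {
    stopifnot(reads_per_bin >= 1)
    m <- map$matrix
    n <- nrow(m)
    ut <- upper.tri(m, diag = TRUE)
    noisy <- rbinom(sum(ut), size = reads_per_bin, prob = m[ut]) /
      reads_per_bin
    m[ut] <- noisy
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    map <- contact_map(m, bin_size, map$start)
  }
  attr(map, "truth") <- list(scenario = "contact_map",
                             loop_bases = loop_base_coords(config, lattice),
                             n_conformations = n_conformations,
                             reads_per_bin = reads_per_bin, seed = seed)
  map
}
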