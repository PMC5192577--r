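#' @useDynLib chromodyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm lm.fit coef predict fitted residuals rnorm rbinom
#'   rpois runif rexp sd var nls pnorm qnorm quantile approx setNames
#' @importFrom utils head tail read.table write.table modifyList
NULL

# Boltzmann constant, J/K
.kB <- 1.380649e-23

.TOPOLOGIES <- c("loop_rosette", "globule", "blob")
.SOLVENTS <- c("theta", "good")

# Relaxation-spectrum laws per conformation: tau_1 prefactor c_tau in
# tau_1 = c_tau * eta_s * R_g^3 / (kB T); mode-time exponent x_tau in
# tau_p = tau_1 / p^x_tau; amplitude prefactor c_a and exponent x_a in
# a_p = c_a * R_g^2 / p^x_a.
.mode_law <- function(topology, solvent = "theta") {
  topology <- match.arg(topology, .TOPOLOGIES)
  solvent <- match.arg(solvent, .SOLVENTS)
  if (topology == "loop_rosette" && solvent == "theta") {
    list(tag = "loop_rosette/theta", c_tau = 6.111, x_tau = 3 / 2,
         c_a = 0.152, x_a = 2)
  } else if (topology == "loop_rosette" && solvent == "good") {
    list(tag = "loop_rosette/good", c_tau = 4.114, x_tau = 17 / 20,
         c_a = 0.172, x_a = 9 / 4)
  } else if (topology == "globule") {
    list(tag = "globule", c_tau = 7.151, x_tau = 1,
         c_a = 0.236, x_a = 5 / 3)
  } else {
    list(tag = "blob", c_tau = 5.849, x_tau = 3 / 2,
         c_a = 0.152, x_a = 2)
  }
}

#' Polymer parameters of a chromatin domain
#'
#' Bundles the topology and physical parameters that determine the size of a
#' topologically independent chromatin domain: contour length `L` of the
#' fiber it contains, persistence length `l_p`, and for loop-rosette
#' (loop-cluster) topologies the number of loops `f`.
#'
#' @param topology one of `"loop_rosette"`, `"globule"`, `"blob"`.
#' @param L contour length of the chromatin fiber in the domain, nm.
#' @param l_p persistence length of the fiber, nm.
#' @param f number of loops in the cluster (integer >= 1); accepted but
#'   ignored for globule and blob topologies.
#' @param solvent `"theta"` or `"good"`; only meaningful for loop rosettes.
#' @return an object of class `polymer_params`.
#' @export
polymer_params <- function(topology = c("loop_rosette", "globule", "blob"),
                           L, l_p, f = 1L, solvent = c("theta", "good")) {
  topology <- match.arg(topology)
  solvent <- match.arg(solvent)
  stopifnot(is.numeric(L), length(L) == 1L, L > 0,
            is.numeric(l_p), length(l_p) == 1L, l_p > 0)
  f <- as.integer(f)
  if (is.na(f) || f < 1L) stop("loop count 'f' must be an integer >= 1")
  structure(list(topology = topology, solvent = solvent,
                 L = as.numeric(L), l_p = as.numeric(l_p), f = f),
            class = "polymer_params")
}

#' @export
print.polymer_params <- function(x, ...) {
  cat(sprintf("Polymer domain: %s%s\n", x$topology,
              if (x$topology == "loop_rosette")
                sprintf(" (%s solvent, f = %d loops)", x$solvent, x$f)
              else ""))
  cat(sprintf("  L   = %.4g nm contour length\n", x$L))
  cat(sprintf("  l_p = %.4g nm persistence length\n", x$l_p))
  cat(sprintf("  R_g = %.4g nm\n", gyration_radius(x)))
  invisible(x)
}

#' Physical environment of the nucleoplasm
#'
#' Solvent viscosity and temperature that enter the hydrodynamic relaxation
#' times. The default viscosity is calibrated so that the theta-solvent
#' rosette spectrum maps a first-mode time of 161 ms onto a gyration radius
#' of 297 nm at 310.15 K.
#'
#' @param eta_s solvent viscosity, Pa s.
#' @param T absolute temperature, K.
#' @return an object of class `physical_environment` with derived `kBT` (J).
#' @export
physical_environment <- function(eta_s = 4.306e-3, T = 310.15) {
  stopifnot(eta_s > 0, T > 0)
  structure(list(eta_s = eta_s, T = T, kBT = .kB * T),
            class = "physical_environment")
}

#' Chromatin fiber calibration constants
#'
#' Constants used to convert between the spatial volume of a domain and its
#' genomic content: nucleosomal repeat length, mean nuclear nucleosome
#' concentration interval, local chromatin density relative to the nuclear
#' mean, and the effective-volume prefactor `chi_V` in
#' `V = chi_V * (4/3) pi R_g^3` (calibrated so the perinuclear
#' heterochromatin gyration radius and genomic-content interval are mutually
#' consistent).
#'
#' @param NRL nucleosomal repeat length, bp.
#' @param c_nuc two-element interval of mean nucleosome concentration, uM.
#' @param rel_density local nucleosome density relative to the nuclear mean
#'   (0.91 for euchromatin, 1.56 for heterochromatin).
#' @param chi_V dimensionless volume prefactor.
#' @return an object of class `chromatin_calibration`.
#' @export
chromatin_calibration <- function(NRL = 191, c_nuc = c(100, 140),
                                  rel_density = 1, chi_V = 0.724) {
  stopifnot(NRL > 0, length(c_nuc) == 2L, all(c_nuc >= 0),
            c_nuc[1] <= c_nuc[2], rel_density > 0, chi_V > 0)
  structure(list(NRL = NRL, c_nuc = as.numeric(c_nuc),
                 rel_density = rel_density, chi_V = chi_V),
            class = "chromatin_calibration")
}

#' Radius of gyration of a chromatin domain
#'
#' Closed-form gyration radius for the four domain conformations:
#' \deqn{R_g^2 = \frac{L l_p}{6}\frac{2f-1}{f^2}} (loop rosette, theta
#' solvent), \deqn{R_g^2 = \frac{L^{6/5} l_p^{4/5}}{9.59}
#' \frac{1.92 f - 0.92}{f^{11/5}}} (loop rosette, good solvent),
#' \deqn{R_g^2 = L^{2/3} l_p^{4/3} / 1.76} (globule) and
#' \deqn{R_g^2 = L l_p / 3} (blob).
#'
#' @param params a [polymer_params()] object.
#' @return gyration radius, nm.
#' @export
gyration_radius <- function(params) {
  stopifnot(inherits(params, "polymer_params"))
  L <- params$L; lp <- params$l_p; f <- params$f
  rg2 <- switch(paste(params$topology,
                      if (params$topology == "loop_rosette") params$solvent
                      else "", sep = "/"),
    "loop_rosette/theta" = (L * lp / 6) * (2 * f - 1) / f^2,
    "loop_rosette/good" = (L^(6 / 5) * lp^(4 / 5) / 9.59) *
      (1.92 * f - 0.92) / f^(11 / 5),
    "globule/" = L^(2 / 3) * lp^(4 / 3) / 1.76,
    "blob/" = L * lp / 3,
    stop("unknown topology/solvent combination"))
  sqrt(rg2)
}

#' Relaxation-mode spectrum of a domain
#'
#' Mode times and amplitudes of the internal (Rouse-Zimm type) relaxation of
#' a domain of gyration radius `R_g`. The first-mode time is
#' `tau_1 = c_tau * eta_s R_g^3 / (kB T)` with conformation-specific
#' prefactor (6.111 theta rosette, 4.114 good-solvent rosette, 7.151
#' globule, 5.849 blob); higher modes follow `tau_p = tau_1 / p^x` and
#' amplitudes `a_p = c_a R_g^2 / p^y` with conformation-specific exponents.
#'
#' @param R_g gyration radius, nm.
#' @param topology,solvent conformation tag as in [polymer_params()].
#' @param env a [physical_environment()].
#' @param p_max truncation order; default: smallest p with
#'   `a_p/a_1 < 1e-3`, capped at 50.
#' @return object of class `mode_spectrum` with fields `tau_p` (s), `a_p`
#'   (nm^2), `tag`, `p_max`, `R_g`.
#' @export
mode_spectrum <- function(R_g, topology = "loop_rosette", solvent = "theta",
                          env = physical_environment(), p_max = NULL) {
  stopifnot(R_g > 0, inherits(env, "physical_environment"))
  law <- .mode_law(topology, solvent)
  if (is.null(p_max)) {
    p_max <- min(50L, ceiling(1000^(1 / law$x_a)))
  }
  p_max <- as.integer(p_max)
  if (is.na(p_max) || p_max < 1L) stop("p_max must be >= 1")
  # R_g in nm -> m for the hydrodynamic time
  tau_1 <- law$c_tau * env$eta_s * (R_g * 1e-9)^3 / env$kBT
  p <- seq_len(p_max)
  structure(list(tag = law$tag, topology = topology, solvent = solvent,
                 R_g = R_g, tau_p = tau_1 / p^law$x_tau,
                 a_p = law$c_a * R_g^2 / p^law$x_a, p_max = p_max,
                 law = law),
            class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(sprintf("Relaxation-mode spectrum (%s), %d modes\n", x$tag, x$p_max))
  cat(sprintf("  R_g   = %.4g nm\n", x$R_g))
  cat(sprintf("  tau_1 = %.4g ms, a_1 = %.4g nm^2\n",
              1e3 * x$tau_p[1], x$a_p[1]))
  invisible(x)
}

#' Domain geometry from a relaxation time
#'
#' Inverts the first-mode relaxation law: given `tau_1`, the gyration radius
#' is `R_g = (tau_1 kB T / (c_tau eta_s))^{1/3}` with the conformation
#' prefactor `c_tau`. Also reports the effective domain volume
#' `V = chi_V (4/3) pi R_g^3` and, through [genomic_content()], the genomic
#' content interval.
#'
#' @param tau_1 first-mode relaxation time, s.
#' @param topology,solvent conformation tag.
#' @param env a [physical_environment()].
#' @param calib a [chromatin_calibration()].
#' @return object of class `domain_geometry` with `R_g` (nm), `V` (um^3)
#'   and `gc_range` (bp).
#' @export
rg_from_relaxation <- function(tau_1, topology = "loop_rosette",
                               solvent = "theta",
                               env = physical_environment(),
                               calib = chromatin_calibration()) {
  stopifnot(tau_1 > 0)
  law <- .mode_law(topology, solvent)
  R_g <- (tau_1 * env$kBT / (law$c_tau * env$eta_s))^(1 / 3) * 1e9  # nm
  geom <- structure(list(R_g = R_g,
                         V = calib$chi_V * (4 / 3) * pi * (R_g * 1e-3)^3,
                         gc_range = c(NA_real_, NA_real_),
                         tag = law$tag),
                    class = "domain_geometry")
  geom$gc_range <- genomic_content(geom, calib)
  geom
}

#' @export
print.domain_geometry <- function(x, ...) {
  cat(sprintf("Domain geometry (%s)\n", x$tag))
  cat(sprintf("  R_g = %.4g nm, V = %.4g um^3\n", x$R_g, x$V))
  cat(sprintf("  genomic content %.3g - %.3g Mb\n",
              x$gc_range[1] / 1e6, x$gc_range[2] / 1e6))
  invisible(x)
}

#' Genomic content of a domain
#'
#' Converts the effective domain volume into a genomic-content interval:
#' the number of nucleosomes in the domain is the local nucleosome
#' concentration (`rel_density * c_nuc`, uM) times the volume, and each
#' nucleosome accounts for one repeat length of DNA. Evaluated at both
#' endpoints of the nuclear concentration interval.
#'
#' @param geom a `domain_geometry` (or any list with `R_g` in nm).
#' @param calib a [chromatin_calibration()].
#' @return two-element numeric interval, bp.
#' @export
genomic_content <- function(geom, calib = chromatin_calibration()) {
  stopifnot(inherits(calib, "chromatin_calibration"))
  R_g_um <- geom$R_g * 1e-3
  V <- calib$chi_V * (4 / 3) * pi * R_g_um^3           # um^3
  per_uM_per_um3 <- 6.02214076e2                        # nucleosomes
  n_nuc <- calib$rel_density * calib$c_nuc * per_uM_per_um3 * V
  sort(n_nuc * calib$NRL)
}

#' Mean-squared displacement of a chromatin segment
#'
#' Confined-diffusion MSD implied by a relaxation-mode spectrum:
#' `msd(t) = 2 sum_p a_p (1 - exp(-t/tau_p))`, approaching the plateau
#' `2 sum_p a_p` (twice the stationary segment variance).
#'
#' @param spectrum a [mode_spectrum()].
#' @param times numeric vector of times, s.
#' @return object of class `msd_curve` with `times` (s), `msd` (nm^2),
#'   `plateau` (nm^2).
#' @export
segment_msd <- function(spectrum, times) {
  stopifnot(inherits(spectrum, "mode_spectrum"), all(times >= 0))
  msd <- vapply(times, function(t)
    2 * sum(spectrum$a_p * (1 - exp(-t / spectrum$tau_p))), numeric(1))
  structure(list(times = times, msd = msd, plateau = 2 * sum(spectrum$a_p)),
            class = "msd_curve")
}

#' Parameter surface linking mass density, persistence length and loop count
#'
#' For a domain of known gyration radius and genomic content, each assumed
#' linear mass density (nucleosomes per 11 nm) fixes the contour length
#' `L = gc / (density * NRL / 11)`; the gyration-radius branch of the
#' conformation is then solved for the persistence length at each loop
#' count. Rows inside the plausibility box (density 0.5-6 nucleosomes/11 nm,
#' l_p 10-200 nm, f <= 20) are flagged.
#'
#' @param R_g gyration radius, nm.
#' @param gc genomic content, bp.
#' @param calib a [chromatin_calibration()] (for the repeat length).
#' @param topology,solvent conformation tag.
#' @param f_grid integer vector of loop counts (ignored for globule/blob).
#' @param density_grid numeric vector of mass densities, nucleosomes/11 nm.
#' @return data.frame with columns `density`, `f`, `L`, `l_p`, `plausible`.
#' @export
parameter_surface <- function(R_g, gc, calib = chromatin_calibration(),
                              topology = "loop_rosette", solvent = "theta",
                              f_grid = 1:20,
                              density_grid = seq(0.5, 6, by = 0.5)) {
  stopifnot(R_g > 0, gc > 0)
  law_tag <- .mode_law(topology, solvent)$tag
  if (topology != "loop_rosette") f_grid <- 1L
  rows <- list()
  for (rho in density_grid) {
    L <- gc / (rho * calib$NRL / 11)                     # nm
    for (f in f_grid) {
      lp <- switch(law_tag,
        "loop_rosette/theta" = 6 * R_g^2 * f^2 / ((2 * f - 1) * L),
        "loop_rosette/good" =
          (9.59 * R_g^2 * f^(11 / 5) /
             ((1.92 * f - 0.92) * L^(6 / 5)))^(5 / 4),
        "globule" = (1.76 * R_g^2 / L^(2 / 3))^(3 / 4),
        "blob" = 3 * R_g^2 / L)
      if (!is.finite(lp) || lp <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        density = rho, f = as.integer(f), L = L, l_p = lp,
        plausible = rho >= 0.5 && rho <= 6 && lp >= 10 && lp <= 200 &&
          f <= 20)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a parameter table as TSV
#'
#' @param table data.frame (e.g. from [parameter_surface()]).
#' @param path output file.
#' @export
write_parameter_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
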