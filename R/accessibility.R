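#' Accessible-volume model of a chromatin domain
#'
#' Static versus fluctuation-expanded accessibility of a domain for probes
#' of given radius: the chromatin fiber of length `L` and diameter `d_f`,
#' dilated by the probe radius, excludes a cylinder volume from the domain.
#' The dynamic mode uses the fluctuation-expanded volume `V_dyn` (default
#' twice the static volume, since domain volume fluctuations are of the
#' same order as the volume itself).
#'
#' @param V static domain volume, um^3.
#' @param L chromatin fiber contour length inside the domain, nm.
#' @param d_f effective fiber diameter, nm.
#' @param V_dyn fluctuation-expanded volume, um^3 (default `2 V`).
#' @return object of class `accessibility_model`.
#' @export
accessibility_model <- function(V, L, d_f = 14, V_dyn = 2 * V) {
  stopifnot(V > 0, L > 0, d_f > 0, V_dyn >= V)
  structure(list(V = V, V_dyn = V_dyn, L = L, d_f = d_f),
            class = "accessibility_model")
}

#' @export
print.accessibility_model <- function(x, ...) {
  cat(sprintf("Domain accessibility model: V = %.3g um^3 (dyn %.3g), L = %.3g nm, d_f = %g nm\n",
              x$V, x$V_dyn, x$L, x$d_f))
  cat(sprintf("  accessibility limits r_50: static %.3g nm, dynamic %.3g nm\n",
              accessibility_limit(x, "static"),
              accessibility_limit(x, "dynamic")))
  invisible(x)
}

#' Accessible volume fraction for a probe
#'
#' `A = max(0, 1 - L pi (d_f/2 + r_p)^2 / V_mode)` where `V_mode` is the
#' static or the fluctuation-expanded domain volume.
#'
#' @param model an [accessibility_model()].
#' @param r_p probe radius, nm (vectorized).
#' @param mode `"static"` or `"dynamic"`.
#' @return accessible fraction in \[0, 1\].
#' @export
accessible_fraction <- function(model, r_p, mode = c("static", "dynamic")) {
  stopifnot(inherits(model, "accessibility_model"), all(r_p >= 0))
  mode <- match.arg(mode)
  V_nm3 <- (if (mode == "static") model$V else model$V_dyn) * 1e9
  pmax(0, 1 - model$L * pi * (model$d_f / 2 + r_p)^2 / V_nm3)
}

#' Accessibility limit (50% probe radius)
#'
#' The probe radius at which the accessible fraction drops to one half, in
#' closed form: `r_50 = sqrt(V_mode / (2 pi L)) - d_f / 2`. When even a
#' point probe sees less than half the volume, the limit is reported as 0
#' with the `undefined` attribute set.
#'
#' @param model an [accessibility_model()].
#' @param mode `"static"` or `"dynamic"`.
#' @return r_50, nm.
#' @export
accessibility_limit <- function(model, mode = c("static", "dynamic")) {
  stopifnot(inherits(model, "accessibility_model"))
  mode <- match.arg(mode)
  if (accessible_fraction(model, 0, mode) <= 0.5) {
    out <- 0
    attr(out, "undefined") <- TRUE
    return(out)
  }
  V_nm3 <- (if (mode == "static") model$V else model$V_dyn) * 1e9
  sqrt(V_nm3 / (2 * pi * model$L)) - model$d_f / 2
}

#' Accessibility table over probe radii
#'
#' @param model an [accessibility_model()].
#' @param r_p probe radii, nm.
#' @return data.frame `r_p`, `A_static`, `A_dynamic`.
#' @export
accessibility_table <- function(model, r_p = seq(0, 50, by = 1)) {
  data.frame(r_p = r_p,
             A_static = accessible_fraction(model, r_p, "static"),
             A_dynamic = accessible_fraction(model, r_p, "dynamic"))
}

#' Accessibility model from domain geometry and mass density
#'
#' Convenience constructor: takes a gyration radius (nm) and genomic
#' content (bp), converts the genomic content into fiber length via the
#' mass density (nucleosomes per 11 nm) and repeat length, and uses the
#' calibrated effective volume `chi_V (4/3) pi R_g^3`.
#'
#' @param R_g gyration radius, nm.
#' @param gc genomic content, bp.
#' @param density linear mass density, nucleosomes/11 nm.
#' @param calib a [chromatin_calibration()].
#' @param d_f fiber diameter, nm.
#' @param dyn_factor `V_dyn / V`.
#' @return an [accessibility_model()].
#' @export
accessibility_from_geometry <- function(R_g, gc, density = 1.6,
                                        calib = chromatin_calibration(),
                                        d_f = 14, dyn_factor = 2) {
  V <- calib$chi_V * (4 / 3) * pi * (R_g * 1e-3)^3
  L <- gc / (density * calib$NRL / 11)
  accessibility_model(V, L, d_f, dyn_factor * V)
}
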