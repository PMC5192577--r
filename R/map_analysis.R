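#' Extract a domain submatrix with a masked diagonal band
#'
#' Cuts the bins covering `interval` out of a contact map and marks the
#' diagonal and its vicinity (`|i - j| * bin_size <= diag_mask_halfwidth`)
#' as missing (NA), mirroring the removal of the self-contact band before
#' projection analysis.
#'
#' @param map a `contact_map`.
#' @param interval two-element genomic interval (bp) inside the map.
#' @param diag_mask_halfwidth half-width of the masked band, bp (the
#'   diagonal itself is always masked).
#' @return a `contact_map` restricted to the interval, with NA band.
#' @export
extract_domain <- function(map, interval = NULL, diag_mask_halfwidth = 30000) {
  stopifnot(inherits(map, "contact_map"), diag_mask_halfwidth >= 0)
  pos <- map_positions(map)
  if (is.null(interval)) interval <- c(pos[1], pos[length(pos)] + map$bin_size)
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  if (interval[1] < pos[1] - 1e-9 ||
      interval[2] > pos[length(pos)] + map$bin_size + 1e-9)
    stop("interval lies outside the map")
  keep <- which(pos >= interval[1] & pos + map$bin_size <= interval[2])
  if (length(keep) < 2L) stop("interval covers fewer than two bins")
  m <- map$matrix[keep, keep, drop = FALSE]
  nb <- length(keep)
  hw_bins <- floor(diag_mask_halfwidth / map$bin_size + 1e-9)
  d <- abs(row(m) - col(m))
  m[d <= hw_bins] <- NA_real_
  out <- structure(list(matrix = m, bin_size = map$bin_size,
                        start = pos[keep[1]]),
                   class = "contact_map")
  out
}

#' One-dimensional projection profile of a domain map
#'
#' For every column of the masked domain matrix, the profile value is the
#' average of the maximum and the mean over non-missing entries; columns
#' with no data are missing.
#'
#' @param domain_map a masked `contact_map` from [extract_domain()].
#' @return object of class `map_profile` with `positions` (bp, bin starts),
#'   `values` and `provenance`.
#' @export
global_profile <- function(domain_map) {
  stopifnot(inherits(domain_map, "contact_map"))
  m <- domain_map$matrix
  vals <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0L) return(NA_real_)
    (max(col) + mean(col)) / 2
  })
  structure(list(positions = map_positions(domain_map), values = unname(vals),
                 provenance = list(kind = "global", anchor = NA_real_)),
            class = "map_profile")
}

#' Local projection around an anchor site
#'
#' Mean over the rows within `halfwidth` of the anchor, per column,
#' excluding masked bins — the orthogonal view that reveals the partner
#' sites a given loop base interacts with.
#'
#' @param domain_map a masked `contact_map`.
#' @param anchor genomic position of the anchor, bp.
#' @param halfwidth vicinity half-width, bp.
#' @return a `map_profile`.
#' @export
local_projection <- function(domain_map, anchor, halfwidth = 27500) {
  stopifnot(inherits(domain_map, "contact_map"), halfwidth > 0)
  pos <- map_positions(domain_map)
  band <- which(abs(pos + domain_map$bin_size / 2 -
                    anchor) <= halfwidth + domain_map$bin_size / 2)
  if (length(band) == 0L) stop("anchor lies outside the domain")
  sub <- domain_map$matrix[band, , drop = FALSE]
  if (all(is.na(sub))) stop("anchor band is fully masked")
  vals <- colMeans(sub, na.rm = TRUE)
  vals[!is.finite(vals)] <- NA_real_
  structure(list(positions = pos, values = unname(vals),
                 provenance = list(kind = "local", anchor = anchor)),
            class = "map_profile")
}

#' @export
print.map_profile <- function(x, ...) {
  cat(sprintf("%s projection profile, %d bins",
              x$provenance$kind, length(x$values)))
  if (x$provenance$kind == "local")
    cat(sprintf(" (anchor %g bp)", x$provenance$anchor))
  cat("\n")
  invisible(x)
}

#' Peak detection by sliding parabolic fits
#'
#' Fits a parabola to every continuous stretch of `fit_window` (12 data
#' points at 2.5-kb bins), keeps concave fits whose vertex falls inside the
#' window, merges candidates closer than one window (highest fitted value
#' wins; ties go to the leftmost), and accepts maxima whose fitted value
#' exceeds `threshold_frac` times the profile average.
#'
#' @param profile a `map_profile`.
#' @param fit_window fitting window, bp.
#' @param threshold_frac acceptance threshold as a fraction of the mean of
#'   the non-missing profile values.
#' @param curvature_z required significance of the fitted (negative)
#'   curvature, in standard errors; guards against spurious maxima on flat
#'   noisy profiles.
#' @return numeric vector of peak positions, bp (possibly empty).
#' @export
detect_peaks <- function(profile, fit_window = 30000, threshold_frac = 0.8,
                         curvature_z = 2.5) {
  stopifnot(inherits(profile, "map_profile"))
  pos <- profile$positions
  val <- profile$values
  bin <- if (length(pos) > 1L) pos[2] - pos[1] else fit_window
  w <- max(3L, round(fit_window / bin))
  if (w > length(pos)) stop("fit window larger than the profile")
  prof_mean <- mean(val, na.rm = TRUE)
  if (!is.finite(prof_mean)) return(numeric(0))
  cand_pos <- numeric(0)
  cand_height <- numeric(0)
  x0 <- 0:(w - 1L)                      # bin units for conditioning
  X0 <- cbind(1, x0, x0^2)
  xtx_inv_33 <- solve(crossprod(X0))[3, 3]
  for (i in seq_len(length(pos) - w + 1L)) {
    idx <- i:(i + w - 1L)
    v <- val[idx]
    if (anyNA(v)) next
    fit <- lm.fit(X0, v)
    cf <- fit$coefficients
    if (!is.finite(cf[3]) || cf[3] >= 0) next
    s2 <- sum(fit$residuals^2) / (w - 3L)
    if (cf[3] > -curvature_z * sqrt(s2 * xtx_inv_33)) next
    xv <- -cf[2] / (2 * cf[3])
    if (xv < 0 || xv > x0[w]) next
    cand_pos <- c(cand_pos, pos[idx[1]] + xv * bin)
    cand_height <- c(cand_height, cf[1] + cf[2] * xv + cf[3] * xv^2)
  }
  if (length(cand_pos) == 0L) return(numeric(0))
  # merge within one window: greedy by height, ties leftmost
  ord <- order(-cand_height, cand_pos)
  kept_pos <- numeric(0)
  kept_height <- numeric(0)
  for (k in ord) {
    if (all(abs(cand_pos[k] - kept_pos) >= fit_window)) {
      kept_pos <- c(kept_pos, cand_pos[k])
      kept_height <- c(kept_height, cand_height[k])
    }
  }
  keep <- kept_height > threshold_frac * prof_mean
  sort(kept_pos[keep])
}

#' Call loop-base pairs from a masked domain map
#'
#' Global-projection peaks define anchors; the local projection around each
#' anchor yields its partner sites. A pair recovered from both of its
#' anchors (within one fit window) is called with high confidence, a pair
#' seen from only one direction with low confidence.
#'
#' @param domain_map a masked `contact_map` from [extract_domain()].
#' @param fit_window parabolic fit window, bp.
#' @param threshold_frac peak acceptance threshold (fraction of profile
#'   mean).
#' @param local_halfwidth half-width of the local projection band, bp.
#' @return data.frame of class `loop_calls`: `site_i < site_j` (bp) and
#'   `confidence` (`"high"`/`"low"`); zero rows when nothing is found.
#' @export
call_loop_bases <- function(domain_map, fit_window = 30000,
                            threshold_frac = 0.8, local_halfwidth = 27500,
                            curvature_z = 2.5) {
  stopifnot(inherits(domain_map, "contact_map"))
  empty <- data.frame(site_i = numeric(0), site_j = numeric(0),
                      confidence = character(0))
  anchors <- detect_peaks(global_profile(domain_map), fit_window,
                          threshold_frac, curvature_z)
  if (length(anchors) == 0L) return(structure(empty, class = c("loop_calls",
                                                               "data.frame")))
  directed <- list()
  for (a in anchors) {
    partners <- tryCatch(
      detect_peaks(local_projection(domain_map, a, local_halfwidth),
                   fit_window, threshold_frac, curvature_z),
      error = function(e) numeric(0))
    partners <- partners[abs(partners - a) >= fit_window]
    for (p in partners) directed[[length(directed) + 1L]] <- c(a, p)
  }
  if (length(directed) == 0L)
    return(structure(empty, class = c("loop_calls", "data.frame")))
  dm <- do.call(rbind, directed)
  pairs <- cbind(pmin(dm[, 1], dm[, 2]), pmax(dm[, 1], dm[, 2]))
  # bidirectional: a directed pair whose reverse also exists within one
  # fit window in both coordinates
  bidir <- vapply(seq_len(nrow(dm)), function(k) {
    any(abs(dm[, 1] - dm[k, 2]) < fit_window &
        abs(dm[, 2] - dm[k, 1]) < fit_window)
  }, logical(1))
  # deduplicate pairs within one fit window, preferring high confidence
  ord <- order(!bidir, pairs[, 1], pairs[, 2])
  out <- empty
  for (k in ord) {
    dup <- nrow(out) > 0L &&
      any(abs(out$site_i - pairs[k, 1]) < fit_window &
          abs(out$site_j - pairs[k, 2]) < fit_window)
    if (!dup)
      out <- rbind(out, data.frame(site_i = pairs[k, 1],
                                   site_j = pairs[k, 2],
                                   confidence = if (bidir[k]) "high"
                                                else "low"))
  }
  out <- out[order(out$site_i, out$site_j), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("loop_calls", "data.frame"))
}

#' @export
print.loop_calls <- function(x, ...) {
  cat(sprintf("Loop calls: %d pair(s) (%d high confidence)\n", nrow(x),
              sum(x$confidence == "high")))
  if (nrow(x) > 0L) print.data.frame(x)
  invisible(x)
}

#' Write loop calls as BEDPE-like TSV
#'
#' @param calls a `loop_calls` data.frame.
#' @param path output file.
#' @param chrom chromosome label.
#' @param bin_size bin size used to form end coordinates, bp.
#' @export
write_loop_calls <- function(calls, path, chrom = "chr", bin_size = 2500) {
  df <- data.frame(chrom1 = chrom, start1 = calls$site_i,
                   end1 = calls$site_i + bin_size,
                   chrom2 = chrom, start2 = calls$site_j,
                   end2 = calls$site_j + bin_size,
                   confidence = calls$confidence)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ground-truth loop-base coordinates of a configuration
#'
#' The boundaries of consecutive loops in every domain (f + 1 coordinates
#' for an f-loop domain), in bp from the start of the configuration; the
#' planted truth that loop calling should recover.
#'
#' @param config a `domain_config` or configuration string.
#' @param lattice a [lattice_spec()].
#' @param variant loop-length variant (as in [build_initial_chain()]).
#' @return numeric vector of genomic positions, bp.
#' @export
loop_base_coords <- function(config, lattice = lattice_spec(),
                             variant = "mean") {
  if (is.character(config)) config <- parse_domain_config(config)
  segs <- .expand_config(config, lattice, variant)
  bases <- numeric(0)
  bp <- 0
  prev_kind <- ""
  for (sg in segs) {
    if (sg$kind == "loop") {
      bases <- c(bases, bp)                    # loop start boundary
    } else if (prev_kind == "loop") {
      bases <- c(bases, bp)                    # end of a loop run
    }
    bp <- bp + sg$beads * lattice$bp_per_bond
    prev_kind <- sg$kind
  }
  if (prev_kind == "loop") bases <- c(bases, bp)
  unique(bases)
}
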