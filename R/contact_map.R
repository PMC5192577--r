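#' Construct a contact-map object
#'
#' A symmetric genomic contact-probability matrix at fixed bin size.
#' Coordinates are 0-based, half-open genomic bins: bin `i` covers
#' `[start + (i-1)*bin_size, start + i*bin_size)`.
#'
#' @param matrix square symmetric numeric matrix with values in \[0, 1\]
#'   (NA marks masked entries).
#' @param bin_size bin size, bp.
#' @param start genomic start coordinate of the first bin, bp.
#' @return object of class `contact_map`.
#' @export
contact_map <- function(matrix, bin_size = 2500, start = 0) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix), bin_size > 0)
  if (max(abs(matrix - t(matrix)), na.rm = TRUE) > 1e-12)
    stop("contact matrix must be symmetric")
  rng <- range(matrix, na.rm = TRUE)
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
    stop("contact probabilities must lie in [0, 1]")
  structure(list(matrix = matrix, bin_size = bin_size, start = start),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map: %d x %d bins of %g bp (%.3g Mb from %g bp)\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_size,
              nrow(x$matrix) * x$bin_size / 1e6, x$start))
  invisible(x)
}

#' Bin positions (bp, bin starts) of a contact map
#' @param map a `contact_map`.
#' @export
map_positions <- function(map) {
  map$start + (seq_len(nrow(map$matrix)) - 1L) * map$bin_size
}

#' Contact-probability map of a simulated ensemble
#'
#' `P(i, j)` is the fraction of conformations in which any bead pair of
#' genomic bins i and j lies within the capture radius. The default capture
#' radius is the bonded-neighbour scale `sqrt(3) a` of the 26-neighbour
#' lattice, so chain-adjacent beads always register as contacts.
#'
#' @param ensemble a `chain_ensemble` from [sample_ensemble()].
#' @param capture_radius contact distance threshold, nm.
#' @param bin_size genomic bin size, bp; must be a multiple of the
#'   lattice's bp per bond.
#' @return a [contact_map()].
#' @export
contact_map_from_ensemble <- function(ensemble, capture_radius = NULL,
                                      bin_size = 2500) {
  stopifnot(inherits(ensemble, "chain_ensemble"),
            length(ensemble$conformations) >= 1L)
  lat <- ensemble$chain$lattice
  if (is.null(capture_radius)) capture_radius <- sqrt(3) * lat$a
  if (bin_size %% lat$bp_per_bond != 0)
    stop("bin_size must be a multiple of the lattice bp per bond")
  n <- nrow(ensemble$chain$coords)
  # bead i covers [(i-1), i) bonds worth of sequence
  bead_bp <- (seq_len(n) - 1L) * lat$bp_per_bond
  bin <- as.integer(bead_bp %/% bin_size)
  n_bins <- max(bin) + 1L
  counts <- cpp_contact_counts(ensemble$conformations, bin, n_bins,
                               capture_radius / lat$a + 1e-9)
  contact_map(counts / length(ensemble$conformations), bin_size, 0)
}

#' Read / write contact maps as dense text matrices
#'
#' The text format is a one-line comment header
#' `# chromodyn contact map: bin_size=<bp> start=<bp>` followed by dense
#' whitespace-delimited rows at full float precision; `read_map(write_map())`
#' is the identity.
#'
#' @param path file path.
#' @param symmetrize for `read_map`: when TRUE, an asymmetric input is
#'   replaced by `(M + t(M))/2` instead of being rejected.
#' @return `read_map` returns a [contact_map()]; `write_map` its path.
#' @export
read_map <- function(path, symmetrize = FALSE) {
  header <- readLines(path, n = 1L)
  if (!grepl("bin_size=", header)) stop("missing contact-map header")
  bin_size <- as.numeric(sub(".*bin_size=([0-9.eE+-]+).*", "\\1", header))
  start <- if (grepl("start=", header))
    as.numeric(sub(".*start=([0-9.eE+-]+).*", "\\1", header)) else 0
  m <- as.matrix(read.table(path, skip = 1L))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("contact matrix must be square")
  asym <- max(abs(m - t(m)), na.rm = TRUE)
  if (asym > 1e-12) {
    if (!symmetrize)
      stop(sprintf("asymmetric matrix (max |M - t(M)| = %g); use symmetrize",
                   asym))
    m <- (m + t(m)) / 2
  }
  contact_map(m, bin_size, start)
}

#' @param map a `contact_map`.
#' @rdname read_map
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chromodyn contact map: bin_size=%.17g start=%.17g",
                     map$bin_size, map$start), con)
  write.table(format(map$matrix, digits = 17, trim = TRUE,
                     scientific = TRUE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Rebin a contact map
#'
#' Downsampling to a coarser bin (an integer multiple) takes block means;
#' upsampling to a finer bin (an integer divisor) interpolates bilinearly.
#' Symmetry is preserved.
#'
#' @param map a `contact_map`.
#' @param new_bin_size target bin size, bp.
#' @return a [contact_map()].
#' @export
rebin <- function(map, new_bin_size) {
  stopifnot(inherits(map, "contact_map"), new_bin_size > 0)
  old <- map$bin_size
  if (new_bin_size == old) return(map)
  m <- map$matrix
  if (new_bin_size > old) {
    if (new_bin_size %% old != 0)
      stop("coarser bin size must be a multiple of the current one")
    k <- new_bin_size %/% old
    if (nrow(m) %% k != 0)
      stop("matrix size is not divisible by the rebinning factor")
    nb <- nrow(m) %/% k
    grp <- rep(seq_len(nb), each = k)
    # block means via two successive group-means
    half <- apply(m, 2, function(col) tapply(col, grp, mean))
    out <- t(apply(half, 1, function(row) tapply(row, grp, mean)))
    out <- unname(as.matrix(out))
  } else {
    if (old %% new_bin_size != 0)
      stop("finer bin size must divide the current one")
    k <- old %/% new_bin_size
    nb <- nrow(m) * k
    # bilinear interpolation on bin-centre coordinates
    oc <- (seq_len(nrow(m)) - 0.5) * old
    nc <- (seq_len(nb) - 0.5) * new_bin_size
    interp_rows <- apply(m, 2, function(col)
      approx(oc, col, xout = nc, rule = 2)$y)
    out <- apply(interp_rows, 1, function(row)
      approx(oc, row, xout = nc, rule = 2)$y)
    out <- (out + t(out)) / 2  # guard symmetry against float noise
  }
  contact_map(out, new_bin_size, map$start)
}

#' Azimuthally (diagonal-band) averaged contact decay
#'
#' Mean contact probability as a function of genomic separation.
#' @param map a `contact_map`.
#' @return data.frame with `separation` (bp) and `p`.
#' @export
contact_decay <- function(map) {
  m <- map$matrix
  n <- nrow(m)
  sep <- (0:(n - 1L)) * map$bin_size
  p <- vapply(0:(n - 1L), function(d) {
    i <- seq_len(n - d)
    mean(m[cbind(i, i + d)], na.rm = TRUE)
  }, numeric(1))
  data.frame(separation = sep, p = p)
}
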