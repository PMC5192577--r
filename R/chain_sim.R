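#' Lattice specification for chain simulations
#'
#' Chains are modeled as beads on a 3D cubic lattice with grid constant
#' `a` (the assumed fiber diameter); consecutive beads occupy one of the 26
#' surrounding sites, giving bond lengths `a`, `sqrt(2) a` and `sqrt(3) a`
#' with mean bond length close to `b = sqrt(2) a`. One bond corresponds to
#' `bp_per_bond` of genomic sequence.
#'
#' @param a grid constant, nm.
#' @param bp_per_bond genomic content per bond, bp.
#' @return object of class `lattice_spec` with derived `b = sqrt(2) a`.
#' @export
lattice_spec <- function(a = 30, bp_per_bond = 2500) {
  stopifnot(a > 0, bp_per_bond > 0)
  structure(list(a = a, b = sqrt(2) * a, bp_per_bond = bp_per_bond),
            class = "lattice_spec")
}

# ---- domain-configuration grammar ------------------------------------------
# lin(x) - dom(y)[loop(z) - loop(z2/z3/...) - ...] - dom(y2)[glob(y2)] - ...
# lengths in kb; multi-valued loop lengths (slash-separated) are length
# variants varied synchronously across all multi-valued loops.

#' Parse a domain-configuration string
#'
#' Parses the domain grammar `lin(x)` (linear stretch of x kb),
#' `dom(y)[...]` (domain of y kb made of `loop(z)` elements or a single
#' `glob(z)` globular stretch), with elements joined by dashes. Loop lengths
#' may list several slash-separated variants that are varied synchronously.
#' The declared domain size is checked against the sum of its content
#' (at the variant mean) and rejected when they disagree by more than 2.5%.
#'
#' @param text configuration string.
#' @return object of class `domain_config`.
#' @export
parse_domain_config <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("–", "-", text)          # en-dash separators
  pos <- 1L
  n <- nchar(s)
  skip_ws <- function() {
    while (pos <= n && grepl("^\\s$", substr(s, pos, pos))) pos <<- pos + 1L
  }
  fail <- function(msg) stop(sprintf("config parse error at position %d: %s",
                                     pos, msg), call. = FALSE)
  eat <- function(pattern) {
    m <- regmatches(substr(s, pos, n), regexpr(paste0("^", pattern),
                                               substr(s, pos, n)))
    if (length(m) == 0L) return(NULL)
    pos <<- pos + nchar(m)
    m
  }
  parse_len <- function(tok) {
    v <- suppressWarnings(as.numeric(strsplit(tok, "/", fixed = TRUE)[[1]]))
    if (anyNA(v) || any(v <= 0)) fail("invalid length")
    v
  }
  elements <- list()
  repeat {
    skip_ws()
    if (pos > n) break
    kw <- eat("(lin|dom)")
    if (is.null(kw)) fail("expected 'lin' or 'dom'")
    skip_ws()
    if (is.null(eat("\\("))) fail("expected '('")
    skip_ws()
    len <- eat("[0-9./]+")
    if (is.null(len)) fail("expected a length")
    skip_ws()
    if (is.null(eat("\\)"))) fail("expected ')'")
    if (kw == "lin") {
      v <- parse_len(len)
      if (length(v) != 1L) fail("lin length cannot have variants")
      elements[[length(elements) + 1L]] <- list(type = "lin", kb = v)
    } else {
      dom_kb <- parse_len(len)
      if (length(dom_kb) != 1L) fail("dom length cannot have variants")
      skip_ws()
      if (is.null(eat("\\["))) fail("expected '[' after dom(...)")
      content <- list()
      repeat {
        skip_ws()
        ckw <- eat("(loop|glob)")
        if (is.null(ckw)) fail("expected 'loop' or 'glob'")
        skip_ws()
        if (is.null(eat("\\("))) fail("expected '('")
        skip_ws()
        clen <- eat("[0-9./]+")
        if (is.null(clen)) fail("expected a length")
        skip_ws()
        if (is.null(eat("\\)"))) fail("expected ')'")
        v <- parse_len(clen)
        if (ckw == "glob" && length(v) != 1L) fail("glob cannot have variants")
        content[[length(content) + 1L]] <- list(type = ckw, kb = v)
        skip_ws()
        if (!is.null(eat("\\]"))) break
        if (is.null(eat("-"))) fail("expected '-' or ']' in dom content")
      }
      types <- vapply(content, `[[`, "", "type")
      if (any(types == "glob") && length(content) != 1L)
        fail("a dom may contain either loops or a single glob")
      content_kb <- sum(vapply(content, function(e) mean(e$kb), numeric(1)))
      if (abs(content_kb - dom_kb) > 0.025 * dom_kb)
        fail(sprintf("dom content mismatch: declared %g kb, content %g kb",
                     dom_kb, content_kb))
      elements[[length(elements) + 1L]] <-
        list(type = "dom", kb = dom_kb, content = content)
    }
    skip_ws()
    if (pos > n) break
    if (is.null(eat("-"))) fail("expected '-' between elements")
  }
  if (length(elements) == 0L) stop("empty configuration")
  structure(list(elements = elements), class = "domain_config")
}

#' Serialize a domain configuration to its canonical string
#' @param config a `domain_config`.
#' @return character string; `parse_domain_config()` of it round-trips.
#' @export
format_domain_config <- function(config) {
  stopifnot(inherits(config, "domain_config"))
  fmt_len <- function(kb) paste(format(kb, trim = TRUE, scientific = FALSE),
                                collapse = "/")
  parts <- vapply(config$elements, function(el) {
    if (el$type == "lin") {
      sprintf("lin(%s)", fmt_len(el$kb))
    } else {
      inner <- vapply(el$content, function(ce)
        sprintf("%s(%s)", ce$type, fmt_len(ce$kb)), "")
      sprintf("dom(%s)[%s]", fmt_len(el$kb), paste(inner, collapse = " - "))
    }
  }, "")
  paste(parts, collapse = " - ")
}

#' @export
print.domain_config <- function(x, ...) {
  cat("Domain configuration:\n  ", format_domain_config(x), "\n", sep = "")
  cat(sprintf("  total %g kb in %d elements\n", total_kb(x),
              length(x$elements)))
  invisible(x)
}

#' Total genomic length of a configuration (variant mean), kb
#' @param config a `domain_config`.
#' @export
total_kb <- function(config) {
  sum(vapply(config$elements, function(el) {
    if (el$type == "lin") el$kb
    else sum(vapply(el$content, function(ce) mean(ce$kb), numeric(1)))
  }, numeric(1)))
}

#' Number of length variants encoded in a configuration
#' @param config a `domain_config`.
#' @export
n_variants <- function(config) {
  nv <- 1L
  for (el in config$elements) {
    if (el$type == "dom")
      for (ce in el$content)
        if (length(ce$kb) > 1L) nv <- max(nv, length(ce$kb))
  }
  nv
}

# Expand a config into a per-segment bead plan. variant = "mean" or an
# integer index into the synchronous variant lists.
.expand_config <- function(config, lattice, variant = "mean") {
  pick <- function(kb) {
    if (identical(variant, "mean")) mean(kb)
    else kb[((as.integer(variant) - 1L) %% length(kb)) + 1L]
  }
  segs <- list()
  for (ei in seq_along(config$elements)) {
    el <- config$elements[[ei]]
    if (el$type == "lin") {
      nb <- max(1L, round(el$kb * 1000 / lattice$bp_per_bond))
      segs[[length(segs) + 1L]] <-
        list(kind = "lin", element = ei, beads = nb,
             tag = sprintf("lin%d", ei))
    } else {
      for (ci in seq_along(el$content)) {
        ce <- el$content[[ci]]
        kb <- pick(ce$kb)
        nb <- max(2L, round(kb * 1000 / lattice$bp_per_bond))
        segs[[length(segs) + 1L]] <-
          list(kind = ce$type, element = ei, beads = nb,
               tag = sprintf("dom%d:%s%d", ei, ce$type, ci))
      }
    }
  }
  segs
}

# ---- deterministic initial layout ------------------------------------------
# Every element advances the chain along +z: linear stretches run straight
# up, each loop occupies its own z-layer as a flattened hairpin whose first
# and last beads are lattice neighbours, and globs fill a boustrophedon
# cuboid. Layouts of successive elements therefore never collide.

.layout_loop <- function(base, nb) {
  x0 <- base[1]; y0 <- base[2]; z <- base[3]
  if (nb %% 2L == 0L) {
    m <- nb %/% 2L
    xs <- c(x0 + 0:(m - 1L), x0 + (m - 1L):0)
    ys <- c(rep(y0, m), rep(y0 + 1L, m))
  } else {
    m <- (nb + 1L) %/% 2L
    xs <- c(x0 + 0:(m - 1L), x0 + (m - 2L):0)
    ys <- c(rep(y0, m), rep(y0 + 1L, nb - m))
  }
  cbind(xs, ys, rep(z, nb))
}

.layout_glob <- function(base, nb) {
  s <- ceiling(nb^(1 / 3))
  # serpentine order of one s x s plane
  plane <- do.call(rbind, lapply(0:(s - 1L), function(y) {
    xs <- 0:(s - 1L)
    if (y %% 2L == 1L) xs <- rev(xs)
    cbind(xs, y)
  }))
  coords <- matrix(0L, nrow = nb, ncol = 3)
  k <- 1L
  for (l in 0:(s - 1L)) {
    ord <- if (l %% 2L == 0L) seq_len(nrow(plane)) else rev(seq_len(nrow(plane)))
    for (r in ord) {
      coords[k, ] <- c(base[1] + plane[r, 1], base[2] + plane[r, 2],
                       base[3] + l)
      k <- k + 1L
      if (k > nb) break
    }
    if (k > nb) break
  }
  coords
}

#' Build an initial self-avoiding lattice chain from a configuration
#'
#' Lays out the configuration deterministically on the lattice: all chain
#' invariants (no double occupancy, 26-neighbour bonds, loop closure between
#' each loop's first and last bead, consecutive loop bases within one
#' lattice step) hold by construction. Globular stretches additionally carry
#' a spherical confinement whose radius gives volume fraction `phi`.
#'
#' @param config a `domain_config` or configuration string.
#' @param lattice a [lattice_spec()].
#' @param variant `"mean"` or integer index selecting synchronous loop-length
#'   variants.
#' @param phi target volume fraction of globular stretches inside their
#'   confinement sphere.
#' @return object of class `lattice_chain`: integer `coords` (N x 3, lattice
#'   units), `annotation`, `loops` (bead index ranges), `edges`, confinement
#'   data, the `lattice` and the source `config`.
#' @export
build_initial_chain <- function(config, lattice = lattice_spec(),
                                variant = "mean", phi = 0.1) {
  if (is.character(config)) config <- parse_domain_config(config)
  stopifnot(inherits(config, "domain_config"), phi > 0, phi < 1)
  segs <- .expand_config(config, lattice, variant)
  coords <- NULL
  annotation <- character(0)
  loops <- NULL
  conf_group <- integer(0)
  conf_center <- NULL
  conf_radius <- numeric(0)
  cursor <- c(0L, 0L, -1L)   # next bead goes to cursor + (0,0,1)
  for (sg in segs) {
    base <- cursor + c(0L, 0L, 1L)
    if (sg$kind == "lin") {
      xyz <- cbind(base[1], base[2], base[3] + 0:(sg$beads - 1L))
      grp <- rep(-1L, sg$beads)
    } else if (sg$kind == "loop") {
      xyz <- .layout_loop(base, sg$beads)
      s_idx <- if (is.null(coords)) 1L else nrow(coords) + 1L
      loops <- rbind(loops, c(s_idx, s_idx + sg$beads - 1L))
      grp <- rep(-1L, sg$beads)
    } else {  # glob
      xyz <- .layout_glob(base, sg$beads)
      g <- length(conf_radius)
      ctr <- colMeans(xyz)
      r_c <- (3 * sg$beads / (4 * pi * phi))^(1 / 3)
      conf_center <- rbind(conf_center, ctr)
      conf_radius <- c(conf_radius, max(r_c, max(sqrt(colSums(
        (t(xyz) - ctr)^2)))))
      grp <- rep(g, sg$beads)
    }
    coords <- rbind(coords, xyz)
    annotation <- c(annotation, rep(sg$tag, sg$beads))
    conf_group <- c(conf_group, grp)
    cursor <- coords[nrow(coords), ]
  }
  storage.mode(coords) <- "integer"
  dimnames(coords) <- NULL
  n <- nrow(coords)
  edges <- cbind(1:(n - 1L), 2:n)
  if (!is.null(loops)) edges <- rbind(edges, loops)
  # chain bonds where a tail-regrowth cut is legal: both beads outside
  # every loop (cuts at loop-base junctions would rigidly translate whole
  # loop clusters - expensive and almost never accepted) and no confined
  # bead downstream
  cut_ok <- rep(TRUE, n - 1L)
  if (!is.null(loops))
    for (k in seq_len(nrow(loops))) {
      lo <- max(1L, loops[k, 1] - 1L)
      hi <- min(n - 1L, loops[k, 2])
      cut_ok[lo:hi] <- FALSE
    }
  if (any(conf_group >= 0L)) {
    last_conf <- max(which(conf_group >= 0L))
    cut_ok[seq_len(min(last_conf, n - 1L))] <- FALSE
  }
  chain <- structure(list(coords = coords, annotation = annotation,
                          loops = loops, edges = edges,
                          cut_candidates = which(cut_ok) - 1L,
                          conf_group = conf_group,
                          conf_center = if (is.null(conf_center))
                            matrix(0, 0, 3) else unname(conf_center),
                          conf_radius = conf_radius,
                          lattice = lattice, config = config,
                          variant = variant),
                     class = "lattice_chain")
  validate_chain(chain)
  chain
}

#' Validate the invariants of a lattice chain
#'
#' Checks single occupancy of lattice sites, 26-neighbour connectivity of
#' consecutive beads, and loop closure (first and last bead of every loop
#' are lattice neighbours).
#'
#' @param chain a `lattice_chain`.
#' @param self_avoiding check single occupancy (default TRUE).
#' @return the chain, invisibly; errors on violation.
#' @export
validate_chain <- function(chain, self_avoiding = TRUE) {
  xyz <- chain$coords
  if (self_avoiding &&
      anyDuplicated(paste(xyz[, 1], xyz[, 2], xyz[, 3])) > 0L)
    stop("double occupancy of lattice sites")
  d <- abs(xyz[chain$edges[, 1], , drop = FALSE] -
           xyz[chain$edges[, 2], , drop = FALSE])
  cheb <- pmax(d[, 1], d[, 2], d[, 3])
  if (any(cheb != 1L))
    stop("bond (chain or loop-closure) outside the 26-neighbourhood")
  invisible(chain)
}

#' @export
print.lattice_chain <- function(x, ...) {
  cat(sprintf("Lattice chain: %d beads (%g kb), %d loop(s), a = %g nm\n",
              nrow(x$coords),
              nrow(x$coords) * x$lattice$bp_per_bond / 1000,
              if (is.null(x$loops)) 0L else nrow(x$loops), x$lattice$a))
  invisible(x)
}

#' Monte Carlo equilibration of a lattice chain
#'
#' Runs single-bead Metropolis moves (symmetric proposals to one of the 26
#' surrounding sites, rejected when a bond would stretch beyond one lattice
#' step, a site is doubly occupied, or a confined bead would leave its
#' sphere). One sweep is one attempted move per bead.
#'
#' @param chain a `lattice_chain`.
#' @param n_sweeps number of sweeps; default 100 per bead
#'   (`100 * n_beads` sweeps).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param self_avoiding enforce single occupancy (TRUE) or run a phantom
#'   chain (FALSE).
#' @param p_tail fraction of attempted moves that are tail regrowths
#'   (resampling one chain bond outside all loops and rigidly translating
#'   the downstream chain; accelerates linear-stretch relaxation).
#' @return the chain with updated coordinates and an `mc_stats` attribute
#'   (accepted/attempted move counts).
#' @export
mc_equilibrate <- function(chain, n_sweeps = NULL, seed = 1L,
                           self_avoiding = TRUE, p_tail = 0.2) {
  stopifnot(inherits(chain, "lattice_chain"))
  n <- nrow(chain$coords)
  if (is.null(n_sweeps)) n_sweeps <- 100 * n
  set.seed(seed)
  res <- cpp_mc_run(chain$coords, chain$edges - 1L, n_sweeps * n,
                    self_avoiding, chain$conf_group, chain$conf_center,
                    chain$conf_radius, chain$cut_candidates, p_tail)
  chain$coords <- res$coords
  attr(chain, "mc_stats") <- list(accepted = res$accepted,
                                  attempted = res$attempted,
                                  acceptance = res$accepted / res$attempted)
  validate_chain(chain, self_avoiding)
  chain
}

# continue MC from current state without reseeding (used by sample_ensemble)
.mc_continue <- function(chain, n_sweeps, self_avoiding = TRUE,
                         p_tail = 0.2) {
  n <- nrow(chain$coords)
  res <- cpp_mc_run(chain$coords, chain$edges - 1L, n_sweeps * n,
                    self_avoiding, chain$conf_group, chain$conf_center,
                    chain$conf_radius, chain$cut_candidates, p_tail)
  chain$coords <- res$coords
  chain
}

#' Sample an ensemble of equilibrated conformations
#'
#' Builds the chain, equilibrates it, then records a conformation every
#' `sweeps_between` sweeps. Reproducible under a fixed seed.
#'
#' @param config `domain_config` or configuration string.
#' @param n_conformations number of conformations to record.
#' @param sweeps_between sweeps between recorded conformations (default 10
#'   per bead).
#' @param seed RNG seed.
#' @param lattice a [lattice_spec()].
#' @param equil_sweeps equilibration sweeps before sampling (default 100 per
#'   bead).
#' @param self_avoiding enforce single occupancy.
#' @param variant loop-length variant passed to [build_initial_chain()].
#' @param phi globule confinement volume fraction.
#' @return object of class `chain_ensemble`: template `chain`, list
#'   `conformations` of integer coordinate matrices, `seed`.
#' @export
sample_ensemble <- function(config, n_conformations, sweeps_between = NULL,
                            seed = 1L, lattice = lattice_spec(),
                            equil_sweeps = NULL, self_avoiding = TRUE,
                            variant = "mean", phi = 0.1) {
  stopifnot(n_conformations >= 1)
  chain <- build_initial_chain(config, lattice, variant, phi)
  n <- nrow(chain$coords)
  if (is.null(sweeps_between)) sweeps_between <- 10 * n
  if (is.null(equil_sweeps)) equil_sweeps <- 100 * n
  chain <- mc_equilibrate(chain, equil_sweeps, seed, self_avoiding)
  conformations <- vector("list", n_conformations)
  conformations[[1L]] <- chain$coords
  if (n_conformations > 1L) {
    for (i in 2:n_conformations) {
      chain <- .mc_continue(chain, sweeps_between, self_avoiding)
      conformations[[i]] <- chain$coords
    }
  }
  validate_chain(chain, self_avoiding)
  structure(list(chain = chain, conformations = conformations, seed = seed,
                 self_avoiding = self_avoiding),
            class = "chain_ensemble")
}

#' @export
print.chain_ensemble <- function(x, ...) {
  st <- chain_statistics(x)
  cat(sprintf("Chain ensemble: %d conformations of %d beads\n",
              length(x$conformations), nrow(x$chain$coords)))
  cat(sprintf("  <R_g> = %.1f +- %.1f nm\n", st$rg_mean, st$rg_sd))
  invisible(x)
}

.rg_nm <- function(xyz, a) {
  ctr <- colMeans(xyz)
  a * sqrt(mean(rowSums((sweep(xyz, 2, ctr))^2)))
}

#' Summary statistics of a conformational ensemble
#'
#' @param ensemble a `chain_ensemble`.
#' @return list with `rg` (per-conformation gyration radius, nm), `rg_mean`,
#'   `rg_sd`, `end_to_end` (mean end-to-end distance, nm) and `bond_hist`
#'   (table of chain bond lengths, nm) with `bond_mean`.
#' @export
chain_statistics <- function(ensemble) {
  stopifnot(inherits(ensemble, "chain_ensemble"),
            length(ensemble$conformations) >= 1L)
  a <- ensemble$chain$lattice$a
  rg <- vapply(ensemble$conformations, .rg_nm, numeric(1), a = a)
  n <- nrow(ensemble$chain$coords)
  ee <- vapply(ensemble$conformations, function(xyz)
    a * sqrt(sum((xyz[n, ] - xyz[1L, ])^2)), numeric(1))
  bonds <- unlist(lapply(ensemble$conformations, function(xyz) {
    d <- xyz[-1L, , drop = FALSE] - xyz[-n, , drop = FALSE]
    round(a * sqrt(rowSums(d^2)), 6)
  }))
  list(rg = rg, rg_mean = mean(rg), rg_sd = sd(rg),
       end_to_end = mean(ee), bond_hist = table(bonds),
       bond_mean = mean(bonds))
}

#' Export a conformation as an XYZ-like TSV
#'
#' Columns: bead index, element tag, x, y, z in nm.
#' @param chain a `lattice_chain`.
#' @param path output file.
#' @export
write_chain_tsv <- function(chain, path) {
  a <- chain$lattice$a
  df <- data.frame(bead = seq_len(nrow(chain$coords)),
                   element = chain$annotation,
                   x = chain$coords[, 1] * a, y = chain$coords[, 2] * a,
                   z = chain$coords[, 3] * a)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Model chromatin configuration strings
#'
#' `example_rosette_config()` is the 5-Mb loop-cluster model configuration
#' (four rosette domains joined by relaxed linear stretches; the first
#' domain's loops alternate 166/167 kb so six loops sum to 999 kb, and two
#' loops of the 1300-kb domain carry synchronous length variants);
#' `example_globule_config()` is its globular counterpart.
#' @name example_configs
#' @export
example_rosette_config <- function() {
  paste0(
    "lin(100) - dom(1000)[loop(166) - loop(167) - loop(166) - loop(167) - ",
    "loop(166) - loop(167)] - lin(150) - ",
    "dom(1300)[loop(100/125/150/175/200) - loop(95) - loop(90) - loop(85) - ",
    "loop(120/145/170/195/220) - loop(150) - loop(125) - loop(115) - ",
    "loop(160) - loop(150)] - lin(150) - ",
    "dom(1000)[loop(185) - loop(120) - loop(95) - loop(120) - loop(235) - ",
    "loop(245)] - lin(50) - ",
    "dom(1100)[loop(138) - loop(160) - loop(95) - loop(170) - loop(160) - ",
    "loop(183) - loop(128) - loop(68)] - lin(150)")
}

#' @rdname example_configs
#' @export
example_globule_config <- function() {
  paste0("lin(100) - dom(1000)[glob(1000)] - lin(150) - ",
         "dom(1300)[glob(1300)] - lin(150) - dom(1000)[glob(1000)] - ",
         "lin(50) - dom(1100)[glob(1100)] - lin(150)")
}

#' The ten-loop 1300-kb rosette domain as a standalone configuration
#' @rdname example_configs
#' @export
rosette_1300_config <- function() {
  paste0("dom(1300)[loop(100/125/150/175/200) - loop(95) - loop(90) - ",
         "loop(85) - loop(120/145/170/195/220) - loop(150) - loop(125) - ",
         "loop(115) - loop(160) - loop(150)]")
}
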