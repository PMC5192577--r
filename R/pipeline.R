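# Pipeline orchestration: YAML/list configuration, schema validation and
# the two end-to-end workflows (structure: config -> ensemble -> map ->
# loop calls; dynamics: traces -> correlate -> window scan -> relaxation
# fit -> domain geometry).

.config_blocks <- c("polymer", "chain", "map", "fcs", "binding",
                    "accessibility", "synth", "seed", "out_dir",
                    "log_level")

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list. Unknown top-level keys are
#' rejected; a global `seed` is required.
#'
#' @param config path to a YAML file or a named list.
#' @return validated configuration list of class `pipeline_config`.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .config_blocks)
  if (length(unknown) > 0)
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config must set a global 'seed'")
  structure(config, class = c("pipeline_config", "list"))
}

.cfg <- function(config, block, key, default) {
  v <- config[[block]][[key]]
  if (is.null(v)) default else v
}

.polymer_env <- function(config) {
  physical_environment(eta_s = .cfg(config, "polymer", "eta_s", 4.306e-3),
                       T = .cfg(config, "polymer", "T", 310.15))
}

.polymer_calib <- function(config) {
  chromatin_calibration(
    NRL = .cfg(config, "polymer", "NRL", 191),
    c_nuc = .cfg(config, "polymer", "c_nuc", c(100, 140)),
    rel_density = .cfg(config, "polymer", "rel_density", 1),
    chi_V = .cfg(config, "polymer", "chi_V", 0.724))
}

#' Structure pipeline: configuration to loop calls and ensemble geometry
#'
#' Runs the full structural workflow: parse the domain configuration,
#' sample a Monte Carlo ensemble, compute the contact map, mask and analyze
#' each domain, and report loop calls plus ensemble gyration statistics.
#' Artifacts (map, loop calls, conformation) are written under `out_dir`
#' when set, along with the resolved config and a JSON report.
#'
#' @param config pipeline configuration ([load_config()] input).
#' @return report list of class `pipeline_report`.
#' @export
run_structure_pipeline <- function(config) {
  config <- load_config(config)
  if (is.null(config$chain$config))
    stop("structure pipeline requires chain$config")
  lattice <- lattice_spec(a = .cfg(config, "chain", "a", 30),
                          bp_per_bond = .cfg(config, "chain",
                                             "bp_per_bond", 2500))
  parsed <- parse_domain_config(config$chain$config)
  ens <- sample_ensemble(parsed,
                         n_conformations = .cfg(config, "chain", "n", 50),
                         sweeps_between = config$chain$sweeps_between,
                         equil_sweeps = config$chain$equil_sweeps,
                         seed = config$seed, lattice = lattice,
                         phi = .cfg(config, "chain", "phi", 0.1))
  stats <- chain_statistics(ens)
  map <- contact_map_from_ensemble(
    ens, capture_radius = config$map$capture_radius,
    bin_size = .cfg(config, "map", "bin_size", 2500))
  masked <- extract_domain(
    map, diag_mask_halfwidth = .cfg(config, "map", "diag_mask", 30000))
  calls <- call_loop_bases(
    masked, fit_window = .cfg(config, "map", "fit_window", 30000),
    threshold_frac = .cfg(config, "map", "threshold_frac", 0.8))
  report <- structure(list(
    kind = "structure", seed = config$seed,
    config_string = format_domain_config(parsed),
    n_conformations = length(ens$conformations),
    rg_mean = stats$rg_mean, rg_sd = stats$rg_sd,
    bond_mean = stats$bond_mean,
    loop_calls = as.data.frame(unclass(calls)),
    planted_bases = loop_base_coords(parsed, lattice)),
    class = c("pipeline_report", "list"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_map(map, file.path(config$out_dir, "contact_map.tsv"))
    write_loop_calls(calls, file.path(config$out_dir, "loop_calls.tsv"),
                     bin_size = map$bin_size)
    write_chain_tsv(ens$chain, file.path(config$out_dir, "conformation.tsv"))
    yaml::write_yaml(unclass(config), file.path(config$out_dir,
                                                "resolved_config.yaml"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Dynamics pipeline: traces to relaxation times and domain geometry
#'
#' For each trace (synthetic, generated from the `synth` block, or read
#' from files): correlate over a window-size grid, select a stable window,
#' fit the composite relaxation model, and convert the first-mode time into
#' gyration radius and genomic content. Traces without a stable
#' window-scan plateau are flagged invalid and skipped.
#'
#' @param config pipeline configuration; either `fcs$traces` (paths of
#'   two-column TSVs with a `# dt=` header) or a `synth` block
#'   (`scenario: ou_bound` with `tau_1`, optionally `n_traces`).
#' @return report list of class `pipeline_report` with one row per trace.
#' @export
run_dynamics_pipeline <- function(config) {
  config <- load_config(config)
  env <- .polymer_env(config)
  calib <- .polymer_calib(config)
  focus <- focus_model(w_0 = .cfg(config, "fcs", "w_0", 200),
                       z_0 = .cfg(config, "fcs", "z_0", 1000))
  topology <- .cfg(config, "fcs", "topology", "loop_rosette")
  solvent <- .cfg(config, "fcs", "solvent", "theta")
  theta_grid <- .cfg(config, "fcs", "window_grid", c(1, 2, 5, 10, 15, 30))
  traces <- list()
  truths <- list()
  if (!is.null(config$fcs$traces)) {
    for (p in config$fcs$traces) {
      traces[[length(traces) + 1L]] <- read_trace(p)
      truths[[length(traces)]] <- NULL
    }
  } else if (!is.null(config$synth)) {
    n_traces <- .cfg(config, "synth", "n_traces", 1)
    tau_1 <- config$synth$tau_1
    if (is.null(tau_1)) stop("synth block requires tau_1 (s)")
    geom <- rg_from_relaxation(tau_1, topology, solvent, env, calib)
    spectrum <- mode_spectrum(geom$R_g, topology, solvent, env,
                              p_max = config$synth$p_max)
    for (i in seq_len(n_traces)) {
      tr <- simulate_ou_trace(
        spectrum, focus,
        n_emitters = .cfg(config, "synth", "n_emitters", 2000),
        brightness = .cfg(config, "synth", "brightness", 4e3),
        duration = .cfg(config, "synth", "duration", 30),
        seed = config$seed + i - 1)
      traces[[i]] <- tr
      truths[[i]] <- generator_truth(tr)
    }
  } else {
    stop("dynamics pipeline requires fcs$traces or a synth block")
  }
  rows <- list()
  for (i in seq_along(traces)) {
    res <- tryCatch({
      scan <- window_scan(traces[[i]], theta_grid, "relaxation",
                          topology = topology, solvent = solvent,
                          focus = focus, env = env, calib = calib)
      if (!scan$valid) {
        list(trace = i, valid = FALSE)
      } else {
        fit <- scan$fit
        out <- list(trace = i, valid = TRUE, window = scan$selected,
                    tau_1 = fit$coefficients$tau_1, R_g = fit$R_g,
                    gc_lo = fit$gc_range[1], gc_hi = fit$gc_range[2])
        if (!is.null(truths[[i]])) out$tau_1_truth <- truths[[i]]$tau_1
        out
      }
    }, error = function(e) list(trace = i, valid = FALSE,
                                error = conditionMessage(e)))
    rows[[i]] <- res
  }
  valid <- vapply(rows, function(r) isTRUE(r$valid), logical(1))
  report <- structure(list(kind = "dynamics", seed = config$seed,
                           n_traces = length(traces),
                           n_valid = sum(valid), traces = rows),
                      class = c("pipeline_report", "list"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config), file.path(config$out_dir,
                                                "resolved_config.yaml"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (%s), seed %d\n", x$kind, x$seed))
  if (x$kind == "structure") {
    cat(sprintf("  <R_g> = %.1f +- %.1f nm over %d conformations\n",
                x$rg_mean, x$rg_sd, x$n_conformations))
    cat(sprintf("  %d loop call(s), %d planted base(s)\n",
                nrow(x$loop_calls), length(x$planted_bases)))
  } else {
    cat(sprintf("  %d/%d trace(s) valid\n", x$n_valid, x$n_traces))
    for (r in x$traces) {
      if (isTRUE(r$valid))
        cat(sprintf("  trace %d: tau_1 = %.1f ms, R_g = %.0f nm\n",
                    r$trace, 1e3 * r$tau_1, r$R_g))
      else cat(sprintf("  trace %d: invalid\n", r$trace))
    }
  }
  invisible(x)
}

#' Write / read an intensity trace as TSV with a metadata header
#'
#' Header comment line carries `dt`; columns are the channels.
#' @param trace an [fcs_trace()].
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chromodyn trace: dt=%.17g channels=%d", trace$dt,
                     ncol(trace$counts)), con)
  write.table(trace$counts, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("dt=", header)) stop("missing trace header with dt")
  dt <- as.numeric(sub(".*dt=([0-9.eE+-]+).*", "\\1", header))
  m <- as.matrix(read.table(path, skip = 1L))
  dimnames(m) <- NULL
  fcs_trace(m, dt)
}
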