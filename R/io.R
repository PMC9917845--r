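# File formats: tidy CSV for profiles/observations (comment-char '#'
# provenance headers), two-column text for spectra, YAML run configs.

.pkg_version <- function() {
  as.character(utils::packageVersion("srbcolumn"))
}

# small polynomial content hash for provenance lines (no external digest dep)
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  b <- utf8ToInt(s)
  h <- 0
  for (v in b) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.provenance <- function(seed, hash) {
  c(paste0("# srbcolumn ", .pkg_version()),
    paste0("# config_hash: ", hash),
    paste0("# seed: ", if (is.null(seed)) "NA" else seed))
}

.write_csv_prov <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write / read steady-state profile tables
#'
#' Tidy CSV (depth, species, value, unit) with provenance header lines
#' (package version, config hash, seed) prefixed by `#`.
#'
#' @param result `srb_profile`.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(result, path, seed = NULL) {
  .write_csv_prov(result$profiles, path, seed, .config_hash(result$config))
  invisible(path)
}

#' @rdname write_profiles
#' @export
write_minerals <- function(result, path, seed = NULL) {
  .write_csv_prov(result$minerals, path, seed, .config_hash(result$config))
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Read observed depth profiles from tidy CSV
#'
#' Expects columns depth, replicate, species, value (extra columns are
#' ignored); malformed files raise an error naming the offending column.
#'
#' @param path CSV path.
#' @param detection_limits Optional named detection-limit overrides (mg/L).
#' @return `observed_profiles`.
#' @export
read_observed_profiles <- function(path, detection_limits = NULL) {
  d <- utils::read.csv(path, comment.char = "#")
  if (nrow(d) == 0) stop("no observation rows in ", path, call. = FALSE)
  need <- c("depth", "replicate", "species", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("observations file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(d$depth) || !is.numeric(d$value)) {
    bad <- if (!is.numeric(d$depth)) "depth" else "value"
    stop("column '", bad, "' in ", path, " is not numeric", call. = FALSE)
  }
  observed_profiles(d[need], detection_limits)
}

#' Write / read two-column spectrum files
#'
#' Plain text: `# label / # edge <element> <energy>` header then
#' energy and absorption columns.
#'
#' @param spec `xanes_spectrum`.
#' @param path File path.
#' @return `path` (write) or `xanes_spectrum` (read).
#' @export
write_spectrum <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# label ", spec$label),
               paste0("# edge ", spec$edge_element, " ", spec$edge_energy)),
             con)
  utils::write.table(data.frame(energy = spec$energy,
                                absorption = spec$absorption),
                     con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  hdr <- readLines(path, n = 10)
  lab <- sub("^# label ", "", grep("^# label ", hdr, value = TRUE)[1])
  edge <- strsplit(sub("^# edge ", "", grep("^# edge ", hdr,
                                            value = TRUE)[1]), " ")[[1]]
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  xanes_spectrum(d$energy, d$absorption,
                 label = if (is.na(lab)) basename(path) else lab,
                 edge_element = if (length(edge) == 2) edge[1] else "Zn",
                 edge_energy = if (length(edge) == 2) as.numeric(edge[2])
                 else 9659)
}

#' Load a run configuration file
#'
#' YAML with top-level blocks `column`, `influent`, `kinetics` and scalar
#' `thermo` (path or null), `seed`, `verbosity`. Unknown keys anywhere are
#' rejected. The bundled default reproduces the study column.
#'
#' @param path YAML path; `NULL` loads the bundled default.
#' @return List: `config` (`column_config`), `params` (`kinetic_params`),
#'   `db` (`thermo_db`), `seed`, `verbosity`, `hash`.
#' @export
load_run_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_run.yaml", package = "srbcolumn")
  }
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  chk <- function(block, allowed, where) {
    extra <- setdiff(names(block), allowed)
    if (length(extra)) {
      stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
  }
  chk(y, c("column", "influent", "kinetics", "thermo", "seed", "verbosity"),
      "config")
  chk(y$column, c("length", "diameter", "hrt", "n_cells", "sampling_depths",
                  "temperature"), "column")
  chk(y$influent, c("ph", "do", "so4", "tic", "zn", "cu", "cd", "ca", "si",
                    "ethanol_mmol"), "influent")
  chk(y$kinetics, c("k1", "k2", "k3", "k4", "k5", "time_unit", "do_gate",
                    "gate_sharpness", "calcite_area", "calcite_mass",
                    "calcite_coeffs"), "kinetics")
  # a config without an influent block means the study feed (which carries
  # the nominal 1.0 mmol/L ethanol dose)
  inf_args <- utils::modifyList(list(ethanol_mmol = 1.0),
                                y$influent %||% list())
  influent <- do.call(influent_composition, inf_args)
  config <- do.call(column_config,
                    c(y$column %||% list(), list(influent = influent)))
  params <- do.call(kinetic_params, y$kinetics %||% list())
  db <- if (is.null(y$thermo)) default_thermo_db() else load_thermo_db(y$thermo)
  list(config = config, params = params, db = db,
       seed = y$seed %||% 1, verbosity = y$verbosity %||% 1,
       hash = .config_hash(y))
}

#' Pipeline commands
#'
#' Thin entry points tying the modules into a reproducible pipeline; the
#' CLI script shipped under `inst/cli/srbcol` dispatches to them.
#' `cmd_simulate` writes port profiles, per-depth mineral deposition and a
#' run log; `cmd_calibrate` refits the kinetic constants to an observation
#' file and writes a fit report plus residuals; `cmd_lcf` fits target
#' spectra against a reference library and writes a fraction/R-factor
#' table; `cmd_synth` writes a synthetic observation set.
#'
#' @param config_path YAML run config (`NULL` = bundled default).
#' @param out_dir Output directory (created if needed).
#' @param engine Forward engine: `lagrangian` single-parcel steady state or
#'   the equivalent `time_stepped` operator-splitting loop.
#' @return `cmd_simulate`: the `srb_profile`, invisibly.
#' @export
cmd_simulate <- function(config_path = NULL, out_dir = ".",
                         engine = c("lagrangian", "time_stepped")) {
  engine <- match.arg(engine)
  rc <- load_run_config(config_path)
  res <- if (engine == "lagrangian") {
    steady_profile(rc$config, rc$params, rc$db)
  } else {
    simulate_to_steady_state(rc$config, rc$params, rc$db)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_profiles(res, file.path(out_dir, "profiles.csv"), rc$seed)
  write_minerals(res, file.path(out_dir, "minerals.csv"), rc$seed)
  writeLines(c(.provenance(rc$seed, rc$hash),
               paste0("# engine: ", res$method),
               paste0("# pore_volumes: ", res$pore_volumes),
               paste0("# thermo: ", rc$db$source)),
             file.path(out_dir, "run_log.txt"))
  invisible(res)
}

#' @rdname cmd_simulate
#' @param obs_path Observations CSV (tidy depth/replicate/species/value).
#' @param n_starts Optimizer starts.
#' @param seed Seed override (default: config seed).
#' @export
cmd_calibrate <- function(config_path = NULL, obs_path, out_dir = ".",
                          n_starts = 1, seed = NULL) {
  rc <- load_run_config(config_path)
  obs <- read_observed_profiles(obs_path)
  seed <- seed %||% rc$seed
  fit <- fit_kinetics(obs, init = rc$params, config = rc$config, db = rc$db,
                      seed = seed, n_starts = n_starts)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep_df <- data.frame(parameter = names(fit$log10_k),
                       estimate = 10^fit$log10_k,
                       log10 = fit$log10_k, se_log10 = fit$se_log10,
                       identifiable = !(names(fit$log10_k) %in%
                                          fit$non_identifiable))
  .write_csv_prov(rep_df, file.path(out_dir, "fit_report.csv"), seed, rc$hash)
  resid <- .calib_residuals(fit$params, obs, rc$config, rc$db)
  rd <- obs$data
  rd$weighted_residual <- resid
  .write_csv_prov(rd, file.path(out_dir, "fit_residuals.csv"), seed, rc$hash)
  invisible(fit)
}

#' @rdname cmd_simulate
#' @param target_paths Spectrum files to fit.
#' @param ref_paths Reference spectrum files.
#' @param out_path Output CSV.
#' @param sum_constrained Constrain fractions to sum to 1?
#' @export
cmd_lcf <- function(target_paths, ref_paths, out_path = "lcf_report.csv",
                    sum_constrained = FALSE) {
  refs <- lapply(ref_paths, read_spectrum)
  rows <- lapply(target_paths, function(tp) {
    tg <- read_spectrum(tp)
    r <- lcf_fit(tg, refs, sum_constrained = sum_constrained)
    out <- as.data.frame(as.list(round(100 * r$fractions, 2)))
    names(out) <- names(r$fractions)
    cbind(data.frame(sample = tg$label), out,
          data.frame(r_factor = r$r_factor))
  })
  df <- do.call(rbind, rows)
  .write_csv_prov(df, out_path, NULL, .config_hash(ref_paths))
  invisible(df)
}

#' @rdname cmd_simulate
#' @param out_path Output CSV for the synthetic observations.
#' @param noise_cv,n_replicates Noise structure (see [synthetic_spec()]).
#' @export
cmd_synth <- function(config_path = NULL, out_path = "synthetic_obs.csv",
                      noise_cv = 0.05, n_replicates = 2, seed = NULL) {
  rc <- load_run_config(config_path)
  seed <- seed %||% rc$seed
  sp <- synthetic_spec(rc$params, rc$config, noise_cv = noise_cv,
                       n_replicates = n_replicates, seed = seed)
  obs <- generate_observed_profiles(sp, rc$db)
  .write_csv_prov(obs$data, out_path, seed, rc$hash)
  invisible(obs)
}
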