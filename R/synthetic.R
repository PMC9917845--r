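#' Specification of a synthetic column observation study
#'
#' Bundles the generating forward model and noise structure used to emulate
#' the study's sampling design: 7 ports, duplicate columns, multiplicative
#' measurement noise, detection-limit censoring.
#'
#' @param params Generating `kinetic_params`.
#' @param config Generating `column_config`. The default uses a 16-cell grid,
#'   a resolution at which the kinetically controlled port profiles are
#'   grid-converged well below the 5% measurement noise.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise on concentrations (pH instead receives additive
#'   Gaussian noise with the same numeric standard deviation, in pH units).
#' @param n_replicates Number of replicate columns (the study ran duplicates).
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(params = kinetic_params(),
                           config = column_config(n_cells = 16),
                           noise_cv = 0.05, n_replicates = 2, seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(params = params, config = config, noise_cv = noise_cv,
                 n_replicates = n_replicates, seed = seed),
            class = "synthetic_spec")
}

#' Generate synthetic observed depth profiles
#'
#' Runs the forward model at the generating parameters and multiplies every
#' port concentration by lognormal noise with unit mean and coefficient of
#' variation `noise_cv` (sdlog = sqrt(log(1 + cv^2)), meanlog = -sdlog^2/2);
#' pH receives additive Gaussian noise. Values falling below the species
#' detection limit are truncated (reported at the limit), mirroring
#' left-censored laboratory reporting.
#'
#' @param spec `synthetic_spec`.
#' @param db `thermo_db`.
#' @return `observed_profiles` carrying the generating truth in
#'   `attr(, "truth")`.
#' @export
generate_observed_profiles <- function(spec, db = default_thermo_db()) {
  fw <- steady_profile(spec$config, spec$params, db)
  base <- fw$profiles
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  reps <- lapply(seq_len(spec$n_replicates), function(r) {
    v <- base$value
    is_ph <- base$species == "pH"
    if (spec$noise_cv > 0) {
      v[!is_ph] <- v[!is_ph] *
        stats::rlnorm(sum(!is_ph), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      v[is_ph] <- v[is_ph] + stats::rnorm(sum(is_ph), 0, spec$noise_cv)
    }
    data.frame(depth = base$depth, replicate = r, species = base$species,
               value = v)
  })
  d <- do.call(rbind, reps)
  obs <- observed_profiles(d)
  dl <- obs$detection_limits[d$species]
  cens <- !is.na(dl) & d$species != "pH" & d$value < dl
  d$value[cens] <- dl[cens]
  out <- observed_profiles(d, obs$detection_limits)
  attr(out, "truth") <- fw
  out
}

.EDGE_ENERGY <- c(Zn = 9659, Cu = 8979, Cd = 26711)

#' Generate a synthetic XANES reference library
#'
#' Builds `n_refs` distinct normalized reference spectra for one absorption
#' edge: an arctangent edge step plus reference-specific Gaussian white-line
#' and post-edge features, on a 0.5 eV grid from -50 to +100 eV about the
#' edge. Construction is retried (bounded) until all pairwise correlations
#' are below 0.99, so the library is usable as an LCF design matrix. The
#' spectra are built on the normalized scale (unit edge step, non-negative
#' absorption) and can be used directly as LCF standards.
#'
#' @param edge Element symbol: "Zn", "Cu" or "Cd" (K edges), or a numeric
#'   edge energy in eV.
#' @param n_refs Number of references (>= 2).
#' @param seed Integer seed; the library is reproducible from it.
#' @return List of `xanes_spectrum` objects labelled `<edge>_ref<i>`.
#' @export
generate_reference_spectra <- function(edge = "Zn", n_refs = 3, seed = 1) {
  if (n_refs < 2) stop("n_refs must be >= 2", call. = FALSE)
  e0 <- if (is.numeric(edge)) edge else .EDGE_ENERGY[[edge]]
  lab <- if (is.numeric(edge)) paste0("E", edge) else edge
  grid <- seq(e0 - 50, e0 + 100, by = 0.5)
  set.seed(seed)
  for (try in 1:50) {
    specs <- lapply(seq_len(n_refs), function(i) {
      width <- stats::runif(1, 1, 3)
      shift <- stats::runif(1, -2, 2)
      stepf <- 0.5 + atan((grid - e0 - shift) / width) / pi
      npk <- sample(1:3, 1)
      pk <- rep(0, length(grid))
      for (q in seq_len(npk)) {
        pos <- stats::runif(1, 3, 45)
        wid <- stats::runif(1, 2, 9)
        amp <- stats::runif(1, 0.2, 0.9)
        pk <- pk + amp * exp(-0.5 * ((grid - e0 - pos) / wid)^2)
      }
      xanes_spectrum(grid, stepf + pk, label = paste0(lab, "_ref", i),
                     edge_element = lab, edge_energy = e0)
    })
    M <- vapply(specs, function(s) s$absorption, numeric(length(grid)))
    cors <- stats::cor(M)
    if (max(cors[upper.tri(cors)]) < 0.99) return(specs)
  }
  stop("could not generate a sufficiently distinct reference library",
       call. = FALSE)
}

#' Mix reference spectra into a synthetic target
#'
#' @param refs List of `xanes_spectrum` on a common grid.
#' @param weights Non-negative weights, one per reference.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Seed for the noise draw.
#' @return `xanes_spectrum` of the mixture.
#' @export
mix_spectra <- function(refs, weights, noise_sd = 0, seed = 1) {
  if (length(refs) != length(weights) || any(weights < 0)) {
    stop("need one non-negative weight per reference", call. = FALSE)
  }
  grid <- refs[[1]]$energy
  M <- vapply(refs, function(s) s$absorption, numeric(length(grid)))
  y <- as.numeric(M %*% weights)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  xanes_spectrum(grid, y, label = "mixture",
                 edge_element = refs[[1]]$edge_element,
                 edge_energy = refs[[1]]$edge_energy)
}
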