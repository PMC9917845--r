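#' XANES spectrum container
#'
#' @param energy Strictly increasing energy grid, eV (>= 20 points).
#' @param absorption Absorption values, same length as `energy`.
#' @param label Identifier.
#' @param edge_element Element symbol of the absorption edge.
#' @param edge_energy Edge energy E0, eV (e.g. Zn K 9659, Cu K 8979,
#'   Cd K 26711).
#' @return Object of class `xanes_spectrum`.
#' @export
xanes_spectrum <- function(energy, absorption, label = "spectrum",
                           edge_element = "Zn", edge_energy = 9659) {
  if (length(energy) != length(absorption)) {
    stop("energy and absorption must have equal length", call. = FALSE)
  }
  if (length(energy) < 20) stop("need >= 20 points", call. = FALSE)
  if (any(diff(energy) <= 0)) {
    stop("energy grid must be strictly increasing", call. = FALSE)
  }
  structure(list(energy = energy, absorption = absorption, label = label,
                 edge_element = edge_element, edge_energy = edge_energy),
            class = "xanes_spectrum")
}

#' @export
print.xanes_spectrum <- function(x, ...) {
  cat("<xanes_spectrum>", x$label, ":", x$edge_element, "edge at",
      x$edge_energy, "eV;", length(x$energy), "points,",
      format(min(x$energy)), "-", format(max(x$energy)), "eV\n")
  invisible(x)
}

#' Interpolate a spectrum onto a target energy grid
#'
#' Linear interpolation; requesting points outside the measured range is an
#' error (no extrapolation).
#'
#' @param spec `xanes_spectrum`.
#' @param target_grid Energies, eV, within the spectrum's range.
#' @return Regridded `xanes_spectrum`.
#' @export
regrid <- function(spec, target_grid) {
  if (min(target_grid) < min(spec$energy) - 1e-9 ||
      max(target_grid) > max(spec$energy) + 1e-9) {
    stop("target grid extends beyond the measured energy range",
         call. = FALSE)
  }
  xanes_spectrum(target_grid,
                 stats::approx(spec$energy, spec$absorption,
                               xout = target_grid)$y,
                 label = spec$label, edge_element = spec$edge_element,
                 edge_energy = spec$edge_energy)
}

#' Edge-step normalization of a XANES spectrum
#'
#' Fits a straight line to the pre-edge window, subtracts it, fits a line to
#' the post-edge window, and scales the spectrum so the post-edge line
#' evaluates to 1 at the edge energy. Output is invariant to positive
#' scaling of the input.
#'
#' @param spec `xanes_spectrum`.
#' @param pre_range Length-2 eV window below the edge.
#' @param post_range Length-2 eV window above the edge.
#' @return Normalized `xanes_spectrum`.
#' @export
normalize_edge <- function(spec,
                           pre_range = spec$edge_energy + c(-50, -15),
                           post_range = spec$edge_energy + c(40, 95)) {
  e <- spec$energy; a <- spec$absorption
  pre <- e >= pre_range[1] & e <= pre_range[2]
  post <- e >= post_range[1] & e <= post_range[2]
  if (sum(pre) < 2 || sum(post) < 2) {
    stop("normalization windows must each contain >= 2 points", call. = FALSE)
  }
  if (post_range[1] <= spec$edge_energy) {
    stop("post-edge window must lie above the edge energy", call. = FALSE)
  }
  cpre <- stats::coef(stats::lm(a[pre] ~ e[pre]))
  a1 <- a - (cpre[1] + cpre[2] * e)
  cpost <- stats::coef(stats::lm(a1[post] ~ e[post]))
  step <- cpost[1] + cpost[2] * spec$edge_energy
  if (abs(step) < 1e-12) {
    stop("degenerate spectrum: zero edge step", call. = FALSE)
  }
  xanes_spectrum(e, a1 / step, label = spec$label,
                 edge_element = spec$edge_element,
                 edge_energy = spec$edge_energy)
}

#' Misfit R-factor of a fitted spectrum
#'
#' `sum((target - fit)^2) / sum(target^2)` over the common grid.
#'
#' @param target,fit `xanes_spectrum` objects on the same grid.
#' @return Dimensionless R-factor (0 for a perfect fit; invariant to common
#'   positive scaling).
#' @export
r_factor <- function(target, fit) {
  if (length(target$energy) != length(fit$energy) ||
      max(abs(target$energy - fit$energy)) > 1e-9) {
    stop("spectra must share a common grid", call. = FALSE)
  }
  denom <- sum(target$absorption^2)
  if (denom <= 0) stop("zero-norm target: R-factor undefined", call. = FALSE)
  sum((target$absorption - fit$absorption)^2) / denom
}

#' Linear combination fitting of a XANES spectrum
#'
#' Expresses the target spectrum as a non-negative weighted sum of reference
#' spectra over a fit window around the edge, by non-negative least squares.
#' Without the sum constraint the fractions may total away from 1 (the
#' convention of standard XANES analysis software, whose reported fractions
#' routinely sum to e.g. 101.5%); with `sum_constrained = TRUE` they total
#' exactly 1.
#'
#' @param target `xanes_spectrum`.
#' @param refs List of reference `xanes_spectrum` objects (>= 1).
#' @param sum_constrained Constrain fractions to sum to 1?
#' @param fit_range eV window around (relative to) the edge energy; default
#'   -20 to +80 eV.
#' @param normalized Are the inputs already edge-step normalized? If FALSE
#'   they are normalized first.
#' @return Object of class `lcf_result`: `fractions` (named, >= 0),
#'   `r_factor`, `fit_range`, `sum_constrained`, `condition_number`, plus
#'   the fitted spectrum. Collinear references (condition number > 1e6)
#'   trigger a warning.
#' @export
lcf_fit <- function(target, refs, sum_constrained = FALSE,
                    fit_range = c(-20, 80), normalized = TRUE) {
  if (length(refs) < 1) stop("need at least one reference", call. = FALSE)
  if (!normalized) {
    target <- normalize_edge(target)
    refs <- lapply(refs, normalize_edge)
  }
  e0 <- target$edge_energy
  lo <- max(e0 + fit_range[1], min(target$energy),
            vapply(refs, function(r) min(r$energy), 0))
  hi <- min(e0 + fit_range[2], max(target$energy),
            vapply(refs, function(r) max(r$energy), 0))
  grid <- target$energy[target$energy >= lo & target$energy <= hi]
  if (length(grid) < 2) stop("empty overlap window", call. = FALSE)
  y <- regrid(target, grid)$absorption
  A <- vapply(refs, function(r) regrid(r, grid)$absorption,
              numeric(length(grid)))
  A <- matrix(A, ncol = length(refs))
  labs <- vapply(refs, function(r) r$label, "")
  if (anyDuplicated(labs)) labs <- make.unique(labs)
  colnames(A) <- labs
  cond <- kappa(A, exact = TRUE)
  if (cond > 1e6) {
    warning("reference spectra are nearly collinear (condition number ",
            format(cond, digits = 3), ")", call. = FALSE)
  }
  if (sum_constrained) {
    w <- sqrt(1e10)
    x <- pracma::lsqnonneg(rbind(A, rep(w, ncol(A))), c(y, w))$x
    if (sum(x) > 0) x <- x / sum(x)
  } else {
    x <- pracma::lsqnonneg(A, y)$x
  }
  fit <- xanes_spectrum(grid, as.numeric(A %*% x), label = "lcf_fit",
                        edge_element = target$edge_element,
                        edge_energy = e0)
  tgt <- xanes_spectrum(grid, y, label = target$label,
                        edge_element = target$edge_element,
                        edge_energy = e0)
  structure(list(fractions = stats::setNames(x, colnames(A)),
                 r_factor = r_factor(tgt, fit),
                 fit_range = c(lo, hi), sum_constrained = sum_constrained,
                 condition_number = cond, fitted = fit, target = tgt),
            class = "lcf_result")
}

#' @export
print.lcf_result <- function(x, ...) {
  cat("<lcf_result> R-factor", format(x$r_factor, digits = 4),
      if (x$sum_constrained) "(sum-constrained)" else "", "\n")
  print(round(x$fractions, 4))
  invisible(x)
}
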