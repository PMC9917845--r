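#' Kinetic parameters of the column model
#'
#' Bundles the five microbial rate constants, the dissolved-oxygen gate that
#' switches sulfate-reducing metabolism on, and the calcite kinetic settings.
#' The microbial rate laws are bilinear in concentration:
#' \itemize{
#'   \item aerobic ethanol oxidation to acetate, rate `k1 [EtOH][DO]`
#'   \item aerobic acetate oxidation to bicarbonate, rate `k2 [Ac][DO]`
#'   \item sulfidogenic ethanol oxidation to acetate, rate `k3 [EtOH][SO4]`
#'   \item sulfidogenic acetate oxidation to bicarbonate, rate `k4 [Ac][SO4]`
#'   \item sulfate reduction to bisulfide, rate `k5 [SO4]`
#' }
#' Concentrations enter the laws in mmol/L. `k1`-`k4` are in L/mmol per model
#' time unit (`time_unit` seconds, default 3600, i.e. per hour); `k5` is in
#' 1/s as printed in the source rate law. This molar per-hour basis is the
#' one under which the published constants reproduce the observed spatial
#' structure of the column (oxygen depletion to the ~2 mg/L SRB activation
#' level near 0.2 m depth); see the methods vignette for the full argument.
#'
#' The three anaerobic laws are multiplied by a DO gate g(DO): a hard switch
#' at `do_gate` mg/L by default (`gate_sharpness = 0`), or a logistic ramp of
#' width `gate_sharpness` mg/L.
#'
#' @param k1,k2,k3,k4 Bilinear rate constants, L/mmol per time unit.
#' @param k5 First-order sulfate reduction constant, 1/s.
#' @param time_unit Seconds per model time unit for `k1`-`k4`.
#' @param do_gate DO threshold (mg/L) below which SRB metabolism is active.
#' @param gate_sharpness Logistic width (mg/L); 0 gives a hard switch.
#' @param calcite_area Specific surface area of calcite, m2/g.
#' @param calcite_mass Reactive calcite mass, g per L pore water. The default
#'   0 renders the limestone packing unreactive, consistent with the
#'   negligible Ca release observed at near-neutral pH.
#' @param calcite_coeffs Three signed coefficients of the temperature-specific
#'   calcite rate constant k6 = c1[H+] + c2[CO2] + c3[H2O] (g/m2/s with
#'   concentrations in g/L); k6 is clipped at 0 so the law only dissolves.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(k1 = 2.4e-1, k2 = 3.6e-2, k3 = 4.8e-2,
                           k4 = 9.8e-3, k5 = 5.0e-6, time_unit = 3600,
                           do_gate = 2.0, gate_sharpness = 0,
                           calcite_area = 0.05, calcite_mass = 0,
                           calcite_coeffs = c(-29.59, -144.9, -322.9)) {
  ks <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5)
  if (any(ks < 0)) stop("rate constants must be >= 0", call. = FALSE)
  if (do_gate < 0) stop("do_gate must be >= 0", call. = FALSE)
  if (calcite_area < 0 || calcite_mass < 0) {
    stop("calcite_area and calcite_mass must be >= 0", call. = FALSE)
  }
  if (time_unit <= 0) stop("time_unit must be > 0", call. = FALSE)
  if (length(calcite_coeffs) != 3) stop("calcite_coeffs must have length 3",
                                        call. = FALSE)
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
                 time_unit = time_unit, do_gate = do_gate,
                 gate_sharpness = gate_sharpness,
                 calcite_area = calcite_area, calcite_mass = calcite_mass,
                 calcite_coeffs = calcite_coeffs),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params> k1..k4 (L/mmol per", x$time_unit, "s):",
      x$k1, x$k2, x$k3, x$k4, "; k5 (1/s):", x$k5,
      "; DO gate", x$do_gate, "mg/L\n")
  invisible(x)
}

#' SRB dissolved-oxygen gate factor
#'
#' @param do DO concentration, mg/L.
#' @param p `kinetic_params`.
#' @return Gate factor in `[0, 1]`; 1 when DO is at or below the gate.
#' @export
do_gate_factor <- function(do, p) {
  if (p$gate_sharpness > 0) {
    stats::plogis((p$do_gate - do) / p$gate_sharpness)
  } else {
    as.numeric(do <= p$do_gate)
  }
}

# molar masses used to move between mg/L and mmol/L on the kinetics surface
.MM <- c(ethanol = 46.068, acetate = 59.044, do = 31.998, so4 = 96.06,
         hs = 33.073, tic = 61.017, h = 1.008)

#' Net microbial reaction rates for one solution composition
#'
#' Assembles the five rate laws and their stoichiometric coupling into signed
#' net production rates. Stoichiometry, written toward the carbonate/acetate
#' /bisulfide components (protons counted as total dissolved proton excess):
#' aerobic ethanol -> acetate consumes 1 O2 and yields 1 H+; aerobic acetate
#' -> 2 HCO3- consumes 2 O2 and yields 1 H+; sulfidogenic ethanol -> acetate
#' yields 0.5 H+ per ethanol; sulfidogenic acetate -> 2 HCO3-; sulfate ->
#' bisulfide 1:1 (the single sulfate sink -- the sulfidogenic donor laws do
#' not additionally consume sulfate).
#'
#' @param ctx List or data.frame with `ethanol`, `acetate`, `do`, `so4`
#'   concentrations in mg/L.
#' @param p `kinetic_params`.
#' @return Named vector of net rates in mg/L per model time unit for
#'   `ethanol`, `acetate`, `do`, `so4`, `hs` (as HS-), `tic` (as HCO3-), and
#'   `h` (proton excess, as H). Zero concentrations give zero rates.
#' @export
microbial_rates <- function(ctx, p) {
  E <- ctx$ethanol / .MM[["ethanol"]]
  A <- ctx$acetate / .MM[["acetate"]]
  DO <- ctx$do / .MM[["do"]]
  S <- ctx$so4 / .MM[["so4"]]
  g <- do_gate_factor(ctx$do, p)
  r <- .raw_rates(E, A, DO, S, g, p)
  c(ethanol = (-r[1] - r[3]) * .MM[["ethanol"]],
    acetate = (r[1] + r[3] - r[2] - r[4]) * .MM[["acetate"]],
    do = (-r[1] - 2 * r[2]) * .MM[["do"]],
    so4 = -r[5] * .MM[["so4"]],
    hs = r[5] * .MM[["hs"]],
    tic = (2 * r[2] + 2 * r[4]) * .MM[["tic"]],
    h = (r[1] + 3 * r[2] + 0.5 * r[3] + 2 * r[4]) * .MM[["h"]])
}

# the five raw rates in mmol/L per time unit (k5 converted from per second)
.raw_rates <- function(E, A, DO, S, g, p) {
  c(p$k1 * E * DO,
    p$k2 * A * DO,
    g * p$k3 * E * S,
    g * p$k4 * A * S,
    g * p$k5 * p$time_unit * S)
}

#' Calcite dissolution rate (transition-state surface law)
#'
#' Rate = k6 * A * (1 - Omega)^(2/3) where Omega is the calcite saturation
#' ratio (10^SI) and k6 = c1[H+] + c2[CO2] + c3[H2O] with concentrations in
#' g/L. The published coefficient triple is negative, which would make the
#' dissolution rate non-positive; k6 is therefore clipped at 0, so with the
#' default coefficients the packing is inert (matching the negligible Ca
#' release at near-neutral pH), while user-supplied positive coefficients
#' recover an active surface-controlled dissolution law. The law never
#' precipitates: at or above saturation the rate is exactly 0 (precipitation
#' is handled by [equilibrate_minerals()]).
#'
#' @param state Converged `solution_state`.
#' @param p `kinetic_params`.
#' @return Dissolution rate in mol calcite per L pore water per second
#'   (>= 0), already scaled by `calcite_area` and `calcite_mass`.
#' @export
calcite_rate <- function(state, p) {
  om <- 10^saturation_index(state, "calcite")
  if (!is.finite(om)) om <- 0
  if (om >= 1) return(0)
  h_gl <- state$conc[["H"]] * 1.008
  co2_gl <- state$conc[["H2CO3"]] * 44.009
  k6 <- max(p$calcite_coeffs[1] * h_gl + p$calcite_coeffs[2] * co2_gl +
              p$calcite_coeffs[3] * 1000, 0)
  k6 * p$calcite_area * p$calcite_mass * (1 - om)^(2 / 3) / 100.087
}

#' Construct a grid-cell state
#'
#' @param totals Named component totals, mol/L (H entry = total proton excess).
#' @param minerals Named mineral inventories, mol per L pore water.
#' @param state Optional cached `solution_state`.
#' @return Object of class `cell_state`.
#' @export
cell_state <- function(totals, minerals = NULL, state = NULL) {
  structure(list(totals = totals,
                 minerals = minerals %||% numeric(0),
                 state = state, active = character(0)),
            class = "cell_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Advance one cell through a kinetics + equilibrium operator-splitting step
#'
#' Integrates the microbial rate laws over `dt` seconds with classical RK4 on
#' an adaptive sub-step (the sub-step is halved until no reacting species
#' would cross zero), applies frozen-state calcite dissolution when
#' configured, then re-speciates the solution at the updated total proton
#' excess and equilibrates the allowed mineral phases. Elemental inventories
#' (dissolved + mineral) are conserved across the step.
#'
#' @param cell `cell_state`.
#' @param dt Step length, seconds.
#' @param p `kinetic_params`.
#' @param db `thermo_db`.
#' @param allowed Minerals permitted to precipitate/dissolve.
#' @return Updated `cell_state` (the speciated state is cached on it).
#' @export
integrate_cell <- function(cell, dt, p, db = default_thermo_db(),
                           allowed = NULL) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  cn <- db$components$name
  tot <- stats::setNames(numeric(length(cn)), cn)
  tot[names(cell$totals)] <- cell$totals
  # kinetic sub-integration, mmol/L in model time units
  y <- c(E = tot[["EtOH"]], A = tot[["Ac"]], DO = tot[["O2"]],
         S = tot[["SO4"]]) * 1000
  acc <- c(HS = 0, TIC = 0, H = 0)
  tau <- dt / p$time_unit
  lam <- p$k1 * y[["DO"]] + p$k2 * y[["DO"]] + (p$k3 + p$k4) * y[["S"]] +
    p$k5 * p$time_unit
  n_sub <- max(1L, min(2^20, ceiling(tau * lam / 0.25)))
  rhs <- function(y) {
    do_mgl <- y[3] * .MM[["do"]]
    g <- do_gate_factor(do_mgl, p)
    r <- .raw_rates(y[1], y[2], y[3], y[4], g, p)
    c(-r[1] - r[3], r[1] + r[3] - r[2] - r[4], -r[1] - 2 * r[2], -r[5],
      r[5], 2 * r[2] + 2 * r[4], r[1] + 3 * r[2] + 0.5 * r[3] + 2 * r[4])
  }
  repeat {
    h <- tau / n_sub
    yy <- c(y, acc)
    ok <- TRUE
    for (s in seq_len(n_sub)) {
      k1v <- rhs(yy)
      k2v <- rhs(yy + h / 2 * k1v)
      k3v <- rhs(yy + h / 2 * k2v)
      k4v <- rhs(yy + h * k3v)
      yn <- yy + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
      if (any(yn[1:4] < -1e-10)) { ok <- FALSE; break }
      yn[1:4][yn[1:4] < 0] <- 0   # clip sub-roundoff negatives
      yy <- yn
    }
    if (ok) break
    n_sub <- n_sub * 2L
    if (n_sub > 2^20) {
      stop("integrate_cell: sub-step underflow (stiff kinetics); state: ",
           paste(sprintf("%s=%.3g", names(y), y), collapse = " "),
           call. = FALSE)
    }
  }
  tot[["EtOH"]] <- yy[["E"]] / 1000
  tot[["Ac"]]   <- yy[["A"]] / 1000
  tot[["O2"]]   <- yy[["DO"]] / 1000
  tot[["SO4"]]  <- yy[["S"]] / 1000
  tot[["HS"]]   <- tot[["HS"]] + yy[["HS"]] / 1000
  tot[["CO3"]]  <- tot[["CO3"]] + yy[["TIC"]] / 1000
  tot[["H"]]    <- tot[["H"]] + yy[["H"]] / 1000
  # frozen-state calcite dissolution over the step
  if (p$calcite_mass > 0 && !is.null(cell$state)) {
    dca <- calcite_rate(cell$state, p) * dt
    tot[["Ca"]] <- tot[["Ca"]] + dca
    tot[["CO3"]] <- tot[["CO3"]] + dca
  }
  warm <- if (!is.null(cell$state)) cell$state$warm else NULL
  st <- tryCatch(
    solve_speciation(tot, db, mode = "total_h", warm = warm),
    srb_solver_error = function(e) solve_speciation(tot, db, mode = "total_h"))
  eq <- equilibrate_minerals(st, allowed = allowed, amounts = cell$minerals,
                             active_init = cell$active)
  structure(list(totals = eq$state$totals, minerals = eq$amounts,
                 state = eq$state, active = names(eq$amounts)[eq$amounts > 0],
                 deltas = eq$deltas),
            class = "cell_state")
}
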