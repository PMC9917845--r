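# Aqueous equilibrium speciation: damped Newton solve of component mole
# balances under mass action, in log concentration space, with an outer
# fixed-point on the Davies activity model. Optionally solves simultaneous
# mineral equilibria (SI = 0 rows with precipitated amounts as extra
# unknowns); that path is driven by equilibrate_minerals().

.LN10 <- log(10)

# Core solver. totals: named mol/L over db components (H entry = total
# dissolved proton excess in "total_h" mode). mode: "fixed_ph", "total_h" or
# "charge_balance". active_minerals: character vector of mineral names whose
# SI is pinned to 0 with precipitation extent delta as unknown. warm: list
# (lnc, I) from a previous nearby solve.
.speciate <- function(totals, db, mode, pH = NA_real_,
                      active_minerals = character(), warm = NULL,
                      maxit = 200, tol = 1e-10, tol_si = 1e-9) {
  cn <- db$components$name
  nc <- length(cn)
  tot <- numeric(nc); names(tot) <- cn
  tot[names(totals)] <- totals
  # sub-roundoff negatives from exact-cancellation mineral transfers
  tiny <- tot < 0 & tot > -1e-12 & cn != "H"
  tot[tiny] <- 0
  if (any(tot[setdiff(cn, "H")] < 0)) {
    stop("negative component total: ",
         paste(cn[tot < 0 & cn != "H"], collapse = ", "), call. = FALSE)
  }
  iH <- match("H", cn)
  nm_act <- match(active_minerals, db$minerals$name)
  if (anyNA(nm_act)) stop("unknown mineral in active set", call. = FALSE)
  NUM <- db$nu_min[nm_act, , drop = FALSE]

  has_min <- colSums(abs(NUM)) > 0
  absent <- (tot <= 0) & !has_min
  absent[iH] <- FALSE
  # active species: all non-H components they use must be present
  nuH0 <- db$nu; nuH0[, iH] <- 0
  sp_act <- which(!(abs(nuH0) %*% absent > 0))
  NUs <- db$nu[sp_act, , drop = FALSE]
  has_sp <- colSums(abs(NUs)) > 0
  solved <- !absent & (has_sp | has_min)
  solved[iH] <- mode != "fixed_ph"
  fixedc <- !absent & !solved           # inert comps: free conc == total
  fixedc[iH] <- FALSE                   # fixed-pH H enters via its activity
  is <- which(solved); ifx <- which(fixedc)
  ns <- length(is); nmin <- length(nm_act)
  if (ns == 0L && nmin == 0L) {
    # nothing to solve (e.g. fixed-pH water with no totals)
    return(.spec_pack(tot, db, mode, pH, numeric(0), integer(0), ifx, absent,
                      lnc = numeric(0), csp = numeric(0)[0], sp_act = integer(0),
                      I = 0, niter = 0L, maxres = 0))
  }

  NUs_s <- NUs[, is, drop = FALSE]
  NUs_f <- NUs[, ifx, drop = FALSE]
  NUM_s <- NUM[, is, drop = FALSE]
  lnK <- .LN10 * db$logk[sp_act]
  z_all <- db$z_comp; z_sp <- db$z_spec[sp_act]
  s_scale <- pmax(abs(tot[is]), 1e-8)

  # initial guess
  x <- log(pmax(0.5 * abs(tot[is]), 1e-10))
  names(x) <- cn[is]
  if (solved[iH]) x[cn[is] == "H"] <- log(1e-7)
  if (!is.null(warm) && !is.null(warm$lnc)) {
    w <- warm$lnc[cn[is]]
    ok <- !is.na(w) & is.finite(w)
    x[ok] <- w[ok]
  }
  delta <- rep(0, nmin)
  I <- if (!is.null(warm) && !is.null(warm$I)) warm$I else 0.005
  lnaH_fix <- if (mode == "fixed_ph") -.LN10 * pH else NA_real_
  balance_rows <- if (mode == "total_h") seq_len(ns) else which(cn[is] != "H")
  cb_row <- mode == "charge_balance"
  niter_tot <- 0L

  for (outer in 1:40) {
    lg_c <- .log10_gamma(z_all, I)        # per component
    lg_s <- .log10_gamma(z_sp, I)         # per species
    lngam_s <- .LN10 * lg_c[is]
    # constant part of species log conc: logK, fixed comps, fixed aH
    cst <- lnK - .LN10 * lg_s
    if (length(ifx)) {
      cst <- cst + as.numeric(NUs_f %*% (.LN10 * lg_c[ifx] + log(pmax(tot[ifx], 1e-300))))
    }
    if (mode == "fixed_ph") cst <- cst + NUs[, iH] * lnaH_fix

    eval_res <- function(x, delta) {
      ci <- exp(x)
      lncj <- cst + as.numeric(NUs_s %*% (lngam_s + x))
      cj <- exp(lncj)
      diss <- ci + as.numeric(t(NUs_s) %*% cj)
      held <- if (nmin) as.numeric(t(NUM_s) %*% delta) else 0
      R <- (diss + held - tot[is]) / s_scale
      if (cb_row) {
        allc <- z_all[is] * ci
        q <- sum(allc) + sum(z_sp * cj)
        qs <- sum(abs(allc)) + sum(abs(z_sp) * cj)
        if (length(ifx)) {
          q <- q + sum(z_all[ifx] * tot[ifx])
          qs <- qs + sum(abs(z_all[ifx]) * tot[ifx])
        }
        R[cn[is] == "H"] <- q / max(qs, 1e-14)
      }
      Rm <- if (nmin) {
        log10a <- lg_c[is] + x / .LN10
        as.numeric(NUM_s %*% log10a) +
          (if (length(ifx)) as.numeric(NUM[, ifx, drop = FALSE] %*%
                                         (lg_c[ifx] + log10(pmax(tot[ifx], 1e-300)))) else 0) +
          (if (mode == "fixed_ph") NUM[, iH] * (-pH) else 0) -
          db$logksp[nm_act]
      } else numeric(0)
      list(R = R, Rm = Rm, ci = ci, cj = cj,
           f = max(abs(c(R[balance_rows], if (cb_row) R[cn[is] == "H"], Rm / 10))))
    }

    ev <- eval_res(x, delta)
    converged <- FALSE
    for (it in seq_len(maxit)) {
      niter_tot <- niter_tot + 1L
      if (max(abs(ev$R)) < tol && (nmin == 0L || max(abs(ev$Rm)) < tol_si)) {
        converged <- TRUE; break
      }
      W <- NUs_s * ev$cj
      Jb <- (diag(ev$ci, ns) + t(NUs_s) %*% W) / s_scale
      if (cb_row) {
        k <- which(cn[is] == "H")
        allc <- z_all[is] * ev$ci
        qs <- sum(abs(allc)) + sum(abs(z_sp) * ev$cj) +
          (if (length(ifx)) sum(abs(z_all[ifx]) * tot[ifx]) else 0)
        Jb[k, ] <- (z_all[is] * ev$ci + as.numeric(t(W) %*% z_sp)) / max(qs, 1e-14)
      }
      if (nmin) {
        Jd <- t(NUM_s) / s_scale
        # electroneutral formulas do not move the charge-balance residual
        if (cb_row) Jd[cn[is] == "H", ] <- 0
        J <- rbind(cbind(Jb, Jd),
                   cbind(NUM_s / .LN10, matrix(0, nmin, nmin)))
        Rfull <- c(ev$R, ev$Rm)
      } else {
        J <- Jb; Rfull <- ev$R
      }
      step <- tryCatch(solve(J, -Rfull), error = function(e) {
        # near-singular (metal almost fully precipitated): pseudo-inverse
        sv <- svd(J)
        pos <- sv$d > max(sv$d) * 1e-13
        as.numeric(sv$v[, pos, drop = FALSE] %*%
                     ((t(sv$u[, pos, drop = FALSE]) %*% -Rfull) / sv$d[pos]))
      })
      sx <- step[seq_len(ns)]
      cap <- max(abs(sx))
      if (cap > 6) step <- step * (6 / cap)
      lam <- 1
      f0 <- ev$f
      for (bt in 1:30) {
        xn <- x + lam * step[seq_len(ns)]
        dn <- if (nmin) delta + lam * step[ns + seq_len(nmin)] else delta
        evn <- eval_res(xn, dn)
        if (is.finite(evn$f) && (evn$f < f0 || evn$f < tol)) break
        lam <- lam / 2
      }
      x <- xn; delta <- dn; ev <- evn
    }
    if (!converged) {
      cond <- simpleError(paste0("speciation solver did not converge; max residual ",
                                 format(max(abs(c(ev$R, ev$Rm))), digits = 4)))
      class(cond) <- c("srb_solver_error", class(cond))
      cond$residuals <- c(ev$R, ev$Rm)
      stop(cond)
    }
    Inew <- 0.5 * (sum(z_all[is]^2 * ev$ci) + sum(z_sp^2 * ev$cj) +
                     (if (length(ifx)) sum(z_all[ifx]^2 * tot[ifx]) else 0) +
                     (if (mode == "fixed_ph") 10^(-pH) else 0))
    if (abs(Inew - I) < 1e-10 * max(Inew, 1e-6)) { I <- Inew; break }
    I <- Inew
  }

  .spec_pack(tot, db, mode, pH, delta, nm_act, ifx, absent,
             lnc = x, csp = ev$cj, sp_act = sp_act, I = I,
             niter = niter_tot, maxres = max(abs(c(ev$R, ev$Rm))))
}

# assemble the solver output into a solution_state
.spec_pack <- function(tot, db, mode, pH, delta, nm_act, ifx, absent,
                       lnc, csp, sp_act, I, niter, maxres) {
  cn <- db$components$name
  conc_c <- numeric(length(cn)); names(conc_c) <- cn
  conc_c[ifx] <- tot[ifx]
  conc_c[names(lnc)] <- exp(lnc)
  if (mode == "fixed_ph") {
    gH <- activity_coefficient(1, I)
    conc_c["H"] <- 10^(-pH) / gH
  }
  lg_c <- .log10_gamma(db$z_comp, I)
  act_c <- conc_c * 10^lg_c
  act_c[absent] <- 0
  act_s <- numeric(nrow(db$species)); names(act_s) <- db$species$name
  conc_s <- act_s
  if (length(sp_act)) {
    conc_s[sp_act] <- csp
    act_s[sp_act] <- csp * 10^(.log10_gamma(db$z_spec[sp_act], I))
  }
  pH_out <- if (mode == "fixed_ph") pH else -log10(act_c[["H"]])
  # dissolved totals actually held in solution (after mineral transfer)
  diss <- conc_c + as.numeric(t(db$nu) %*% conc_s)
  names(diss) <- cn
  deltas <- numeric(nrow(db$minerals)); names(deltas) <- db$minerals$name
  if (length(nm_act)) deltas[nm_act] <- delta
  st <- list(totals = tot - as.numeric(t(db$nu_min) %*% deltas),
             pH = unname(pH_out), ionic_strength = I,
             activities = c(act_c, act_s),
             conc = c(conc_c, conc_s),
             temperature = db$temperature, mode = mode,
             converged = TRUE, iterations = niter, max_residual = maxres,
             db = db, warm = list(lnc = lnc, I = I))
  class(st) <- "solution_state"
  list(state = st, deltas = deltas)
}

#' Solve aqueous equilibrium speciation
#'
#' Newton solve of the component mole balances under mass action, with Davies
#' activity corrections updated by an outer fixed point on ionic strength.
#' Three closure modes: `fixed_ph` (proton activity prescribed, proton balance
#' dropped), `charge_balance` (pH solved so the solution is electroneutral),
#' and `total_h` (pH solved from a prescribed total dissolved proton excess,
#' the closure used inside the transport loop where kinetic reactions
#' increment the proton inventory).
#'
#' @param totals Named numeric vector of component totals in mol/L. Missing
#'   components are zero. In `total_h` mode the `H` entry is the total proton
#'   excess (may be negative).
#' @param db A `thermo_db`; defaults to the bundled table.
#' @param mode Closure mode, see above.
#' @param pH Prescribed pH for `fixed_ph` mode.
#' @param warm Optional warm start (the `warm` element of a previous state).
#' @param maxit,tol Newton iteration cap and relative mole-balance tolerance.
#' @return A `solution_state`: dissolved totals, pH, ionic strength, free and
#'   complexed concentrations, activities, convergence metadata.
#' @examples
#' st <- solve_speciation(c(CO3 = 5e-4), mode = "fixed_ph", pH = 7.21)
#' st$pH
#' @export
solve_speciation <- function(totals, db = default_thermo_db(),
                             mode = c("fixed_ph", "charge_balance", "total_h"),
                             pH = NA_real_, warm = NULL, maxit = 200,
                             tol = 1e-10) {
  mode <- match.arg(mode)
  if (mode == "fixed_ph" && !is.finite(pH)) {
    stop("fixed_ph mode requires a pH", call. = FALSE)
  }
  .speciate(totals, db, mode, pH = pH, warm = warm,
            maxit = maxit, tol = tol)$state
}

#' @export
print.solution_state <- function(x, ...) {
  cat("<solution_state> pH", format(x$pH, digits = 4),
      " I =", format(x$ionic_strength, digits = 3), "mol/L,",
      "mode:", x$mode, "\n")
  invisible(x)
}

#' Relative mass-action residual of every active secondary species
#'
#' Diagnostic for the convergence invariant: at a converged state each
#' species activity equals its formation constant times the component
#' activity product.
#' @param state A `solution_state`.
#' @return Named vector of |a_j - K_j prod a_i^nu| / a_j for species with
#'   nonzero activity.
#' @export
mass_action_residuals <- function(state) {
  db <- state$db
  a <- state$activities
  out <- numeric(0)
  for (j in seq_len(nrow(db$species))) {
    sp <- db$species$name[j]
    aj <- a[[sp]]
    if (aj <= 0) next
    nu <- db$nu[j, ]
    used <- nu != 0
    if (any(a[db$components$name[used]] <= 0)) next
    pred <- 10^db$logk[[sp]] * prod(a[db$components$name[used]]^nu[used])
    out[sp] <- abs(aj - pred) / aj
  }
  out
}

#' Saturation index of a mineral phase
#'
#' SI = log10(IAP) - log10(Ksp), with the ion activity product taken from the
#' state's activities. If a component required by the mineral has zero
#' activity (absent from solution) the SI is `-Inf`, the documented sentinel
#' for "cannot precipitate".
#'
#' @param state A converged `solution_state`.
#' @param mineral Mineral name present in the database.
#' @param db Database; defaults to the state's own.
#' @return Dimensionless saturation index.
#' @export
saturation_index <- function(state, mineral, db = state$db) {
  m <- match(mineral, db$minerals$name)
  if (is.na(m)) stop("unknown mineral: ", mineral, call. = FALSE)
  nu <- db$nu_min[m, ]
  used <- which(nu != 0)
  a <- state$activities[db$components$name[used]]
  if (any(a[nu[used] > 0] <= 0)) return(-Inf)
  sum(nu[used] * log10(a)) - db$logksp[[mineral]]
}
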