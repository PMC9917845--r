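#' Equilibrium precipitation and dissolution of mineral phases
#'
#' Brings a converged solution to equilibrium with a set of allowed mineral
#' phases by an active-set loop: any allowed mineral supersaturated beyond
#' tolerance is added to the active set and its saturation index pinned to
#' zero (precipitated amount becomes an extra Newton unknown); any phase with
#' accumulated mass and SI below -tolerance dissolves, up to full exhaustion
#' of its inventory. Component mass is conserved exactly: dissolved totals
#' plus stoichiometry-weighted mineral transfer equal the input totals.
#'
#' @param state A converged `solution_state` (its closure mode and pH carry
#'   over to the re-solves).
#' @param allowed Character vector of mineral names permitted to react;
#'   default all minerals in the database.
#' @param amounts Named vector of pre-existing mineral inventories
#'   (mol per L pore water); default none.
#' @param tol_si SI tolerance defining "at equilibrium".
#' @param max_iter Active-set iteration cap; exceeding it is an error.
#' @param active_init Optional warm-start guess for the equilibrium active
#'   set (e.g. the phases active in a neighbouring grid cell); phases not
#'   actually supersaturated are dropped automatically.
#' @return List with elements `state` (new `solution_state`), `deltas`
#'   (named mol/L precipitated this call, negative = dissolved) and
#'   `amounts` (updated inventories).
#' @examples
#' st <- solve_speciation(c(Zn = 2e-4, HS = 5e-4, Na = 1e-3),
#'                        mode = "fixed_ph", pH = 7)
#' eq <- equilibrate_minerals(st, allowed = "sphalerite")
#' eq$deltas[["sphalerite"]]
#' @export
equilibrate_minerals <- function(state, allowed = NULL, amounts = NULL,
                                 tol_si = 1e-8, max_iter = 60,
                                 active_init = NULL) {
  db <- state$db
  if (is.null(allowed)) allowed <- db$minerals$name
  bad <- setdiff(allowed, db$minerals$name)
  if (length(bad)) stop("unknown mineral(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  amt <- stats::setNames(rep(0, length(allowed)), allowed)
  if (!is.null(amounts)) amt[names(amounts)] <- amounts
  if (any(amt < 0)) stop("mineral amounts must be >= 0", call. = FALSE)

  tot0 <- state$totals
  eff <- tot0                      # totals credited with fully-dissolved mass
  released <- stats::setNames(rep(0, length(allowed)), allowed)
  cn <- db$components$name
  si0 <- vapply(allowed, function(m) saturation_index(state, m), 0)
  # dissolution candidates are credited back into solution up front; if the
  # water cannot actually hold that mass, the precipitation path below
  # returns the excess, which nets out as partial dissolution. This keeps
  # every mineral Newton solve on the well-behaved supersaturated side.
  dis <- allowed[amt > 0 & si0 < -tol_si]
  for (m in dis) {
    eff <- eff + amt[[m]] * db$nu_min[match(m, db$minerals$name), ]
    names(eff) <- cn
    released[m] <- amt[[m]]
  }
  if (length(dis)) {
    state <- .speciate(eff, db, state$mode, pH = state$pH,
                       warm = state$warm)$state
    si0 <- vapply(allowed, function(m) saturation_index(state, m), 0)
  }
  # precipitating phases are activated one at a time (most supersaturated
  # first), starting from any warm-start phases that are supersaturated
  active <- intersect(intersect(active_init %||% character(0), allowed),
                      allowed[si0 > tol_si])
  cur <- state
  deltas <- stats::setNames(rep(0, length(allowed)), allowed)

  for (iter in seq_len(max_iter)) {
    if (length(active)) {
      res <- tryCatch(
        .speciate(eff, db, state$mode, pH = state$pH,
                  active_minerals = active, warm = cur$warm),
        srb_solver_error = function(e)
          .speciate(eff, db, state$mode, pH = state$pH,
                    active_minerals = active))
      cur <- res$state
      d <- res$deltas[active]
      # full dissolution: a phase asked to give back more than it holds
      avail <- amt[active] - released[active]
      over <- d < -(avail + 1e-15)
      if (any(over)) {
        m <- active[over]
        give <- avail[m]
        eff <- eff + as.numeric(t(db$nu_min[match(m, db$minerals$name), ,
                                            drop = FALSE]) %*% give)
        names(eff) <- cn
        released[m] <- released[m] + give
        active <- setdiff(active, m)
        next
      }
      deltas[] <- 0
      deltas[active] <- d
    } else {
      res <- .speciate(eff, db, state$mode, pH = state$pH, warm = cur$warm)
      cur <- res$state
      deltas[] <- 0
    }
    si <- vapply(allowed, function(m) saturation_index(cur, m), 0)
    cand <- setdiff(allowed[si > tol_si], active)
    if (length(cand)) {
      active <- c(active, cand[which.max(si[cand])])
      next
    }
    # converged active set
    final <- deltas - released
    new_amt <- pmax(amt + final, 0)
    cur$totals <- stats::setNames(
      tot0 - as.numeric(t(db$nu_min[match(allowed, db$minerals$name), ,
                                    drop = FALSE]) %*% final), cn)
    return(list(state = cur, deltas = final, amounts = new_amt))
  }
  stop("equilibrate_minerals: active-set iteration cap reached", call. = FALSE)
}
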