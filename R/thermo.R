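#' Load a thermodynamic database
#'
#' Reads the structured text table of aqueous components, secondary species and
#' mineral phases used by the equilibrium solver. Each species row carries a
#' log10 formation constant from the master components (25 degC, zero ionic
#' strength reference); each mineral row carries a log10 solubility product for
#' its dissolution reaction written toward the components. Water is implicit
#' (activity 1). The bundled table is a reconstruction of a minteq-family
#' aqueous model restricted to the neutralized-AMD column chemistry: carbonate
#' and sulfide protonation, bisulfate, acetate protonation, metal OH/CO3/SO4
#' ion pairs for Ca/Zn/Cu/Cd, and the seven product minerals (calcite,
#' smithsonite, otavite, malachite, sphalerite, covellite, greenockite).
#' Sulfate and sulfide are independent components: their interconversion is
#' kinetic only (redox disequilibrium), so no redox couples appear here.
#'
#' @param path Path to a thermodynamic table CSV. `NULL` loads the bundled
#'   table `thermo_srb.csv`.
#' @param temperature Reference temperature in degC attached to the database.
#'   Constants are used at their 25 degC values (no enthalpy data shipped).
#' @return An object of class `thermo_db`: lists of components, species and
#'   minerals plus precomputed stoichiometric matrices.
#' @export
load_thermo_db <- function(path = NULL, temperature = 25) {
  if (is.null(path)) {
    path <- system.file("extdata", "thermo_srb.csv", package = "srbcolumn")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("thermodynamic table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric",
                                        "numeric", "numeric", "character"))
  need <- c("kind", "name", "charge", "molar_mass", "logk", "stoichiometry")
  if (!all(need %in% names(raw))) {
    stop("thermo table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  comp <- raw[raw$kind == "component", ]
  spec <- raw[raw$kind == "species", ]
  mins <- raw[raw$kind == "mineral", ]
  if (anyDuplicated(raw$name)) {
    stop("duplicate names in thermo table: ",
         paste(unique(raw$name[duplicated(raw$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(comp$molar_mass)) || any(comp$molar_mass <= 0)) {
    stop("component molar masses must be positive", call. = FALSE)
  }
  cn <- comp$name
  parse_stoich <- function(s, who) {
    if (is.na(s) || !nzchar(s)) stop("empty stoichiometry for ", who, call. = FALSE)
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1L)
    vals <- as.numeric(vapply(kv, `[`, "", 2L))
    if (any(is.na(vals))) stop("bad stoichiometry '", s, "' for ", who, call. = FALSE)
    bad <- setdiff(keys, cn)
    if (length(bad)) {
      stop("stoichiometry of ", who, " references undefined component(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    out <- numeric(length(cn)); names(out) <- cn
    out[keys] <- vals
    out
  }
  nu <- t(vapply(seq_len(nrow(spec)),
                 function(j) parse_stoich(spec$stoichiometry[j], spec$name[j]),
                 numeric(length(cn))))
  rownames(nu) <- spec$name
  nu_min <- t(vapply(seq_len(nrow(mins)),
                     function(j) parse_stoich(mins$stoichiometry[j], mins$name[j]),
                     numeric(length(cn))))
  rownames(nu_min) <- mins$name
  zc <- comp$charge
  # charge consistency: species charge must equal stoichiometry-weighted sum
  zs <- as.numeric(nu %*% zc)
  if (any(abs(zs - spec$charge) > 1e-9)) {
    stop("species charge inconsistent with stoichiometry: ",
         paste(spec$name[abs(zs - spec$charge) > 1e-9], collapse = ", "),
         call. = FALSE)
  }
  zm <- as.numeric(nu_min %*% zc)
  if (any(abs(zm) > 1e-9)) {
    stop("mineral formula not electroneutral: ",
         paste(mins$name[abs(zm) > 1e-9], collapse = ", "), call. = FALSE)
  }
  db <- list(
    components = data.frame(name = cn, charge = zc,
                            molar_mass = comp$molar_mass,
                            stringsAsFactors = FALSE),
    species = data.frame(name = spec$name, charge = spec$charge,
                         logk = spec$logk, stringsAsFactors = FALSE),
    minerals = data.frame(name = mins$name, logksp = mins$logk,
                          stringsAsFactors = FALSE),
    nu = nu, nu_min = nu_min,
    z_comp = stats::setNames(zc, cn),
    z_spec = stats::setNames(spec$charge, spec$name),
    logk = stats::setNames(spec$logk, spec$name),
    logksp = stats::setNames(mins$logk, mins$name),
    molar_mass = stats::setNames(comp$molar_mass, cn),
    temperature = temperature,
    source = path
  )
  class(db) <- "thermo_db"
  db
}

.srb_env <- new.env(parent = emptyenv())

#' Default bundled thermodynamic database (cached)
#' @return A `thermo_db` object.
#' @export
default_thermo_db <- function() {
  if (is.null(.srb_env$db)) .srb_env$db <- load_thermo_db()
  .srb_env$db
}

#' @export
print.thermo_db <- function(x, ...) {
  cat("<thermo_db>", nrow(x$components), "components,",
      nrow(x$species), "aqueous species,",
      nrow(x$minerals), "minerals;",
      "reference", x$temperature, "degC\n")
  invisible(x)
}
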