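# Shared fixtures, built in code at test time.

# Table-average influent totals (mol/L) with charge-balancing background,
# used where a realistic water is needed without running the full column.
influent_totals_fixture <- function() {
  inf <- influent_state(paper_influent())
  inf$totals
}

# A toy diprotic-acid database with all charges zero (so every activity
# coefficient is exactly 1) for closed-form acid-base partition oracles.
# Association constants mirror the carbonate system's pK's.
toy_acid_db <- function() {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "kind,name,charge,molar_mass,logk,stoichiometry",
    "component,H,0,1.008,,",
    "component,A,0,60.0,,",
    "species,B1,0,61.0,10.329,A:1;H:1",
    "species,B2,0,62.0,16.681,A:1;H:2"
  ), path)
  load_thermo_db(path)
}

# a cheap kinetic parameter set with all microbial rates off
dead_kinetics <- function() {
  kinetic_params(k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0)
}

# elemental totals (dissolved + minerals) of a cell, for conservation checks
cell_element_totals <- function(totals, minerals, db = default_thermo_db()) {
  E <- srbcolumn:::.element_matrix(db)
  tt <- setNames(numeric(nrow(db$components)), db$components$name)
  tt[names(totals)] <- totals
  diss <- as.numeric(tt %*% E$comp)
  mm <- setNames(numeric(nrow(db$minerals)), db$minerals$name)
  if (length(minerals)) mm[names(minerals)] <- minerals
  held <- as.numeric(mm %*% E$mineral)
  setNames(diss + held, colnames(E$comp))
}
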