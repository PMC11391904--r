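#' Physical constants and unit conversion
#'
#' All internal quantities are in Hartree atomic units: energies in Hartree,
#' lengths in Bohr, dipoles in e*Bohr, masses in electron masses, time in
#' atomic time units. External files may declare other units; they are
#' converted on load.
#'
#' @name units
NULL

## CODATA 2018 conversion factors
.EV_PER_HARTREE <- 27.211386245988
.ANGSTROM_PER_BOHR <- 0.529177210903
.FS_PER_AUT <- 0.02418884326509  # 1 a.u. time in fs
.AMU_PER_ME <- 1 / 1822.888486209

#' Convert a value between declared units and atomic units
#'
#' @param x numeric array.
#' @param from unit name (see Details).
#' @param quantity one of "energy", "length", "force", "nac", "smooth_nac",
#'   "dipole", "time", "mass".
#' @details Recognised unit names: energies "hartree"/"ev"; lengths
#'   "bohr"/"angstrom"; forces "hartree/bohr"/"ev/angstrom"; NACs "1/bohr"/
#'   "1/angstrom"; smoothed NACs "hartree/bohr"/"ev/angstrom"; dipoles "au"/
#'   "debye"; time "aut"/"fs"; mass "me"/"amu". Conversion is exact and
#'   deterministic.
#' @return x converted to atomic units.
#' @export
to_atomic_units <- function(x, from, quantity) {
  f <- unit_factor(from, quantity)
  x * f
}

#' @rdname to_atomic_units
#' @export
from_atomic_units <- function(x, from, quantity) {
  x / unit_factor(from, quantity)
}

unit_factor <- function(unit, quantity) {
  unit <- tolower(unit)
  tab <- switch(quantity,
    energy = c(hartree = 1, ha = 1, ev = 1 / .EV_PER_HARTREE),
    length = c(bohr = 1, angstrom = 1 / .ANGSTROM_PER_BOHR,
               a = 1 / .ANGSTROM_PER_BOHR),
    force = c("hartree/bohr" = 1,
              "ev/angstrom" = .ANGSTROM_PER_BOHR / .EV_PER_HARTREE),
    nac = c("1/bohr" = 1, "1/angstrom" = .ANGSTROM_PER_BOHR),
    smooth_nac = c("hartree/bohr" = 1,
                   "ev/angstrom" = .ANGSTROM_PER_BOHR / .EV_PER_HARTREE),
    dipole = c(au = 1, debye = 0.3934303),
    time = c(aut = 1, fs = 1 / .FS_PER_AUT),
    mass = c(me = 1, amu = 1 / .AMU_PER_ME),
    stop("unknown quantity: ", quantity)
  )
  if (!unit %in% names(tab)) {
    stop(sprintf("unknown unit '%s' for %s; accepted: %s",
                 unit, quantity, paste(names(tab), collapse = ", ")))
  }
  unname(tab[[unit]])
}

#' Convert femtoseconds to atomic time units
#' @param t_fs time in fs
#' @return time in a.u.
#' @export
fs_to_aut <- function(t_fs) t_fs / .FS_PER_AUT

#' @rdname fs_to_aut
#' @param t_aut time in a.u.
#' @export
aut_to_fs <- function(t_aut) t_aut * .FS_PER_AUT

#' Hartree/eV conversion helpers
#' @param x numeric
#' @export
hartree_to_ev <- function(x) x * .EV_PER_HARTREE

#' @rdname hartree_to_ev
#' @export
ev_to_hartree <- function(x) x / .EV_PER_HARTREE

element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca"
)

symbol_to_z <- function(sym) {
  z <- match(sym, element_symbols)
  if (anyNA(z)) {
    ## unknown symbols of form "X<number>" map to that atomic number
    bad <- is.na(z)
    m <- regmatches(sym[bad], regexec("^X([0-9]+)$", sym[bad]))
    zn <- vapply(m, function(g) if (length(g) == 2) as.integer(g[2]) else NA_integer_,
                 integer(1))
    z[bad] <- zn
    if (anyNA(z)) stop("unknown element symbol: ",
                       paste(sym[is.na(z)], collapse = ", "))
  }
  z
}

z_to_symbol <- function(z) {
  ifelse(z >= 1 & z <= length(element_symbols),
         element_symbols[pmin(z, length(element_symbols))],
         paste0("X", z))
}

## standard atomic masses (amu) for the light elements used here
.ATOMIC_MASSES_AMU <- c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011,
                        14.007, 15.999, 18.998, 20.180)

#' Standard atomic mass for an element
#' @param z atomic number
#' @return mass in electron-mass units
#' @export
atomic_mass <- function(z) {
  stopifnot(all(z >= 1))
  amu <- ifelse(z <= length(.ATOMIC_MASSES_AMU), .ATOMIC_MASSES_AMU[z], 2 * z)
  to_atomic_units(amu, "amu", "mass")
}
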