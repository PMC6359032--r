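#' Physical unit conversion constants
#'
#' Conversion factors used throughout the package. Energies are carried in
#' hartree internally and converted at the boundaries; coordinates are
#' Angstrom in XYZ files and Bohr for all density work (the cube-file
#' convention).
#'
#' @format A named numeric vector with elements
#'   `hartree_to_ev` (27.2114), `hartree_to_kcal` (627.509),
#'   `hartree_to_kj` (2625.50) and `bohr_to_angstrom` (0.529177).
#' @export
rk_units <- c(
  hartree_to_ev   = 27.2114,
  hartree_to_kcal = 627.509,
  hartree_to_kj   = 2625.50,
  bohr_to_angstrom = 0.529177
)

#' Convert energies between hartree, eV, kcal/mol and kJ/mol
#'
#' @param x numeric vector of energies.
#' @param from,to one of `"hartree"`, `"ev"`, `"kcal"`, `"kj"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_energy(1, "hartree", "kcal")  # 627.509
#' @export
convert_energy <- function(x, from = "hartree", to = "hartree") {
  per_hartree <- c(hartree = 1,
                   ev   = rk_units[["hartree_to_ev"]],
                   kcal = rk_units[["hartree_to_kcal"]],
                   kj   = rk_units[["hartree_to_kj"]])
  from <- match.arg(tolower(from), names(per_hartree))
  to   <- match.arg(tolower(to),   names(per_hartree))
  x / per_hartree[[from]] * per_hartree[[to]]
}

#' Convert lengths between Angstrom and Bohr
#'
#' @param x numeric vector of lengths.
#' @param from,to `"angstrom"` or `"bohr"`.
#' @return numeric vector in the target unit.
#' @export
convert_length <- function(x, from = "angstrom", to = "bohr") {
  per_bohr <- c(bohr = 1, angstrom = rk_units[["bohr_to_angstrom"]])
  from <- match.arg(tolower(from), names(per_bohr))
  to   <- match.arg(tolower(to),   names(per_bohr))
  x / per_bohr[[from]] * per_bohr[[to]]
}
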