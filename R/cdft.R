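## Conceptual-DFT reactivity: global indices from frontier orbital
## energies (Koopmans-style), condensed Fukui functions from Hirshfeld
## charge triplets, and the NBO second-order stabilization formula.

#' Global reactivity indices from frontier orbital energies
#'
#' Computes the conceptual-DFT global descriptors from HOMO/LUMO energies
#' in the Koopmans-style frontier approximation:
#' \deqn{E_{gap} = E_{LUMO} - E_{HOMO}, \quad
#'       \eta = (E_{LUMO} - E_{HOMO})/2, \quad s = 1/(2\eta),}
#' \deqn{\chi = -(E_{LUMO} + E_{HOMO})/2, \quad \mu = -\chi, \quad
#'       \omega = \mu^2/(2\eta).}
#' All energies in eV; softness in 1/eV. Inputs may be vectors (one row
#' per molecule/medium) or a data.frame with `homo` and `lumo` columns.
#'
#' @param homo HOMO energy (eV), or a data.frame with columns
#'   `homo`, `lumo` (extra columns are carried through).
#' @param lumo LUMO energy (eV) when `homo` is numeric.
#' @return data.frame with columns `egap`, `eta`, `s`, `chi`, `mu`,
#'   `omega` (plus any carried-through identifier columns).
#' @examples
#' global_indices(-8.900, 0.753)
#' @export
global_indices <- function(homo, lumo = NULL) {
  if (is.data.frame(homo)) {
    df <- homo
    names(df) <- tolower(names(df))
    if (!all(c("homo", "lumo") %in% names(df)))
      stop("data.frame input needs 'homo' and 'lumo' columns")
    homo <- df$homo; lumo <- df$lumo
    carry <- df[setdiff(names(df), c("homo", "lumo"))]
  } else {
    carry <- NULL
  }
  if (any(homo >= lumo))
    stop("domain error: E_HOMO must be below E_LUMO")
  egap <- lumo - homo
  eta <- egap / 2
  chi <- -(lumo + homo) / 2
  out <- data.frame(homo = homo, lumo = lumo, egap = egap, eta = eta,
                    s = 1 / (2 * eta), chi = chi, mu = -chi,
                    omega = chi^2 / (2 * eta))
  if (!is.null(carry) && ncol(carry)) out <- cbind(carry, out)
  out
}

#' Condensed Fukui functions from a Hirshfeld charge triplet
#'
#' Per-atom Fukui indices from the charges of the N, N-1 and N+1 electron
#' states: \eqn{f^- = q_{N-1} - q_N} (electrophilic attack),
#' \eqn{f^+ = q_N - q_{N+1}} (nucleophilic attack), and the radical index
#' \eqn{f^0 = (q_{N-1} - q_{N+1})/2 = (f^- + f^+)/2}.
#'
#' @param q_n Hirshfeld charge(s) of the neutral N-electron state (e), or
#'   a data.frame with columns `q_n`, `q_nm1`, `q_np1`.
#' @param q_nm1 charge(s) of the (N-1)-electron (one electron removed)
#'   state.
#' @param q_np1 charge(s) of the (N+1)-electron (one electron added)
#'   state.
#' @return data.frame with columns `f_minus`, `f_plus`, `f_zero`.
#' @examples
#' condensed_fukui(q_n = -0.30, q_nm1 = -0.18, q_np1 = -0.45)
#' @export
condensed_fukui <- function(q_n, q_nm1 = NULL, q_np1 = NULL) {
  if (is.data.frame(q_n)) {
    df <- q_n
    names(df) <- tolower(names(df))
    need <- c("q_n", "q_nm1", "q_np1")
    if (!all(need %in% names(df)))
      stop("contract error: charge triplet needs columns ",
           paste(need, collapse = ", "))
    carry <- df[setdiff(names(df), need)]
    q_nm1 <- df$q_nm1; q_np1 <- df$q_np1; q_n <- df$q_n
  } else {
    carry <- NULL
  }
  if (is.null(q_nm1) || is.null(q_np1) || anyNA(c(q_n, q_nm1, q_np1)))
    stop("contract error: all three charge states (N, N-1, N+1) required")
  f_minus <- q_nm1 - q_n
  f_plus <- q_n - q_np1
  out <- data.frame(f_minus = f_minus, f_plus = f_plus,
                    f_zero = (f_minus + f_plus) / 2)
  if (!is.null(carry) && ncol(carry)) out <- cbind(carry, out)
  out
}

#' Rank atoms by a condensed Fukui index
#'
#' Sorts atoms ascending by the chosen index (so the last entry is the
#' most reactive site); exact ties keep input order and are flagged.
#'
#' @param fukui data.frame with an atom identifier column (`atom`) and the
#'   index columns `f_minus` / `f_plus` (e.g. from [condensed_fukui()]).
#' @param mode `"f_minus"` (electrophilic attack) or `"f_plus"`
#'   (nucleophilic attack).
#' @return the input rows sorted ascending by the chosen index, with a
#'   logical `tied` column marking rows whose value equals another row's.
#' @export
rank_fukui <- function(fukui, mode = c("f_minus", "f_plus")) {
  mode <- match.arg(mode)
  if (nrow(fukui) < 1L) stop("at least one atom required")
  v <- fukui[[mode]]
  ord <- order(v)  # stable: ties keep input (atom-index) order
  out <- fukui[ord, , drop = FALSE]
  out$tied <- duplicated(v[ord]) | duplicated(v[ord], fromLast = TRUE)
  rownames(out) <- NULL
  out
}

#' NBO second-order perturbation stabilization energy
#'
#' The donor-acceptor stabilization of natural bond orbital analysis:
#' \deqn{E^{(2)} = q_i F_{ij}^2 / (\varepsilon_j - \varepsilon_i)}
#' with occupancy \eqn{q_i}, off-diagonal Fock element \eqn{F_{ij}} and
#' diagonal elements \eqn{\varepsilon_i, \varepsilon_j}, all in hartree;
#' the result is reported in kcal/mol.
#'
#' @param q_i donor orbital occupancy (electrons, >= 0).
#' @param f_ij off-diagonal Fock matrix element (hartree).
#' @param eps_i,eps_j diagonal Fock elements of donor and acceptor
#'   (hartree); `eps_j > eps_i` required.
#' @return stabilization energy E(2) in kcal/mol.
#' @examples
#' e2_stabilization(2, 0.05, 0, 0.5)  # 6.275 kcal/mol
#' @export
e2_stabilization <- function(q_i, f_ij, eps_i, eps_j) {
  if (any(q_i < 0)) stop("domain error: occupancy q_i must be >= 0")
  if (any(eps_j <= eps_i))
    stop("domain error: acceptor eps_j must exceed donor eps_i")
  convert_energy(q_i * f_ij^2 / (eps_j - eps_i), "hartree", "kcal")
}
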