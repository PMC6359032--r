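## Seeded synthetic-data generators. Each generator is a deterministic
## function of (seed, spec) with independent per-record substreams, so
## adding records never perturbs earlier ones, and zero-noise outputs are
## exactly consistent with the analysis stages they feed (cycle closure,
## Fukui recovery, virial relation by construction).

# independent substream: derive a 31-bit sub-seed from (seed, index)
.substream_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
  as.integer(s)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a toy hydrogen-bonded geometry
#'
#' Produces small stand-in geometries exposing at least one D-H...A
#' hydrogen-bond motif within the standard geometric window (H...A
#' between 1.6 and 2.4 Angstrom, D-H...A angle above 140 degrees):
#' either a water-like dimer with two fragment annotations (donor and
#' acceptor molecules) or a single-fragment hydroxylated chain with an
#' intramolecular contact. A small seeded jitter perturbs the template
#' without leaving the motif window; the same seed reproduces identical
#' coordinates.
#'
#' @param kind `"hbonded_dimer"` or `"intramolecular_chain"`.
#' @param seed integer seed.
#' @param jitter Cartesian jitter amplitude, Angstrom.
#' @return a [molecule_geometry()] with a `motif` attribute listing
#'   `donor`, `hydrogen`, `acceptor` atom indices.
#' @export
toy_geometry <- function(kind = c("hbonded_dimer", "intramolecular_chain"),
                         seed = 1L, jitter = 0.03) {
  kind <- match.arg(kind)
  if (kind == "hbonded_dimer") {
    # water dimer template: donor O1-H2...O4 along x
    elements <- c("O", "H", "H", "O", "H", "H")
    coords <- rbind(
      c(0.000, 0.000, 0.000),   # O1 donor
      c(0.957, 0.000, 0.000),   # H2 bridging
      c(-0.240, 0.927, 0.000),  # H3
      c(2.900, 0.000, 0.000),   # O4 acceptor
      c(3.460, 0.760, 0.000),   # H5
      c(3.460, -0.760, 0.000))  # H6
    fragments <- list(donor = 1:3, acceptor = 4:6)
    motif <- c(donor = 1L, hydrogen = 2L, acceptor = 4L)
  } else {
    # 1,3-propanediol-like chain folded into an O-H...O contact
    elements <- c("O", "H", "C", "H", "H", "C", "H", "H", "O", "H")
    coords <- rbind(
      c(0.000, 0.000, 0.000),    # O1
      c(0.820, 1.740, 0.300),    # H2 on O1, pointing at O9
      c(-0.700, 1.180, 0.000),   # C3
      c(-1.340, 1.150, 0.890),   # H4
      c(-1.340, 1.150, -0.890),  # H5
      c(0.130, 2.450, 0.000),    # C6
      c(0.770, 2.480, 0.890),    # H7
      c(0.770, 2.480, -0.890),   # H8
      c(1.100, 3.350, 0.550),    # O9 acceptor
      c(1.960, 3.100, 0.200))    # H10
    fragments <- list(molecule = 1:10)
    motif <- c(donor = 1L, hydrogen = 2L, acceptor = 9L)
  }
  n <- length(elements)
  jit <- .with_seed(.substream_seed(seed, 1L),
                    matrix(stats::runif(n * 3L, -jitter, jitter), n, 3L))
  # the bridge atoms are kept exact so the motif window always holds
  jit[motif, ] <- 0
  geom <- molecule_geometry(elements, coords + jit,
                            name = paste0(kind, "_seed", seed),
                            fragments = fragments)
  attr(geom, "motif") <- motif
  geom
}

#' Synthesize Hirshfeld charge triplets with prescribed Fukui targets
#'
#' Draws the neutral-state charge from a seeded normal distribution and
#' sets \eqn{q_{N-1} = q_N + f^-} and \eqn{q_{N+1} = q_N - f^+}, so
#' [condensed_fukui()] recovers the targets exactly.
#'
#' @param f_minus,f_plus numeric vectors of per-atom target indices.
#' @param seed integer seed.
#' @param q_scale standard deviation of the neutral charges.
#' @return data.frame with columns `atom`, `q_n`, `q_nm1`, `q_np1`.
#' @export
synth_charge_triplets <- function(f_minus, f_plus, seed = 1L,
                                  q_scale = 0.2) {
  n <- length(f_minus)
  stopifnot(length(f_plus) == n)
  q_n <- vapply(seq_len(n), function(i)
    .with_seed(.substream_seed(seed, i), stats::rnorm(1, 0, q_scale)),
    numeric(1))
  data.frame(atom = seq_len(n), q_n = q_n,
             q_nm1 = q_n + f_minus, q_np1 = q_n - f_plus)
}

#' Synthesize species enthalpies with prescribed cycle targets
#'
#' Solves the HAT/SET-PT/SPLET cycle backwards: given target BDE, IP and
#' PA (kcal/mol) and a medium with reference enthalpies, draws a seeded
#' parent enthalpy and sets the radical, cation and anion enthalpies so
#' [mechanism_profile()] returns the targets exactly; the implied PDE and
#' ETE then satisfy the closure identity to machine precision.
#'
#' @param bde,ip,pa numeric target vectors (kcal/mol), one entry per site.
#' @param medium a [medium()] or resolvable name with reference
#'   enthalpies.
#' @param site optional site labels.
#' @param seed integer seed.
#' @param media media table for name resolution.
#' @return data.frame with columns `site`, `medium`, `h_parent`,
#'   `h_cation`, `h_radical`, `h_anion`.
#' @export
synth_enthalpy_set <- function(bde, ip, pa, medium = "gas", site = NULL,
                               seed = 1L, media = default_media()) {
  m <- resolve_medium(medium, media, require_refs = TRUE)
  n <- length(bde)
  stopifnot(length(ip) == n, length(pa) == n)
  h_parent <- vapply(seq_len(n), function(i)
    .with_seed(.substream_seed(seed, i), stats::rnorm(1, -1000, 50)),
    numeric(1))
  data.frame(
    site = if (is.null(site)) paste0("O", seq_len(n) + 1L, "-H") else site,
    medium = m$name,
    h_parent = h_parent,
    h_cation = ip + h_parent - m$H_electron,
    h_radical = bde + h_parent - m$H_hydrogen,
    h_anion = pa + h_parent - m$H_proton)
}

#' Synthesize BCP records of prescribed hydrogen-bond classes
#'
#' Samples (rho, G, V) inside the requested Rozas class region and sets
#' the Laplacian to \eqn{4(2G + V)} so the local virial residual is
#' exactly zero; [classify_hbond()] recovers the requested classes.
#' Optional Gaussian noise on the Laplacian emulates numerical
#' integration error.
#'
#' @param classes character vector of target classes (`"weak"`,
#'   `"medium"`, `"strong"`).
#' @param seed integer seed.
#' @param lap_sd standard deviation of additive Laplacian noise (a.u.).
#' @param lap_sign optional required Laplacian sign per record (`"+"` or
#'   `"-"`); a request inconsistent with the class (e.g. strong with a
#'   positive Laplacian) is a spec error.
#' @return data.frame with columns `bond`, `target_class`, `rho`, `lap`,
#'   `v`, `g`.
#' @export
synth_bcp_records <- function(classes, seed = 1L, lap_sd = 0,
                              lap_sign = NULL) {
  classes <- match.arg(classes, c("weak", "medium", "strong"),
                       several.ok = TRUE)
  kcal <- rk_units[["hartree_to_kcal"]]
  if (!is.null(lap_sign)) {
    need <- c(weak = "+", medium = "+", strong = "-")
    bad <- which(lap_sign != need[classes])
    if (length(bad))
      stop("spec error: class '", classes[bad[1L]],
           "' requires Laplacian sign '", need[classes[bad[1L]]], "'")
  }
  one <- function(i) {
    cls <- classes[i]
    .with_seed(.substream_seed(seed, i), {
      if (cls == "weak") {
        # |E_HB| < 12 kcal/mol -> |V| < 24/627.509; H > 0 -> G > |V|
        v <- -stats::runif(1, 0.008, 0.035)
        g <- -v * stats::runif(1, 1.02, 1.25)
        rho <- stats::runif(1, 0.005, 0.035)
      } else if (cls == "medium") {
        # 12 <= |E_HB| <= 24 -> |V| in [25, 47]/627.509; lap > 0 > H
        v <- -stats::runif(1, 2 * 12.5 / kcal, 2 * 23.5 / kcal)
        g <- -v * stats::runif(1, 0.55, 0.95)
        rho <- stats::runif(1, 0.04, 0.08)
      } else {
        # |E_HB| > 24 -> |V| > 48/627.509; lap < 0 -> G < |V|/2
        v <- -stats::runif(1, 2 * 26 / kcal, 2 * 60 / kcal)
        g <- -v * stats::runif(1, 0.20, 0.45)
        rho <- stats::runif(1, 0.15, 0.30)
      }
      lap <- 4 * (2 * g + v) + if (lap_sd > 0) stats::rnorm(1, 0, lap_sd)
        else 0
      data.frame(bond = sprintf("B%02d", i), target_class = cls,
                 rho = rho, lap = lap, v = v, g = g)
    })
  }
  do.call(rbind, lapply(seq_along(classes), one))
}
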