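## Promolecular-density grid engine: additive free-atom exponential
## densities with analytic gradient and Hessian, the reduced density
## gradient (RDG/NCI), the independent gradient model descriptor delta-g
## with intra/inter fragment partitioning, sign(lambda2)*rho, scatter
## data, vdW-surface extraction and a promolecular BCP locator.

#' Promolecular atomic density model
#'
#' A promolecular density is the superposition of spherically averaged
#' free-atom densities, each represented as a sum of up to three
#' exponential shells \eqn{\rho_{el}(r) = \sum_k c_k e^{-\alpha_k r}}
#' (a.u., r in Bohr). The default table carries the established
#' three-exponential promolecular fits for H-Ne used by NCI-type
#' analyses; it can be extended or replaced, each element mapping to a
#' data.frame with columns `c` (> 0) and `alpha` (> 0, 1/Bohr).
#'
#' @param shells optional named list of data.frames with columns `c` and
#'   `alpha` to override or extend the built-in table.
#' @return an object of class `atomic_density_model` (named list of shell
#'   tables keyed by element symbol).
#' @export
promolecular_model <- function(shells = NULL) {
  sh <- function(c, b) data.frame(c = c, alpha = 1 / b)  # fits use exp(-r/b)
  tab <- list(
    H  = sh(0.2815, 0.5288),
    He = sh(2.437, 0.3379),
    Li = sh(c(11.84, 0.06332), c(0.1912, 0.9992)),
    Be = sh(c(31.34, 0.3694), c(0.1390, 0.6945)),
    B  = sh(c(67.82, 0.8527), c(0.1059, 0.5300)),
    C  = sh(c(120.2, 1.172, 0.0126), c(0.0884, 0.4832, 1.0000)),
    N  = sh(c(190.9, 2.247, 0.0275), c(0.0767, 0.3890, 0.9545)),
    O  = sh(c(289.5, 3.426, 0.0543), c(0.0669, 0.3427, 0.9126)),
    F  = sh(c(406.3, 4.924, 0.0996), c(0.0608, 0.3055, 0.8750)),
    Ne = sh(c(561.3, 6.684, 0.1713), c(0.0549, 0.2755, 0.8354))
  )
  if (!is.null(shells)) {
    for (el in names(shells)) {
      s <- as.data.frame(shells[[el]])
      if (!all(c("c", "alpha") %in% names(s)))
        stop("shell table for ", el, " needs columns 'c' and 'alpha'")
      if (any(s$c <= 0) || any(s$alpha <= 0))
        stop("shell coefficients and exponents must be positive")
      tab[[el]] <- s[c("c", "alpha")]
    }
  }
  structure(tab, class = "atomic_density_model")
}

# radial value / first / second derivative sums of one element's shells
# at distances r (Bohr): rho, drho/dr, d2rho/dr2
.shell_radial <- function(shells, r) {
  rho <- d1 <- d2 <- numeric(length(r))
  for (k in seq_len(nrow(shells))) {
    e <- shells$c[k] * exp(-shells$alpha[k] * r)
    rho <- rho + e
    d1 <- d1 - shells$alpha[k] * e
    d2 <- d2 + shells$alpha[k]^2 * e
  }
  list(rho = rho, d1 = d1, d2 = d2)
}

# per-atom density/gradient/Hessian contributions at `points` (Bohr).
# Returns rho (n), grad (n x 3), hess (n x 6: xx yy zz xy xz yz) per atom
# via the callback, which is handed (atom_index, rho_a, grad_a, hess_a).
.per_atom_fields <- function(geometry, model, points, callback,
                             want_hessian = TRUE) {
  pos <- convert_length(geometry$coords, "angstrom", "bohr")
  for (a in seq_along(geometry$elements)) {
    el <- geometry$elements[a]
    shells <- model[[el]]
    if (is.null(shells))
      stop("model error: no promolecular shells for element ", el)
    d <- cbind(points[, 1L] - pos[a, 1L], points[, 2L] - pos[a, 2L],
               points[, 3L] - pos[a, 3L])
    r <- sqrt(d[, 1L]^2 + d[, 2L]^2 + d[, 3L]^2)
    r <- pmax(r, 1e-12)  # guard the nuclear cusp
    rad <- .shell_radial(shells, r)
    gr <- rad$d1 / r  # drho/dr * (1/r), multiplies the displacement vector
    grad_a <- d * gr
    hess_a <- NULL
    if (want_hessian) {
      cc <- (rad$d2 - rad$d1 / r) / r^2
      hess_a <- cbind(cc * d[, 1L]^2 + gr,
                      cc * d[, 2L]^2 + gr,
                      cc * d[, 3L]^2 + gr,
                      cc * d[, 1L] * d[, 2L],
                      cc * d[, 1L] * d[, 3L],
                      cc * d[, 2L] * d[, 3L])
    }
    callback(a, rad$rho, grad_a, hess_a)
  }
  invisible(NULL)
}

#' Promolecular density, gradient and Hessian at arbitrary points
#'
#' Sums the analytic (closed-form, no finite differences) density,
#' gradient and Hessian contributions of every atom's exponential shells.
#'
#' @param geometry a [molecule_geometry()] (coordinates in Angstrom).
#' @param points numeric n x 3 matrix of evaluation points in Bohr.
#' @param model an [promolecular_model()]; every element of the geometry
#'   must be present in it.
#' @param hessian compute the Hessian (set `FALSE` to save time).
#' @return list with `rho` (length n), `grad` (n x 3) and `hessian`
#'   (n x 6, columns xx, yy, zz, xy, xz, yz; `NULL` if not requested).
#' @export
promolecular_field <- function(geometry, points,
                               model = promolecular_model(),
                               hessian = TRUE) {
  points <- matrix(as.numeric(points), ncol = 3L)
  n <- nrow(points)
  rho <- numeric(n)
  grad <- matrix(0, n, 3L)
  hess <- if (hessian) matrix(0, n, 6L) else NULL
  .per_atom_fields(geometry, model, points, function(a, r_a, g_a, h_a) {
    rho <<- rho + r_a
    grad <<- grad + g_a
    if (hessian) hess <<- hess + h_a
  }, want_hessian = hessian)
  list(rho = as.numeric(rho), grad = unname(grad),
       hessian = if (hessian) unname(hess) else NULL)
}

#' Reduced density gradient (NCI descriptor)
#'
#' \deqn{S = \frac{|\nabla\rho|}{2(3\pi^2)^{1/3}\rho^{4/3}}}
#' Voxels with density at or below `floor` are masked (`NA`) rather than
#' raising an error, since S diverges as the density vanishes.
#'
#' @param rho density values (a.u.).
#' @param grad_norm gradient norms (a.u.), or an n x 3 gradient matrix.
#' @param floor density mask threshold (a.u.).
#' @return numeric vector of S values (unitless scale), `NA` where
#'   masked.
#' @export
rdg_field <- function(rho, grad_norm, floor = 1e-10) {
  if (is.matrix(grad_norm))
    grad_norm <- sqrt(rowSums(grad_norm^2))
  s <- rep(NA_real_, length(rho))
  ok <- rho > floor
  s[ok] <- grad_norm[ok] / (2 * (3 * pi^2)^(1 / 3) * rho[ok]^(4 / 3))
  s
}

#' IGM descriptor delta-g with fragment partitioning
#'
#' The independent-gradient-model upper bound on the gradient replaces
#' the signed sum of per-atom gradient contributions by the component-wise
#' sum of their absolute values; the descriptor is the norm excess
#' \eqn{\delta g = |\nabla\rho^{IGM}| - |\nabla\rho| \ge 0}, which is
#' non-zero only where atomic gradients cancel, i.e. in interaction
#' regions. With fragments, the inter-fragment part uses signed sums
#' within each fragment and absolute sums across fragments:
#' \eqn{\delta g^{inter} = |\nabla\rho^{IGM,inter}| - |\nabla\rho|} and
#' \eqn{\delta g^{intra} = \delta g - \delta g^{inter}}; both are
#' non-negative. Atoms not listed in any fragment count as singleton
#' fragments.
#'
#' @inheritParams promolecular_field
#' @param fragments named list of atom-index vectors (defaults to the
#'   geometry's own fragments; `NULL` for no partition).
#' @return data.frame with `rho`, `grad_norm`, `delta_g` and - when
#'   fragments are given - `delta_g_intra`, `delta_g_inter`.
#' @export
delta_g <- function(geometry, points, model = promolecular_model(),
                    fragments = geometry$fragments) {
  points <- matrix(as.numeric(points), ncol = 3L)
  n <- nrow(points)
  n_atoms <- length(geometry$elements)
  frag_of <- NULL
  if (!is.null(fragments)) {
    fragments <- lapply(fragments, as.integer)
    if (anyDuplicated(unlist(fragments)))
      stop("contract error: fragments overlap")
    frag_of <- integer(n_atoms)
    for (fi in seq_along(fragments)) frag_of[fragments[[fi]]] <- fi
    loose <- which(frag_of == 0L)  # singleton fragments for loose atoms
    frag_of[loose] <- length(fragments) + seq_along(loose)
    n_frag <- max(frag_of)
  }
  rho <- numeric(n)
  total <- matrix(0, n, 3L)      # signed sum of atomic gradients
  abssum <- matrix(0, n, 3L)     # component-wise |.| sum (IGM bound)
  frag_sum <- if (!is.null(frag_of))
    lapply(seq_len(n_frag), function(i) matrix(0, n, 3L)) else NULL
  .per_atom_fields(geometry, model, points, function(a, r_a, g_a, h_a) {
    rho <<- rho + r_a
    total <<- total + g_a
    abssum <<- abssum + abs(g_a)
    if (!is.null(frag_of)) {
      fi <- frag_of[a]
      frag_sum[[fi]] <<- frag_sum[[fi]] + g_a
    }
  }, want_hessian = FALSE)
  nrm <- function(m) sqrt(m[, 1L]^2 + m[, 2L]^2 + m[, 3L]^2)
  grad_norm <- nrm(total)
  dg <- pmax(nrm(abssum) - grad_norm, 0)
  out <- data.frame(rho = rho, grad_norm = grad_norm, delta_g = dg)
  if (!is.null(frag_of)) {
    inter_abs <- matrix(0, n, 3L)
    for (fi in seq_len(n_frag)) inter_abs <- inter_abs + abs(frag_sum[[fi]])
    dg_inter <- pmax(nrm(inter_abs) - grad_norm, 0)
    out$delta_g_inter <- pmin(dg_inter, dg)
    out$delta_g_intra <- dg - out$delta_g_inter
  }
  out
}

# eigenvalues of symmetric 3x3 matrices, rows = (xx, yy, zz, xy, xz, yz),
# returned ascending; analytic (trigonometric) form, fully vectorized
.sym3_eigenvalues <- function(H) {
  a <- H[, 1L]; b <- H[, 2L]; c <- H[, 3L]
  d <- H[, 4L]; e <- H[, 5L]; f <- H[, 6L]
  p1 <- d^2 + e^2 + f^2
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  ps <- ifelse(p > 0, p, 1)
  aa <- (a - q) / ps; bb <- (b - q) / ps; cc <- (c - q) / ps
  dd <- d / ps; ee <- e / ps; ff <- f / ps
  detB <- aa * (bb * cc - ff^2) - dd * (dd * cc - ff * ee) +
    ee * (dd * ff - bb * ee)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  hi <- q + 2 * p * cos(phi)
  lo <- q + 2 * p * cos(phi + 2 * pi / 3)
  mid <- 3 * q - hi - lo
  out <- cbind(lo, mid, hi)
  # already-diagonal rows: return the sorted diagonal exactly
  if (any(diagonal <- p1 == 0))
    out[diagonal, ] <- t(apply(cbind(a, b, c)[diagonal, , drop = FALSE],
                               1L, sort))
  out
}

#' Density signed by the middle Hessian eigenvalue
#'
#' Computes sign(lambda2) * rho with the Hessian eigenvalues sorted
#' ascending (lambda2 the middle one, standard NCI convention): negative
#' values mark attractive interactions, positive values steric repulsion.
#' Points with lambda2 exactly zero return +rho and are flagged.
#'
#' @param hessian a symmetric 3 x 3 matrix, or an n x 6 matrix of
#'   components (xx, yy, zz, xy, xz, yz) as produced by
#'   [promolecular_field()].
#' @param rho density value(s).
#' @return numeric vector of sign(lambda2) * rho with attribute
#'   `zero_lambda2` (logical vector flagging exact zeros).
#' @export
signed_lambda2_density <- function(hessian, rho) {
  if (is.matrix(hessian) && nrow(hessian) == 3L && ncol(hessian) == 3L) {
    if (max(abs(hessian - t(hessian))) > 1e-10)
      stop("contract error: hessian must be symmetric")
    hessian <- matrix(c(hessian[1, 1], hessian[2, 2], hessian[3, 3],
                        hessian[1, 2], hessian[1, 3], hessian[2, 3]),
                      nrow = 1L)
  }
  ev <- .sym3_eigenvalues(hessian)
  lam2 <- ev[, 2L]
  zero <- abs(lam2) <= 1e-14 * pmax(abs(ev[, 1L]), abs(ev[, 3L]))
  out <- ifelse(lam2 < 0 & !zero, -rho, rho)
  attr(out, "zero_lambda2") <- zero
  out
}

#' Build a regular grid box around a molecule
#'
#' @param geometry a [molecule_geometry()].
#' @param spacing voxel step in Bohr (default 0.2, the standard NCI grid
#'   setting).
#' @param padding box margin beyond the molecular extent, Bohr.
#' @return list with `origin`, `spacing`, `dims` and the point matrix
#'   `points` (`prod(dims)` x 3, Bohr, z-fastest order).
#' @export
make_grid <- function(geometry, spacing = 0.2, padding = 4) {
  pos <- convert_length(geometry$coords, "angstrom", "bohr")
  lo <- apply(pos, 2L, min) - padding
  hi <- apply(pos, 2L, max) + padding
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  g <- list(origin = lo, spacing = rep(spacing, 3L), dims = dims)
  g$points <- grid_points(g)
  g
}

#' Scatter table of a descriptor against sign(lambda2) * rho
#'
#' One point per unmasked voxel whose x value lies within `x_range`, in
#' deterministic z-fastest voxel order.
#'
#' @param x sign(lambda2) * rho values (a.u.).
#' @param y descriptor values (delta-g or RDG); `NA` marks masked voxels.
#' @param x_range inclusive x window, default `c(-0.05, 0.05)` a.u.
#' @return data.frame with columns `x`, `y` and the original voxel index
#'   `voxel`.
#' @export
scatter_table <- function(x, y, x_range = c(-0.05, 0.05)) {
  keep <- which(!is.na(x) & !is.na(y) & x >= x_range[1L] & x <= x_range[2L])
  data.frame(voxel = keep, x = as.numeric(x)[keep], y = y[keep])
}

#' Locate a promolecular bond critical point between two atoms
#'
#' Minimizes the gradient-norm of the promolecular density by a damped
#' Newton iteration started at the internuclear midpoint (step capped at
#' 0.2 Bohr, convergence at |grad rho| < 1e-8 a.u., at most 200
#' iterations). Non-convergence is reported in the result, not raised.
#'
#' @inheritParams promolecular_field
#' @param atom_a,atom_b distinct 1-based atom indices.
#' @param step_cap,tol,max_iter iteration controls.
#' @return list with `position` (Bohr), `rho`, `grad_norm`,
#'   `eigenvalues` (Hessian, ascending), `converged` and `iterations`.
#' @export
locate_bcp <- function(geometry, atom_a, atom_b,
                       model = promolecular_model(),
                       step_cap = 0.2, tol = 1e-8, max_iter = 200L) {
  if (atom_a == atom_b) stop("atoms must be distinct")
  pos <- convert_length(geometry$coords, "angstrom", "bohr")
  if (sqrt(sum((pos[atom_a, ] - pos[atom_b, ])^2)) < 1e-9)
    stop("geometry error: atoms coincide")
  x <- (pos[atom_a, ] + pos[atom_b, ]) / 2
  converged <- FALSE
  it <- 0L
  f <- promolecular_field(geometry, matrix(x, 1L), model)
  gn <- sqrt(sum(f$grad^2))
  while (it < max_iter) {
    it <- it + 1L
    if (gn < tol) { converged <- TRUE; break }
    Hm <- matrix(c(f$hessian[1, 1], f$hessian[1, 4], f$hessian[1, 5],
                   f$hessian[1, 4], f$hessian[1, 2], f$hessian[1, 6],
                   f$hessian[1, 5], f$hessian[1, 6], f$hessian[1, 3]), 3L)
    step <- tryCatch(-solve(Hm, as.numeric(f$grad)),
                     error = function(e) -as.numeric(f$grad))
    sn <- sqrt(sum(step^2))
    if (sn > step_cap) step <- step * step_cap / sn
    # damp: halve the step until the gradient norm does not increase
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- promolecular_field(geometry, matrix(xn, 1L), model)
      gnn <- sqrt(sum(fn$grad^2))
      if (gnn <= gn || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- xn; f <- fn; gn <- gnn
  }
  if (gn < tol) converged <- TRUE
  list(position = as.numeric(x), rho = f$rho[1L], grad_norm = gn,
       eigenvalues = as.numeric(.sym3_eigenvalues(f$hessian)),
       converged = converged, iterations = it)
}

#' Extract the van der Waals surface voxels of a density grid
#'
#' The vdW surface is the density isosurface at rho = 0.001 e/Bohr^3;
#' a voxel belongs to the extracted shell when its density is at or above
#' the isovalue and at least one of its six face neighbours is below it.
#'
#' @param grid a grid description from [make_grid()] (with `dims`).
#' @param rho density values on the grid (z-fastest order).
#' @param iso isovalue, a.u.
#' @return integer vector of voxel indices on the surface shell.
#' @export
vdw_surface <- function(grid, rho, iso = 0.001) {
  d <- grid$dims
  arr <- array(rho >= iso, dim = c(d[3L], d[2L], d[1L]))  # z, y, x
  inside <- arr
  has_out <- array(FALSE, dim = dim(arr))
  shift <- function(a, dim, by) {
    idx <- rep(list(quote(expr = )), 3L)
    n <- dim(a)[dim]
    src <- seq_len(n) + by
    src[src < 1L | src > n] <- NA
    idx[[dim]] <- src
    out <- do.call(`[`, c(list(a), idx))
    out[is.na(out)] <- FALSE  # treat beyond-box as below iso
    array(out, dim = dim(a))
  }
  for (dim in 1:3) for (by in c(-1L, 1L))
    has_out <- has_out | !shift(arr, dim, by)
  which(as.vector(inside & has_out))
}

#' Full IGM/NCI grid analysis of a molecule
#'
#' Convenience driver: builds the grid, evaluates the promolecular
#' fields, and returns rho, RDG, delta-g (with the fragment split when
#' the geometry carries fragments) and sign(lambda2) * rho as
#' [grid_field()] objects plus the delta-g scatter table.
#'
#' @inheritParams promolecular_field
#' @param spacing,padding grid controls (Bohr).
#' @param x_range scatter window for sign(lambda2) * rho.
#' @param floor density mask threshold for the RDG.
#' @return list with `grid`, `fields` (named list of [grid_field()]) and
#'   `scatter` (data.frame).
#' @export
igm_analysis <- function(geometry, model = promolecular_model(),
                         spacing = 0.2, padding = 4,
                         x_range = c(-0.05, 0.05), floor = 1e-10) {
  grid <- make_grid(geometry, spacing, padding)
  f <- promolecular_field(geometry, grid$points, model)
  dg <- delta_g(geometry, grid$points, model)
  s <- rdg_field(f$rho, f$grad, floor)
  sl2 <- signed_lambda2_density(f$hessian, f$rho)
  gf <- function(v, q) grid_field(grid$origin, grid$spacing, grid$dims, v, q)
  fields <- list(rho = gf(f$rho, "rho"),
                 rdg = gf(s, "rdg"),
                 delta_g = gf(dg$delta_g, "delta_g"),
                 sign_lambda2_rho = gf(as.numeric(sl2), "sign_lambda2_rho"))
  if (!is.null(dg$delta_g_intra)) {
    fields$delta_g_intra <- gf(dg$delta_g_intra, "delta_g_intra")
    fields$delta_g_inter <- gf(dg$delta_g_inter, "delta_g_inter")
  }
  list(grid = grid, fields = fields,
       scatter = scatter_table(as.numeric(sl2), dg$delta_g, x_range))
}
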