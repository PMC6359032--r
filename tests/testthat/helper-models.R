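# shared test helpers: toy single-shell density models and oracles

# single-exponential H model with known closed forms
toy_h_model <- function(c = 0.2, alpha = 2.0) {
  promolecular_model(list(H = data.frame(c = c, alpha = alpha)))
}

# two H atoms `sep` Bohr apart along x (coordinates stored in Angstrom)
toy_pair <- function(sep = 2, elements = c("H", "H")) {
  b2a <- rk_units[["bohr_to_angstrom"]]
  molecule_geometry(elements, rbind(c(0, 0, 0), c(sep * b2a, 0, 0)),
                    name = "pair")
}

# central finite-difference gradient of the promolecular density
fd_gradient <- function(geom, p, model, h = 1e-5) {
  vapply(1:3, function(k) {
    e <- matrix(0, 1, 3); e[k] <- h
    (promolecular_field(geom, p + e, model, hessian = FALSE)$rho -
       promolecular_field(geom, p - e, model, hessian = FALSE)$rho) / (2 * h)
  }, numeric(1))
}

# symmetric 3x3 from the packed (xx, yy, zz, xy, xz, yz) row
unpack_hessian <- function(h6) {
  matrix(c(h6[1], h6[4], h6[5],
           h6[4], h6[2], h6[6],
           h6[5], h6[6], h6[3]), 3, 3)
}

# brute-force 1-D grid search for the on-axis gradient-norm minimum
# between two atoms (oracle for locate_bcp)
axis_grid_search <- function(geom, model, resolution = 1e-4) {
  pos <- convert_length(geom$coords, "angstrom", "bohr")
  ts <- seq(0.2, 0.8, by = resolution / sqrt(sum((pos[2, ] - pos[1, ])^2)))
  pts <- outer(1 - ts, pos[1, ]) + outer(ts, pos[2, ])
  f <- promolecular_field(geom, pts, model, hessian = FALSE)
  gn <- sqrt(rowSums(f$grad^2))
  pts[which.min(gn), ]
}
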