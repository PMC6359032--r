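test_that("promolecular field has the closed-form single-atom profile", {
  g <- molecule_geometry("H", matrix(0, 1, 3))
  mod <- toy_h_model(c = 0.2, alpha = 2.0)
  r <- 1.3
  f <- promolecular_field(g, matrix(c(r, 0, 0), 1), mod)
  expect_equal(f$rho, 0.2 * exp(-2 * r), tolerance = 1e-12)
  # gradient points toward the nucleus with magnitude c*alpha*exp(-alpha r)
  expect_equal(as.numeric(f$grad),
               c(-0.2 * 2 * exp(-2 * r), 0, 0), tolerance = 1e-12)
  expect_error(promolecular_field(
    molecule_geometry("S", matrix(0, 1, 3)), matrix(1, 1, 3)),
    "model error.*S")
})

test_that("analytic gradient and Hessian match finite differences", {
  g <- toy_pair(sep = 2.2, elements = c("O", "H"))
  mod <- promolecular_model()
  set.seed(17)
  for (i in 1:5) {
    p <- matrix(rnorm(3, 0, 1.5), 1)
    f <- promolecular_field(g, p, mod)
    expect_lt(max(abs(fd_gradient(g, p, mod) - f$grad)), 1e-6)
    h <- 1e-4
    numh <- vapply(1:3, function(k) {
      e <- matrix(0, 1, 3); e[k] <- h
      as.numeric((promolecular_field(g, p + e, mod, hessian = FALSE)$grad -
        promolecular_field(g, p - e, mod, hessian = FALSE)$grad) / (2 * h))
    }, numeric(3))
    expect_lt(max(abs(numh - unpack_hessian(f$hessian[1, ]))), 1e-4)
  }
  # symmetric pair: gradient vanishes at the midpoint
  hh <- toy_pair(2)
  fm <- promolecular_field(hh, matrix(c(1, 0, 0), 1), toy_h_model())
  expect_equal(as.numeric(fm$grad), c(0, 0, 0), tolerance = 1e-14)
})

test_that("RDG satisfies the unit point, masking and homogeneity", {
  expect_equal(rdg_field(0.01, 0), 0)
  expect_equal(rdg_field((3 * pi^2)^(-1), 2 * (3 * pi^2)^(-1)), 1)
  # density at or below the floor is masked, not an error
  expect_true(is.na(rdg_field(0, 0.1)))
  expect_true(is.na(rdg_field(-1e-3, 0.1)))
  # scaling (rho, grad) by lambda scales S by lambda^(-1/3)
  set.seed(2)
  rho <- runif(20, 1e-4, 0.1); gn <- runif(20, 0, 0.3)
  lam <- 3.7
  expect_equal(rdg_field(lam * rho, lam * gn),
               lam^(-1 / 3) * rdg_field(rho, gn), tolerance = 1e-12)
})

test_that("delta_g vanishes for one atom and matches the midpoint form", {
  mod <- toy_h_model(c = 0.2, alpha = 2.0)
  single <- molecule_geometry("H", matrix(0.3, 1, 3))
  set.seed(8)
  pts <- matrix(rnorm(60), 20)
  expect_equal(delta_g(single, pts, mod)$delta_g, rep(0, 20))

  # two-atom cancellation at the symmetric midpoint: the closed form is
  # 2 * c * alpha * exp(-alpha * r)
  hh <- toy_pair(2)
  dg <- delta_g(hh, matrix(c(1, 0, 0), 1), mod)
  expect_equal(dg$grad_norm, 0, tolerance = 1e-14)
  expect_lt(abs(dg$delta_g - 0.108268), 1e-6)
  expect_equal(dg$delta_g, 2 * 0.2 * 2 * exp(-2), tolerance = 1e-12)
})

test_that("fragment partition of delta_g is non-negative and additive", {
  geom <- toy_geometry("hbonded_dimer", seed = 3)
  grid <- make_grid(geom, spacing = 0.45, padding = 2.5)
  dg <- delta_g(geom, grid$points)
  expect_true(all(dg$delta_g >= 0))
  expect_true(all(dg$delta_g_intra >= 0))
  expect_true(all(dg$delta_g_inter >= 0))
  expect_equal(dg$delta_g_intra + dg$delta_g_inter, dg$delta_g,
               tolerance = 1e-12)

  # whole molecule as one fragment: everything is intramolecular
  one <- delta_g(geom, grid$points,
                 fragments = list(all = seq_along(geom$elements)))
  expect_equal(one$delta_g_inter, rep(0, nrow(grid$points)))
  expect_equal(one$delta_g_intra, one$delta_g)

  # one atom per fragment: everything is intermolecular
  singletons <- delta_g(geom, grid$points,
                        fragments = as.list(seq_along(geom$elements)))
  expect_equal(singletons$delta_g_inter, singletons$delta_g)

  expect_error(delta_g(geom, grid$points,
                       fragments = list(a = 1:3, b = 3:6)), "overlap")
})

test_that("sign(lambda2)*rho takes the middle ascending eigenvalue", {
  expect_equal(as.numeric(signed_lambda2_density(diag(c(1, 2, 3)), 0.01)),
               0.01)
  expect_equal(as.numeric(signed_lambda2_density(diag(c(-3, -1, 2)), 0.01)),
               -0.01)
  z <- signed_lambda2_density(diag(c(-1, 0, 2)), 0.01)
  expect_equal(as.numeric(z), 0.01)  # zero lambda2 reports +rho, flagged
  expect_true(attr(z, "zero_lambda2"))
  ns <- matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)
  expect_error(signed_lambda2_density(ns, 0.01), "symmetric")

  # off-nucleus points of one spherical exponential atom have two
  # negative tangential curvatures: lambda2 < 0, result -rho
  g <- molecule_geometry("H", matrix(0, 1, 3))
  mod <- toy_h_model()
  set.seed(4)
  pts <- matrix(rnorm(30, 0, 1), 10)
  f <- promolecular_field(g, pts, mod)
  expect_equal(as.numeric(signed_lambda2_density(f$hessian, f$rho)),
               -f$rho)
  # and the analytic eigenvalues agree with eigen() on the same points
  ana <- reactikit:::.sym3_eigenvalues(f$hessian)
  for (i in 1:10)
    expect_equal(ana[i, ], sort(eigen(unpack_hessian(f$hessian[i, ]),
                                      symmetric = TRUE)$values),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("scatter table filters deterministically and monotonically", {
  expect_equal(nrow(scatter_table(numeric(0), numeric(0))), 0L)
  x <- c(-0.2, -0.04, 0.01, 0.04, 0.2, NA)
  y <- c(1, 2, 3, 4, 5, 6)
  s <- scatter_table(x, y)
  expect_equal(s$voxel, c(2L, 3L, 4L))  # z-fastest voxel order
  wider <- scatter_table(x, y, x_range = c(-1, 1))
  expect_gte(nrow(wider), nrow(s))
})

test_that("promolecular BCP locator matches oracles and NCI signature", {
  mod <- toy_h_model()
  hh <- toy_pair(2)
  r <- locate_bcp(hh, 1, 2, mod)
  expect_true(r$converged)
  expect_equal(r$position, c(1, 0, 0), tolerance = 1e-6)

  # asymmetric pair: compare with a brute-force axial grid search
  asym <- toy_pair(2.4, elements = c("O", "H"))
  full <- promolecular_model()
  r2 <- locate_bcp(asym, 1, 2, full)
  expect_true(r2$converged)
  oracle <- axis_grid_search(asym, full)
  expect_lt(sqrt(sum((r2$position - oracle)^2)), 1e-3)
  # (3, -1) saddle: two negative curvatures, one positive
  expect_lt(r2$eigenvalues[1], 0)
  expect_lt(r2$eigenvalues[2], 0)
  expect_gt(r2$eigenvalues[3], 0)

  expect_error(locate_bcp(hh, 1, 1, mod), "distinct")
  dup <- molecule_geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(locate_bcp(dup, 1, 2, mod), "coincide")
})

test_that("vdW surface extraction yields a nonempty shell", {
  geom <- toy_geometry("hbonded_dimer", seed = 1)
  grid <- make_grid(geom, spacing = 0.4, padding = 4)
  rho <- promolecular_field(geom, grid$points, hessian = FALSE)$rho
  surf <- vdw_surface(grid, rho, iso = 0.001)
  expect_gt(length(surf), 0L)
  # surface voxels sit at the isovalue boundary: all at or above iso
  expect_true(all(rho[surf] >= 0.001))
  # and strictly fewer than the full interior
  expect_lt(length(surf), sum(rho >= 0.001))
})
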