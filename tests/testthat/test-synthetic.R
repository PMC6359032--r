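test_that("toy geometries expose a valid hydrogen-bond motif", {
  for (seed in c(1L, 9L, 123L)) {
    g <- toy_geometry("hbonded_dimer", seed = seed)
    motif <- attr(g, "motif")
    expect_length(g$fragments, 2L)
    hb <- hbond_geometry(g, motif["donor"], motif["hydrogen"],
                         motif["acceptor"])
    expect_gt(hb$distance, 1.6)
    expect_lt(hb$distance, 2.4)
    expect_gt(hb$angle, 140)
  }
  chain <- toy_geometry("intramolecular_chain", seed = 2)
  expect_length(chain$fragments, 1L)
  motif <- attr(chain, "motif")
  hb <- hbond_geometry(chain, motif["donor"], motif["hydrogen"],
                       motif["acceptor"])
  expect_gt(hb$distance, 1.6)
  expect_lt(hb$distance, 2.4)
  expect_gt(hb$angle, 140)
  # single fragment implies a purely intramolecular delta_g
  pts <- make_grid(chain, spacing = 0.8, padding = 2)$points
  dg <- delta_g(chain, pts)
  expect_equal(dg$delta_g_inter, rep(0, nrow(pts)))
})

test_that("generators are bit-reproducible functions of the seed", {
  expect_identical(toy_geometry("hbonded_dimer", seed = 5),
                   toy_geometry("hbonded_dimer", seed = 5))
  expect_false(identical(toy_geometry("hbonded_dimer", 5)$coords,
                         toy_geometry("hbonded_dimer", 6)$coords))
  expect_identical(synth_charge_triplets(c(0.1, 0.2), c(0.3, 0.4), seed = 7),
                   synth_charge_triplets(c(0.1, 0.2), c(0.3, 0.4), seed = 7))
  expect_identical(synth_enthalpy_set(100, 150, 50, seed = 7),
                   synth_enthalpy_set(100, 150, 50, seed = 7))
  expect_identical(synth_bcp_records(c("weak", "strong"), seed = 7),
                   synth_bcp_records(c("weak", "strong"), seed = 7))
  # independent substreams: earlier records unchanged when more are added
  a <- synth_charge_triplets(c(0.1, 0.2), c(0.3, 0.4), seed = 7)
  b <- synth_charge_triplets(c(0.1, 0.2, 0.3), c(0.3, 0.4, 0.5), seed = 7)
  expect_identical(a, b[1:2, ])
})

test_that("charge triplets invert the condensed Fukui formulas exactly", {
  t <- synth_charge_triplets(f_minus = 0.12, f_plus = 0.15, seed = 1)
  f <- condensed_fukui(t[c("q_n", "q_nm1", "q_np1")])
  expect_equal(f$f_minus, 0.12, tolerance = 1e-12)
  expect_equal(f$f_plus, 0.15, tolerance = 1e-12)
  expect_equal(f$f_zero, 0.135)

  z <- synth_charge_triplets(0, 0, seed = 2)
  expect_identical(z$q_n, z$q_nm1)
  expect_identical(z$q_n, z$q_np1)

  # per-atom targets summing to 1 move one full electron between states
  fm <- c(0.2, 0.3, 0.5)
  t3 <- synth_charge_triplets(fm, rep(0, 3), seed = 3)
  expect_equal(sum(t3$q_nm1) - sum(t3$q_n), 1)
})

test_that("enthalpy sets invert the thermodynamic cycle exactly", {
  s <- synth_enthalpy_set(bde = 97.70, ip = 150.75, pa = 321.48,
                          medium = "gas", seed = 1)
  p <- mechanism_profile(s$h_parent, s$h_cation, s$h_radical, s$h_anion,
                         "gas", site = s$site)
  expect_equal(p$bde, 97.70)
  expect_equal(p$ip, 150.75)
  expect_equal(p$pa, 321.48)
  expect_equal(p$pde, 261.48)
  expect_equal(p$ete, 90.75)

  # printed water targets with user-supplied aqueous references
  media <- default_media()
  media$water <- medium("water", 78.35, H_hydrogen = -313.95,
                        H_electron = -25.28, H_proton = -239.65)
  s <- synth_enthalpy_set(bde = 104.03, ip = 133.99, pa = 49.78,
                          medium = "water", seed = 2, media = media)
  p <- mechanism_profile(s$h_parent, s$h_cation, s$h_radical, s$h_anion,
                         media$water, site = s$site)
  expect_equal(p$bde, 104.03)
  expect_equal(p$ip, 133.99)
  expect_equal(p$pa, 49.78)
  expect_lt(abs(p$closure_setpt), 1e-9)
  expect_lt(abs(p$closure_splet), 1e-9)

  zero_medium <- medium("null", 1, 0, 0, 0)
  z <- synth_enthalpy_set(0, 0, 0, zero_medium, seed = 3)
  expect_equal(z$h_parent, z$h_cation)
  expect_equal(z$h_parent, z$h_radical)
  expect_equal(z$h_parent, z$h_anion)
})

test_that("BCP records invert the classifier with zero virial residual", {
  recs <- synth_bcp_records(rep("weak", 10), seed = 1)
  cls <- classify_hbond(recs$rho, recs$lap, recs$v, recs$g)
  expect_true(all(cls$class == "weak"))
  expect_equal(bcp_energetics(recs$rho, recs$lap, recs$v,
                              recs$g)$virial_residual,
               rep(0, 10))

  mixed <- synth_bcp_records(rep(c("weak", "medium", "strong"), 5),
                             seed = 2)
  cls <- classify_hbond(mixed$rho, mixed$lap, mixed$v, mixed$g)
  expect_equal(cls$class, mixed$target_class)

  # Laplacian noise propagates linearly into the virial residual
  noisy <- synth_bcp_records(rep("weak", 200), seed = 3, lap_sd = 1e-4)
  res <- bcp_energetics(noisy$rho, noisy$lap, noisy$v, noisy$g)
  expect_true(all(abs(res$virial_residual) < 4 * (1e-4 / 4)))
  expect_gt(stats::sd(res$virial_residual), 0)

  expect_error(synth_bcp_records("strong", lap_sign = "+"), "spec error")
})
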