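test_that("Lennard-Jones energy matches the 12-6 form and a hand sum", {
  top <- point_topology(2, chain = c("A", "B"))
  rmin <- 2 * 1.908
  fr <- rbind(c(0, 0, 0), c(rmin, 0, 0))
  expect_equal(lj_energy(fr, top, cbind(1L, 2L)), -0.1094,
               tolerance = 1e-12)
  fr_far <- rbind(c(0, 0, 0), c(1e5, 0, 0))
  expect_lt(abs(lj_energy(fr_far, top, cbind(1L, 2L))), 1e-12)
  # 3-atom system vs explicit pairwise sum
  top3 <- point_topology(3, chain = c("A", "B", "B"), residue = 1:3,
                         rmin_half = c(1.9, 1.7, 1.5),
                         eps = c(0.1, 0.2, 0.05))
  fr3 <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.5, 3.1, 0))
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  manual <- 0
  for (k in 1:3) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    r <- sqrt(sum((fr3[i, ] - fr3[j, ])^2))
    rm_ <- top3$lj_rmin_half[i] + top3$lj_rmin_half[j]
    ep <- sqrt(top3$lj_epsilon[i] * top3$lj_epsilon[j])
    manual <- manual + ep * ((rm_ / r)^12 - 2 * (rm_ / r)^6)
  }
  expect_equal(lj_energy(fr3, top3, pairs), manual, tolerance = 1e-12)
  expect_error(lj_energy(rbind(c(0, 0, 0), c(0, 0, 0)), top,
                         cbind(1L, 2L)), "zero")
})

test_that("Coulomb energy uses 332.0636 and scales as 1/r", {
  top <- point_topology(2, charge = c(1, -1), chain = c("A", "B"))
  fr <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(coulomb_energy(fr, top, cbind(1L, 2L)), -332.0636,
               tolerance = 1e-12)
  e1 <- coulomb_energy(fr * 2, top, cbind(1L, 2L))
  expect_equal(e1, -332.0636 / 2, tolerance = 1e-12)
  top0 <- point_topology(2, charge = c(0, -1), chain = c("A", "B"))
  expect_equal(coulomb_energy(fr, top0, cbind(1L, 2L)), 0)
  # dielectric scaling
  expect_equal(coulomb_energy(fr, top, cbind(1L, 2L), dielectric = 2),
               -332.0636 / 2, tolerance = 1e-12)
})

test_that("effective Born radii: isolated value, descreening direction", {
  top <- point_topology(1, born = 2.09)
  fr <- matrix(0, 1, 3)
  expect_equal(effective_born_radii(fr, top), 2.0)  # intrinsic minus offset
  top2 <- point_topology(2, born = c(2.09, 2.09), chain = c("A", "B"))
  fr2 <- rbind(c(0, 0, 0), c(3, 0, 0))
  a2 <- effective_born_radii(fr2, top2)
  expect_true(all(a2 > 2.0))   # neighbors only enlarge the radius
  expect_error(effective_born_radii(rbind(c(0, 0, 0), c(0, 0, 0)), top2),
               "identical centers")
})

test_that("HCT descreening matches a numerical quadrature oracle", {
  # 3-atom cluster; per-pair descreening integral evaluated by Monte Carlo:
  # I_ij = (1/4pi) * int over the scaled sphere of j, outside rho_i, of
  # |x - x_i|^-4 dV
  top <- point_topology(3, born = c(1.7, 1.6, 1.9),
                        screen = c(0.8, 0.75, 0.72))
  fr <- rbind(c(0, 0, 0), c(3.2, 0, 0), c(1.2, 2.9, 0.5))
  rho <- top$born_radius - 0.09
  sr <- top$screen_factor * rho
  set.seed(61)
  mc_I <- function(i) {
    total <- 0
    for (j in setdiff(1:3, i)) {
      n_pts <- 4e5
      u <- matrix(rnorm(3 * n_pts), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      rad <- sr[j] * runif(n_pts)^(1 / 3)
      pts <- sweep(u * rad, 2L, fr[j, ], "+")
      d <- sqrt(rowSums(sweep(pts, 2L, fr[i, ])^2))
      vol <- 4 / 3 * pi * sr[j]^3
      total <- total + vol * mean(ifelse(d > rho[i], 1 / d^4, 0)) / (4 * pi)
    }
    total
  }
  alpha <- effective_born_radii(fr, top)
  for (i in 1:3) {
    alpha_mc <- 1 / (1 / rho[i] - mc_I(i))
    expect_equal(alpha[i], alpha_mc, tolerance = 0.02)
  }
})

test_that("GB single ion equals the Born closed form", {
  top <- point_topology(1, charge = 1, born = 2.09)
  fr <- matrix(0, 1, 3)
  born <- -0.5 * (1 - 1 / 78.5) * 332.0636 / 2
  expect_equal(gb_polar_energy(fr, top), born, tolerance = 1e-6 * abs(born))
  # all charges zero -> 0
  top0 <- point_topology(3, charge = rep(0, 3))
  fr3 <- matrix(rnorm(9), 3, 3) * 3
  expect_equal(gb_polar_energy(fr3, top0), 0)
})

test_that("two-ion GB matches a term-by-term hand evaluation", {
  top <- point_topology(2, charge = c(1, -1), born = c(2.09, 1.59),
                        chain = c("A", "B"))
  fr <- rbind(c(0, 0, 0), c(40, 0, 0))
  alpha <- effective_born_radii(fr, top)
  r <- 40
  fgb <- sqrt(r^2 + alpha[1] * alpha[2] *
                exp(-r^2 / (4 * alpha[1] * alpha[2])))
  pref <- -0.5 * 332.0636 * (1 - 1 / 78.5)
  manual <- pref * (1 / alpha[1] + 1 / alpha[2] + 2 * (1 * -1) / fgb)
  expect_equal(gb_polar_energy(fr, top), manual, tolerance = 1e-10)
})

test_that("SASA: sphere area, additivity of distant atoms, containment", {
  top <- point_topology(1, rmin_half = 1.5)
  fr <- matrix(0, 1, 3)
  expect_equal(sasa(fr, top), 4 * pi * 2.9^2, tolerance = 0.01)
  top2 <- point_topology(2, rmin_half = c(1.5, 1.9), chain = c("A", "B"))
  fr2 <- rbind(c(0, 0, 0), c(100, 0, 0))
  s2 <- sasa(fr2, top2)
  expect_equal(s2, 4 * pi * c(2.9, 3.3)^2, tolerance = 1e-9)
  # full burial: small atom centered just off a much larger one
  top3 <- point_topology(2, rmin_half = c(0.3, 3.6), chain = c("A", "B"))
  s3 <- sasa(rbind(c(1, 0, 0), c(0, 0, 0)), top3)
  expect_equal(s3[1], 0)
  # missing radius errors
  top_na <- top
  top_na$lj_rmin_half <- NA_real_
  expect_error(sasa(fr, top_na), "missing vdW radius")
})

test_that("non-polar term is gamma * SASA + beta", {
  expect_equal(nonpolar_energy(1000), 5)
  expect_equal(nonpolar_energy(0), 0)
  expect_equal(nonpolar_energy(2 * 750), 2 * nonpolar_energy(750))
  expect_equal(nonpolar_energy(100, gamma = 0.01, beta = 1.5), 2.5)
})

test_that("frame energy identities hold exactly and compose from parts", {
  cfg <- scenario_config(n_frames = 1, n_res_per_helix = 4,
                         helices = c(2, 1, 1), d_closed = 20, d_open = 28,
                         charge_scheme = "polar", noise_sigma = 0, seed = 6)
  sim <- generate_trajectory(cfg)
  fr <- get_frame(sim$trajectory, 1)
  top <- sim$topology
  fe <- frame_energy(fr, top, n_points = 240)
  expect_identical(fe$H_gas, fe$E_vdW + fe$E_ele)
  expect_identical(fe$G_solvation, fe$G_pol + fe$G_nonpol)
  expect_identical(fe$G_total, fe$H_gas + fe$G_solvation)
  expect_equal(fe$G_nonpol, 0.005 * fe$SASA, tolerance = 1e-12)
  # composition from independently called components
  pairs <- nonbonded_pairs(top)
  expect_equal(fe$E_vdW, lj_energy(fr, top, pairs), tolerance = 1e-12)
  expect_equal(fe$E_ele, coulomb_energy(fr, top, pairs), tolerance = 1e-12)
  expect_equal(fe$G_pol, gb_polar_energy(fr, top), tolerance = 1e-12)
  expect_equal(fe$SASA, sum(sasa(fr, top, n_points = 240)),
               tolerance = 1e-12)
  # translation invariance
  fe2 <- frame_energy(fr + 7.3, top, n_points = 240)
  expect_equal(fe2$G_total, fe$G_total, tolerance = 1e-8)
  # neutral single atom: G_total reduces to gamma * sphere SASA
  top1 <- point_topology(1, rmin_half = 1.5)
  fe1 <- frame_energy(matrix(0, 1, 3), top1)
  expect_equal(fe1$G_total, 0.005 * 4 * pi * 2.9^2, tolerance = 1e-4)
})

test_that("binding energy vanishes for distant uncharged monomers", {
  top <- point_topology(4, chain = rep(c("A", "B"), each = 2),
                        residue = c(1, 2, 3, 4))
  fr <- rbind(c(0, 0, 0), c(4, 0, 0), c(500, 0, 0), c(504, 0, 0))
  traj <- trajectory(array(fr, dim = c(4, 3, 1)))
  be <- binding_energy(traj, top, n_points = 480)
  expect_lt(abs(be$mean["dG_total"]), 1e-6)
})

test_that("binding energy is symmetric under chain relabeling", {
  cfg <- scenario_config(n_frames = 2, n_res_per_helix = 4,
                         helices = c(2, 1, 1), d_closed = 20, d_open = 28,
                         charge_scheme = "ion_pair", noise_sigma = 0.05,
                         seed = 62)
  sim <- generate_trajectory(cfg)
  be <- binding_energy(sim$trajectory, sim$topology, n_points = 120)
  top_sw <- sim$topology
  top_sw$chain_id <- ifelse(top_sw$chain_id == "A", "B", "A")
  be_sw <- binding_energy(sim$trajectory, top_sw, n_points = 120)
  expect_equal(be$mean, be_sw$mean, tolerance = 1e-10)
})

test_that("two-particle binding matches hand-evaluated terms", {
  top <- point_topology(2, charge = c(1, -1), chain = c("A", "B"),
                        rmin_half = c(1.9, 1.7), born = c(2.09, 1.79))
  fr <- rbind(c(0, 0, 0), c(3, 0, 0))
  traj <- trajectory(array(fr, dim = c(2, 3, 1)))
  be <- binding_energy(traj, top, n_points = 960)
  # gas phase
  rm_ <- 1.9 + 1.7
  ep <- 0.1094
  e_vdw <- ep * ((rm_ / 3)^12 - 2 * (rm_ / 3)^6)
  e_ele <- -332.0636 / 3
  expect_equal(unname(be$mean["dE_vdW"]), e_vdw, tolerance = 1e-10)
  expect_equal(unname(be$mean["dE_ele"]), e_ele, tolerance = 1e-10)
  # GB: complex pair term + self-term shifts from descreened radii
  alpha <- effective_born_radii(fr, top)
  rho <- c(2.0, 1.7)
  pref <- -0.5 * 332.0636 * (1 - 1 / 78.5)
  fgb <- sqrt(9 + alpha[1] * alpha[2] * exp(-9 / (4 * alpha[1] * alpha[2])))
  d_pol <- pref * (1 / alpha[1] + 1 / alpha[2] - 2 / fgb) -
    pref * (1 / rho[1] + 1 / rho[2])
  expect_equal(unname(be$mean["dG_pol"]), d_pol, tolerance = 1e-8)
  # non-polar: buried area strictly negative contribution
  expect_lt(unname(be$mean["dG_nonpol"]), 0)
})

test_that("per-residue decomposition conserves every component", {
  cfg <- scenario_config(n_frames = 5, n_res_per_helix = 4,
                         helices = c(2, 1, 1), d_closed = 20, d_open = 28,
                         charge_scheme = "ion_pair", noise_sigma = 0.05,
                         seed = 63)
  sim <- generate_trajectory(cfg)
  dec <- per_residue_decomposition(sim$trajectory, sim$topology,
                                   n_points = 120)
  tot <- attr(dec, "totals")
  expect_lt(abs(sum(dec$dE_vdW) - tot["E_vdW"]), 1e-6)
  expect_lt(abs(sum(dec$dE_ele) - tot["E_ele"]), 1e-6)
  expect_lt(abs(sum(dec$dG_pol) - tot["G_pol"]), 1e-6)
  expect_lt(abs(sum(dec$dG_nonpol) - tot["G_nonpol"]), 1e-6)
  expect_equal(dec$hydrophobic_part, dec$dE_vdW + dec$dG_nonpol)
  # the planted ion-pair residues dominate the spectrum
  ord <- order(-abs(dec$dG_total))
  ion_res <- sim$topology$residue_index[sim$topology$charge != 0]
  expect_setequal(dec$residue_index[ord[1:2]], ion_res)
})

test_that("single-residue monomers attribute everything to those residues", {
  top <- point_topology(2, charge = c(1, -1), chain = c("A", "B"),
                        residue = c(1, 2))
  fr <- rbind(c(0, 0, 0), c(4, 0, 0))
  traj <- trajectory(array(fr, dim = c(2, 3, 1)))
  dec <- per_residue_decomposition(traj, top, n_points = 240)
  tot <- attr(dec, "totals")
  expect_equal(sum(dec$dG_total), unname(sum(tot)), tolerance = 1e-9)
  expect_equal(nrow(dec), 2L)
})

test_that("interaction spectrum statistics behave on known tables", {
  set.seed(64)
  tab <- data.frame(residue_index = 1:200,
                    dG_total = rnorm(200, sd = 0.2),
                    hydrophobic_part = rnorm(200))
  tab$dG_total[c(5, 50, 120)] <- c(-2, 1.5, -3)
  st_same <- interaction_spectrum_stats(tab, tab)
  expect_equal(st_same$correlation, 1)
  expect_equal(st_same$favorable_1, 2)
  expect_equal(st_same$unfavorable_1, 1)
  # independent tables: near-zero correlation
  tab2 <- tab
  tab2$hydrophobic_part <- rnorm(200)
  expect_lt(abs(interaction_spectrum_stats(tab, tab2)$correlation), 0.2)
})

test_that("quasi-harmonic entropy: rigid zero, closed form, monotonicity", {
  set.seed(65)
  base <- matrix(rnorm(12, sd = 4), 4, 3)
  top <- point_topology(4)
  rigid <- trajectory(array(rep(base, 30), dim = c(4, 3, 30)))
  est0 <- suppressWarnings(quasiharmonic_entropy(rigid, top))
  expect_equal(est0$minus_T_S, 0)
  expect_equal(est0$n_modes, 0L)
  # single 1-D harmonic coordinate: closed-form quasi-harmonic value
  sigma <- 0.5; n <- 3000; Tt <- 300
  coords <- array(rep(base, n), dim = c(4, 3, n))
  coords[1, 1, ] <- coords[1, 1, ] + rnorm(n, sd = sigma)
  est <- suppressWarnings(
    quasiharmonic_entropy(trajectory(coords), top, T = Tt, align = FALSE))
  kB <- 0.0019872041; hbar <- 0.01517873
  lam <- 12 * var(coords[1, 1, ])
  om <- sqrt(kB * Tt * 418.4 / lam)
  a <- hbar * om / (kB * Tt)
  S <- kB * (a / (exp(a) - 1) - log(1 - exp(-a)))
  expect_equal(est$minus_T_S, -Tt * S, tolerance = 1e-8)
  expect_equal(est$n_modes, 1L)
  # entropy grows (minus_T_S falls) with the planted noise
  vals <- vapply(c(0.2, 0.5, 1.0), function(sg) {
    set.seed(66)
    cc <- array(rep(base, 400), dim = c(4, 3, 400)) +
      array(rnorm(4 * 3 * 400, sd = sg), dim = c(4, 3, 400))
    suppressWarnings(
      quasiharmonic_entropy(trajectory(cc), top, align = FALSE))$minus_T_S
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})
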