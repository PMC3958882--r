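# three-atom line: donor at origin, H on the axis, acceptor placed at a
# chosen distance/angle
hbond_frame <- function(d_DA, angle_deg) {
  D <- c(0, 0, 0); H <- c(1, 0, 0)
  # place A so that |D - A| = d_DA and angle D-H-A = angle_deg
  th <- angle_deg * pi / 180
  # solve for A on the plane: A = H + r*(cos(pi - th') ...); parametrize by
  # direction from H making the requested angle with (D - H)
  u <- c(-1, 0, 0)                      # direction H -> D
  # rotate u by angle th about z to get direction H -> A
  v <- c(cos(th) * u[1] - sin(th) * u[2],
         sin(th) * u[1] + cos(th) * u[2], 0)
  # find r > 0 with |D - (H + r v)| = d_DA
  # |(D - H) - r v|^2 = 1 + r^2 - 2 r (D-H).v
  b <- sum((D - c(1, 0, 0)) * v)
  r <- b + sqrt(b^2 - 1 + d_DA^2)
  A <- c(1, 0, 0) + r * v
  rbind(D, c(1, 0, 0), A)
}

test_that("hydrogen-bond criteria are distance <= 3.5 A and angle >= 120 deg", {
  cases <- list(list(3.4, 150, TRUE),   # both criteria met
                list(3.6, 180, FALSE),  # too long
                list(3.0, 119, FALSE))  # too bent
  for (cs in cases) {
    fr <- hbond_frame(cs[[1]], cs[[2]])
    res <- detect_hbond(fr, 1L, 2L, 3L)
    expect_equal(res$present, cs[[3]],
                 label = sprintf("d=%g angle=%g", cs[[1]], cs[[2]]))
    expect_equal(res$distance, cs[[1]], tolerance = 1e-9)
    expect_equal(res$angle, cs[[2]], tolerance = 1e-6)
  }
  # distance boundary is inclusive: exact collinear 3.5 A geometry
  fr_b <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.5, 0, 0))
  expect_true(detect_hbond(fr_b, 1L, 2L, 3L)$present)
  expect_error(detect_hbond(hbond_frame(3, 150), 1L, 1L, 3L), "distinct")
})

test_that("detection is invariant under rigid motion", {
  set.seed(51)
  fr <- hbond_frame(3.45, 125)
  base <- detect_hbond(fr, 1L, 2L, 3L)
  for (k in 1:3) {
    rm_ <- random_rigid_motion()
    moved <- detect_hbond(apply_rigid(fr, rm_), 1L, 2L, 3L)
    expect_equal(moved$present, base$present)
    expect_equal(moved$distance, base$distance, tolerance = 1e-9)
    expect_equal(moved$angle, base$angle, tolerance = 1e-6)
  }
})

test_that("occupancy is the percent of frames present", {
  frames <- list(hbond_frame(3.0, 170), hbond_frame(3.2, 160),
                 hbond_frame(3.4, 150), hbond_frame(5.0, 170))
  coords <- array(NA_real_, dim = c(3, 3, 4))
  for (i in 1:4) coords[, , i] <- frames[[i]]
  traj <- trajectory(coords)
  rec <- hbond_occupancy(traj, 1L, 2L, 3L)
  expect_equal(rec$occupancy, 75)
  # never formed
  coords0 <- coords
  for (i in 1:4) coords0[, , i] <- hbond_frame(6, 180)
  expect_equal(hbond_occupancy(trajectory(coords0), 1L, 2L, 3L)$occupancy, 0)
})

test_that("planted occupancies are recovered within binomial error", {
  cfg <- scenario_config(
    n_frames = 1000, noise_sigma = 0.1, seed = 52,
    planted_hbonds = data.frame(donor_res = 35, acceptor_res = 110,
                                occupancy = 0.8))
  sim <- generate_trajectory(cfg)
  hb <- sim$ground_truth$hbonds
  rec <- hbond_occupancy(sim$trajectory, hb$donor_atom, hb$hydrogen_atom,
                         hb$acceptor_atom)
  expect_equal(rec$occupancy, 80, tolerance = 3 / 80)
  # detection matches the planted per-frame truth exactly
  expect_identical(rec$present,
                   as.logical(sim$ground_truth$hbond_present[1, ]))
})

test_that("occupancies of disjoint-in-time bonds add up", {
  # two bonds alternately formed: occupancy(A) + occupancy(B) = 100
  frames <- vector("list", 10)
  coords <- array(NA_real_, dim = c(6, 3, 10))
  for (i in 1:10) {
    on_first <- i %% 2 == 1
    coords[1:3, , i] <- hbond_frame(if (on_first) 3.0 else 6.0, 170)
    coords[4:6, , i] <- hbond_frame(if (on_first) 6.0 else 3.0, 170) +
      matrix(rep(c(50, 0, 0), each = 3), 3, 3)
  }
  traj <- trajectory(coords)
  o1 <- hbond_occupancy(traj, 1L, 2L, 3L)$occupancy
  o2 <- hbond_occupancy(traj, 4L, 5L, 6L)$occupancy
  expect_equal(o1 + o2, 100)
})

test_that("hydrophobic contacts use nonpolar heavy atoms below the cutoff", {
  top <- point_topology(4, element = c("C", "C", "O", "C"),
                        polarity = c("nonpolar", "nonpolar", "polar",
                                     "nonpolar"),
                        residue = c(1, 2, 3, 3), chain = c("A", "B", "B", "B"))
  fr <- rbind(c(0, 0, 0), c(3.5, 0, 0), c(0, 3.0, 0), c(0, 0, 50))
  cc <- hydrophobic_contacts(fr, 1L, 2:4, top)
  expect_equal(nrow(cc), 1L)           # only the 3.5 A carbon pair
  expect_equal(cc$residue_2, 2)
  expect_equal(cc$min_distance, 3.5, tolerance = 1e-9)
  # same pair at 5.0 A: no contact
  fr2 <- fr; fr2[2, 1] <- 5
  expect_equal(nrow(hydrophobic_contacts(fr2, 1L, 2:4, top)), 0L)
  # carbon-oxygen at 3.0 A excluded by polarity even though close
  expect_false(3 %in% cc$residue_2)
  expect_error(hydrophobic_contacts(fr, 1:2, 2:4, top), "overlap")
})

test_that("contact populations recover planted toggling", {
  cfg <- scenario_config(
    n_frames = 800, noise_sigma = 0.1, seed = 53,
    planted_contacts = data.frame(res_1 = 42, res_2 = 115,
                                  population = 0.5))
  sim <- generate_trajectory(cfg)
  s1 <- which(sim$topology$residue_index == 42)
  s2 <- which(sim$topology$residue_index == 115)
  tab <- contact_population(sim$trajectory, s1, s2, sim$topology,
                            data.frame(res_1 = 42, res_2 = 115))
  expect_equal(tab$population, 50, tolerance = 5 / 50)
  # always-touching pair
  cfg2 <- scenario_config(
    n_frames = 50, noise_sigma = 0.1, seed = 54,
    planted_contacts = data.frame(res_1 = 42, res_2 = 115, population = 1))
  sim2 <- generate_trajectory(cfg2)
  tab2 <- contact_population(sim2$trajectory,
                             which(sim2$topology$residue_index == 42),
                             which(sim2$topology$residue_index == 115),
                             sim2$topology,
                             data.frame(res_1 = 42, res_2 = 115))
  expect_equal(tab2$population, 100)
  # empty pair list -> empty table
  empty <- contact_population(sim2$trajectory, 1:3, 10:12, sim2$topology,
                              data.frame(res_1 = integer(0),
                                         res_2 = integer(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("minimum side-chain distance series matches planted geometry", {
  cfg <- scenario_config(
    n_frames = 600, noise_sigma = 0.1, seed = 55,
    planted_hbonds = data.frame(donor_res = 35, acceptor_res = 110,
                                occupancy = 0.725))
  sim <- generate_trajectory(cfg)
  res <- min_sidechain_distance_series(sim$trajectory, 35, 110,
                                       sim$topology)
  expect_equal(res$fraction_below, 72.5, tolerance = 5 / 72.5)
  expect_equal(length(res$distance), 600L)
  # planted-present frames sit at the 2.9 A donor-acceptor geometry
  present <- as.logical(sim$ground_truth$hbond_present[1, ])
  expect_equal(unname(res$distance[present][1]), 2.9, tolerance = 1e-6)
  # residue without side-chain atoms errors
  bare <- point_topology(4, name = c("N", "CA", "C", "O"),
                         element = c("N", "C", "C", "O"),
                         residue = rep(1, 4))
  bare2 <- topology(rbind(as.data.frame(bare),
                          data.frame(atom_id = 5, name = "CB", element = "C",
                                     residue_index = 2, residue_name = "ALA",
                                     chain_id = "A", mass = 12, charge = 0,
                                     lj_rmin_half = 1.9, lj_epsilon = 0.1,
                                     born_radius = 1.7, screen_factor = 0.72,
                                     polarity_class = "nonpolar")))
  coords <- array(rnorm(15), dim = c(5, 3, 1))
  expect_error(
    min_sidechain_distance_series(trajectory(coords), 1, 2, bare2),
    "no side-chain heavy atoms")
})

test_that("two fixed single-atom side chains give a constant series", {
  top <- point_topology(4, name = c("CA", "CB", "CA", "CB"),
                        residue = c(1, 1, 2, 2))
  coords <- array(NA_real_, dim = c(4, 3, 3))
  fr <- rbind(c(-2, 0, 0), c(0, 0, 0), c(5, 0, 0), c(3, 0, 0))
  for (i in 1:3) coords[, , i] <- fr
  res <- min_sidechain_distance_series(trajectory(coords), 1, 2, top)
  expect_equal(res$distance, rep(3, 3))
  expect_equal(res$fraction_below, 100)
})
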