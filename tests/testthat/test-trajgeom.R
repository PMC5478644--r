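test_that("atom_distance is the Euclidean norm", {
  fr <- rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0))
  expect_equal(atom_distance(fr, 1, 2), 5.0)
  expect_equal(atom_distance(fr, 1, 3), 0.0)  # distinct atoms, same position
  expect_error(atom_distance(fr, 2, 2), "same atom")
  set.seed(11)
  fr2 <- matrix(rnorm(30), 10, 3)
  i <- 3; j <- 8
  expect_equal(atom_distance(fr2, i, j),
               sqrt(sum((fr2[i, ] - fr2[j, ])^2)), tolerance = 1e-12)
})

test_that("pocket series on a single frame has mean = min = max", {
  traj <- make_pocket_trajectory(3, seed = 1)
  one <- Trajectory(traj$topology, traj$frames[3])
  s <- pocket_distance_series(one, pocket_definition("wt"))
  for (d in s) {
    expect_equal(d$mean, d$min)
    expect_equal(d$mean, d$max)
  }
})

test_that("planted gate range 9.9-16.3 is reported exactly", {
  traj <- make_pocket_trajectory(80, seed = 5)
  s <- pocket_distance_series(traj, pocket_definition("wt"))
  expect_equal(s$d2$min, 9.9, tolerance = 0.05)
  expect_equal(s$d2$max, 16.3, tolerance = 0.05)
})

test_that("series statistics equal a frame-loop recomputation", {
  traj <- make_pocket_trajectory(50, seed = 9, sigma = 0.4)
  pocket <- pocket_definition("wt")
  s <- pocket_distance_series(traj, pocket)
  # independent recomputation: explicit loop straight over frames
  idx <- list(
    d1 = c(1, 2), d2 = c(1, 3), d3 = c(1, 4), d4 = c(2, 5))
  for (lbl in names(idx)) {
    vals <- sapply(traj$frames, function(f) {
      sqrt(sum((f[idx[[lbl]][1], ] - f[idx[[lbl]][2], ])^2))
    })
    expect_equal(s[[lbl]]$values, vals)
    expect_equal(s[[lbl]]$mean, mean(vals))
    expect_equal(s[[lbl]]$min, min(vals))
    expect_equal(s[[lbl]]$max, max(vals))
  }
})

test_that("N51A pocket uses CB at residue 51 and errors when unresolvable", {
  traj <- make_pocket_trajectory(5, variant = "N51A", seed = 2)
  s <- pocket_distance_series(traj, pocket_definition("N51A"))
  expect_length(s, 4L)
  expect_error(pocket_distance_series(traj, pocket_definition("wt")), "d1")
})

test_that("series concatenation equals concatenated per-part series", {
  traj <- make_pocket_trajectory(24, seed = 3)
  p <- pocket_definition("wt")
  whole <- pocket_distance_series(traj, p)
  part1 <- pocket_distance_series(Trajectory(traj$topology, traj$frames[1:10]), p)
  part2 <- pocket_distance_series(Trajectory(traj$topology, traj$frames[11:24]), p)
  expect_equal(whole$d2$values, c(part1$d2$values, part2$d2$values))
})

test_that("pocket statistics are invariant to a rigid transform of all frames", {
  traj <- make_pocket_trajectory(10, seed = 4)
  rot <- random_rotation(7)
  moved <- Trajectory(traj$topology,
                      lapply(traj$frames, apply_rigid, rot = rot,
                             trans = c(5, -3, 11)))
  p <- pocket_definition("wt")
  expect_equal(pocket_distance_series(moved, p)$d2$values,
               pocket_distance_series(traj, p)$d2$values, tolerance = 1e-9)
})

test_that("ring breadths reproduce the published vdW-inclusive values", {
  radii <- vdw_radius_table()
  b_c <- ring_breadth(substrate_ring_geometry("C"), radii)
  b_5mc <- ring_breadth(substrate_ring_geometry("5mC"), radii)
  b_5hmc <- ring_breadth(substrate_ring_geometry("5hmC"), radii)
  expect_equal(b_c, 7.8, tolerance = 0.3 / 7.8)
  expect_equal(b_5mc, 8.8, tolerance = 0.3 / 8.8)
  expect_gte(b_5hmc[["min"]], 8.8)
  expect_lte(b_5hmc[["max"]], 9.8)
})

test_that("breadth is a two-flank vdW span verified by a direct oracle", {
  geom <- substrate_ring_geometry("C")
  radii <- vdw_radius_table()
  # direct projection oracle over all flank atom pairs
  at <- geom$atoms
  a <- at[at$side == "carbonyl", ]
  b <- at[at$side == "subst", ]
  best <- -Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2) +
      vdw_radius(radii, a$element[i]) + vdw_radius(radii, b$element[j])
    best <- max(best, d)
  }
  expect_equal(ring_breadth(geom, radii), best, tolerance = 1e-12)
})

test_that("breadth ordering and substituent monotonicity hold", {
  radii <- vdw_radius_table()
  b_c <- ring_breadth(substrate_ring_geometry("C"), radii)
  b_5mc <- ring_breadth(substrate_ring_geometry("5mC"), radii)
  b_5hmc <- ring_breadth(substrate_ring_geometry("5hmC"), radii)
  expect_gt(b_5mc, b_c)
  expect_gte(b_5hmc[["max"]], b_5mc)
  # including the methyl hydrogens can only widen the envelope
  b_h <- ring_breadth(substrate_ring_geometry("5mC"), radii,
                      include_substituent_hydrogens = TRUE)
  expect_gte(b_h, b_5mc)
})

test_that("ring geometry invariants: axes orthogonal, ring coplanar", {
  for (kind in c("C", "5mC")) {
    geom <- substrate_ring_geometry(kind)
    expect_lt(abs(sum(geom$depth_axis * geom$breadth_axis)), 1e-9)
    ring <- geom$atoms[geom$atoms$name %in%
                         c("N1", "C2", "N3", "C4", "C5", "C6"), ]
    expect_lt(max(abs(ring$z)), 0.1)
  }
})

test_that("fit verdicts follow the gate minimum", {
  gate <- make_pocket_trajectory(
    20, targets = list(d1 = c(min = 8, mean = 9, max = 10),
                       d2 = c(min = 10.4, mean = 12.5, max = 15.1),
                       d3 = c(min = 7, mean = 8, max = 9),
                       d4 = c(min = 9, mean = 10, max = 11)),
    variant = "N51A", seed = 6)
  d2 <- pocket_distance_series(gate, pocket_definition("N51A"))$d2
  v <- fit_assessment(8.8, d2)
  expect_true(v$fits_at_min)
  expect_equal(v$clearance, 10.4 - 8.8, tolerance = 1e-9)
  boundary <- fit_assessment(d2$min, d2)
  expect_true(boundary$fits_at_min)
  expect_equal(boundary$clearance, 0.0, tolerance = 1e-9)
})

test_that("hydrated 5hmC fails the wild-type gate minimum", {
  gate <- make_pocket_trajectory(20, seed = 8)  # d2 planted 9.9-16.3
  d2 <- pocket_distance_series(gate, pocket_definition("wt"))$d2
  radii <- vdw_radius_table()
  v <- fit_assessment(9.8, d2, hydration_bulk = radii$water_bulk_min)
  expect_false(v$fits_at_min)  # 9.8 + 2.8 = 12.6 > 9.9
  expect_equal(v$clearance, 9.9 - 12.6, tolerance = 0.05)
  # a breadth interval uses its maximum
  vi <- fit_assessment(c(8.8, 9.8), d2, hydration_bulk = radii$water_bulk_min)
  expect_false(vi$fits_at_min)
})

test_that("superpose is exact on identical and rigidly moved structures", {
  st <- helix_structure()
  sp <- superpose(st, st)
  expect_equal(sp$rmsd, 0.0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  rotz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))  # 90 deg about z
  moved <- set_coords(st, apply_rigid(coords(st), rotz, c(4, -2, 7)))
  sp2 <- superpose(moved, st)
  expect_lt(sp2$rmsd, 1e-9)
  expect_equal(det(sp2$rotation), 1.0, tolerance = 1e-9)
})

test_that("superpose rmsd matches the quaternion-method oracle", {
  set.seed(21)
  xa <- matrix(rnorm(30, 0, 3), 10, 3)
  xb <- xa + matrix(rnorm(30, 0, 0.1), 10, 3)
  sta <- tiny_structure(xa)
  stb <- tiny_structure(xb)
  sp <- superpose(sta, stb)
  expect_equal(sp$rmsd, quaternion_rmsd(xa, xb), tolerance = 1e-9)
  expect_gte(sp$rmsd, 0)
  # invariance to a pre-applied rigid transform of mobile
  pre <- set_coords(sta, apply_rigid(xa, random_rotation(3), c(1, 2, 3)))
  expect_equal(superpose(pre, stb)$rmsd, sp$rmsd, tolerance = 1e-9)
})

test_that("superpose error contracts: too few atoms, unmatched sets", {
  st <- helix_structure()
  two <- tiny_structure(coords(st)[1:2, ], res_num = 1:2)
  expect_error(superpose(two, two), "underdetermined")
  other <- tiny_structure(coords(st), res_num = 11:20)
  expect_error(superpose(st, other), "matched")
})

test_that("segment rmsd isolates a planted displaced segment", {
  st <- helix_structure()
  seg <- 4:6
  xyz <- coords(st)
  # displace only the segment atoms; keep the superposition set fixed
  superpose_sel <- atom_selector(res_num = setdiff(1:10, seg))
  moved <- xyz
  moved[seg, 1] <- moved[seg, 1] + 0.5
  st2 <- set_coords(st, moved)
  expect_equal(segment_rmsd(st2, st, superpose_sel,
                            atom_selector(res_num = seg)), 0.5,
               tolerance = 1e-9)
  expect_equal(segment_rmsd(st, st, atom_selector(name = "CA"),
                            atom_selector(res_num = seg)), 0.0,
               tolerance = 1e-12)
  expect_error(segment_rmsd(st, st, atom_selector(name = "CA"),
                            atom_selector(res_name = "ZZZ")), "empty segment")
})

test_that("segment rmsd equals a direct frame-loop recomputation", {
  set.seed(31)
  st <- helix_structure()
  st2 <- set_coords(st, coords(st) + matrix(rnorm(30, 0, 0.2), 10, 3))
  seg_sel <- atom_selector(res_num = 2:5)
  got <- segment_rmsd(st2, st, atom_selector(name = "CA"), seg_sel)
  sp <- superpose(st2, st)
  xm <- coords(sp$fitted_mobile)[2:5, ]
  xt <- coords(st)[2:5, ]
  expect_equal(got, sqrt(mean(rowSums((xm - xt)^2))), tolerance = 1e-12)
  expect_gte(got, 0)
})
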