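test_that("vdW detection respects the radius-sum boundary", {
  st <- tiny_structure(rbind(c(0, 0, 0), c(3.4, 0, 0)), res_num = 1:2)
  ga <- select_atoms(st, atom_selector(res_num = 1))
  gb <- select_atoms(st, atom_selector(res_num = 2))
  radii <- vdw_radius_table()
  # r_C + r_C = 3.4: boundary counts as contact
  expect_equal(nrow(detect_vdw_contacts(st, ga, gb, radii, tolerance = 0)), 1L)
  far <- tiny_structure(rbind(c(0, 0, 0), c(4.2, 0, 0)), res_num = 1:2)
  expect_equal(nrow(detect_vdw_contacts(
    far, select_atoms(far, atom_selector(res_num = 1)),
    select_atoms(far, atom_selector(res_num = 2)), radii, tolerance = 0.6)), 0L)
})

test_that("vdW detector equals the brute-force oracle on random fixtures", {
  radii <- vdw_radius_table()
  for (seed in 1:25) {
    st <- random_structure(40, seed = seed, spread = 12)
    ga <- select_atoms(st, atom_selector(res_num = 1:20))
    gb <- select_atoms(st, atom_selector(res_num = 21:40))
    got <- detect_vdw_contacts(st, ga, gb, radii, tolerance = 0.6)
    ra <- vdw_radius(radii, ga$element)
    rb <- vdw_radius(radii, gb$element)
    want <- brute_vdw(coords(st), ga$index, gb$index, ra, rb, 0.6)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      ord <- order(want[, 1], want[, 2])
      expect_equal(got$a, want[ord, 1])
      expect_equal(got$b, want[ord, 2])
      expect_equal(got$distance, want[ord, 3], tolerance = 1e-12)
    }
  }
})

test_that("hydrogen bonds require both the distance and the angle gate", {
  mk <- function(angle_ok) {
    h <- if (angle_ok) c(0.96, 0.15, 0) else c(0.4, 0.88, 0)
    Structure(data.frame(
      serial = 1:3, name = c("ND2", "HD21", "O2"),
      element = c("N", "H", "O"), res_name = c("ASN", "ASN", "DC"),
      res_num = c(51L, 51L, 201L), chain = "A",
      x = c(0, h[1], 2.9), y = c(0, h[2], 0), z = 0))
  }
  st <- mk(TRUE)
  donors <- select_atoms(st, atom_selector(name = "ND2"))
  acceptors <- select_atoms(st, atom_selector(name = "O2"))
  hb <- detect_hbonds(st, donors, acceptors)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_gt(hb$angle, 120)
  # ~90 degree D-H...A: rejected despite the 2.9 A distance
  bad <- mk(FALSE)
  expect_equal(nrow(detect_hbonds(
    bad, select_atoms(bad, atom_selector(name = "ND2")),
    select_atoms(bad, atom_selector(name = "O2")))), 0L)
})

test_that("hydrogen-free donors fall back to the distance criterion", {
  st <- tiny_structure(rbind(c(0, 0, 0), c(3.0, 0, 0)), name = c("N", "O"),
                       element = c("N", "O"), res_num = 1:2)
  hb <- detect_hbonds(st, select_atoms(st, atom_selector(res_num = 1)),
                      select_atoms(st, atom_selector(res_num = 2)))
  expect_equal(nrow(hb), 1L)
  expect_true(is.na(hb$angle))
  expect_error(detect_hbonds(st, select_atoms(st, atom_selector(res_num = 1)),
                             select_atoms(st, atom_selector(res_num = 1))),
               "same atom")
})

test_that("the planted N51-to-O2 hydrogen bond is detected in the fixture", {
  fx <- make_complex_fixture("wt", "C")
  topo <- fx$traj$topology
  donors <- select_atoms(topo, atom_selector(res_num = 51, name = "ND2"))
  acceptors <- select_atoms(topo, atom_selector(res_num = 201, name = "O2"))
  hb <- detect_hbonds(topo, donors, acceptors)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_equal(hb$angle, 165, tolerance = 0.5)
})

test_that("ideal coaxial stacks are detected and tilted ones rejected", {
  st <- stacked_rings_structure(separation = 3.5)
  hits <- detect_stacking(st, list(ring_spec_for(1), ring_spec_for(2)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$plane_angle, 0, tolerance = 1e-6)
  expect_equal(hits$lateral_offset, 0, tolerance = 1e-9)
  expect_equal(hits$centroid_distance, 3.5, tolerance = 1e-9)
  tilted <- stacked_rings_structure(separation = 3.5, tilt_deg = 60)
  expect_equal(nrow(detect_stacking(
    tilted, list(ring_spec_for(1), ring_spec_for(2)))), 0L)
  line <- tiny_structure(cbind(1:6, 0, 0), name = paste0("C", 1:6),
                         res_num = rep(1L, 6))
  expect_error(detect_stacking(line, list(ring_spec_for(1))), "collinear")
})

test_that("three coaxial rings give both adjacent stack pairs", {
  st <- stacked_rings_structure(separation = 3.5, n_rings = 3)
  hits <- detect_stacking(st, list(ring_spec_for(1), ring_spec_for(2),
                                   ring_spec_for(3)))
  keys <- paste(hits$ring_i, hits$ring_j)
  expect_true(all(c("ring1 ring2", "ring2 ring3") %in% keys))
  expect_false("ring1 ring3" %in% keys)  # 7 A apart: beyond centroid_max
})

test_that("triple-stack occupancy counts frames with both pairs stacked", {
  stacked <- stacked_rings_structure(separation = 3.5, n_rings = 3)
  apart <- stacked_rings_structure(separation = 8, n_rings = 3)
  frames <- c(rep(list(coords(stacked)), 4), rep(list(coords(apart)), 6))
  traj <- Trajectory(stacked, frames)
  out <- triple_stack_series(traj, ring_spec_for(1, "W84"),
                             ring_spec_for(2, "Y114"), ring_spec_for(3, "G"))
  expect_equal(unname(out$occupancy["W84:Y114:G"]), 0.4)
  expect_equal(out$stability, "unstable/alternative")
  all_on <- Trajectory(stacked, rep(list(coords(stacked)), 5))
  expect_equal(triple_stack_series(all_on, ring_spec_for(1, "W84"),
                                   ring_spec_for(2, "Y114"),
                                   ring_spec_for(3, "G"))$stability, "stable")
})

test_that("an alternative stack can dominate the triple", {
  # W84 ring far away; A ring stacked against Y114:G in every frame
  apart_w <- tiny_structure(matrix(c(50, 50, 50), 1, 3), name = "CX",
                            res_num = 9L)
  base <- stacked_rings_structure(separation = 3.5, n_rings = 3)
  # rings: 1 = A, 2 = Y114, 3 = G; W84 = a distant flat ring (res 4)
  far_ring <- stacked_rings_structure(separation = 3.5, n_rings = 1)
  at <- far_ring$atoms
  at$res_num <- 4L
  at$serial <- at$serial + 100L
  at$x <- at$x + 60
  merged <- Structure(rbind(base$atoms, at))
  traj <- Trajectory(merged, rep(list(coords(merged)), 5))
  out <- triple_stack_series(traj, ring_w84 = ring_spec_for(4, "W84"),
                             ring_y114 = ring_spec_for(2, "Y114"),
                             ring_g = ring_spec_for(3, "G"),
                             ring_a = ring_spec_for(1, "A"))
  expect_equal(unname(out$occupancy["A:Y114:G"]), 1.0)
  expect_equal(unname(out$occupancy["W84:Y114:G"]), 0.0)
  expect_equal(out$dominant, "A:Y114:G")
  expect_equal(out$stability, "unstable/alternative")
})

test_that("aggregate_network counts planted interactions exactly", {
  fx <- make_complex_fixture("wt", "C")
  net <- aggregate_network(fx$traj, fx$protein_sel, fx$substrate_sel,
                           complex_label = fx$complex_label)
  expect_equal(unname(net$counts["n_vdw"]), 3L)
  expect_equal(unname(net$counts["n_hbond"]), 1L)
  expect_equal(unname(net$counts["n_total"]), 4L)
  # zero-interaction input
  empty <- make_interaction_frame(list())
  net0 <- aggregate_network(Trajectory(empty, list(coords(empty))),
                            atom_selector(res_num = 999),
                            atom_selector(res_num = 1000))
  expect_equal(unname(net0$counts["n_total"]), 0L)
  expect_equal(nrow(net0$records), 0L)
})

test_that("occupancy 0.5 sits on the counting boundary", {
  fx <- make_complex_fixture("wt", "C")
  present <- coords(fx$traj$topology)
  gone <- present
  gone[, 1] <- gone[, 1] + 500  # move everything apart in frame 2? no:
  # move only the substrate atoms far away so no interaction survives
  subs_idx <- select_atoms(fx$traj$topology, fx$substrate_sel)$index
  gone <- present
  gone[subs_idx, 1] <- gone[subs_idx, 1] + 500
  traj2 <- Trajectory(fx$traj$topology, list(present, gone))
  net <- aggregate_network(traj2, fx$protein_sel, fx$substrate_sel)
  expect_true(all(net$records$occupancy == 0.5))
  expect_equal(unname(net$counts["n_total"]), 4L)  # 0.5 >= 0.5 counts
  strict <- aggregate_network(traj2, fx$protein_sel, fx$substrate_sel,
                              config = interaction_config(occupancy_threshold = 0.6))
  expect_equal(unname(strict$counts["n_total"]), 0L)
})

test_that("hbond and vdw classifications are exclusive per frame", {
  fx <- make_complex_fixture("wt", "5mC")
  net <- aggregate_network(fx$traj, fx$protein_sel, fx$substrate_sel)
  keys_hb <- with(net$records[net$records$kind == "hbond", ],
                  paste(partner_a, partner_b))
  keys_vdw <- with(net$records[net$records$kind == "vdw", ],
                   paste(partner_a, partner_b))
  expect_length(intersect(keys_hb, keys_vdw), 0L)
})

test_that("network aggregation is invariant to frame order and rigid moves", {
  fx <- make_complex_fixture("wt", "C")
  subs_idx <- select_atoms(fx$traj$topology, fx$substrate_sel)$index
  f1 <- coords(fx$traj$topology)
  f2 <- f1
  f2[subs_idx, 1] <- f2[subs_idx, 1] + 500
  net_ab <- aggregate_network(Trajectory(fx$traj$topology, list(f1, f2)),
                              fx$protein_sel, fx$substrate_sel)
  net_ba <- aggregate_network(Trajectory(fx$traj$topology, list(f2, f1)),
                              fx$protein_sel, fx$substrate_sel)
  expect_equal(net_ab$records, net_ba$records)
  rot <- random_rotation(5)
  moved <- lapply(list(f1, f2), apply_rigid, rot = rot, trans = c(3, 1, -9))
  net_mv <- aggregate_network(Trajectory(fx$traj$topology, moved),
                              fx$protein_sel, fx$substrate_sel)
  expect_equal(net_mv$counts, net_ab$counts)
  expect_equal(net_mv$records$occupancy, net_ab$records$occupancy)
})

test_that("counts shrink monotonically under stricter cutoffs", {
  st <- random_structure(60, seed = 8, spread = 9)
  ga <- select_atoms(st, atom_selector(res_num = 1:30))
  gb <- select_atoms(st, atom_selector(res_num = 31:60))
  radii <- vdw_radius_table()
  n_loose <- nrow(detect_vdw_contacts(st, ga, gb, radii, tolerance = 0.6))
  n_tight <- nrow(detect_vdw_contacts(st, ga, gb, radii, tolerance = 0.0))
  expect_lte(n_tight, n_loose)
})

test_that("network_diff reproduces the wt-vs-N51A and C-vs-5mC signatures", {
  wt_c <- make_complex_fixture("wt", "C")
  n51a_c <- make_complex_fixture("N51A", "C")
  wt_5mc <- make_complex_fixture("wt", "5mC")
  net <- function(fx) aggregate_network(fx$traj, fx$protein_sel,
                                        fx$substrate_sel,
                                        complex_label = fx$complex_label)
  nw <- net(wt_c)
  # self-diff is empty
  self <- network_diff(nw, nw)
  expect_length(self$gained, 0L)
  expect_length(self$lost, 0L)
  expect_equal(length(self$shared), nrow(nw$records))
  # N51A loses exactly the N51 hydrogen bond to the C2 carbonyl
  d1 <- network_diff(nw, net(n51a_c))
  expect_equal(d1$lost, "hbond|ASN51:ND2|DC201:O2")
  expect_length(d1$gained, 0L)
  # methylation gains exactly the methyl bridges to W84 and T27
  d2 <- network_diff(nw, net(wt_5mc))
  expect_setequal(d2$gained, c("vdw|TRP84:CZ2|5mC-methyl",
                               "vdw|THR27:CG2|5mC-methyl"))
  expect_setequal(d2$lost, c("vdw|THR27:CG2|DC201:C4",
                             "vdw|THR27:CB|DC201:C6"))
})
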