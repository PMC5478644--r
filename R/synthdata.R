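# Synthetic-data generators: planted pocket trajectories, planted
# interaction frames, clustered conformations, clone sets and gel lanes.
# Every generator is deterministic under a fixed seed, and each exists so
# that the matching analyzer can be shown to recover what was planted.

# Planted series with exact min/max (endpoint frames) and exact mean:
# values drawn N(mean, sigma), clipped to [min, max], frames 1 and 2 set
# to min and max, and the remaining frames recentred so the series mean
# equals the target exactly.
planted_series <- function(n, target, sigma) {
  if (!(target["min"] <= target["mean"] && target["mean"] <= target["max"])) {
    stop("infeasible distance targets: need min <= mean <= max")
  }
  if (n < 3L && target["min"] < target["max"]) {
    stop("need >= 3 frames to plant distinct min/max endpoints")
  }
  if (target["min"] == target["max"]) return(rep(target["mean"], n))
  v <- stats::rnorm(n, target["mean"], sigma)
  v <- pmin(pmax(v, target["min"]), target["max"])
  v[1L] <- target["min"]
  v[2L] <- target["max"]
  rest <- 3:n
  shift <- (target["mean"] * n - sum(v)) / length(rest)
  v[rest] <- pmin(pmax(v[rest] + shift, target["min"]), target["max"])
  # one correcting pass in case clipping ate part of the shift
  resid <- target["mean"] * n - sum(v)
  room <- if (resid > 0) target["max"] - v[rest] else v[rest] - target["min"]
  take <- if (sum(room) > 0) pmin(abs(resid) * room / sum(room), room) else 0
  v[rest] <- v[rest] + sign(resid) * take
  unname(v)
}

pocket_atom_table <- function(variant) {
  name51 <- if (variant == "wt") "ND2" else "CB"
  res51 <- if (variant == "wt") "ASN" else "ALA"
  data.frame(
    serial = 1:8,
    name = c(name51, "CE2", "CB", "SG", "CE1", "CA", "CA", "CA"),
    element = c(if (variant == "wt") "N" else "C", "C", "C", "S", "C",
                "C", "C", "C"),
    res_name = c(res51, "TYR", "PRO", "CYS", "HIS", "GLY", "GLY", "GLY"),
    res_num = c(51L, 114L, 86L, 87L, 56L, 10L, 11L, 12L),
    chain = "A",
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
}

#' Generate a pocket trajectory with planted distance statistics
#'
#' Builds a minimal topology holding the four pocket-defining atoms
#' (residue 51 probe, Y114 CE2, P86 CB, C87 SG, H56 CE1) plus decoy
#' atoms, and moves the pocket atoms along fixed axes so that each
#' labeled pair's distance series realizes its planted min and max
#' exactly (endpoint frames) and its mean exactly (recentred draw with
#' jitter `sigma`). Decoy atoms receive i.i.d. Gaussian jitter.
#'
#' @param n_frames number of frames (>= 3).
#' @param targets named list `d1`..`d4`, each `c(min=, mean=, max=)` in
#'   Angstrom.
#' @param sigma jitter standard deviation in Angstrom (default 0.5).
#' @param variant `"wt"` or `"N51A"` (controls the residue-51 atom).
#' @param seed RNG seed.
#' @return a `Trajectory` whose [pocket_distance_series()] statistics
#'   equal the plant.
#' @export
make_pocket_trajectory <- function(n_frames,
                                   targets = list(
                                     d1 = c(min = 8.0, mean = 9.0, max = 10.0),
                                     d2 = c(min = 9.9, mean = 12.5, max = 16.3),
                                     d3 = c(min = 7.0, mean = 8.0, max = 9.0),
                                     d4 = c(min = 9.0, mean = 10.0, max = 11.0)),
                                   sigma = 0.5,
                                   variant = c("wt", "N51A"), seed = 1) {
  variant <- match.arg(variant)
  stopifnot(all(c("d1", "d2", "d3", "d4") %in% names(targets)))
  series <- with_seed(seed, lapply(targets, function(tg) {
    planted_series(n_frames, tg[c("min", "mean", "max")], sigma)
  }))
  topo_atoms <- pocket_atom_table(variant)
  # orthogonal placement axes so each pair's distance is set independently:
  # residue 51 anchored at origin; Y114 along x; P86 along y; C87 along z;
  # H56 offset from Y114 along y.
  decoy_base <- matrix(c(20, 20, 20, 24, 20, 20, 20, 24, 20), 3L, 3L,
                       byrow = TRUE)
  frames <- with_seed(derive_seed(seed, 2L), lapply(seq_len(n_frames), function(f) {
    y114 <- c(series$d1[f], 0, 0)
    rbind(c(0, 0, 0),
          y114,
          c(0, series$d2[f], 0),
          c(0, 0, series$d3[f]),
          y114 + c(0, series$d4[f], 0),
          decoy_base + matrix(stats::rnorm(9L, 0, sigma), 3L, 3L))
  }))
  topo <- Structure(topo_atoms, title = sprintf("planted pocket (%s)", variant))
  topo <- set_coords(topo, frames[[1L]])
  Trajectory(topo, frames)
}

# ---- planted interaction frames -------------------------------------------

plant_atom <- function(env, name, element, res_name, res_num, xyz,
                       chain = "A") {
  env$rows[[length(env$rows) + 1L]] <- data.frame(
    serial = length(env$rows) + 1L, name = name, element = element,
    res_name = res_name, res_num = res_num, chain = chain,
    x = xyz[1L], y = xyz[2L], z = xyz[3L], stringsAsFactors = FALSE)
}

#' Build a structure in which exactly the planted interactions hold
#'
#' Each planted contact is constructed on its own 20-Angstrom lattice
#' cell, so that only the intended pairs satisfy the default detector
#' criteria and every non-planted pair sits far beyond its threshold.
#' Supported kinds:
#' \describe{
#'   \item{vdw}{`list(kind="vdw", a=c(res_name, name, element),
#'     b=(...), res_a=, res_b=, distance=)` — two heavy atoms at the
#'     given distance.}
#'   \item{hbond}{`list(kind="hbond", donor=..., acceptor=..., res_d=,
#'     res_a=, distance=, angle=)` — donor with one hydrogen aimed at
#'     the acceptor at the given D...A distance and D-H...A angle.}
#'   \item{stack}{`list(kind="stack", labels=c(..), res=c(..),
#'     res_names=c(..), separation=)` — coaxially stacked parallel
#'     hexagons at the given separation (two or more rings).}
#' }
#'
#' @param contacts list of planted contact descriptions.
#' @param group_a_res,group_b_res residue numbers belonging to the
#'   "protein" and "substrate" sides (used by callers to build
#'   selectors; stored in the result attributes).
#' @return a `Structure`.
#' @export
make_interaction_frame <- function(contacts, group_a_res = NULL,
                                   group_b_res = NULL) {
  env <- new.env()
  env$rows <- list()
  cell <- 0L
  origin <- function() {
    cell <<- cell + 1L
    c((cell %% 5L) * 20, (cell %/% 5L %% 5L) * 20, (cell %/% 25L) * 20)
  }
  for (ct in contacts) {
    o <- origin()
    if (ct$kind == "vdw") {
      plant_atom(env, ct$a[2L], ct$a[3L], ct$a[1L], ct$res_a, o)
      plant_atom(env, ct$b[2L], ct$b[3L], ct$b[1L], ct$res_b,
                 o + c(ct$distance, 0, 0))
    } else if (ct$kind == "hbond") {
      d <- ct$distance
      plant_atom(env, ct$donor[2L], ct$donor[3L], ct$donor[1L], ct$res_d, o)
      # hydrogen 1.0 A from the donor, bent so that angle(D-H...A) = angle
      acc <- o + c(d, 0, 0)
      h <- if (ct$angle >= 180) {
        o + c(1.0, 0, 0)
      } else {
        phi <- theta_h(d, ct$angle)
        o + 1.0 * c(cos(phi), sin(phi), 0)
      }
      plant_atom(env, paste0("H", substr(ct$donor[2L], 2L, 4L), "1"), "H",
                 ct$donor[1L], ct$res_d, h)
      plant_atom(env, ct$acceptor[2L], ct$acceptor[3L], ct$acceptor[1L],
                 ct$res_a, acc)
    } else if (ct$kind == "stack") {
      nr <- length(ct$labels)
      for (k in seq_len(nr)) {
        hex <- hexagon_coords(center = o + c(0, 0, (k - 1L) * ct$separation))
        for (v in seq_len(6L)) {
          plant_atom(env, paste0("C", v, "R"), "C", ct$res_names[k],
                     ct$res[k], hex[v, ])
        }
      }
    } else {
      stop("unknown planted contact kind: ", ct$kind)
    }
  }
  if (!length(env$rows)) {
    # an empty plant still needs a carrier atom for a valid Structure
    plant_atom(env, "CA", "C", "GLY", 999L, c(0, 0, 0))
  }
  atoms <- do.call(rbind, env$rows)
  atoms$serial <- seq_len(nrow(atoms))
  st <- Structure(atoms, title = "planted interaction frame")
  attr(st, "group_a_res") <- group_a_res
  attr(st, "group_b_res") <- group_b_res
  st
}

# Hydrogen placement angle: put H 1.0 A from D in the D-A plane such that
# the D-H...A angle equals `angle` degrees. Solved from the triangle
# D-H-A: given |DH| = 1, |DA| = d, interior angle at H (between H->D and
# H->A) = angle.
theta_h <- function(d, angle) {
  # place H at polar angle phi from the D->A axis; solve numerically
  phi <- stats::uniroot(function(p) {
    h <- c(cos(p), sin(p), 0)
    a <- c(d, 0, 0)
    v1 <- -h
    v2 <- a - h
    acos(sum(v1 * v2) / (vnorm(v1) * vnorm(v2))) * 180 / pi - angle
  }, c(1e-6, pi - 1e-6))$root
  phi
}

hexagon_coords <- function(center, radius = 1.39) {
  t(vapply(0:5, function(k) {
    center + radius * c(cos(k * pi / 3), sin(k * pi / 3), 0)
  }, numeric(3L)))
}

#' Planted enzyme-substrate complex fixtures
#'
#' Builds a one-frame trajectory whose interaction network carries the
#' qualitative signatures observed for the four enzyme:substrate
#' complexes: wild-type complexes include the N51 ND2 hydrogen bond to
#' the cytosine C2 carbonyl (O2), which the N51A complexes lack;
#' 5mC complexes add the methyl-bridge vdW contacts (methyl to W84 and
#' T27) that partially replace the T27 to C4-C5-C6 contacts of the C
#' complexes.
#'
#' @param variant `"wt"` or `"N51A"`.
#' @param base `"C"` or `"5mC"`.
#' @return list with `traj` (one-frame `Trajectory`), `protein_sel`,
#'   `substrate_sel` and the `complex_label`.
#' @export
make_complex_fixture <- function(variant = c("wt", "N51A"),
                                 base = c("C", "5mC")) {
  variant <- match.arg(variant)
  base <- match.arg(base)
  # each planted contact lives in its own lattice cell, so every contact
  # uses its own atoms; the methyl's two contacts use the two methyl atom
  # names (C5M, C7), which partner labeling collapses to "5mC-methyl"
  contacts <- list(
    # pyrimidine ring held by Y114 (both variants, both bases)
    list(kind = "vdw", a = c("TYR", "CE2", "C"), b = c("DC", "C5", "C"),
         res_a = 114L, res_b = 201L, distance = 3.6))
  if (variant == "wt") {
    contacts <- c(contacts, list(
      list(kind = "hbond", donor = c("ASN", "ND2", "N"),
           acceptor = c("DC", "O2", "O"),
           res_d = 51L, res_a = 201L, distance = 2.9, angle = 165)))
  }
  if (base == "C") {
    contacts <- c(contacts, list(
      list(kind = "vdw", a = c("THR", "CG2", "C"), b = c("DC", "C4", "C"),
           res_a = 27L, res_b = 201L, distance = 3.5),
      list(kind = "vdw", a = c("THR", "CB", "C"), b = c("DC", "C6", "C"),
           res_a = 27L, res_b = 201L, distance = 3.5)))
  } else {
    contacts <- c(contacts, list(
      list(kind = "vdw", a = c("TRP", "CZ2", "C"), b = c("DC", "C5M", "C"),
           res_a = 84L, res_b = 201L, distance = 3.6),
      list(kind = "vdw", a = c("THR", "CG2", "C"), b = c("DC", "C7", "C"),
           res_a = 27L, res_b = 201L, distance = 3.6)))
  }
  st <- make_interaction_frame(contacts)
  list(traj = Trajectory(st, list(coords(st))),
       protein_sel = atom_selector(res_num = c(27L, 51L, 84L, 114L)),
       substrate_sel = atom_selector(res_num = 201L),
       complex_label = paste0(variant, ":", base))
}

#' Generate a trajectory of planted conformational clusters
#'
#' Places `k` cluster centers (random per-atom displacement fields with
#' pairwise RMSD of about `spread`) and draws `frames_per_cluster`
#' members per center with Gaussian per-coordinate noise, so that the
#' intra/inter separation ratio is about `spread / (noise * sqrt(2))`.
#' Frames are emitted cluster by cluster; the true labels are returned
#' alongside.
#'
#' @param k number of clusters (>= 2).
#' @param frames_per_cluster members per cluster.
#' @param spread target pairwise center RMSD in Angstrom.
#' @param noise per-coordinate member noise standard deviation in
#'   Angstrom.
#' @param n_atoms number of (C-alpha) atoms in the synthetic protein.
#' @param seed RNG seed.
#' @return list with `traj` (a `Trajectory`) and `labels` (true cluster
#'   id per frame).
#' @export
make_clustered_trajectory <- function(k, frames_per_cluster = 5L, spread = 5,
                                      noise = 0.2, n_atoms = 30L, seed = 1) {
  if (k < 2L) stop("need k >= 2 planted clusters")
  with_seed(seed, {
    backbone <- matrix(stats::rnorm(n_atoms * 3L, 0, 5), n_atoms, 3L)
    # independent displacement fields: pairwise E[RMSD] = tau * sqrt(6)
    tau <- spread / sqrt(6)
    centers <- lapply(seq_len(k), function(i) {
      backbone + matrix(stats::rnorm(n_atoms * 3L, 0, tau), n_atoms, 3L)
    })
    frames <- list()
    labels <- integer(0)
    for (ci in seq_len(k)) {
      for (f in seq_len(frames_per_cluster)) {
        frames[[length(frames) + 1L]] <-
          centers[[ci]] + matrix(stats::rnorm(n_atoms * 3L, 0, noise),
                                 n_atoms, 3L)
        labels <- c(labels, ci)
      }
    }
    atoms <- data.frame(serial = seq_len(n_atoms), name = "CA", element = "C",
                        res_name = "GLY", res_num = seq_len(n_atoms),
                        chain = "A", x = backbone[, 1L], y = backbone[, 2L],
                        z = backbone[, 3L], stringsAsFactors = FALSE)
    list(traj = Trajectory(Structure(atoms, "planted clusters"), frames),
         labels = labels, centers = centers)
  })
}

#' Generate a synthetic clone set from an NNCN design
#'
#' Per clone and per non-flank C position, the C reads as T with its
#' motif's deamination probability; independently, every position is
#' substituted uniformly (to one of the three other bases) with the
#' sequencing error rate `error_rate`.
#'
#' @param design an `NncnDesign`.
#' @param p named per-motif deamination probabilities (missing motifs
#'   default to `p_default`), or a single number for all motifs.
#' @param n_clones clones per oligo.
#' @param error_rate uniform per-position substitution rate in
#'   [0, 0.05].
#' @param p_default default motif probability (0).
#' @param seed RNG seed.
#' @return named character vector of clone sequences; names are
#'   `<oligo>_clone<i>`, attribute `oligo_id` maps clones to oligos.
#' @export
make_clone_set <- function(design, p, n_clones = 20L, error_rate = 0,
                           p_default = 0, seed = 1) {
  stopifnot(inherits(design, "NncnDesign"))
  if (error_rate < 0 || error_rate > 0.05) {
    stop("error_rate must lie in [0, 0.05]")
  }
  if (is.null(names(p)) && length(p) == 1L) {
    p <- stats::setNames(rep(p, 64L), ALL_NNCN_MOTIFS())
  }
  if (any(p < 0 | p > 1)) stop("deamination probabilities must lie in [0, 1]")
  nts <- c("A", "C", "G", "T")
  with_seed(seed, {
    out <- character(0)
    oligo_of <- character(0)
    for (id in names(design$oligos)) {
      refseq <- design$oligos[[id]]
      sites <- design$c_index[design$c_index$oligo == id, , drop = FALSE]
      site_p <- p[sites$context]
      site_p[is.na(site_p)] <- p_default
      for (cl in seq_len(n_clones)) {
        chars <- strsplit(refseq, "")[[1L]]
        flip <- stats::runif(nrow(sites)) < site_p
        chars[sites$position[flip]] <- "T"
        if (error_rate > 0) {
          err <- which(stats::runif(length(chars)) < error_rate)
          for (e in err) {
            chars[e] <- sample(setdiff(nts, chars[e]), 1L)
          }
        }
        nm <- sprintf("%s_clone%d", id, cl)
        out[nm] <- paste(chars, collapse = "")
        oligo_of[nm] <- id
      }
    }
    attr(out, "oligo_id") <- oligo_of
    out
  })
}

#' Generate replicate gel lanes with planted deamination efficiencies
#'
#' Runs [simulate_assay()] per replicate and converts the fragment
#' counts into band intensities with multiplicative log-normal noise of
#' sigma `noise_sigma` — the synthetic counterpart of quantified
#' phosphorimager lanes.
#'
#' @param efficiency planted per-reaction deamination probability.
#' @param oligo a `SubstrateOligo` (default: the standard 80-nt C
#'   substrate; its `base_kind` decides the chemistry branch).
#' @param glyco a `GlycosylaseSpec` matching the substrate.
#' @param n_molecules molecules per lane (default 1e5).
#' @param n_replicates replicate lanes (default 3, the assay's replicate
#'   structure).
#' @param noise_sigma log-normal sigma on band intensities (default
#'   0.05).
#' @param seed RNG seed.
#' @param label lane label prefix.
#' @return list of `GelLane`s, one per replicate.
#' @export
make_gel_lanes <- function(efficiency, oligo = standard_assay_oligo("C"),
                           glyco = glycosylase_spec("UDG"),
                           n_molecules = 1e5, n_replicates = 3L,
                           noise_sigma = 0.05, seed = 1, label = "lane") {
  if (efficiency < 0 || efficiency > 1) stop("efficiency must lie in [0, 1]")
  enz <- enzyme_profile("custom",
                        efficiency = stats::setNames(
                          rep(efficiency, 3L), c("C", "5mC", "5hmC")))
  lapply(seq_len(n_replicates), function(r) {
    sim <- simulate_assay(oligo, enz, glyco, n_molecules,
                          seed = derive_seed(seed, r))
    bands <- data.frame(length = c(sim$product_length, sim$substrate_length),
                        intensity = c(sim$product_fraction,
                                      1 - sim$product_fraction))
    noise <- with_seed(derive_seed(seed, 100L + r),
                       exp(stats::rnorm(2L, 0, noise_sigma)))
    bands$intensity <- bands$intensity * noise
    gel_lane(bands, label = sprintf("%s_rep%d", label, r))
  })
}
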