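# Protein-substrate interaction fingerprinting: van der Waals contacts,
# hydrogen bonds and pi-stacking per frame, aggregated into per-complex
# interaction networks with frame occupancies and mean distances.

#' Detector configuration
#'
#' Geometric criteria for the three interaction detectors, with
#' community-standard defaults: hydrogen bonds at heavy-atom
#' donor-acceptor distance <= 3.5 Angstrom and D-H...A angle >= 120
#' degrees; vdW contacts within the radius sum plus 0.6 Angstrom;
#' stacking at centroid distance <= 4.5 Angstrom, interplanar angle <= 30
#' degrees and lateral offset <= 2.0 Angstrom. An interaction "exists"
#' for a trajectory when its frame occupancy reaches
#' `occupancy_threshold`; a stack is "stable" at `stable_threshold`.
#'
#' @param vdw_tolerance,hbond_dmax,hbond_angle_min,stack_centroid_max,stack_plane_angle_max,stack_offset_max
#'   geometric cutoffs (Angstrom / degrees).
#' @param occupancy_threshold,stable_threshold occupancy cutoffs in [0,1].
#' @return list of class `InteractionConfig`.
#' @export
interaction_config <- function(vdw_tolerance = 0.6, hbond_dmax = 3.5,
                               hbond_angle_min = 120,
                               stack_centroid_max = 4.5,
                               stack_plane_angle_max = 30,
                               stack_offset_max = 2.0,
                               occupancy_threshold = 0.5,
                               stable_threshold = 0.7) {
  structure(list(vdw_tolerance = vdw_tolerance, hbond_dmax = hbond_dmax,
                 hbond_angle_min = hbond_angle_min,
                 stack_centroid_max = stack_centroid_max,
                 stack_plane_angle_max = stack_plane_angle_max,
                 stack_offset_max = stack_offset_max,
                 occupancy_threshold = occupancy_threshold,
                 stable_threshold = stable_threshold),
            class = "InteractionConfig")
}

frame_coords <- function(struct, frame = NULL) {
  if (is.null(frame)) coords(struct) else as.matrix(frame)
}

#' Detect van der Waals contacts between two atom groups
#'
#' Reports every heavy-atom pair (one atom from each group) whose
#' distance is at most the sum of the two vdW radii plus `tolerance`.
#' Pairs listed in `exclude_pairs` (atom index pairs already classified
#' as hydrogen bonds in the same frame) are skipped: the classification
#' is exclusive, so an atom pair is a contact or an H-bond, never both.
#'
#' @param struct a `Structure` carrying atom identities.
#' @param group_a,group_b atom tables from [select_atoms()] (disjoint).
#' @param radii a `VdwRadiusTable`.
#' @param tolerance Angstrom added to the radius sum (default 0.6).
#' @param frame optional n x 3 coordinate matrix overriding the
#'   structure's own coordinates.
#' @param exclude_pairs two-column matrix of atom index pairs to skip.
#' @return data.frame with columns `a`, `b` (atom indices), `distance`.
#' @export
detect_vdw_contacts <- function(struct, group_a, group_b, radii = vdw_radius_table(),
                                tolerance = 0.6, frame = NULL,
                                exclude_pairs = NULL) {
  xyz <- frame_coords(struct, frame)
  ga <- group_a[group_a$element != "H", , drop = FALSE]
  gb <- group_b[group_b$element != "H", , drop = FALSE]
  if (nrow(ga) == 0L || nrow(gb) == 0L) {
    return(data.frame(a = integer(0), b = integer(0), distance = numeric(0)))
  }
  if (length(intersect(ga$index, gb$index))) {
    stop("vdW contact groups must be disjoint")
  }
  ra <- vdw_radius(radii, ga$element)
  rb <- vdw_radius(radii, gb$element)
  xa <- xyz[ga$index, , drop = FALSE]
  xb <- xyz[gb$index, , drop = FALSE]
  # squared-distance matrix, vectorized
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  cutoff <- outer(ra, rb, "+") + tolerance
  hit <- which(dmat <= cutoff, arr.ind = TRUE)
  out <- data.frame(a = ga$index[hit[, 1L]], b = gb$index[hit[, 2L]],
                    distance = dmat[hit])
  if (!is.null(exclude_pairs) && nrow(out) && NROW(exclude_pairs)) {
    key <- paste(out$a, out$b)
    exkey <- c(paste(exclude_pairs[, 1L], exclude_pairs[, 2L]),
               paste(exclude_pairs[, 2L], exclude_pairs[, 1L]))
    out <- out[!key %in% exkey, , drop = FALSE]
  }
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hydrogens geometrically attached to a donor heavy atom: any H atom of
# the same residue within 1.25 Angstrom.
attached_hydrogens <- function(struct, xyz, donor_row) {
  at <- struct$atoms
  cand <- which(at$element == "H" & at$chain == donor_row$chain &
                  at$res_num == donor_row$res_num)
  if (!length(cand)) return(integer(0))
  d <- sqrt(rowSums((xyz[cand, , drop = FALSE] -
                       matrix(xyz[donor_row$index, ], length(cand), 3L,
                              byrow = TRUE))^2))
  cand[d <= 1.25]
}

#' Detect hydrogen bonds between donors and acceptors
#'
#' A bond is reported when the donor-acceptor heavy-atom distance is at
#' most `d_max` and, if the donor carries hydrogens, the best D-H...A
#' angle over its attached hydrogens is at least `angle_min` degrees.
#' Donors without hydrogens (e.g. a structure stripped of protons) are
#' judged on the distance criterion alone and report `angle = NA`.
#'
#' @param struct a `Structure`.
#' @param donors atom table of donor heavy atoms (N/O/S).
#' @param acceptors atom table of acceptor atoms (N/O).
#' @param d_max heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param angle_min D-H...A angle cutoff in degrees (default 120).
#' @param frame optional coordinate matrix overriding the structure's.
#' @return data.frame with columns `donor`, `hydrogen` (index or NA),
#'   `acceptor`, `distance`, `angle` (degrees or NA).
#' @export
detect_hbonds <- function(struct, donors, acceptors, d_max = 3.5,
                          angle_min = 120, frame = NULL) {
  xyz <- frame_coords(struct, frame)
  if (!all(donors$element %in% c("N", "O", "S"))) {
    stop("hydrogen-bond donors must be N, O or S heavy atoms")
  }
  if (!all(acceptors$element %in% c("N", "O"))) {
    stop("hydrogen-bond acceptors must be N or O atoms")
  }
  out <- data.frame(donor = integer(0), hydrogen = integer(0),
                    acceptor = integer(0), distance = numeric(0),
                    angle = numeric(0))
  for (i in seq_len(nrow(donors))) {
    drow <- donors[i, ]
    hyd <- attached_hydrogens(struct, xyz, drow)
    for (j in seq_len(nrow(acceptors))) {
      arow <- acceptors[j, ]
      if (drow$index == arow$index) {
        stop("hydrogen-bond donor and acceptor are the same atom")
      }
      d <- vnorm(xyz[drow$index, ] - xyz[arow$index, ])
      if (d > d_max) next
      if (length(hyd)) {
        angs <- vapply(hyd, function(h) {
          v1 <- xyz[drow$index, ] - xyz[h, ]
          v2 <- xyz[arow$index, ] - xyz[h, ]
          cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
          acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        }, numeric(1L))
        best <- which.max(angs)
        if (angs[best] < angle_min) next
        out <- rbind(out, data.frame(donor = drow$index,
                                     hydrogen = hyd[best],
                                     acceptor = arow$index, distance = d,
                                     angle = angs[best]))
      } else {
        out <- rbind(out, data.frame(donor = drow$index, hydrogen = NA_integer_,
                                     acceptor = arow$index, distance = d,
                                     angle = NA_real_))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Aromatic ring specification
#'
#' Names a ring (e.g. the W84 indole six-membered ring, the Y114 phenol
#' ring, a purine ring of the substrate) by its owner residue selector
#' and member atom names. At least five member atoms are required.
#'
#' @param label ring label, e.g. `"W84-indole"`.
#' @param owner an `AtomSelector` for the owning residue.
#' @param members character vector of member atom names (>= 5).
#' @return object of class `RingSpec`.
#' @export
ring_spec <- function(label, owner, members) {
  if (length(members) < 5L) stop("a ring needs at least 5 member atoms")
  structure(list(label = label, owner = owner, members = members),
            class = "RingSpec")
}

# Resolve a RingSpec in a structure/frame: centroid, unit normal of the
# best-fit plane, and planarity (max |distance to plane|).
resolve_ring <- function(struct, ring, xyz) {
  sel <- ring$owner
  sel$name <- ring$members
  rows <- select_atoms(struct, sel)
  if (nrow(rows) < 5L) {
    stop("ring ", ring$label, " resolves only ", nrow(rows), " atoms (need >= 5)")
  }
  pts <- xyz[rows$index, , drop = FALSE]
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2L, ctr)
  sv <- svd(cen)
  if (sv$d[2L] < 1e-6) {
    stop("degenerate ring ", ring$label, ": member atoms are collinear")
  }
  normal <- sv$v[, 3L]
  planarity <- max(abs(cen %*% normal))
  list(label = ring$label, centroid = ctr, normal = normal,
       planarity = planarity)
}

#' Detect pi-stacking between aromatic rings
#'
#' A ring pair stacks when the centroid distance is at most
#' `centroid_max`, the interplanar angle (between best-fit plane
#' normals, folded to [0, 90] degrees) is at most `plane_angle_max`, and
#' the lateral offset (the centroid-separation component parallel to the
#' mean plane of the two rings) is at most `offset_max`.
#'
#' @param struct a `Structure`.
#' @param rings list of `RingSpec`s.
#' @param centroid_max,plane_angle_max,offset_max cutoffs (Angstrom,
#'   degrees, Angstrom).
#' @param frame optional coordinate matrix.
#' @return data.frame with `ring_i`, `ring_j` (labels),
#'   `centroid_distance`, `plane_angle`, `lateral_offset`.
#' @export
detect_stacking <- function(struct, rings, centroid_max = 4.5,
                            plane_angle_max = 30, offset_max = 2.0,
                            frame = NULL) {
  xyz <- frame_coords(struct, frame)
  res <- lapply(rings, resolve_ring, struct = struct, xyz = xyz)
  out <- data.frame(ring_i = character(0), ring_j = character(0),
                    centroid_distance = numeric(0), plane_angle = numeric(0),
                    lateral_offset = numeric(0))
  if (length(res) < 2L) return(out)
  for (i in seq_len(length(res) - 1L)) {
    for (j in seq(i + 1L, length(res))) {
      sep <- res[[j]]$centroid - res[[i]]$centroid
      d <- vnorm(sep)
      if (d > centroid_max) next
      cosang <- abs(sum(res[[i]]$normal * res[[j]]$normal))
      ang <- acos(pmin(1, cosang)) * 180 / pi
      if (ang > plane_angle_max) next
      # mean-plane normal: average the two normals (sign-aligned)
      n2 <- res[[j]]$normal * sign(sum(res[[i]]$normal * res[[j]]$normal))
      nm <- unit_vector(res[[i]]$normal + n2)
      offset <- vnorm(sep - sum(sep * nm) * nm)
      if (offset > offset_max) next
      out <- rbind(out, data.frame(ring_i = res[[i]]$label,
                                   ring_j = res[[j]]$label,
                                   centroid_distance = d, plane_angle = ang,
                                   lateral_offset = offset))
    }
  }
  rownames(out) <- NULL
  out
}

#' Triple-stack occupancy over a trajectory
#'
#' Tracks the W84:Y114:G and A:Y114:G triple stacks frame by frame. A
#' triple is present in a frame when both of its adjacent ring pairs
#' satisfy the stacking criteria. The verdict is `"stable"` when the
#' W84:Y114:G occupancy reaches `stable_threshold`, otherwise
#' `"unstable/alternative"` with the dominant triple named.
#'
#' @param traj a `Trajectory`.
#' @param ring_w84,ring_y114,ring_g,ring_a `RingSpec`s for the four rings
#'   (`ring_a` may be `NULL` when no adenine ring is present).
#' @param config an `InteractionConfig`.
#' @return list with per-triple occupancies, per-frame flags, the
#'   stability label and the dominant triple.
#' @export
triple_stack_series <- function(traj, ring_w84, ring_y114, ring_g,
                                ring_a = NULL,
                                config = interaction_config()) {
  stopifnot(inherits(traj, "Trajectory"))
  topo <- traj$topology
  check_pair <- function(xyz, r1, r2) {
    nrow(detect_stacking(topo, list(r1, r2),
                         centroid_max = config$stack_centroid_max,
                         plane_angle_max = config$stack_plane_angle_max,
                         offset_max = config$stack_offset_max,
                         frame = xyz)) > 0L
  }
  wyg <- vapply(traj$frames, function(f) {
    check_pair(f, ring_w84, ring_y114) && check_pair(f, ring_y114, ring_g)
  }, logical(1L))
  ayg <- if (is.null(ring_a)) rep(FALSE, length(traj$frames)) else {
    vapply(traj$frames, function(f) {
      check_pair(f, ring_a, ring_y114) && check_pair(f, ring_y114, ring_g)
    }, logical(1L))
  }
  occ_wyg <- mean(wyg)
  occ_ayg <- mean(ayg)
  dominant <- if (occ_ayg > occ_wyg) "A:Y114:G" else "W84:Y114:G"
  label <- if (occ_wyg >= config$stable_threshold) "stable" else "unstable/alternative"
  list(occupancy = c("W84:Y114:G" = occ_wyg, "A:Y114:G" = occ_ayg),
       frames = data.frame(wyg = wyg, ayg = ayg),
       stability = label, dominant = dominant)
}

# Partner label for network records. Contacts from any atom of a 5mC
# methyl group (C5M/C7 carbon and its hydrogens, the names unique to
# 5-methylpyrimidines) collapse onto one "5mC-methyl" partner so that
# network diffs narrate the methyl bridge as a single partner.
partner_label <- function(struct, index,
                          methyl_atoms = c("C5M", "C7", "H51", "H52", "H53",
                                           "H71", "H72", "H73")) {
  a <- struct$atoms[index, ]
  if (a$name %in% methyl_atoms) {
    return("5mC-methyl")
  }
  sprintf("%s%d:%s", a$res_name, a$res_num, a$name)
}

#' Aggregate per-frame detections into an interaction network
#'
#' Runs the hydrogen-bond and vdW detectors (plus optional stacking) on
#' every frame between a protein group and a substrate group, collapses
#' detections into one record per (kind, partner pair), and computes each
#' record's frame occupancy and mean distance over present frames.
#' H-bonds take precedence over vdW for the same atom pair within a
#' frame. Counts include only records at or above the occupancy
#' threshold.
#'
#' @param traj a `Trajectory`.
#' @param protein_sel,substrate_sel `AtomSelector`s for the two groups.
#' @param radii a `VdwRadiusTable`.
#' @param config an `InteractionConfig`.
#' @param rings optional list of `RingSpec`s for stacking records.
#' @param complex_label free-text label, e.g. `"wt:C"`.
#' @return object of class `InteractionNetwork`: `records` (kind,
#'   partner_a, partner_b, occupancy, mean_distance) and `counts`
#'   (`n_vdw`, `n_hbond`, `n_stack`, `n_total`).
#' @export
aggregate_network <- function(traj, protein_sel, substrate_sel,
                              radii = vdw_radius_table(),
                              config = interaction_config(), rings = NULL,
                              complex_label = "") {
  stopifnot(inherits(traj, "Trajectory"))
  topo <- traj$topology
  prot <- select_atoms(topo, protein_sel)
  subs <- select_atoms(topo, substrate_sel)
  nfr <- length(traj$frames)
  seen <- new.env(parent = emptyenv())
  note <- function(kind, la, lb, dist, fr) {
    key <- paste(kind, la, lb, sep = "|")
    rec <- get0(key, envir = seen)
    if (is.null(rec)) {
      rec <- list(kind = kind, partner_a = la, partner_b = lb,
                  present = logical(nfr), dsum = 0, dn = 0L)
    }
    rec$present[fr] <- TRUE
    rec$dsum <- rec$dsum + dist
    rec$dn <- rec$dn + 1L
    assign(key, rec, envir = seen)
  }
  donors_p <- prot[prot$element %in% c("N", "O", "S"), , drop = FALSE]
  donors_s <- subs[subs$element %in% c("N", "O", "S"), , drop = FALSE]
  acc_p <- prot[prot$element %in% c("N", "O"), , drop = FALSE]
  acc_s <- subs[subs$element %in% c("N", "O"), , drop = FALSE]
  for (fr in seq_len(nfr)) {
    xyz <- traj$frames[[fr]]
    hb <- rbind(detect_hbonds(topo, donors_p, acc_s, config$hbond_dmax,
                              config$hbond_angle_min, frame = xyz),
                detect_hbonds(topo, donors_s, acc_p, config$hbond_dmax,
                              config$hbond_angle_min, frame = xyz))
    hb_pairs <- if (nrow(hb)) cbind(hb$donor, hb$acceptor) else NULL
    if (nrow(hb)) {
      for (i in seq_len(nrow(hb))) {
        # orient the record protein-side first
        da <- hb$donor[i] %in% prot$index
        ia <- if (da) hb$donor[i] else hb$acceptor[i]
        ib <- if (da) hb$acceptor[i] else hb$donor[i]
        note("hbond", partner_label(topo, ia), partner_label(topo, ib),
             hb$distance[i], fr)
      }
    }
    vw <- detect_vdw_contacts(topo, prot, subs, radii, config$vdw_tolerance,
                              frame = xyz, exclude_pairs = hb_pairs)
    if (nrow(vw)) {
      for (i in seq_len(nrow(vw))) {
        note("vdw", partner_label(topo, vw$a[i]), partner_label(topo, vw$b[i]),
             vw$distance[i], fr)
      }
    }
    if (!is.null(rings)) {
      st <- detect_stacking(topo, rings, config$stack_centroid_max,
                            config$stack_plane_angle_max,
                            config$stack_offset_max, frame = xyz)
      if (nrow(st)) {
        for (i in seq_len(nrow(st))) {
          note("stack", st$ring_i[i], st$ring_j[i], st$centroid_distance[i], fr)
        }
      }
    }
  }
  keys <- sort(ls(envir = seen))
  records <- do.call(rbind, lapply(keys, function(k) {
    rec <- get(k, envir = seen)
    data.frame(kind = rec$kind, partner_a = rec$partner_a,
               partner_b = rec$partner_b, occupancy = mean(rec$present),
               mean_distance = rec$dsum / rec$dn, stringsAsFactors = FALSE)
  }))
  if (is.null(records)) {
    records <- data.frame(kind = character(0), partner_a = character(0),
                          partner_b = character(0), occupancy = numeric(0),
                          mean_distance = numeric(0))
  }
  above <- records[records$occupancy >= config$occupancy_threshold, , drop = FALSE]
  counts <- c(n_vdw = sum(above$kind == "vdw"),
              n_hbond = sum(above$kind == "hbond"),
              n_stack = sum(above$kind == "stack"))
  counts <- c(counts, n_total = sum(counts))
  structure(list(complex_label = complex_label, records = records,
                 counts = counts, config = config),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork %s: %d vdW + %d H-bond + %d stack = %d\n",
              x$complex_label, x$counts["n_vdw"], x$counts["n_hbond"],
              x$counts["n_stack"], x$counts["n_total"]))
  invisible(x)
}

network_keys <- function(net, threshold = NULL) {
  threshold <- threshold %||% net$config$occupancy_threshold
  r <- net$records[net$records$occupancy >= threshold, , drop = FALSE]
  sort(paste(r$kind, r$partner_a, r$partner_b, sep = "|"))
}

#' Difference between two interaction networks
#'
#' Set differences on record keys `(kind, partner_a, partner_b)` at each
#' network's occupancy threshold: records `gained` by `net_b`, `lost`
#' from `net_a`, and `shared`. Deterministic key ordering.
#'
#' @param net_a,net_b `InteractionNetwork`s over comparable labelings.
#' @return list with character vectors `gained`, `lost`, `shared`.
#' @export
network_diff <- function(net_a, net_b) {
  ka <- network_keys(net_a)
  kb <- network_keys(net_b)
  list(gained = setdiff(kb, ka), lost = setdiff(ka, kb),
       shared = intersect(ka, kb))
}

#' Write an interaction network to TSV (records) and JSON (counts)
#'
#' @param net an `InteractionNetwork`.
#' @param tsv_path path of the record table (kind, partner_a, partner_b,
#'   occupancy, mean_distance).
#' @param json_path optional path for the counts + config echo.
#' @return `tsv_path`, invisibly.
#' @export
write_network <- function(net, tsv_path, json_path = NULL) {
  utils::write.table(net$records, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(complex_label = net$complex_label,
                              counts = as.list(net$counts),
                              config = unclass(net$config)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
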