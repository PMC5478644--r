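# Substrate ring geometry: idealized pyrimidine coordinates, van der Waals
# radii, ring breadths and the steric fit verdict against the pocket gate.

#' Bondi van der Waals radius table
#'
#' Radii in Angstrom (Bondi 1964 set). Individual elements can be
#' overridden; all radii must stay in (0.5, 3.0) Angstrom. The table also
#' carries the documented hydration constants `water_bulk_min` (2.8) and
#' `water_bulk_max` (3.2): the steric bulk, in Angstrom, that a single
#' bound water molecule adds to a hydrophilic group such as the 5hmC
#' hydroxyl.
#'
#' @param override named numeric vector of element -> radius overrides.
#' @return object of class `VdwRadiusTable`.
#' @export
vdw_radius_table <- function(override = NULL) {
  radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
             F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Se = 1.90,
             Zn = 1.39, Mg = 1.73, Na = 2.27)
  if (!is.null(override)) {
    stopifnot(is.numeric(override), !is.null(names(override)))
    radii[names(override)] <- override
  }
  if (any(radii <= 0.5 | radii >= 3.0)) {
    stop("vdW radii must lie in (0.5, 3.0) Angstrom")
  }
  structure(list(radii = radii, water_bulk_min = 2.8, water_bulk_max = 3.2),
            class = "VdwRadiusTable")
}

#' Look up van der Waals radii for elements
#' @param table a `VdwRadiusTable`.
#' @param element character vector of element symbols.
#' @return numeric radii in Angstrom.
#' @export
vdw_radius <- function(table, element) {
  stopifnot(inherits(table, "VdwRadiusTable"))
  el <- paste0(toupper(substr(element, 1L, 1L)),
               tolower(substr(element, 2L, 10L)))
  r <- table$radii[el]
  if (any(is.na(r))) {
    stop("no vdW radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

# Idealized cytosine frame: standard planar base reference coordinates
# (z = 0), Angstrom. C1' is the glycosidic sugar carbon; exocyclic
# substituents are placed from standard bond lengths along the external
# bisector at the ring atom.
cytosine_ring_frame <- function() {
  rbind(
    "C1'" = c(-2.477, 5.402, 0),
    N1  = c(-1.285, 4.542, 0),
    C2  = c(-1.472, 3.158, 0),
    O2  = c(-2.628, 2.709, 0),
    N3  = c(-0.391, 2.344, 0),
    C4  = c( 0.837, 2.868, 0),
    N4  = c( 1.875, 2.027, 0),
    C5  = c( 1.056, 4.275, 0),
    C6  = c(-0.023, 5.068, 0))
}

# Direction of the exocyclic substituent at ring atom `at`: opposite the
# sum of the unit vectors toward its two ring neighbours (in-plane).
exocyclic_dir <- function(ring, at, nb1, nb2) {
  unit_vector(-(unit_vector(ring[nb1, ] - ring[at, ]) +
                  unit_vector(ring[nb2, ] - ring[at, ])))
}

#' Idealized substrate ring geometry
#'
#' Builds the idealized planar geometry of deoxycytidine (`"C"`),
#' 5-methyl-deoxycytidine (`"5mC"`) or 5-hydroxymethyl-deoxycytidine
#' (`"5hmC"`) in a standard base reference frame (ring in the z = 0
#' plane). The depth axis is the C1' -> C4 direction (the ring enters the
#' catalytic pocket C4-first, toward the zinc); the breadth axis is the
#' in-plane direction perpendicular to it. For 5hmC the hydroxymethyl
#' oxygen is rotatable about the C5-CH2 bond and is scanned on a dihedral
#' grid by [ring_breadth()].
#'
#' Bond lengths: C5-CH3/CH2 1.496, C-H 1.08, N-H 1.01, CH2-OH 1.43
#' Angstrom; tetrahedral angle at the hydroxymethyl carbon.
#'
#' @param base_kind one of `"C"`, `"5mC"`, `"5hmC"`.
#' @param dihedral_step grid step in degrees for the 5hmC hydroxymethyl
#'   dihedral scan (default 10).
#' @return object of class `SubstrateRingGeometry` with the atom table
#'   (name, element, side, rotatable flag, coordinates), `depth_axis`,
#'   `breadth_axis` and the dihedral grid.
#' @export
substrate_ring_geometry <- function(base_kind = c("C", "5mC", "5hmC"),
                                    dihedral_step = 10) {
  base_kind <- match.arg(base_kind)
  ring <- cytosine_ring_frame()
  h6 <- ring["C6", ] + 1.08 * exocyclic_dir(ring, "C6", "N1", "C5")
  amine_dir <- unit_vector(ring["N4", ] - ring["C4", ])
  rot2d <- function(v, th) c(v[1L] * cos(th) - v[2L] * sin(th),
                             v[1L] * sin(th) + v[2L] * cos(th), 0)
  h41 <- ring["N4", ] + 1.01 * rot2d(amine_dir, pi / 3)
  h42 <- ring["N4", ] + 1.01 * rot2d(amine_dir, -pi / 3)
  c5dir <- exocyclic_dir(ring, "C5", "C4", "C6")

  atom <- function(name, element, xyz, side, rotatable = FALSE) {
    data.frame(name = name, element = element, side = side,
               rotatable = rotatable, x = xyz[1L], y = xyz[2L], z = xyz[3L],
               stringsAsFactors = FALSE)
  }
  common <- rbind(
    atom("N1", "N", ring["N1", ], "ring"),
    atom("C2", "C", ring["C2", ], "ring"),
    atom("O2", "O", ring["O2", ], "carbonyl"),
    atom("N3", "N", ring["N3", ], "ring"),
    atom("C4", "C", ring["C4", ], "ring"),
    atom("N4", "N", ring["N4", ], "ring"),
    atom("H41", "H", h41, "ring"),
    atom("H42", "H", h42, "ring"),
    atom("C5", "C", ring["C5", ], "ring"),
    atom("C6", "C", ring["C6", ], "ring"),
    atom("H6", "H", h6, "subst"))

  cm <- ring["C5", ] + 1.496 * c5dir
  atoms <- switch(
    base_kind,
    "C" = rbind(common, atom("H5", "H", ring["C5", ] + 1.08 * c5dir, "subst")),
    "5mC" = {
      hs <- methyl_hydrogens(cm, ring["C5", ], in_plane_anti = TRUE)
      rbind(common, atom("C5M", "C", cm, "subst"),
            atom("H51", "H", hs[1L, ], "subst_h"),
            atom("H52", "H", hs[2L, ], "subst_h"),
            atom("H53", "H", hs[3L, ], "subst_h"))
    },
    "5hmC" = {
      o5 <- hydroxymethyl_oxygen(cm, ring["C5", ], phi = pi)
      rbind(common, atom("C5M", "C", cm, "subst"),
            atom("O5M", "O", o5, "subst", rotatable = TRUE))
    })
  rownames(atoms) <- NULL

  depth_axis <- unit_vector(ring["C4", ] - ring["C1'", ])
  breadth_axis <- unit_vector(c(-depth_axis[2L], depth_axis[1L], 0))
  grid <- if (base_kind == "5hmC") seq(0, 360 - dihedral_step,
                                       by = dihedral_step) else numeric(0)
  structure(list(base_kind = base_kind, atoms = atoms,
                 anchor = ring["C1'", ], c5 = ring["C5", ], c5m = cm,
                 depth_axis = depth_axis, breadth_axis = breadth_axis,
                 rotatable = base_kind == "5hmC", dihedral_grid = grid),
            class = "SubstrateRingGeometry")
}

# Three methyl hydrogens around the C5->CM axis (C-H 1.09, tetrahedral);
# with in_plane_anti one hydrogen lies in the base plane pointing away
# from the ring.
methyl_hydrogens <- function(cm, c5, in_plane_anti = TRUE) {
  u <- unit_vector(cm - c5)
  v <- unit_vector(c(-u[2L], u[1L], 0))
  w <- c(0, 0, 1)
  ang <- (180 - 109.47) * pi / 180
  phis <- if (in_plane_anti) c(pi, pi / 3, -pi / 3) else c(0, 2, 4) * pi / 3
  t(vapply(phis, function(phi) {
    d <- cos(ang) * u + sin(ang) * (cos(phi) * v + sin(phi) * w)
    cm + 1.09 * d
  }, numeric(3L)))
}

# Hydroxymethyl oxygen for dihedral phi about the C5->CM axis
# (C-O 1.43, tetrahedral angle at CM). phi = pi is the in-plane
# outward-pointing rotamer.
hydroxymethyl_oxygen <- function(cm, c5, phi) {
  u <- unit_vector(cm - c5)
  v <- unit_vector(c(-u[2L], u[1L], 0))
  w <- c(0, 0, 1)
  ang <- (180 - 109.47) * pi / 180
  cm + 1.43 * (cos(ang) * u + sin(ang) * (cos(phi) * v + sin(phi) * w))
}

# Lateral vdW span of one configuration: largest in-plane-projected
# distance between a carbonyl-side atom and a C5/C6-side atom, plus both
# radii. Projection onto the base plane keeps out-of-plane rotamer atoms
# from inflating the lateral width.
lateral_span <- function(atoms, radii, include_subst_h = FALSE) {
  keep <- atoms$side != "subst_h" | include_subst_h
  atoms <- atoms[keep, , drop = FALSE]
  a <- atoms[atoms$side == "carbonyl", , drop = FALSE]
  b <- atoms[atoms$side %in% c("subst", "subst_h"), , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("geometry error: missing carbonyl or substituent atoms")
  }
  best <- -Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
      span <- d + vdw_radius(radii, a$element[i]) + vdw_radius(radii, b$element[j])
      if (span > best) best <- span
    }
  }
  best
}

#' Ring breadth including van der Waals radii
#'
#' The breadth of the heterocyclic ring is its lateral vdW-to-vdW span:
#' the distance, projected into the base plane, between the C2-carbonyl
#' (O2) surface on one flank and the C5-substituent surface on the other,
#' including both atoms' van der Waals radii and maximized over the atoms
#' of each flank. This is the widest cross-section that must pass the
#' pocket gate (the residue-51 to P86 distance). For 5hmC the
#' hydroxymethyl dihedral is scanned on the geometry's grid and the
#' breadth is reported as a `[min, max]` range; the headline values use
#' heavy-atom extremes (methyl/hydroxymethyl hydrogens excluded), and the
#' hydrogen-inclusive value is reported alongside.
#'
#' @param geom a `SubstrateRingGeometry`.
#' @param radii a `VdwRadiusTable` (default Bondi).
#' @param include_substituent_hydrogens include methyl/hydroxymethyl
#'   hydrogens in the extremes (default `FALSE`, heavy-atom headline).
#' @return for non-rotatable bases a single breadth in Angstrom; for 5hmC
#'   a named numeric `c(min=, max=)` over the dihedral grid. The value
#'   carries attribute `"per_dihedral"` for rotatable bases.
#' @export
ring_breadth <- function(geom, radii = vdw_radius_table(),
                         include_substituent_hydrogens = FALSE) {
  stopifnot(inherits(geom, "SubstrateRingGeometry"))
  if (!geom$rotatable) {
    return(lateral_span(geom$atoms, radii, include_substituent_hydrogens))
  }
  vals <- vapply(geom$dihedral_grid, function(phi_deg) {
    at <- geom$atoms
    rot <- at$rotatable
    o5 <- hydroxymethyl_oxygen(geom$c5m, geom$c5, phi_deg * pi / 180)
    at$x[rot] <- o5[1L]; at$y[rot] <- o5[2L]; at$z[rot] <- o5[3L]
    lateral_span(at, radii, include_substituent_hydrogens)
  }, numeric(1L))
  out <- c(min = min(vals), max = max(vals))
  attr(out, "per_dihedral") <- data.frame(dihedral = geom$dihedral_grid,
                                          breadth = vals)
  out
}

#' Steric fit verdict of a ring breadth against the pocket gate
#'
#' Compares a substrate ring breadth (or breadth range, in which case the
#' maximum is used) with the pocket gate distance series (the residue 51
#' to P86 distance, which sets the breadth of a ring that can enter the
#' pocket). `hydration_bulk` adds the steric bulk of bound water to the
#' breadth before comparison: a single water molecule adds about 2.8-3.2
#' Angstrom, the documented constants of [vdw_radius_table()].
#'
#' @param breadth breadth in Angstrom, or a `[min, max]` range.
#' @param gate_series a `DistanceSeries` for the gate distance.
#' @param hydration_bulk extra bulk in Angstrom added to the breadth
#'   (default 0).
#' @return list with `fits_at_min`, `fits_at_mean` (logicals) and
#'   `clearance` (Angstrom, gate minimum minus effective breadth; may be
#'   negative).
#' @export
fit_assessment <- function(breadth, gate_series, hydration_bulk = 0) {
  stopifnot(inherits(gate_series, "DistanceSeries"))
  b <- max(breadth) + hydration_bulk
  list(fits_at_min = b <= gate_series$min,
       fits_at_mean = b <= gate_series$mean,
       clearance = gate_series$min - b)
}
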