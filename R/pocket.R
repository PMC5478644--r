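# Catalytic-pocket size analysis: the four atom-pair distances that define
# the pocket, measured over every trajectory frame.
#
# The pocket of the AID catalytic site is sized by four heavy-atom
# distances: residue 51 (ND2 of N51, or CB of A51 in the N51A mutant) to
# Y114 CE2, to P86 CB and to C87 SG, plus Y114 CE2 to H56 CE1 (the pocket
# height). The residue-51 to P86 distance is the gate: it sets the breadth
# of a heterocyclic ring that can enter.

#' Pocket definition
#'
#' The four labeled atom pairs whose distances define the catalytic
#' pocket size. Residue numbers follow the wild-type enzyme numbering;
#' `variant` switches the residue-51 probe atom between ND2 (asparagine)
#' and CB (the alanine mutant).
#'
#' @param variant `"wt"` or `"N51A"`.
#' @param chain chain identifier of the protein (default `"A"`).
#' @param res51,res_y114,res_p86,res_c87,res_h56 residue numbers, should
#'   renumbered structures be analyzed.
#' @return object of class `PocketDefinition`: a list of four labeled
#'   selector pairs (`d1` 51-Y114, `d2` 51-P86 (the gate), `d3` 51-C87,
#'   `d4` Y114-H56).
#' @export
pocket_definition <- function(variant = c("wt", "N51A"), chain = "A",
                              res51 = 51, res_y114 = 114, res_p86 = 86,
                              res_c87 = 87, res_h56 = 56) {
  variant <- match.arg(variant)
  a51 <- atom_selector(chain = chain, res_num = res51,
                       name = if (variant == "wt") "ND2" else "CB")
  y114 <- atom_selector(chain = chain, res_num = res_y114, name = "CE2")
  pairs <- list(
    d1 = list(a = a51, b = y114),
    d2 = list(a = a51,
              b = atom_selector(chain = chain, res_num = res_p86, name = "CB")),
    d3 = list(a = a51,
              b = atom_selector(chain = chain, res_num = res_c87, name = "SG")),
    d4 = list(a = y114,
              b = atom_selector(chain = chain, res_num = res_h56, name = "CE1")))
  structure(list(pairs = pairs, variant = variant), class = "PocketDefinition")
}

#' Euclidean distance between two atoms in a coordinate frame
#'
#' @param frame n x 3 coordinate matrix (one trajectory frame).
#' @param a,b atom row indices into `frame`; must differ.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(frame, a, b) {
  if (a == b) stop("atom_distance: the same atom was passed twice")
  vnorm(frame[a, ] - frame[b, ])
}

new_distance_series <- function(label, values) {
  stopifnot(all(values > 0))
  structure(list(label = label, values = values, mean = mean(values),
                 min = min(values), max = max(values)),
            class = "DistanceSeries")
}

#' @export
print.DistanceSeries <- function(x, ...) {
  cat(sprintf("DistanceSeries %s: n=%d mean=%.2f range=[%.2f, %.2f] A\n",
              x$label, length(x$values), x$mean, x$min, x$max))
  invisible(x)
}

#' Per-frame pocket distance series
#'
#' Measures the four pocket-defining distances in every frame of a
#' trajectory and reports, per pair, the full series together with its
#' mean, minimum and maximum — the statistics used to compare pocket
#' sizes across enzyme variants.
#'
#' @param traj a `Trajectory`.
#' @param pocket a `PocketDefinition`.
#' @return named list of four `DistanceSeries` (`d1`..`d4`).
#' @export
pocket_distance_series <- function(traj, pocket) {
  stopifnot(inherits(traj, "Trajectory"), inherits(pocket, "PocketDefinition"))
  idx <- lapply(names(pocket$pairs), function(lbl) {
    pr <- pocket$pairs[[lbl]]
    c(resolve_one(traj$topology, pr$a, paste0(lbl, " (first atom)"))$index,
      resolve_one(traj$topology, pr$b, paste0(lbl, " (second atom)"))$index)
  })
  names(idx) <- names(pocket$pairs)
  out <- lapply(names(idx), function(lbl) {
    ij <- idx[[lbl]]
    vals <- vapply(traj$frames, function(f) atom_distance(f, ij[1L], ij[2L]),
                   numeric(1L))
    new_distance_series(lbl, vals)
  })
  names(out) <- names(idx)
  out
}

#' Export distance series to TSV
#'
#' Writes one row per frame with columns `frame`, `d1`..`d4` (Angstrom).
#'
#' @param series named list of `DistanceSeries` as returned by
#'   [pocket_distance_series()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_distance_series <- function(series, path) {
  df <- data.frame(frame = seq_along(series[[1L]]$values))
  for (nm in names(series)) df[[nm]] <- series[[nm]]$values
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
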