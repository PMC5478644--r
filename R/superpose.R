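# Least-squares rigid superposition (Kabsch, via SVD) and RMSD, global and
# per-segment. Used for model-vs-crystal comparison and for the pairwise
# RMSD matrices that feed conformational clustering.

# Match atoms of two structures by (res_num, name) within a selection,
# after applying an optional residue-number offset to the mobile
# structure (crystal constructs are frequently renumbered).
match_atoms <- function(mobile, target, sel = NULL, offset = 0L) {
  ma <- select_atoms(mobile, sel)
  ta <- select_atoms(target, sel)
  mkey <- paste(ma$res_num + offset, ma$name)
  tkey <- paste(ta$res_num, ta$name)
  common <- intersect(mkey, tkey)
  unmatched <- c(setdiff(mkey, tkey), setdiff(tkey, mkey))
  if (length(unmatched) && length(common) == 0L) {
    stop("pairing error: no atoms matched; unmatched keys: ",
         paste(utils::head(unmatched, 10L), collapse = ", "))
  }
  mi <- ma$index[match(common, mkey)]
  ti <- ta$index[match(common, tkey)]
  list(mobile = mi, target = ti, unmatched = unmatched)
}

# Kabsch: optimal proper rotation + translation minimizing the RMSD of
# xyz_m onto xyz_t (paired rows).
kabsch <- function(xyz_m, xyz_t) {
  cm <- colMeans(xyz_m)
  ct <- colMeans(xyz_t)
  a <- sweep(xyz_m, 2L, cm)
  b <- sweep(xyz_t, 2L, ct)
  h <- crossprod(a, b)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- ct - as.numeric(rot %*% cm)
  fitted <- t(rot %*% t(xyz_m)) + matrix(trans, nrow(xyz_m), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - xyz_t)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd, fitted = fitted)
}

#' Superpose one structure onto another
#'
#' Least-squares optimal rigid-body superposition (proper rotation,
#' determinant +1) of `mobile` onto `target` over a selection, atoms
#' matched by `(res_num, name)`. The default protein comparison set is
#' C-alpha only; pass `sel = NULL` with care on heterogeneous structures.
#'
#' @param mobile,target `Structure` objects.
#' @param sel an `AtomSelector` restricting the superposition set
#'   (default: C-alpha atoms).
#' @param offset residue-number offset added to `mobile` numbering before
#'   matching (for renumbered constructs).
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom over the superposition set), `matched` (atom index pairs)
#'   and `fitted_mobile` (the transformed full mobile `Structure`).
#' @export
superpose <- function(mobile, target, sel = atom_selector(name = "CA"),
                      offset = 0L) {
  stopifnot(inherits(mobile, "Structure"), inherits(target, "Structure"))
  mm <- match_atoms(mobile, target, sel, offset)
  if (length(mm$unmatched)) {
    stop("pairing error: unmatched atoms in superposition set: ",
         paste(utils::head(mm$unmatched, 10L), collapse = ", "))
  }
  if (length(mm$mobile) < 3L) {
    stop("underdetermined superposition: fewer than 3 matched atoms")
  }
  xm <- coords(mobile)[mm$mobile, , drop = FALSE]
  xt <- coords(target)[mm$target, , drop = FALSE]
  k <- kabsch(xm, xt)
  all_fitted <- t(k$rotation %*% t(coords(mobile))) +
    matrix(k$translation, n_atoms(mobile), 3L, byrow = TRUE)
  list(rotation = k$rotation, translation = k$translation, rmsd = k$rmsd,
       matched = mm, fitted_mobile = set_coords(mobile, all_fitted))
}

#' RMSD of a segment after a global superposition
#'
#' Superposes `mobile` onto `target` over `superpose_sel` and measures
#' the RMSD over `segment_sel` atoms only — the loop-segment comparison
#' used to judge local model accuracy after a global fit.
#'
#' @param mobile,target `Structure` objects.
#' @param superpose_sel selector for the global superposition set.
#' @param segment_sel selector for the measured segment.
#' @param offset residue-number offset for `mobile` (see [superpose()]).
#' @return segment RMSD in Angstrom.
#' @export
segment_rmsd <- function(mobile, target, superpose_sel = atom_selector(name = "CA"),
                         segment_sel, offset = 0L) {
  sp <- superpose(mobile, target, superpose_sel, offset)
  seg <- match_atoms(sp$fitted_mobile, target, segment_sel, offset)
  if (length(seg$mobile) == 0L) stop("selection error: empty segment")
  if (length(seg$unmatched)) {
    stop("pairing error: unmatched segment atoms: ",
         paste(utils::head(seg$unmatched, 10L), collapse = ", "))
  }
  xm <- coords(sp$fitted_mobile)[seg$mobile, , drop = FALSE]
  xt <- coords(target)[seg$target, , drop = FALSE]
  sqrt(mean(rowSums((xm - xt)^2)))
}
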