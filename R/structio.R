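# Structure and trajectory containers plus fixed-column PDB input/output.
#
# A Structure holds an ordered atom table (one row per ATOM/HETATM record);
# a Trajectory couples one topology Structure with per-frame coordinate
# matrices, the carrier for MD frames exchanged as multi-model PDB.

#' Construct a Structure
#'
#' A `Structure` is an ordered atom table plus a free-text title. Atom
#' coordinates are in Angstrom, residue numbering is 1-based as in PDB
#' files, and nucleotide atom names use the PDB prime convention
#' (e.g. `"C1'"`).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_num`, `chain`, `x`, `y`, `z`.
#' @param title free-text title.
#' @return object of class `Structure`.
#' @export
Structure <- function(atoms, title = "") {
  required <- c("serial", "name", "element", "res_name", "res_num",
                "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[required]
  atoms$name <- trimws(as.character(atoms$name))
  atoms$res_name <- trimws(as.character(atoms$res_name))
  atoms$element <- as.character(atoms$element)
  atoms$chain <- as.character(atoms$chain)
  atoms$serial <- as.integer(atoms$serial)
  atoms$res_num <- as.integer(atoms$res_num)
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$res_num < 1L)) stop("res_num must be >= 1")
  if (any(nchar(atoms$name) == 0L)) stop("empty atom name")
  if (anyDuplicated(atoms$serial)) stop("atom serials are not unique")
  key <- paste(atoms$chain, atoms$res_num, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, res_num, name) triple: ", key[duplicated(key)][1L])
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$res_num))), "residues\n")
  invisible(x)
}

#' Number of atoms in a Structure or Trajectory topology
#' @param x a `Structure` or `Trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Coordinates of a Structure as an n x 3 matrix
#' @param x a `Structure`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "Structure"))
  as.matrix(x$atoms[c("x", "y", "z")])
}

#' Replace the coordinates of a Structure
#' @param x a `Structure`.
#' @param xyz n x 3 numeric matrix.
#' @return the modified `Structure`.
#' @export
set_coords <- function(x, xyz) {
  stopifnot(inherits(x, "Structure"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(x$atoms) || ncol(xyz) != 3L) {
    stop("coordinate matrix must be ", nrow(x$atoms), " x 3")
  }
  x$atoms$x <- xyz[, 1L]
  x$atoms$y <- xyz[, 2L]
  x$atoms$z <- xyz[, 3L]
  x
}

#' Construct a Trajectory
#'
#' @param topology a `Structure` giving atom identities (frame 1 coordinates).
#' @param frames list of n_atoms x 3 coordinate matrices, one per frame.
#' @return object of class `Trajectory`.
#' @export
Trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "Structure"))
  if (length(frames) < 1L) stop("a trajectory needs at least one frame")
  na <- nrow(topology$atoms)
  frames <- lapply(seq_along(frames), function(i) {
    f <- as.matrix(frames[[i]])
    if (nrow(f) != na || ncol(f) != 3L) {
      stop("frame ", i, " has ", nrow(f), " atoms; topology has ", na)
    }
    dimnames(f) <- NULL
    f
  })
  structure(list(topology = topology, frames = frames), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames x",
      nrow(x$topology$atoms), "atoms\n")
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  length(traj$frames)
}

# Element inference from a PDB atom name when columns 77-78 are blank.
# Digits and primes are stripped; two-letter metals/halogens that appear
# as full names (ZN, MG, ...) are recognized before the one-letter fallback.
infer_element <- function(name) {
  nm <- toupper(gsub("['0-9*]", "", trimws(name)))
  two <- c("ZN", "MG", "FE", "CL", "BR", "NA", "MN", "CA", "SE", "CU")
  if (nm %in% two) {
    return(paste0(substr(nm, 1L, 1L), tolower(substr(nm, 2L, 2L))))
  }
  substr(nm, 1L, 1L)
}

parse_pdb_atom_line <- function(line, lineno) {
  if (nchar(line) < 54L) {
    stop("malformed ATOM/HETATM record at line ", lineno,
         ": fewer than 54 columns")
  }
  icode <- substr(line, 27L, 27L)
  if (icode != " " && icode != "") {
    stop("insertion code '", icode, "' at line ", lineno,
         " is not supported")
  }
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(line, from, to)))
    if (is.na(v)) {
      stop("malformed ", what, " field at line ", lineno, ": '",
           substr(line, from, to), "'")
    }
    v
  }
  occ <- suppressWarnings(as.numeric(substr(line, 55L, 60L)))
  elem <- trimws(substr(line, 77L, 78L))
  name <- trimws(substr(line, 13L, 16L))
  list(
    serial = as.integer(num(7L, 11L, "serial")),
    name = name,
    altloc = substr(line, 17L, 17L),
    res_name = trimws(substr(line, 18L, 20L)),
    chain = substr(line, 22L, 22L),
    res_num = as.integer(num(23L, 26L, "residue number")),
    x = num(31L, 38L, "x"),
    y = num(39L, 46L, "y"),
    z = num(47L, 54L, "z"),
    occupancy = if (is.na(occ)) 1.0 else occ,
    element = if (nzchar(elem)) elem else infer_element(name)
  )
}

# Parse the ATOM/HETATM records of one MODEL block into an atom data.frame,
# applying the altloc rule: keep highest occupancy, first on tie.
parse_model_atoms <- function(lines, linenos) {
  recs <- mapply(parse_pdb_atom_line, lines, linenos, SIMPLIFY = FALSE)
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(serial = r$serial, name = r$name, altloc = r$altloc,
               element = r$element, res_name = r$res_name,
               res_num = r$res_num, chain = r$chain,
               x = r$x, y = r$y, z = r$z, occupancy = r$occupancy,
               stringsAsFactors = FALSE)
  }))
  key <- paste(df$chain, df$res_num, df$res_name, df$name)
  if (anyDuplicated(key)) {
    keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
      idx[which.max(df$occupancy[idx])]
    }), use.names = FALSE)
    df <- df[sort(keep), , drop = FALSE]
  }
  df$altloc <- NULL
  df$occupancy <- NULL
  df
}

split_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^ATOM", lines) | grepl("^HETATM", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    return(list(list(lines = lines[is_atom], linenos = which(is_atom))))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) < length(model_starts)) {
    model_ends <- c(model_ends, length(lines))
  }
  lapply(seq_along(model_starts), function(i) {
    span <- seq(model_starts[i], model_ends[i])
    sel <- span[is_atom[span]]
    list(lines = lines[sel], linenos = sel)
  })
}

#' Read a Structure from a PDB file
#'
#' Parses `ATOM`/`HETATM` records from the fixed PDB columns. For
#' multi-model files only `MODEL 1` is read (use [read_trajectory()] for
#' all models). Alternate locations keep the highest-occupancy copy
#' (first on tie); insertion codes are rejected; hydrogens are kept.
#'
#' @param path path to a PDB file.
#' @return a `Structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  models <- split_pdb_models(path)
  m1 <- models[[1L]]
  if (length(m1$lines) == 0L) stop("empty structure: no ATOM/HETATM records in ", path)
  atoms <- parse_model_atoms(m1$lines, m1$linenos)
  st <- Structure(atoms, title = basename(path))
  message("read_pdb: ", nrow(st$atoms), " atoms from ", path)
  st
}

#' Read a Trajectory from a multi-model PDB file
#'
#' Every `MODEL` block must contain the same atoms in the same order;
#' `MODEL 1` provides the topology and each model contributes one frame.
#'
#' @param path path to a multi-model PDB file.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  models <- split_pdb_models(path)
  tables <- lapply(models, function(m) parse_model_atoms(m$lines, m$linenos))
  if (nrow(tables[[1L]]) == 0L) stop("empty structure: no ATOM/HETATM records in ", path)
  n0 <- nrow(tables[[1L]])
  for (i in seq_along(tables)) {
    if (nrow(tables[[i]]) != n0) {
      stop("trajectory inconsistency: model ", i, " has ", nrow(tables[[i]]),
           " atoms but model 1 has ", n0)
    }
  }
  topo <- Structure(tables[[1L]], title = basename(path))
  frames <- lapply(tables, function(tb) as.matrix(tb[c("x", "y", "z")]))
  message("read_trajectory: ", length(frames), " frames x ", n0,
          " atoms from ", path)
  Trajectory(topo, frames)
}

format_pdb_atom_line <- function(a, xyz) {
  rec <- if (toupper(a$element) %in% c("ZN", "MG", "FE", "CL", "NA", "MN")) {
    "HETATM"
  } else {
    "ATOM  "
  }
  # name placement: 1-3 char names start in column 14
  nm <- a$name
  nm_field <- if (nchar(nm) >= 4L) substr(nm, 1L, 4L) else paste0(" ", nm)
  el <- a$element
  sprintf("%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000L, nm_field, substr(a$res_name, 1L, 3L),
          a$chain, a$res_num, xyz[1L], xyz[2L], xyz[3L], 1.0, 0.0,
          toupper(substr(el, 1L, 2L)))
}

#' Write a Structure to a PDB file
#' @param x a `Structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "Structure"))
  xyz <- coords(x)
  lines <- vapply(seq_len(nrow(x$atoms)), function(i) {
    format_pdb_atom_line(as.list(x$atoms[i, ]), xyz[i, ])
  }, character(1L))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a Trajectory to a multi-model PDB file
#' @param traj a `Trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  at <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$frames[[f]]
    lines <- vapply(seq_len(nrow(at)), function(i) {
      format_pdb_atom_line(as.list(at[i, ]), xyz[i, ])
    }, character(1L))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Atom selector
#'
#' Matches atoms on any combination of chain, residue number, residue name
#' and atom name. At least one field must be set.
#'
#' @param chain,res_num,res_name,name optional match values (vectors allowed).
#' @return object of class `AtomSelector`.
#' @export
atom_selector <- function(chain = NULL, res_num = NULL, res_name = NULL,
                          name = NULL) {
  if (is.null(chain) && is.null(res_num) && is.null(res_name) &&
      is.null(name)) {
    stop("atom_selector: at least one field must be set")
  }
  structure(list(chain = chain, res_num = res_num, res_name = res_name,
                 name = name), class = "AtomSelector")
}

selector_mask <- function(atoms, sel) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(sel$chain)) keep <- keep & atoms$chain %in% sel$chain
  if (!is.null(sel$res_num)) keep <- keep & atoms$res_num %in% sel$res_num
  if (!is.null(sel$res_name)) keep <- keep & atoms$res_name %in% sel$res_name
  if (!is.null(sel$name)) keep <- keep & atoms$name %in% sel$name
  keep
}

#' Select atoms from a Structure
#'
#' @param x a `Structure`.
#' @param sel an `AtomSelector`, or `NULL` to keep every atom.
#' @return data.frame of matching atom rows, in input order, with an
#'   `index` column giving each atom's row position in `x`. An empty
#'   result is valid.
#' @export
select_atoms <- function(x, sel = NULL) {
  stopifnot(inherits(x, "Structure"))
  atoms <- x$atoms
  idx <- if (is.null(sel)) seq_len(nrow(atoms)) else which(selector_mask(atoms, sel))
  out <- atoms[idx, , drop = FALSE]
  out$index <- idx
  rownames(out) <- NULL
  out
}

# Resolve a selector to exactly one atom row; `label` names the selection
# in error messages (e.g. a pocket pair label).
resolve_one <- function(x, sel, label = "selection") {
  hit <- select_atoms(x, sel)
  if (nrow(hit) != 1L) {
    stop("selection error for ", label, ": matched ", nrow(hit),
         " atoms (need exactly 1)")
  }
  hit
}
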