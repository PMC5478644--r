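# Shared fixture builders and independent oracles. Oracles here are
# deliberately written with different algorithms/code paths than the
# package functions they check.

# Minimal structure from a coordinate matrix; one CA atom per residue
# unless names/elements given.
tiny_structure <- function(xyz, name = "CA", element = "C",
                           res_name = "GLY", chain = "A",
                           res_num = seq_len(nrow(xyz))) {
  xyz <- as.matrix(xyz)
  Structure(data.frame(
    serial = seq_len(nrow(xyz)),
    name = rep_len(name, nrow(xyz)),
    element = rep_len(element, nrow(xyz)),
    res_name = rep_len(res_name, nrow(xyz)),
    res_num = res_num,
    chain = rep_len(chain, nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

random_structure <- function(n, seed, spread = 10, element = "C") {
  set.seed(seed)
  tiny_structure(matrix(runif(n * 3, 0, spread), n, 3), element = element)
}

# A synthetic 10-residue helix used for PDB round-trip tests.
helix_structure <- function() {
  t_ <- seq(0, 3 * pi, length.out = 10)
  tiny_structure(cbind(2.3 * cos(t_), 2.3 * sin(t_), 1.5 * t_),
                 res_name = "ALA")
}

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(xyz, rot, trans) {
  t(rot %*% t(xyz)) + matrix(trans, nrow(xyz), 3, byrow = TRUE)
}

# Horn quaternion-method superposition RMSD: an algorithm independent of
# the package's SVD-based Kabsch implementation.
quaternion_rmsd <- function(xa, xb) {
  a <- sweep(xa, 2, colMeans(xa))
  b <- sweep(xb, 2, colMeans(xb))
  m <- crossprod(a, b)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  n <- rbind(
    c(sxx + syy + szz, syz - szy, szx - sxz, sxy - syx),
    c(syz - szy, sxx - syy - szz, sxy + syx, szx + sxz),
    c(szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy),
    c(sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz))
  lam <- max(eigen(n, symmetric = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(xa)
  sqrt(max(msd, 0))
}

# O(n^2) brute-force vdW contact oracle: double loop, no vectorization.
brute_vdw <- function(xyz, ia, ib, ra, rb, tol) {
  hits <- NULL
  for (i in seq_along(ia)) {
    for (j in seq_along(ib)) {
      d <- sqrt(sum((xyz[ia[i], ] - xyz[ib[j], ])^2))
      if (d <= ra[i] + rb[j] + tol) {
        hits <- rbind(hits, c(ia[i], ib[j], d))
      }
    }
  }
  hits
}

# Exhaustive global-alignment DP score oracle (score only, no traceback).
dp_score <- function(ref, qry, match = 1, mismatch = -1, gap = -2) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(qry, "")[[1]]
  prev <- gap * (0:length(q))
  for (i in seq_along(r)) {
    cur <- numeric(length(q) + 1)
    cur[1] <- gap * i
    for (j in seq_along(q)) {
      cur[j + 1] <- max(prev[j] + ifelse(r[i] == q[j], match, mismatch),
                        prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[length(q) + 1]
}

# Two parallel hexagonal rings stacked along z, optionally tilted.
stacked_rings_structure <- function(separation = 3.5, tilt_deg = 0,
                                    offset = c(0, 0), n_rings = 2) {
  hex <- function(center) {
    t(vapply(0:5, function(k) {
      center + 1.39 * c(cos(k * pi / 3), sin(k * pi / 3), 0)
    }, numeric(3)))
  }
  rows <- NULL
  for (r in seq_len(n_rings)) {
    xyz <- hex(c(0, 0, 0))
    if (r > 1 && tilt_deg != 0) {
      th <- tilt_deg * pi / 180
      rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
      xyz <- t(rot %*% t(xyz))
    }
    xyz <- sweep(xyz, 2, c(offset * (r - 1), (r - 1) * separation), "+")
    rows <- rbind(rows, data.frame(
      serial = (r - 1) * 6 + 1:6,
      name = paste0("C", 1:6), element = "C", res_name = "RNG",
      res_num = r, chain = "A",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
  }
  Structure(rows)
}

ring_spec_for <- function(res, label = paste0("ring", res)) {
  ring_spec(label, atom_selector(res_num = res), paste0("C", 1:6))
}
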