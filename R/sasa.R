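# Shrake-Rupley solvent-accessible surface area and interface burial.

#' Evenly distributed points on the unit sphere (golden spiral)
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  theta <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each heavy atom, test points are distributed on the expanded
#' sphere of radius `r_vdw + probe` via a golden-spiral lattice; the
#' accessible fraction times the expanded-sphere area
#' \eqn{4\pi (r + probe)^2} is that atom's SASA.  Deterministic for a
#' fixed `n_points`.
#'
#' @param atoms atom table (rows of a `structure_model`'s `atoms`);
#'   hydrogens, if present, are dropped with a message.
#' @param rs a [radius_set()].
#' @param n_points number of sphere test points (>= 92; default 960).
#' @param probe probe radius in Angstrom (default from `rs`).
#' @param strict error on elements missing from the radius set instead of
#'   defaulting with a warning?
#' @return A `sasa_result`: list with `per_atom` (numeric, one value per
#'   input heavy atom, Angstrom^2), `per_residue` (data frame `chain`,
#'   `resno`, `ins`, `resid`, `sasa`), `total`, and `parameters`.
#' @examples
#' atoms <- data.frame(chain = "A", resno = 1, ins = "", resid = "ALA",
#'                     atom = "CB", element = "C", x = 0, y = 0, z = 0,
#'                     occ = 1, b = 0, altloc = "", het = FALSE)
#' shrake_rupley(atoms)$total      # ~ 4*pi*(1.7+1.4)^2
#' @export
shrake_rupley <- function(atoms, rs = radius_set(), n_points = 960,
                          probe = rs$probe_radius, strict = FALSE) {
  if (n_points < 92) stop("n_points must be >= 92 for a usable lattice")
  if (any(atoms$element == "H")) {
    message("dropping ", sum(atoms$element == "H"), " hydrogen atom(s) for SASA")
    atoms <- atoms[atoms$element != "H", , drop = FALSE]
  }
  n <- nrow(atoms)
  if (n == 0) stop("no heavy atoms for SASA")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- vdw_radius(atoms$element, rs, strict = strict) + probe
  sphere <- golden_spiral_points(n_points)
  # Neighbor lists from the pairwise distance bound d < r_i + r_j.
  d2 <- as.matrix(stats::dist(xyz))^2
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    pts <- sweep(sphere * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- pts[acc, 1] - xyz[j, 1]
      dy <- pts[acc, 2] - xyz[j, 2]
      dz <- pts[acc, 3] - xyz[j, 3]
      acc[acc] <- dx * dx + dy * dy + dz * dz > rad[j]^2
    }
    per_atom[i] <- sum(acc) / n_points * 4 * pi * rad[i]^2
  }
  key <- residue_uid(atoms)
  res_sasa <- tapply(per_atom, key, sum)
  first <- !duplicated(key)
  per_residue <- data.frame(atoms[first, c("chain", "resno", "ins", "resid")],
                            sasa = as.numeric(res_sasa[key[first]]),
                            stringsAsFactors = FALSE)
  rownames(per_residue) <- NULL
  structure(list(per_atom = per_atom,
                 per_residue = per_residue,
                 total = sum(per_atom),
                 parameters = list(probe = probe, n_points = n_points,
                                   radius_set = rs)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("SASA: ", round(x$total, 1), " A^2 over ", length(x$per_atom),
      " atoms (probe ", x$parameters$probe, " A, ",
      x$parameters$n_points, " points)\n", sep = "")
  invisible(x)
}

#' Interface buried surface area between two atom groups
#'
#' SASA is computed three times (group A alone, group B alone, and the
#' A+B complex in its joint geometry).  Both reporting conventions are
#' returned: `bsa_total = SASA_A + SASA_B - SASA_AB` (the summed burial
#' of both sides) and `bsa_half = bsa_total / 2` (the per-interface
#' area commonly quoted for antibody/antigen interfaces).  Per-residue
#' burial identifies footprint residues.
#'
#' @param a_atoms,b_atoms disjoint atom tables.
#' @param rs a [radius_set()].
#' @param n_points,probe,strict passed to [shrake_rupley()].
#' @param burial_threshold residues with `delta SASA >` this value
#'   (Angstrom^2) enter the burial-based footprint (default 1.0).
#' @param a_id,b_id labels for the two groups.
#' @return An `interface_area`: list with `bsa_total`, `bsa_half`,
#'   `delta_per_side`, `per_residue_burial` (data frame with `side`),
#'   `footprint` (burial-based residue subset), and `parameters`.
#' @export
interface_area <- function(a_atoms, b_atoms, rs = radius_set(),
                           n_points = 960, probe = rs$probe_radius,
                           strict = FALSE, burial_threshold = 1.0,
                           a_id = "A", b_id = "B") {
  if (nrow(a_atoms) == 0 || nrow(b_atoms) == 0) stop("empty atom group")
  key_a <- paste(residue_uid(a_atoms), a_atoms$atom)
  key_b <- paste(residue_uid(b_atoms), b_atoms$atom)
  if (length(intersect(key_a, key_b)))
    stop("atom groups overlap; interface groups must be disjoint")
  sa <- shrake_rupley(a_atoms, rs, n_points, probe, strict)
  sb <- shrake_rupley(b_atoms, rs, n_points, probe, strict)
  sab <- shrake_rupley(rbind(a_atoms, b_atoms), rs, n_points, probe, strict)
  na <- length(sa$per_atom)
  delta_a <- sa$per_atom - sab$per_atom[seq_len(na)]
  delta_b <- sb$per_atom - sab$per_atom[-seq_len(na)]
  bsa_total <- sum(delta_a) + sum(delta_b)

  per_res <- function(atoms, delta, side) {
    key <- residue_uid(atoms)
    first <- !duplicated(key)
    out <- data.frame(atoms[first, c("chain", "resno", "ins", "resid")],
                      delta_sasa = as.numeric(tapply(delta, key, sum)[key[first]]),
                      side = side, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  }
  burial <- rbind(per_res(a_atoms, delta_a, a_id),
                  per_res(b_atoms, delta_b, b_id))
  structure(list(a_id = a_id, b_id = b_id,
                 bsa_total = bsa_total,
                 bsa_half = bsa_total / 2,
                 delta_per_side = c(sum(delta_a), sum(delta_b)),
                 per_residue_burial = burial,
                 footprint = burial[burial$delta_sasa > burial_threshold, ,
                                    drop = FALSE],
                 parameters = list(probe = probe, n_points = n_points,
                                   burial_threshold = burial_threshold)),
            class = "interface_area")
}

#' @export
print.interface_area <- function(x, ...) {
  cat("Interface ", x$a_id, " / ", x$b_id, ":\n",
      "  BSA (total, both sides summed): ", round(x$bsa_total, 1), " A^2\n",
      "  BSA (half, per interface):      ", round(x$bsa_half, 1), " A^2\n",
      "  burial per side: ", round(x$delta_per_side[1], 1), " / ",
      round(x$delta_per_side[2], 1), " A^2\n",
      "  footprint residues (dSASA > ",
      x$parameters$burial_threshold, " A^2): ", nrow(x$footprint), "\n",
      sep = "")
  invisible(x)
}
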