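# Seeded synthetic-structure generators and analytic oracles.  These
# produce inputs with the geometric/statistical structure the analyses
# assume -- toy antigen/probe complexes with designed contact
# distances, ideal helices, Gaussian-jitter trajectories -- plus the
# closed-form two-sphere accessible-area oracle for the SASA module.
# Geometric plausibility only: no rotamers, no Ramachandran-valid
# backbones.

#' Build an ideal alpha-helix model
#'
#' A C-alpha trace on the canonical helix (rise 1.5 Angstrom, twist 100
#' degrees, C-alpha radius 2.3 Angstrom gives a ~3.8 Angstrom
#' consecutive C-alpha distance); with `backbone = TRUE` each residue
#' carries alanine-like pseudo-backbone atoms (N, CA, C, O, CB) at fixed
#' local offsets so contact-classification paths (N/O versus C) are
#' exercisable.
#'
#' @param n number of residues (or taken from `sequence`).
#' @param sequence optional 1-letter sequence; sets residue names.
#' @param rise rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param radius C-alpha radius from the helix axis, Angstrom.
#' @param chain_id chain identifier.
#' @param start_resno author number of the first residue (e.g. 141 to
#'   mimic the alpha2-1 helix).
#' @param backbone add pseudo-backbone atoms?
#' @param id model label.
#' @return A `structure_model`.
#' @examples
#' h <- build_ideal_helix(15, start_resno = 141)
#' range(h$atoms$resno)
#' @export
build_ideal_helix <- function(n = 15, sequence = NULL, rise = 1.5,
                              twist = 100, radius = 2.3, chain_id = "A",
                              start_resno = 1, backbone = FALSE,
                              id = "ideal-helix") {
  if (rise <= 0) stop("rise must be > 0")
  if (!is.null(sequence)) {
    seq1 <- strsplit(sequence, "")[[1]]
    n <- length(seq1)
    resid <- bio3d::aa123(seq1)
  } else {
    resid <- rep("ALA", n)
  }
  if (n < 1) stop("need at least one residue")
  k <- seq_len(n) - 1
  ang <- k * twist * pi / 180
  ca <- cbind(radius * cos(ang), radius * sin(ang), k * rise)
  rows <- list()
  for (i in seq_len(n)) {
    u <- c(cos(ang[i]), sin(ang[i]), 0)             # outward radial
    tv <- c(-sin(ang[i]), cos(ang[i]), 0)           # tangential
    ax <- c(0, 0, 1)
    at <- if (backbone) {
      rbind(N = ca[i, ] - 1.0 * tv - 0.9 * ax,
            CA = ca[i, ],
            C = ca[i, ] + 1.0 * tv + 0.9 * ax,
            O = ca[i, ] + 1.0 * tv + 2.1 * ax,
            CB = ca[i, ] + 1.5 * u)
    } else {
      rbind(CA = ca[i, ])
    }
    rows[[i]] <- data.frame(
      chain = chain_id, resno = start_resno + i - 1, ins = "",
      resid = resid[i], atom = rownames(at),
      element = substr(rownames(at), 1, 1),
      x = at[, 1], y = at[, 2], z = at[, 3],
      occ = 1, b = 0, altloc = "", het = FALSE,
      stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows), id = id)
}

#' Build a toy antigen/probe complex with designed contact distances
#'
#' The antigen is an ideal helix with pseudo-backbone; each probe is an
#' alanine-like residue on its own probe chain whose designated atom is
#' placed exactly `distance` Angstrom from the target residue's CB (the
#' antigen's outermost atom) along the outward helix radial, with the
#' rest of the probe residue placed further out.  The designed distance
#' is therefore the minimal distance between probe and antigen, and the
#' designed placements are the ground-truth contact table, so detector
#' output can be checked against construction.
#' Probes placed inside the antigen's van der Waals envelope raise a
#' warning, not an error (clash fixtures need them).
#'
#' @param n_antigen antigen helix length (residues).
#' @param placements data frame with columns `target_resno`, `distance`
#'   (Angstrom), and optionally `probe_atom` (default `"N"`) and
#'   `probe_resname` (default `"ALA"`).
#' @param antigen_chain,probe_chain chain ids.
#' @param antigen_start first author number of the antigen.
#' @param roles roles assigned to the two chains in the returned map.
#' @param id model label.
#' @return list with `model` (`structure_model`), `map`
#'   (`chain_role_map`), and `truth` (data frame of designed pairs:
#'   `target_resno`, `target_atom` (`"CB"`), `probe_resno`,
#'   `probe_atom`, `distance`).
#' @export
build_toy_complex <- function(n_antigen = 15,
                              placements = data.frame(
                                target_resno = c(144, 146, 150),
                                distance = c(3.5, 3.0, 3.9)),
                              antigen_chain = "A", probe_chain = "P",
                              antigen_start = 141,
                              roles = c(mhc_heavy = "A", ab_light = "P"),
                              id = "toy-complex") {
  if (nrow(placements) > 0 && any(placements$distance <= 0))
    stop("placement distances must be > 0")
  if (is.null(placements$probe_atom))
    placements$probe_atom <- rep("N", nrow(placements))
  if (is.null(placements$probe_resname))
    placements$probe_resname <- rep("ALA", nrow(placements))
  helix <- build_ideal_helix(n_antigen, chain_id = antigen_chain,
                             start_resno = antigen_start, backbone = TRUE,
                             id = id)
  atoms <- helix$atoms
  rows <- list()
  for (i in seq_len(nrow(placements))) {
    tr <- placements$target_resno[i]
    cb <- atoms[atoms$resno == tr & atoms$atom == "CB", , drop = FALSE]
    if (nrow(cb) != 1) stop("target residue ", tr, " not in antigen")
    kidx <- tr - antigen_start
    ang <- kidx * 100 * pi / 180
    u <- c(cos(ang), sin(ang), 0)
    base <- c(cb$x, cb$y, cb$z) + placements$distance[i] * u
    r_pair <- sum(vdw_radius(c(substr(placements$probe_atom[i], 1, 1), "C")))
    if (placements$distance[i] < r_pair - 0.4)
      warning("probe ", i, " placed inside the antigen vdW envelope ",
              "(designed clash fixture)")
    # Designated atom sits exactly at the designed distance; the rest of
    # the residue stacks further outward so it cannot come closer.
    off <- rbind(N = 0, CA = 1.2, C = 2.4, O = 3.3, CB = 2.0)
    names_at <- rownames(off)
    designated <- placements$probe_atom[i]
    if (!designated %in% names_at) stop("probe_atom must be one of N/CA/C/O/CB")
    shift <- off[designated, 1]
    at <- t(vapply(seq_along(names_at), function(j)
      base + (off[j, 1] - shift) * u, numeric(3)))
    rows[[i]] <- data.frame(
      chain = probe_chain, resno = i, ins = "",
      resid = placements$probe_resname[i], atom = names_at,
      element = substr(names_at, 1, 1),
      x = at[, 1], y = at[, 2], z = at[, 3],
      occ = 1, b = 0, altloc = "", het = FALSE,
      stringsAsFactors = FALSE)
  }
  all_atoms <- rbind(atoms, do.call(rbind, rows))
  model <- structure_model(all_atoms, id = id)
  role_vec <- setNames(names(roles), unname(roles))
  map <- chain_role_map(role_vec)
  truth <- if (nrow(placements)) {
    data.frame(target_resno = placements$target_resno,
               target_atom = "CB",
               probe_resno = seq_len(nrow(placements)),
               probe_atom = placements$probe_atom,
               distance = placements$distance,
               stringsAsFactors = FALSE)
  } else {
    data.frame(target_resno = integer(), target_atom = character(),
               probe_resno = integer(),
               probe_atom = character(), distance = numeric())
  }
  list(model = model, map = map, truth = truth)
}

#' Random proper rotation matrix
#'
#' Drawn via QR decomposition of a Gaussian matrix with the determinant
#' forced to +1; uses the current RNG state.
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  q %*% diag(c(1, 1, det(q)))
}

#' Generate a Gaussian-jitter trajectory around a reference model
#'
#' Frame t is the reference plus independent Gaussian displacements with
#' per-residue, per-coordinate standard deviation `sigma`; optionally a
#' random global rigid motion is applied to each frame to exercise the
#' alignment step.  Fully reproducible from `seed`.
#'
#' @param model reference `structure_model`.
#' @param sigma per-residue coordinate standard deviations (Angstrom),
#'   recycled across residues in order.
#' @param t_frames number of frames.
#' @param seed RNG seed.
#' @param rigid_motion apply a random global rotation + translation to
#'   each frame?
#' @return A `trajectory` with attributes `sigma` (per-residue vector)
#'   and `seed`.
#' @export
gen_jitter_trajectory <- function(model, sigma = 0.5, t_frames = 100,
                                  seed = 1, rigid_motion = FALSE) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (t_frames < 1) stop("t_frames must be >= 1")
  atoms <- model$atoms
  key <- residue_uid(atoms)
  res_ids <- unique(key)
  sig_res <- rep_len(sigma, length(res_ids))
  sig_atom <- sig_res[match(key, res_ids)]
  ref <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(ref)
  set.seed(seed)
  coords <- array(NA_real_, c(t_frames, n, 3))
  for (t in seq_len(t_frames)) {
    fr <- ref + matrix(rnorm(3 * n, 0, sig_atom), n, 3)
    if (rigid_motion) {
      tr <- rigid_transform(random_rotation(), rnorm(3, 0, 5))
      fr <- apply_transform(tr, fr)
    }
    coords[t, , ] <- fr
  }
  out <- as_trajectory(coords, atoms[, c("chain", "resno", "ins", "resid",
                                         "atom", "element")])
  attr(out, "sigma") <- sig_res
  attr(out, "seed") <- seed
  out
}

#' Closed-form accessible area of two probe-expanded spheres
#'
#' The analytic oracle for Shrake-Rupley: each sphere is expanded by the
#' probe radius, and the accessible area of sphere i is its full area
#' minus the spherical cap occluded by the other expanded sphere
#' (cap height from the standard two-sphere intersection).  Returns the
#' full `4 pi (r_i + probe)^2` areas once the centers are at least
#' `r1 + r2 + 2 probe` apart; when one expanded sphere engulfs the other
#' (`d <= |R1 - R2|`) the engulfed sphere scores 0 and the larger keeps
#' its full area.
#'
#' @param r1,r2 van der Waals radii, Angstrom.
#' @param d center-center distance, Angstrom.
#' @param probe probe radius, Angstrom.
#' @return numeric length-2 vector `c(area1, area2)`, Angstrom^2.
#' @export
two_sphere_sasa <- function(r1, r2, d, probe = 1.4) {
  if (r1 <= 0 || r2 <= 0 || d <= 0) stop("r1, r2, d must be > 0")
  R1 <- r1 + probe; R2 <- r2 + probe
  full <- 4 * pi * c(R1^2, R2^2)
  if (d >= R1 + R2) return(full)
  if (d <= abs(R1 - R2)) {
    # engulfed: smaller expanded sphere entirely inside the larger
    if (R1 < R2) return(c(0, full[2])) else return(c(full[1], 0))
  }
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(full[1] - 2 * pi * R1 * h1, full[2] - 2 * pi * R2 * h2)
}
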