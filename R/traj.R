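# Post-hoc trajectory statistics: frame alignment, backbone RMSD series,
# RMSD probability distributions, per-residue RMSF.

.BACKBONE <- c("N", "CA", "C", "O")

#' Construct a trajectory
#'
#' @param coords T x N x 3 array of coordinates (Angstrom), constant
#'   atom count across frames.
#' @param atoms atom table of length N (columns as in a
#'   `structure_model`) labelling the second dimension.
#' @param frame_interval optional frame spacing metadata (e.g. ns).
#' @return A `trajectory`.
#' @export
as_trajectory <- function(coords, atoms, frame_interval = NA_real_) {
  d <- dim(coords)
  if (length(d) != 3 || d[3] != 3) stop("coords must be a T x N x 3 array")
  if (d[2] != nrow(atoms)) stop("atom table length does not match coords")
  if (d[1] < 1) stop("trajectory needs at least one frame")
  structure(list(coords = coords, atoms = atoms,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("trajectory: ", d[1], " frames x ", d[2], " atoms\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a trajectory from a multi-model PDB or plain-XYZ file
#'
#' Multi-model PDB is the native dialect (MODEL/ENDMDL frames with a
#' constant atom set).  The plain dialect (`format = "xyz"`) is a
#' whitespace table: a header line `T N`, then `T * N` rows of
#' `x y z`, frame-major; atoms are labelled `CA`/`ALA` serially.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"xyz"`.
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "xyz") "xyz" else "pdb"
  if (format == "pdb") {
    raw <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                            verbose = FALSE))
    at <- raw$atom
    atoms <- data.frame(chain = ifelse(is.na(at$chain), " ", at$chain),
                        resno = as.integer(at$resno),
                        ins = ifelse(is.na(at$insert), "", at$insert),
                        resid = at$resid, atom = at$elety,
                        element = .normalize_element(at$elesy, at$elety),
                        stringsAsFactors = FALSE)
    xyz <- raw$xyz
    t_frames <- nrow(xyz)
    n <- ncol(xyz) / 3
    coords <- array(NA_real_, c(t_frames, n, 3))
    for (i in seq_len(t_frames))
      coords[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    as_trajectory(coords, atoms)
  } else {
    con <- file(path, "r"); on.exit(close(con))
    hdr <- scan(con, n = 2, quiet = TRUE)
    t_frames <- hdr[1]; n <- hdr[2]
    vals <- scan(con, n = t_frames * n * 3, quiet = TRUE)
    coords <- aperm(array(vals, c(3, n, t_frames)), c(3, 2, 1))
    atoms <- data.frame(chain = "A", resno = seq_len(n), ins = "",
                        resid = "ALA", atom = "CA", element = "C",
                        stringsAsFactors = FALSE)
    as_trajectory(coords, atoms)
  }
}

#' Write a trajectory
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @param format `"pdb"` (multi-model) or `"xyz"` (plain dialect of
#'   [read_trajectory()]).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  t_frames <- n_frames(traj)
  if (format == "xyz") {
    con <- file(path, "w"); on.exit(close(con))
    cat(t_frames, dim(traj$coords)[2], "\n", file = con)
    for (i in seq_len(t_frames))
      write.table(format(frame_coords(traj, i), digits = 10), con,
                  row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    a <- traj$atoms
    lines <- character(0)
    for (i in seq_len(t_frames)) {
      xyz <- frame_coords(traj, i)
      recs <- sprintf(
        "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(nrow(a)),
        ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom), "",
        a$resid, a$chain, a$resno, ifelse(nzchar(a$ins), a$ins, " "),
        xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
      lines <- c(lines, sprintf("MODEL     %4d", i), recs, "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}

.resolve_selection <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(nrow(traj$atoms)))
  if (is.character(selection)) {
    if (identical(selection, "backbone"))
      return(which(traj$atoms$atom %in% .BACKBONE))
    if (identical(selection, "ca")) return(which(traj$atoms$atom == "CA"))
    stop("unknown selection keyword '", selection, "'")
  }
  as.integer(selection)
}

#' Align every frame to a reference by Kabsch fit
#'
#' Each frame is superposed on the reference over the selection; the
#' transform carries all atoms along.
#'
#' @param traj a `trajectory`.
#' @param reference frame index, or an N x 3 matrix (e.g. a mean
#'   structure), defining the target.
#' @param selection atom indices, `"backbone"`, `"ca"`, or `NULL` (all
#'   atoms) used for the fit.
#' @return the aligned `trajectory` (attribute `alignment` records the
#'   protocol).
#' @export
align_frames <- function(traj, reference = 1, selection = "backbone") {
  sel <- .resolve_selection(traj, selection)
  if (length(sel) < 3) stop("alignment selection must contain >= 3 atoms")
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  out <- traj$coords
  for (i in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, i)
    fit <- kabsch_superpose(ref[sel, , drop = FALSE], fr[sel, , drop = FALSE])
    out[i, , ] <- apply_transform(fit$transform, fr)
  }
  res <- as_trajectory(out, traj$atoms, traj$frame_interval)
  attr(res, "alignment") <- list(
    reference = if (is.matrix(reference)) "matrix" else reference,
    selection = selection, n_fit = length(sel))
  res
}

#' Per-frame RMSD series against a reference
#'
#' @param traj a `trajectory`.
#' @param reference frame index or N x 3 matrix.
#' @param selection atoms over which RMSD is measured (default
#'   backbone).
#' @param align_first Kabsch-fit each frame on `align_selection` before
#'   measuring?
#' @param align_selection selection for the fit (defaults to
#'   `selection`).
#' @return data frame `frame`, `rmsd` (class `rmsd_series`); attributes
#'   record the protocol.
#' @export
rmsd_series <- function(traj, reference = 1, selection = "backbone",
                        align_first = FALSE, align_selection = selection) {
  sel <- .resolve_selection(traj, selection)
  if (length(sel) == 0) stop("empty RMSD selection")
  if (align_first) traj <- align_frames(traj, reference, align_selection)
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- frame_coords(traj, i)
    sqrt(mean(rowSums((fr[sel, , drop = FALSE] - ref[sel, , drop = FALSE])^2)))
  }, numeric(1))
  structure(data.frame(frame = seq_along(vals), rmsd = vals),
            class = c("rmsd_series", "data.frame"),
            selection = selection, aligned = align_first)
}

#' Probability distribution of an RMSD series
#'
#' Density-normalized histogram P(d) plus the mean and SD taken from
#' the raw series (not from the binned histogram).
#'
#' @param series an `rmsd_series` or numeric vector.
#' @param breaks number of bins or a vector of bin edges (as in
#'   [graphics::hist()]).
#' @return list with `breaks`, `density`, `mids`, `mean`, `sd`;
#'   `sum(density * diff(breaks)) == 1`.
#' @export
rmsd_distribution <- function(series, breaks = 30) {
  x <- if (is.data.frame(series)) series$rmsd else as.numeric(series)
  if (length(x) == 0) stop("empty series")
  if (length(x) < 2) stop("need >= 2 samples for a distribution summary")
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, density = h$density, mids = h$mids,
       mean = mean(x), sd = sd(x))
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are aligned by the two-pass protocol: fit to the first frame,
#' compute the mean structure, re-fit to that mean; the fluctuation of
#' atom i is then \eqn{\sqrt{\langle |r_i - \langle r_i\rangle|^2
#' \rangle}} over frames, and a residue's RMSF is the root of the mean
#' squared fluctuation of its selected atoms.  For isotropic Gaussian
#' jitter of per-coordinate standard deviation sigma the expected RMSF
#' is sigma * sqrt(3).
#'
#' @param traj a `trajectory` with at least 2 frames.
#' @param selection atoms entering the profile (default backbone).
#' @param align_selection atoms used for the alignment fit (defaults to
#'   `selection`).
#' @param align set `FALSE` to skip alignment (frames already fitted).
#' @return An `rmsf_profile`: data frame `chain`, `resno`, `ins`,
#'   `resid`, `rmsf` (Angstrom), in input residue order; attribute
#'   `alignment` records the protocol.
#' @export
rmsf <- function(traj, selection = "backbone", align_selection = selection,
                 align = TRUE) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  sel <- .resolve_selection(traj, selection)
  if (length(sel) == 0) stop("empty RMSF selection")
  if (align) {
    traj <- align_frames(traj, 1, align_selection)
    mean_coords <- apply(traj$coords, c(2, 3), mean)
    traj <- align_frames(traj, mean_coords, align_selection)
  }
  mean_coords <- apply(traj$coords, c(2, 3), mean)
  msf_atom <- vapply(sel, function(j) {
    dx <- sweep(matrix(traj$coords[, j, ], ncol = 3), 2, mean_coords[j, ])
    mean(rowSums(dx^2))
  }, numeric(1))
  at <- traj$atoms[sel, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$ins, sep = "|")
  first <- !duplicated(key)
  res_msf <- tapply(msf_atom, key, mean)
  out <- data.frame(at[first, c("chain", "resno", "ins", "resid")],
                    rmsf = sqrt(as.numeric(res_msf[key[first]])),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("rmsf_profile", "data.frame"),
            alignment = if (align)
              list(protocol = "two-pass (first frame, then mean structure)",
                   selection = align_selection)
            else list(protocol = "none"))
}
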