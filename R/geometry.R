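# Rigid-body superposition (Kabsch), residue correspondence, RMSD.

#' Kabsch superposition of paired point sets
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' moving points onto the reference points.  Reflections are suppressed:
#' the rotation determinant is forced to +1 even when a reflection would
#' lower the RMSD.
#'
#' @param reference N x 3 matrix of reference coordinates (Angstrom).
#' @param moving N x 3 matrix of moving coordinates, paired row-by-row.
#' @return list with `transform` (a `rigid_transform`: `rotation` 3x3,
#'   `translation` length-3) and `rmsd` (Angstrom) such that
#'   `apply_transform(transform, moving)` best fits `reference`.
#' @examples
#' p <- matrix(rnorm(15), 5, 3)
#' fit <- kabsch_superpose(p, p)
#' fit$rmsd
#' @export
kabsch_superpose <- function(reference, moving) {
  reference <- as.matrix(reference); moving <- as.matrix(moving)
  if (!all(dim(reference) == dim(moving)) || ncol(reference) != 3)
    stop("reference and moving must be equal-size N x 3 matrices")
  n <- nrow(reference)
  if (n < 3) stop("at least 3 paired points are required")
  mu_r <- colMeans(reference); mu_m <- colMeans(moving)
  rc <- sweep(reference, 2, mu_r); mc <- sweep(moving, 2, mu_m)
  # Degenerate (collinear) sets have rank < 2 about their centroid.
  if (svd(rc)$d[2] < 1e-8 * max(1, svd(rc)$d[1]) ||
      svd(mc)$d[2] < 1e-8 * max(1, svd(mc)$d[1]))
    stop("degenerate (collinear) point set; superposition is not defined")
  H <- crossprod(mc, rc)                       # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)     # det(R) = +1 always
  t_vec <- as.numeric(mu_r - R %*% mu_m)
  tr <- rigid_transform(R, t_vec)
  fitted <- apply_transform(tr, moving)
  list(transform = tr,
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1
#'   (tolerance 1e-8).
#' @param translation length-3 numeric vector, Angstrom.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation determinant must be +1 (no reflections)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' Computes `x' = R x + t` for each row.
#'
#' @param transform a `rigid_transform`.
#' @param coords N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2, -transform$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% transform$translation))
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then
#' `a`.
#' @param a,b `rigid_transform` objects.
#' @return the composed `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation + a$translation))
}

#' Serialize a rigid transform as 12 numbers
#'
#' Row-major rotation followed by the translation, the layout used in
#' JSON reports.
#' @param transform a `rigid_transform`.
#' @return numeric vector of length 12.
#' @export
flatten_transform <- function(transform) {
  c(as.vector(t(transform$rotation)), transform$translation)
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' @param a,b N x 3 matrices, paired row-by-row.
#' @param superpose_first Kabsch-fit `b` onto `a` before measuring?
#' @return RMSD in Angstrom.
#' @export
rmsd_coords <- function(a, b, superpose_first = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0) stop("empty coordinate set")
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  if (superpose_first) return(kabsch_superpose(a, b)$rmsd)
  sqrt(mean(rowSums((a - b)^2)))
}

# ---- residue correspondence ------------------------------------------------

.residue_table <- function(model, chain) {
  a <- model$atoms[model$atoms$chain == chain & !model$atoms$het, , drop = FALSE]
  a <- a[a$resid %in% .STANDARD_AA, , drop = FALSE]
  if (nrow(a) == 0) stop("chain '", chain, "' has no protein residues")
  key <- residue_uid(a)
  first <- !duplicated(key)
  out <- a[first, c("resno", "ins", "resid"), drop = FALSE]
  out[order(out$resno, out$ins), , drop = FALSE]
}

.aa_identity_matrix <- function() {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V", "X")
  m <- matrix(-1, length(aa), length(aa), dimnames = list(aa, aa))
  diag(m) <- 1
  m
}

#' Residue correspondence between two homologous chains
#'
#' `by_number` pairs residues sharing the author sequence number and
#' insertion code (the natural mode across HLA allelomorphs, which share
#' mature-protein numbering).  `by_alignment` performs a global pairwise
#' sequence alignment (match +1, mismatch -1, gap open -2, extend -1; a
#' gap of length L costs 2 + L) and pairs residues from aligned columns
#' where both are present.
#'
#' @param model_a,model_b `structure_model` objects.
#' @param chain_a,chain_b chain ids in the respective models.
#' @param mode `"by_number"` or `"by_alignment"`.
#' @return data frame with columns `resno_a`, `ins_a`, `resid_a`,
#'   `resno_b`, `ins_b`, `resid_b`; attribute `mode` records the mode.
#' @export
map_residues <- function(model_a, model_b, chain_a, chain_b,
                         mode = c("by_number", "by_alignment")) {
  mode <- match.arg(mode)
  ra <- .residue_table(model_a, chain_a)
  rb <- .residue_table(model_b, chain_b)
  if (mode == "by_number") {
    m <- merge(ra, rb, by = c("resno", "ins"), suffixes = c("_a", "_b"))
    if (nrow(m) == 0) stop("no residues share author numbering between chains")
    out <- data.frame(resno_a = m$resno, ins_a = m$ins, resid_a = m$resid_a,
                      resno_b = m$resno, ins_b = m$ins, resid_b = m$resid_b,
                      stringsAsFactors = FALSE)
    out <- out[order(out$resno_a, out$ins_a), , drop = FALSE]
  } else {
    sa <- bio3d::aa321(ra$resid); sb <- bio3d::aa321(rb$resid)
    sa[is.na(sa) | sa == ""] <- "X"; sb[is.na(sb) | sb == ""] <- "X"
    al <- Biostrings::pairwiseAlignment(
      paste(sa, collapse = ""), paste(sb, collapse = ""),
      type = "global", substitutionMatrix = .aa_identity_matrix(),
      gapOpening = 2, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
    both <- pa != "-" & pb != "-"
    if (!any(both)) stop("alignment produced no paired residues")
    out <- data.frame(resno_a = ra$resno[ia[both]], ins_a = ra$ins[ia[both]],
                      resid_a = ra$resid[ia[both]],
                      resno_b = rb$resno[ib[both]], ins_b = rb$ins[ib[both]],
                      resid_b = rb$resid[ib[both]],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}
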