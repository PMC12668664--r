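# Epitope/paratope footprints, cross-complex footprint overlap on a
# shared ligand numbering, receptor transplantation, and steric clash
# scans -- the machinery behind comparing an antibody's binding site
# with the footprints of inhibitory NK receptors on the same MHC
# surface.

#' Contact-based footprint of a binder on a target
#'
#' Residues of the target role with at least one heavy-atom contact to
#' the binder role(s) at the cutoff, with per-residue partner and
#' contact counts.
#'
#' @param model a `structure_model`.
#' @param map a `chain_role_map`.
#' @param target_role role whose surface carries the footprint (e.g.
#'   `"mhc_heavy"`).
#' @param binder_roles roles of the binder (e.g.
#'   `c("ab_heavy", "ab_light")` or `"receptor"`).
#' @param cutoff contact cutoff, Angstrom.
#' @return A `footprint`: data frame (`chain`, `resno`, `ins`, `resid`,
#'   `n_contacts`, `n_partners`) with attributes `complex_id`,
#'   `target_role`, `binder_roles`, `cutoff`.
#' @export
epitope_footprint <- function(model, map, target_role = "mhc_heavy",
                              binder_roles = c("ab_heavy", "ab_light"),
                              cutoff = 4.0) {
  target <- select_atoms(model, map, target_role)
  binder <- do.call(rbind, lapply(binder_roles, function(r)
    select_atoms(model, map, r)))
  tab <- find_contacts(target, binder, cutoff = cutoff)
  if (nrow(tab) == 0) {
    out <- data.frame(chain = character(), resno = integer(),
                      ins = character(), resid = character(),
                      n_contacts = integer(), n_partners = integer(),
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(tab$chain_a, tab$resno_a, tab$ins_a, sep = "|")
    pkey <- paste(key, tab$chain_b, tab$resno_b, tab$ins_b, sep = "|")
    first <- !duplicated(key)
    n_partners <- tapply(pkey, key, function(k) length(unique(k)))
    out <- data.frame(chain = tab$chain_a[first], resno = tab$resno_a[first],
                      ins = tab$ins_a[first], resid = tab$resid_a[first],
                      n_contacts = as.integer(table(key)[key[first]]),
                      n_partners = as.integer(n_partners[key[first]]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$chain, out$resno, out$ins), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("footprint", "data.frame"),
            complex_id = model$id, target_role = target_role,
            binder_roles = binder_roles, cutoff = cutoff)
}

#' Overlap of several footprints on a shared ligand numbering
#'
#' Footprint residues from each complex are mapped onto a reference
#' numbering (identity by author number by default, or explicit
#' correspondences from [map_residues()]) and intersected.  The Jaccard
#' index is `|shared| / |union|` over the multi-way sets; an optional
#' named segment restricts a second view.  Footprint residues without a
#' mapping are listed, never silently dropped.
#'
#' @param footprints list of `footprint` objects (>= 2), all on
#'   homologous target chains.
#' @param correspondences optional list, parallel to `footprints`, of
#'   [map_residues()] tables mapping each complex's target chain (side
#'   b) onto the reference numbering (side a); `NULL` entries mean
#'   identity (`by_number`).
#' @param restrict optional inclusive author-number range
#'   (`c(start, end)`) for a restricted view.
#' @param restrict_name label for the restricted view (e.g.
#'   `"alpha2_1"`).
#' @return An `overlap_report`: list with `complexes`, per-complex
#'   mapped residue sets, `shared`, `unique_per_complex`, `jaccard`,
#'   `unmapped`, `mode`, and optionally `restricted` (same fields within
#'   the range).
#' @export
compare_footprints <- function(footprints, correspondences = NULL,
                               restrict = NULL, restrict_name = NULL) {
  if (length(footprints) < 2) stop("need at least two footprints")
  ids <- vapply(seq_along(footprints), function(i) {
    id <- attr(footprints[[i]], "complex_id")
    if (is.null(id)) paste0("complex", i) else id
  }, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  mode <- if (is.null(correspondences)) "by_number" else "mapped"
  mapped <- vector("list", length(footprints))
  unmapped <- vector("list", length(footprints))
  for (i in seq_along(footprints)) {
    fp <- footprints[[i]]
    res <- fp$resno
    co <- if (is.null(correspondences)) NULL else correspondences[[i]]
    if (is.null(co)) {
      mapped[[i]] <- sort(unique(res))
      unmapped[[i]] <- integer(0)
    } else {
      hit <- match(res, co$resno_b)
      unmapped[[i]] <- sort(unique(res[is.na(hit)]))
      mapped[[i]] <- sort(unique(co$resno_a[hit[!is.na(hit)]]))
    }
  }
  names(mapped) <- names(unmapped) <- ids
  overlap_sets <- function(sets) {
    shared <- Reduce(intersect, sets)
    un <- Reduce(union, sets)
    uniq <- lapply(seq_along(sets), function(i) {
      others <- Reduce(union, sets[-i])
      sort(setdiff(sets[[i]], others))
    })
    names(uniq) <- names(sets)
    list(sets = sets, shared = sort(shared),
         unique_per_complex = uniq,
         jaccard = if (length(un) == 0) NA_real_ else length(shared) / length(un))
  }
  out <- c(list(complexes = ids, mode = mode, unmapped = unmapped),
           overlap_sets(mapped))
  if (!is.null(restrict)) {
    rs <- lapply(mapped, function(s) s[s >= restrict[1] & s <= restrict[2]])
    out$restricted <- c(list(name = restrict_name, range = restrict),
                        overlap_sets(rs))
  }
  structure(out, class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Footprint overlap (", x$mode, ") across ",
      paste(x$complexes, collapse = ", "), "\n",
      "  shared residues: ", paste(x$shared, collapse = ", "), "\n",
      "  jaccard: ", signif(x$jaccard, 3), "\n", sep = "")
  if (!is.null(x$restricted))
    cat("  restricted to ", x$restricted$name, " (",
        x$restricted$range[1], "-", x$restricted$range[2], "): shared ",
        paste(x$restricted$shared, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Transplant a receptor onto a reference complex
#'
#' Kabsch-fits the donor complex's MHC heavy chain C-alpha atoms (within
#' a named segment, paired by author number) onto the reference complex,
#' then carries the donor's receptor chain(s) through the same
#' transform.  This puts the receptor into the reference frame so a
#' clash scan against the reference antibody answers whether both can
#' bind at once.
#'
#' @param reference,donor `structure_model` objects, each with an
#'   `mhc_heavy` role.
#' @param ref_map,donor_map their `chain_role_map`s.
#' @param align_segment segment name on `mhc_heavy` used for the fit
#'   (default `"alpha1_alpha2"`, residues 1-180).
#' @param receptor_role role of the donor chains to transplant.
#' @param min_pairs minimum C-alpha correspondences for a reliable fit.
#' @return list with `receptor_atoms` (transformed atom table),
#'   `transform`, `fit_rmsd` (Angstrom), `n_fit`.
#' @export
transplant_receptor <- function(reference, donor, ref_map, donor_map,
                                align_segment = "alpha1_alpha2",
                                receptor_role = "receptor",
                                min_pairs = 30) {
  ref_ca <- select_atoms(reference, ref_map, "mhc_heavy", align_segment)
  don_ca <- select_atoms(donor, donor_map, "mhc_heavy", align_segment)
  ref_ca <- ref_ca[ref_ca$atom == "CA", , drop = FALSE]
  don_ca <- don_ca[don_ca$atom == "CA", , drop = FALSE]
  key <- function(a) paste(a$resno, a$ins)
  common <- intersect(key(ref_ca), key(don_ca))
  if (length(common) < min_pairs)
    stop("only ", length(common), " C-alpha correspondences in segment '",
         align_segment, "' (need >= ", min_pairs, "); fit unreliable")
  ref_ca <- ref_ca[match(common, key(ref_ca)), , drop = FALSE]
  don_ca <- don_ca[match(common, key(don_ca)), , drop = FALSE]
  fit <- kabsch_superpose(as.matrix(ref_ca[, c("x", "y", "z")]),
                          as.matrix(don_ca[, c("x", "y", "z")]))
  rec <- select_atoms(donor, donor_map, receptor_role, heavy_only = FALSE)
  rec[, c("x", "y", "z")] <- apply_transform(fit$transform,
                                             as.matrix(rec[, c("x", "y", "z")]))
  list(receptor_atoms = rec, transform = fit$transform,
       fit_rmsd = fit$rmsd, n_fit = length(common))
}

.segment_label <- function(atoms, segments) {
  lab <- rep("(unassigned)", nrow(atoms))
  if (is.null(segments)) return(lab)
  for (nm in names(segments)) {
    rng <- segments[[nm]]
    lab[atoms$resno >= rng[1] & atoms$resno <= rng[2]] <- nm
  }
  lab
}

#' Scan for van der Waals clashes between two atom sets
#'
#' A pair clashes when its distance is below
#' `r_i + r_j - overlap_threshold` (the MolProbity-style overlap
#' convention; 0.4 Angstrom by default, raise to 1.5 for severe-only
#' scans).  Counts are binned by (probe segment x target segment) and
#' the dominant cell named.
#'
#' @param probe_atoms,target_atoms heavy-atom tables.
#' @param rs a [radius_set()].
#' @param overlap_threshold van der Waals overlap defining a clash,
#'   Angstrom.
#' @param probe_segments,target_segments optional named lists of
#'   inclusive resno ranges (e.g. `list(D1 = c(6, 101), D2 = c(105,
#'   200))`) used to attribute clashes to domains.
#' @return A `clash_report`: list with `pairs` (data frame incl.
#'   `overlap`), `n_clashes`, `matrix` (counts by segment), `dominant`
#'   (`c(probe_segment, target_segment)` of the max cell, or `NULL` when
#'   no clash), `overlap_threshold`.
#' @export
clash_scan <- function(probe_atoms, target_atoms, rs = radius_set(),
                       overlap_threshold = 0.4,
                       probe_segments = NULL, target_segments = NULL) {
  probe_atoms <- probe_atoms[probe_atoms$element != "H", , drop = FALSE]
  target_atoms <- target_atoms[target_atoms$element != "H", , drop = FALSE]
  r_p <- suppressWarnings(vdw_radius(probe_atoms$element, rs))
  r_t <- suppressWarnings(vdw_radius(target_atoms$element, rs))
  bound <- max(r_p, 0) + max(r_t, 0) - overlap_threshold
  hits <- .pairs_within(as.matrix(probe_atoms[, c("x", "y", "z")]),
                        as.matrix(target_atoms[, c("x", "y", "z")]),
                        max(bound, 0), "grid")
  keep <- hits$d < r_p[hits$ia] + r_t[hits$ib] - overlap_threshold
  ia <- hits$ia[keep]; ib <- hits$ib[keep]
  pairs <- .pair_columns(probe_atoms, target_atoms, ia, ib, hits$d[keep])
  pairs$overlap <- r_p[ia] + r_t[ib] - pairs$distance
  pseg <- .segment_label(probe_atoms, probe_segments)[ia]
  tseg <- .segment_label(target_atoms, target_segments)[ib]
  pairs$probe_segment <- pseg
  pairs$target_segment <- tseg
  lev_p <- if (is.null(probe_segments)) unique(pseg) else
    union(names(probe_segments), unique(pseg))
  lev_t <- if (is.null(target_segments)) unique(tseg) else
    union(names(target_segments), unique(tseg))
  m <- table(factor(pseg, levels = lev_p), factor(tseg, levels = lev_t))
  m <- as.matrix(m)
  dominant <- NULL
  if (nrow(pairs)) {
    idx <- which(m == max(m), arr.ind = TRUE)[1, ]
    dominant <- c(probe_segment = rownames(m)[idx[1]],
                  target_segment = colnames(m)[idx[2]])
  }
  structure(list(pairs = pairs, n_clashes = nrow(pairs), matrix = m,
                 dominant = dominant,
                 overlap_threshold = overlap_threshold),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat("Clash scan: ", x$n_clashes, " clash pair(s) at overlap > ",
      x$overlap_threshold, " A\n", sep = "")
  if (!is.null(x$dominant))
    cat("  dominant cell: ", x$dominant[1], " x ", x$dominant[2], " (",
        max(x$matrix), " pairs)\n", sep = "")
  invisible(x)
}

#' Per-position peptide contact profile
#'
#' For each position P1..Pn of the bound peptide (ordered by author
#' number), reports whether any heavy-atom contact to the binder exists
#' at the cutoff, with the partner residues.
#'
#' @param model a `structure_model`.
#' @param map a `chain_role_map` with a `peptide` role.
#' @param binder_roles binder roles (default the antibody chains; use
#'   `"receptor"` for KIR complexes).
#' @param cutoff contact cutoff, Angstrom.
#' @return data frame (`position`, `resno`, `resid`, `contacted`,
#'   `n_partners`) with attribute `partners`, a list of partner tables
#'   per position.
#' @export
peptide_contact_profile <- function(model, map,
                                    binder_roles = c("ab_heavy", "ab_light"),
                                    cutoff = 4.0) {
  pep <- select_atoms(model, map, "peptide")
  if (nrow(pep) == 0) stop("no peptide chain in role map/model")
  binder <- do.call(rbind, lapply(binder_roles, function(r)
    select_atoms(model, map, r)))
  tab <- find_contacts(pep, binder, cutoff = cutoff)
  key <- residue_uid(pep)
  first <- !duplicated(key)
  res <- pep[first, c("chain", "resno", "ins", "resid")]
  res <- res[order(res$resno, res$ins), , drop = FALSE]
  partners <- lapply(seq_len(nrow(res)), function(i)
    contact_partners(tab, res$chain[i], res$resno[i], res$ins[i], side = "a"))
  out <- data.frame(position = seq_len(nrow(res)),
                    resno = res$resno, resid = res$resid,
                    contacted = vapply(partners, nrow, integer(1)) > 0,
                    n_partners = vapply(partners, nrow, integer(1)),
                    stringsAsFactors = FALSE)
  attr(out, "partners") <- partners
  out
}
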