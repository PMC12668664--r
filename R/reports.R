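# Report assembly: one call reproduces a full interface, comparison,
# clash, or peptide analysis, with every resolved parameter embedded in
# the output for provenance.  These functions are the orchestration
# surface behind the thin command-line script shipped in inst/cli.

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.resolved_config <- function(...) {
  c(list(tool = "epiblock",
         version = as.character(utils::packageVersion("epiblock"))),
    list(...))
}

#' Full interface report for one complex
#'
#' Computes the contact table (full and closest-per-residue-pair), the
#' contact map, the buried surface area under both conventions, and the
#' contact-based footprints of binder-on-target and target-on-binder --
#' the complete interface description for an antibody/antigen complex.
#'
#' @param model a `structure_model`.
#' @param map a `chain_role_map`.
#' @param target_roles antigen-side roles (default MHC heavy chain,
#'   peptide, beta-2 microglobulin).
#' @param binder_roles antibody-side roles.
#' @param cutoff contact cutoff, Angstrom.
#' @param sasa_n_points,probe SASA parameters.
#' @param bsa_convention which convention to headline (both are always
#'   computed).
#' @param out_dir optional directory; when given, TSV/JSON files are
#'   written there.
#' @return list with `contacts`, `contacts_reduced`, `contact_map`,
#'   `interface` (the `interface_area`), `bsa` (named both ways),
#'   `epitope`, `paratope`, `config`.
#' @export
interface_report <- function(model, map,
                             target_roles = c("mhc_heavy", "peptide", "beta2m"),
                             binder_roles = c("ab_heavy", "ab_light"),
                             cutoff = 4.0, sasa_n_points = 960,
                             probe = 1.4,
                             bsa_convention = c("half", "total"),
                             out_dir = NULL) {
  bsa_convention <- match.arg(bsa_convention)
  target_roles <- intersect(target_roles, unname(map$roles))
  binder_roles <- intersect(binder_roles, unname(map$roles))
  if (!length(target_roles) || !length(binder_roles))
    stop("role map lacks target or binder roles for an interface report")
  tgt <- do.call(rbind, lapply(target_roles, function(r)
    select_atoms(model, map, r)))
  bnd <- do.call(rbind, lapply(binder_roles, function(r)
    select_atoms(model, map, r)))
  contacts <- find_contacts(tgt, bnd, cutoff = cutoff)
  reduced <- reduce_closest(contacts)
  cmap <- export_contact_map(reduced)
  iface <- interface_area(tgt, bnd, n_points = sasa_n_points, probe = probe,
                          a_id = paste(target_roles, collapse = "+"),
                          b_id = paste(binder_roles, collapse = "+"))
  epi <- epitope_footprint(model, map, "mhc_heavy", binder_roles, cutoff)
  para <- lapply(binder_roles, function(r)
    epitope_footprint(model, map, r,
                      c(target_roles), cutoff))
  names(para) <- binder_roles
  bsa <- c(half = iface$bsa_half, total = iface$bsa_total)
  config <- .resolved_config(
    analysis = "interface", complex = model$id, cutoff = cutoff,
    sasa_n_points = sasa_n_points, probe = probe,
    bsa_convention = bsa_convention,
    target_roles = target_roles, binder_roles = binder_roles)
  out <- list(contacts = contacts, contacts_reduced = reduced,
              contact_map = cmap, interface = iface, bsa = bsa,
              epitope = epi, paratope = para, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(contacts, file.path(out_dir, "contacts.tsv"))
    .write_tsv(reduced, file.path(out_dir, "contacts_reduced.tsv"))
    .write_tsv(as.data.frame(cmap), file.path(out_dir, "contact_map.tsv"))
    .write_tsv(iface$per_residue_burial, file.path(out_dir, "burial.tsv"))
    .report_json(list(config = config, bsa = as.list(bsa),
                      bsa_reported = unname(bsa[bsa_convention]),
                      n_contacts = nrow(contacts),
                      epitope_residues = epi$resno),
                 file.path(out_dir, "interface_report.json"))
  }
  invisible(out)
}

#' Cross-complex footprint comparison report
#'
#' Footprints of each complex's binder on its MHC heavy chain are
#' compared on the shared mature numbering; the five-residue overlap
#' question ("which conserved helix residues do all binders engage?")
#' is answered by the `shared` set.
#'
#' @param models list of `structure_model`s (>= 2).
#' @param maps parallel list of `chain_role_map`s.
#' @param binder_roles_list parallel list of binder-role vectors (e.g.
#'   antibody chains for one complex, `"receptor"` for the others).
#' @param cutoff contact cutoff, Angstrom.
#' @param restrict_segment name of an MHC segment for the restricted
#'   view (default the alpha2-1 helix), or `NULL`.
#' @param out_dir optional output directory.
#' @return the `overlap_report`, with `footprints` and `config`
#'   attached as attributes.
#' @export
compare_report <- function(models, maps, binder_roles_list,
                           cutoff = 4.0, restrict_segment = "alpha2_1",
                           out_dir = NULL) {
  stopifnot(length(models) >= 2, length(maps) == length(models),
            length(binder_roles_list) == length(models))
  fps <- lapply(seq_along(models), function(i)
    epitope_footprint(models[[i]], maps[[i]], "mhc_heavy",
                      binder_roles_list[[i]], cutoff))
  restrict <- NULL
  if (!is.null(restrict_segment))
    restrict <- segment_range(maps[[1]], "mhc_heavy", restrict_segment)
  rep <- compare_footprints(fps, restrict = restrict,
                            restrict_name = restrict_segment)
  config <- .resolved_config(
    analysis = "compare", complexes = vapply(models, `[[`, "", "id"),
    cutoff = cutoff, mapping = rep$mode,
    restrict_segment = restrict_segment)
  attr(rep, "footprints") <- fps
  attr(rep, "config") <- config
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .report_json(list(config = config, shared = rep$shared,
                      jaccard = rep$jaccard,
                      unique_per_complex = rep$unique_per_complex,
                      restricted_shared = if (!is.null(rep$restricted))
                        rep$restricted$shared),
                 file.path(out_dir, "compare_report.json"))
  }
  rep
}

#' Receptor-transplant clash report
#'
#' Superposes the donor complex's MHC platform onto the reference
#' complex, transplants its receptor, and scans for van der Waals
#' clashes against the reference antibody, binned by (receptor domain x
#' antibody domain).  A dominant (D2, V_L) cell is the structural
#' signature of an antibody whose light chain occupies the receptor's
#' D2 site.
#'
#' @param reference,donor `structure_model`s.
#' @param ref_map,donor_map their role maps.
#' @param receptor_segments named list of resno ranges for the receptor
#'   domains; `NULL` splits the receptor numbering range at its
#'   midpoint into D1/D2.
#' @param antibody_segments named list for the antibody chains; the
#'   default takes V_H as residues 1-113 of the heavy chain and V_L as
#'   1-107 of the light chain, with the remainder labelled constant.
#' @param align_segment MHC segment for the superposition fit.
#' @param overlap_threshold clash overlap threshold, Angstrom.
#' @param out_dir optional output directory (also writes the
#'   transplanted receptor as PDB for visual inspection).
#' @return list with `transplant` (transform, fit RMSD), `clash` (the
#'   `clash_report`), `config`.
#' @export
clash_report <- function(reference, donor, ref_map, donor_map,
                         receptor_segments = NULL,
                         antibody_segments = NULL,
                         align_segment = "alpha1_alpha2",
                         overlap_threshold = 0.4, out_dir = NULL) {
  tp <- transplant_receptor(reference, donor, ref_map, donor_map,
                            align_segment = align_segment)
  rec <- tp$receptor_atoms
  if (is.null(receptor_segments)) {
    rng <- range(rec$resno)
    mid <- floor((rng[1] + rng[2]) / 2)
    receptor_segments <- list(D1 = c(rng[1], mid), D2 = c(mid + 1, rng[2]))
  }
  ab_h <- select_atoms(reference, ref_map, "ab_heavy")
  ab_l <- select_atoms(reference, ref_map, "ab_light")
  if (is.null(antibody_segments))
    antibody_segments <- list(VH = c(1, 113), VL = c(1, 107))
  seg_of <- function(atoms, v_name, v_range, c_name) {
    lab <- ifelse(atoms$resno >= v_range[1] & atoms$resno <= v_range[2],
                  v_name, c_name)
    lab
  }
  ab <- rbind(ab_h, ab_l)
  ab_lab <- c(seg_of(ab_h, "VH", antibody_segments$VH, "CH1"),
              seg_of(ab_l, "VL", antibody_segments$VL, "CL"))
  # clash_scan attributes by resno ranges; antibody chains overlap in
  # numbering, so attribute via an explicit per-atom label instead.
  cs <- clash_scan(rec, ab, overlap_threshold = overlap_threshold,
                   probe_segments = receptor_segments)
  if (nrow(cs$pairs)) {
    akey <- paste(ab$chain, ab$resno, ab$ins, ab$atom)
    pkey <- paste(cs$pairs$chain_b, cs$pairs$resno_b, cs$pairs$ins_b,
                  cs$pairs$atom_b)
    cs$pairs$target_segment <- ab_lab[match(pkey, akey)]
    m <- table(factor(cs$pairs$probe_segment,
                      levels = names(receptor_segments)),
               factor(cs$pairs$target_segment,
                      levels = unique(ab_lab)))
    cs$matrix <- as.matrix(m)
    idx <- which(cs$matrix == max(cs$matrix), arr.ind = TRUE)[1, ]
    cs$dominant <- c(probe_segment = rownames(cs$matrix)[idx[1]],
                     target_segment = colnames(cs$matrix)[idx[2]])
  }
  config <- .resolved_config(
    analysis = "clash", reference = reference$id, donor = donor$id,
    align_segment = align_segment, overlap_threshold = overlap_threshold,
    fit_rmsd = tp$fit_rmsd, n_fit = tp$n_fit,
    transform = flatten_transform(tp$transform))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pdb(structure_model(rec, id = paste0(donor$id, "-transplanted")),
              file.path(out_dir, "receptor_transplanted.pdb"))
    .report_json(list(config = config, n_clashes = cs$n_clashes,
                      dominant = as.list(cs$dominant),
                      matrix = as.data.frame.matrix(cs$matrix)),
                 file.path(out_dir, "clash_report.json"))
  }
  list(transplant = tp, clash = cs, config = config)
}

#' Peptide contact profile report
#'
#' @param model a `structure_model`.
#' @param map its `chain_role_map`.
#' @param binder_roles binder roles contacting the peptide.
#' @param cutoff contact cutoff, Angstrom.
#' @param out_dir optional output directory.
#' @return the profile data frame from [peptide_contact_profile()] with
#'   a `config` attribute.
#' @export
peptide_report <- function(model, map,
                           binder_roles = c("ab_heavy", "ab_light"),
                           cutoff = 4.0, out_dir = NULL) {
  prof <- peptide_contact_profile(model, map, binder_roles, cutoff)
  config <- .resolved_config(analysis = "peptide", complex = model$id,
                             cutoff = cutoff, binder_roles = binder_roles)
  attr(prof, "config") <- config
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(prof, file.path(out_dir, "peptide_profile.tsv"))
    .report_json(list(config = config,
                      contacted_positions = prof$position[prof$contacted]),
                 file.path(out_dir, "peptide_report.json"))
  }
  prof
}
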