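# Regression analyses against the deposited coordinate accessions.
# The package never fetches files: users place the deposited models
# (9D73, 9D74, 8TQ6, 1EFX, 3VH8, as PDB or mmCIF) in a directory and
# point these functions at it.

#' Locate a directory of deposited coordinate files
#'
#' Checks, in order: the `dir` argument, the option
#' `epiblock.deposited_dir`, the environment variable
#' `EPIBLOCK_DEPOSITED_DIR`.
#'
#' @param dir optional explicit directory.
#' @return the directory path, or `NA_character_` when none is
#'   configured or present.
#' @export
deposited_dir <- function(dir = NULL) {
  cand <- c(dir, getOption("epiblock.deposited_dir"),
            Sys.getenv("EPIBLOCK_DEPOSITED_DIR", unset = NA))
  cand <- cand[!is.na(cand) & nzchar(cand)]
  for (d in cand) if (dir.exists(d)) return(d)
  NA_character_
}

.find_accession <- function(dir, acc) {
  for (ext in c(".pdb", ".ent", ".cif")) {
    for (nm in c(tolower(acc), toupper(acc))) {
      p <- file.path(dir, paste0(nm, ext))
      if (file.exists(p)) return(p)
    }
  }
  stop("accession ", acc, " not found in ", dir,
       " (expected e.g. ", tolower(acc), ".pdb or .cif)")
}

#' Load a deposited accession with roles assigned
#'
#' @param acc accession code (e.g. `"9D73"`).
#' @param dir directory containing the file (see [deposited_dir()]).
#' @param hints optional chain-role hints passed to [assign_roles()].
#' @return list with `model` and `map`.
#' @export
load_accession <- function(acc, dir = deposited_dir(), hints = NULL) {
  if (is.na(dir)) stop("no deposited-structure directory configured")
  model <- parse_structure(.find_accession(dir, acc), id = toupper(acc))
  list(model = model, map = assign_roles(model, hints = hints))
}

#' Regression analyses over the deposited structures
#'
#' Recomputes, from user-supplied deposited coordinate files, the
#' headline structural numbers: protein-residue counts of the two
#' cryo-EM models, the antibody and receptor interface areas, the
#' three-way footprint overlap on the alpha2-1 helix, the partner count
#' of the central epitope lysine (residue 146), the peptide contact
#' profiles, the all-atom crystal-versus-cryo-EM RMSD, and the
#' receptor-transplant clash scan.
#'
#' @param dir directory of deposited files (see [deposited_dir()]).
#' @param hints optional named list of per-accession chain-role hints.
#' @param sasa_n_points SASA lattice size for the interface areas.
#' @return named list of results.
#' @export
run_accession_regressions <- function(dir = deposited_dir(), hints = list(),
                                      sasa_n_points = 960) {
  if (is.na(dir)) stop("no deposited-structure directory configured")
  get <- function(acc) load_accession(acc, dir, hints[[acc]])
  m9d73 <- get("9D73"); m9d74 <- get("9D74")
  m1efx <- get("1EFX"); m3vh8 <- get("3VH8"); m8tq6 <- get("8TQ6")

  iface_of <- function(x, binder_roles) {
    tgt <- do.call(rbind, lapply(
      intersect(c("mhc_heavy", "peptide", "beta2m"), unname(x$map$roles)),
      function(r) select_atoms(x$model, x$map, r)))
    bnd <- do.call(rbind, lapply(binder_roles, function(r)
      select_atoms(x$model, x$map, r)))
    interface_area(tgt, bnd, n_points = sasa_n_points)
  }
  ab_roles <- c("ab_heavy", "ab_light")
  ia_ab <- iface_of(m9d73, ab_roles)
  ia_2dl2 <- iface_of(m1efx, "receptor")
  ia_3dl1 <- iface_of(m3vh8, "receptor")

  fps <- list(
    epitope_footprint(m9d73$model, m9d73$map, binder_roles = ab_roles),
    epitope_footprint(m1efx$model, m1efx$map, binder_roles = "receptor"),
    epitope_footprint(m3vh8$model, m3vh8$map, binder_roles = "receptor"))
  ov <- compare_footprints(fps, restrict = c(141, 155),
                           restrict_name = "alpha2_1")

  tab <- find_contacts(
    select_atoms(m9d73$model, m9d73$map, "mhc_heavy"),
    select_atoms(m9d73$model, m9d73$map, "ab_light"))
  k146 <- contact_partners(tab, role_chain(m9d73$map, "mhc_heavy"), 146)

  prof_ab <- peptide_contact_profile(m9d73$model, m9d73$map, ab_roles)
  prof_kir <- peptide_contact_profile(m1efx$model, m1efx$map, "receptor")

  # All shared atoms (role + residue + atom name intersection) between
  # one crystallographic copy of the X-ray model and the cryo-EM model.
  shared_rmsd <- local({
    roles <- intersect(unname(m9d73$map$roles), unname(m8tq6$map$roles))
    roles <- setdiff(roles, "other")
    a_list <- list(); b_list <- list()
    for (r in roles) {
      a <- select_atoms(m9d73$model, m9d73$map, r)
      b <- select_atoms(m8tq6$model, m8tq6$map, r)
      ka <- paste(a$resno, a$ins, a$atom); kb <- paste(b$resno, b$ins, b$atom)
      common <- intersect(ka, kb)
      a_list[[r]] <- a[match(common, ka), , drop = FALSE]
      b_list[[r]] <- b[match(common, kb), , drop = FALSE]
    }
    a <- do.call(rbind, a_list); b <- do.call(rbind, b_list)
    rmsd_coords(as.matrix(a[, c("x", "y", "z")]),
                as.matrix(b[, c("x", "y", "z")]), superpose_first = TRUE)
  })

  clash <- clash_report(m9d73$model, m1efx$model, m9d73$map, m1efx$map)

  list(protein_residues_9d73 = count_protein_residues(m9d73$model),
       protein_residues_9d74 = count_protein_residues(m9d74$model),
       bsa_half_9d73 = ia_ab$bsa_half,
       bsa_half_1efx = ia_2dl2$bsa_half,
       bsa_half_3vh8 = ia_3dl1$bsa_half,
       bsa_total_9d73 = ia_ab$bsa_total,
       shared_footprint = ov$shared,
       shared_footprint_alpha2_1 = ov$restricted$shared,
       k146_vl_partners = nrow(k146),
       peptide_positions_9d73 = prof_ab$position[prof_ab$contacted],
       peptide_positions_1efx = prof_kir$position[prof_kir$contacted],
       allatom_rmsd_8tq6_vs_9d73 = shared_rmsd,
       clash_dominant = clash$clash$dominant,
       clash_count = clash$clash$n_clashes)
}
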