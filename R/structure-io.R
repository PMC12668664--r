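# Structure input/output and semantic chain roles.
#
# The in-memory representation is a flat atom table (one row per atom) in
# the style of bio3d, wrapped in a `structure_model` object.  Author
# residue numbering is the coordinate convention throughout: epitope
# residues on MHC class I are cited by mature-protein numbers (K146 and
# friends), so sequential indices are never substituted for them.

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

.WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

.atom_template <- function() {
  data.frame(chain = character(), resno = integer(), ins = character(),
             resid = character(), atom = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), b = numeric(), altloc = character(),
             het = logical(), stringsAsFactors = FALSE)
}

#' Construct a structure model from an atom table
#'
#' @param atoms data frame with columns `chain`, `resno`, `ins`, `resid`,
#'   `atom`, `element`, `x`, `y`, `z`, and optionally `occ`, `b`,
#'   `altloc`, `het` (filled with defaults when absent).
#' @param id accession or label for the model.
#' @param model_number integer model number (single-model objects only).
#' @return A `structure_model`: a list with elements `id`, `atoms`,
#'   `model_number`.
#' @export
structure_model <- function(atoms, id = "model", model_number = 1L) {
  required <- c("chain", "resno", "ins", "resid", "atom", "element",
                "x", "y", "z")
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  miss <- setdiff(required, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("structure model must contain at least one atom")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  structure(list(id = id,
                 atoms = atoms[, c(required[1:6], "x", "y", "z",
                                   "occ", "b", "altloc", "het")],
                 model_number = as.integer(model_number)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model '", x$id, "': ", nrow(a), " atoms, ",
      length(unique(a$chain)), " chain(s) [",
      paste(unique(a$chain), collapse = " "), "], ",
      count_protein_residues(x), " standard protein residues\n", sep = "")
  invisible(x)
}

# Unique residue key (chain + author number + insertion code)
residue_uid <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
}

.normalize_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy) | elesy == "", NA, elesy)))
  need <- is.na(el)
  if (any(need)) {
    # Derive from atom name: strip digits/primes, two-letter symbols only
    # for a known set so "CA" stays carbon (calcium arrives as HETATM
    # with element column set in practice).
    nm <- gsub("[0-9*']", "", toupper(trimws(elety[need])))
    two <- substr(nm, 1, 2)
    guess <- ifelse(two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA"),
                    two, substr(nm, 1, 1))
    el[need] <- guess
  }
  el
}

# Altloc policy: for each (chain, resno, ins, atom name) keep the
# highest-occupancy conformer; ties resolve to altloc 'A'.
.resolve_altloc <- function(atoms) {
  alt <- atoms$altloc
  if (!any(nzchar(alt))) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occ, ifelse(nzchar(alt), alt, "A"))
  atoms <- atoms[ord, , drop = FALSE]
  key <- key[ord]
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

#' Read macromolecular coordinates from PDB or mmCIF
#'
#' Parses the first model of a coordinate file into a [structure_model()].
#' HETATM records are retained with the `het` flag set; waters are
#' excluded by default.  Where alternate locations exist, the
#' highest-occupancy conformer is kept (ties resolve to altloc 'A').
#'
#' @param path path to a `.pdb`/`.ent` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @param keep_waters keep water residues (HOH/WAT/DOD)?
#' @param id label for the model; defaults to the file stem.
#' @return A `structure_model`.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(build_ideal_helix(5), f)
#' m <- parse_structure(f)
#' count_protein_residues(m)
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                            keep_waters = FALSE, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0 || !any(at$type == "ATOM")) {
    stop("no ATOM records in '", path, "' (empty structure)")
  }
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    atom = at$elety,
    element = .normalize_element(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  if (!keep_waters) atoms <- atoms[!(atoms$resid %in% .WATER_RESID), , drop = FALSE]
  if (nrow(atoms) == 0) stop("no atoms left after filtering in '", path, "'")
  atoms <- .resolve_altloc(atoms)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  structure_model(atoms, id = id)
}

#' Count standard protein residues in a model
#'
#' Residues whose 3-letter code is one of the 20 standard amino acids,
#' counted by unique (chain, author number, insertion code).  HETATM-only
#' residues (waters, glycans, modified residues) do not count.
#'
#' @param model a `structure_model`.
#' @return integer count.
#' @export
count_protein_residues <- function(model) {
  if (is.null(model) || nrow(model$atoms) == 0) return(0L)
  a <- model$atoms
  keep <- a$resid %in% .STANDARD_AA & !a$het
  length(unique(residue_uid(a[keep, , drop = FALSE])))
}

# ---- chain roles -----------------------------------------------------------

.ROLES <- c("mhc_heavy", "beta2m", "peptide", "ab_heavy", "ab_light",
            "receptor", "other")

.default_segments <- function() {
  data.frame(role = "mhc_heavy",
             segment = c("alpha1_alpha2", "alpha2_1", "alpha2_1_ext",
                         "md_fragment"),
             start = c(1L, 141L, 131L, 127L),
             end = c(180L, 155L, 155L, 158L),
             stringsAsFactors = FALSE)
}

#' Construct a chain role map
#'
#' @param roles named character vector mapping chain id to a role among
#'   `mhc_heavy`, `beta2m`, `peptide`, `ab_heavy`, `ab_light`,
#'   `receptor`, `other`.
#' @param segments data frame with columns `role`, `segment`, `start`,
#'   `end` giving inclusive author-number ranges of named domain
#'   segments; defaults register `alpha1_alpha2` (1-180) and three
#'   alpha2-1 helix definitions in use in the field (`alpha2_1` 141-155,
#'   `alpha2_1_ext` 131-155, `md_fragment` 127-158) on the MHC heavy
#'   chain.
#' @return A `chain_role_map`.
#' @export
chain_role_map <- function(roles, segments = .default_segments()) {
  bad <- setdiff(unname(roles), .ROLES)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    stop("roles must be a named vector keyed by chain id")
  structure(list(roles = roles, segments = segments),
            class = "chain_role_map")
}

#' @export
print.chain_role_map <- function(x, ...) {
  cat("chain_role_map:\n")
  for (ch in names(x$roles)) cat("  chain ", ch, " -> ", x$roles[[ch]], "\n", sep = "")
  if (nrow(x$segments)) {
    cat("segments:\n")
    apply(x$segments, 1, function(s)
      cat("  ", s[["role"]], "/", s[["segment"]], ": ",
          s[["start"]], "-", s[["end"]], "\n", sep = ""))
  }
  invisible(x)
}

role_chain <- function(map, role) {
  ch <- names(map$roles)[map$roles == role]
  if (length(ch) == 0) stop("no chain with role '", role, "' in role map")
  ch
}

segment_range <- function(map, role, segment) {
  s <- map$segments[map$segments$role == role & map$segments$segment == segment, ]
  if (nrow(s) != 1) stop("unknown segment '", segment, "' for role '", role, "'")
  c(s$start, s$end)
}

#' Assign semantic roles to chains
#'
#' Explicit `hints` always win.  For the remaining chains a length-based
#' heuristic is applied: a chain of at most 15 residues is the peptide; a
#' chain of 95-105 residues is beta-2 microglobulin; the longest chain of
#' at least 180 residues whose numbering covers the alpha1-alpha2
#' platform (reaching residue 180) is the MHC heavy chain.  If exactly
#' two chains remain, the longer becomes the antibody heavy chain and the
#' shorter the light chain; a single remaining chain is called the
#' receptor.  Any rule satisfied by more than one chain is an error
#' listing the candidates, which must then be resolved through `hints`.
#'
#' @param model a `structure_model`.
#' @param hints optional named character vector, chain id -> role.
#' @param segments optional extra segment rows appended to the defaults
#'   (data frame with `role`, `segment`, `start`, `end`).
#' @return A `chain_role_map`.
#' @export
assign_roles <- function(model, hints = NULL, segments = NULL) {
  a <- model$atoms[!model$atoms$het, , drop = FALSE]
  chains <- unique(model$atoms$chain)
  nres <- vapply(chains, function(ch) {
    sub <- a[a$chain == ch & a$resid %in% .STANDARD_AA, , drop = FALSE]
    length(unique(residue_uid(sub)))
  }, integer(1))
  maxno <- vapply(chains, function(ch) {
    sub <- a[a$chain == ch, , drop = FALSE]
    if (nrow(sub) == 0) return(NA_integer_)
    max(sub$resno)
  }, integer(1))
  names(nres) <- names(maxno) <- chains

  roles <- setNames(rep(NA_character_, length(chains)), chains)
  if (!is.null(hints)) {
    bad <- setdiff(names(hints), chains)
    if (length(bad)) stop("hint chain(s) not in model: ", paste(bad, collapse = ", "))
    roles[names(hints)] <- unname(hints)
  }
  free <- function() names(roles)[is.na(roles)]
  claim_one <- function(cand, role) {
    if (length(cand) > 1) {
      stop("ambiguous ", role, " assignment: chains ",
           paste(cand, collapse = ", "),
           " all qualify; provide hints to resolve")
    }
    if (length(cand) == 1) roles[cand] <<- role
  }
  pep <- free()[nres[free()] >= 1 & nres[free()] <= 15]
  claim_one(pep, "peptide")
  b2m <- free()[nres[free()] >= 95 & nres[free()] <= 105]
  claim_one(b2m, "beta2m")
  mhc <- free()[nres[free()] >= 180 & !is.na(maxno[free()]) & maxno[free()] >= 180]
  if (length(mhc) > 1) {
    mx <- mhc[nres[mhc] == max(nres[mhc])]
    if (length(mx) > 1) {
      stop("ambiguous mhc_heavy assignment: chains ",
           paste(mx, collapse = ", "), "; provide hints to resolve")
    }
    mhc <- mx
  }
  claim_one(mhc, "mhc_heavy")
  rest <- free()[nres[free()] > 0]
  if (length(rest) == 2) {
    if (nres[rest[1]] == nres[rest[2]]) {
      stop("ambiguous antibody chain assignment: chains ",
           paste(rest, collapse = ", "),
           " have equal length; provide hints to resolve")
    }
    roles[rest[which.max(nres[rest])]] <- "ab_heavy"
    roles[rest[which.min(nres[rest])]] <- "ab_light"
  } else if (length(rest) == 1) {
    roles[rest] <- "receptor"
  } else if (length(rest) > 2) {
    stop("cannot assign roles to ", length(rest), " remaining chains (",
         paste(rest, collapse = ", "), "); provide hints")
  }
  roles[is.na(roles)] <- "other"
  seg <- .default_segments()
  if (!is.null(segments)) seg <- rbind(seg, segments)
  chain_role_map(roles, seg)
}

#' Select atoms by role and optional segment
#'
#' @param model a `structure_model`.
#' @param map a `chain_role_map`.
#' @param role one of the roles present in `map`.
#' @param segment optional segment name registered for that role; the
#'   selection is then restricted to its inclusive author-number range.
#' @param heavy_only drop hydrogens (element H)?
#' @return The atom-table subset (rows of `model$atoms`).
#' @export
select_atoms <- function(model, map, role, segment = NULL, heavy_only = TRUE) {
  ch <- role_chain(map, role)
  a <- model$atoms[model$atoms$chain %in% ch, , drop = FALSE]
  if (!is.null(segment)) {
    rng <- segment_range(map, role, segment)
    a <- a[a$resno >= rng[1] & a$resno <= rng[2], , drop = FALSE]
  }
  if (heavy_only) a <- a[a$element != "H", , drop = FALSE]
  a
}

#' Write a model as fixed-column PDB
#'
#' Coordinates are written to three decimals; the output is parseable by
#' [parse_structure()].  Chain ids longer than one character do not fit
#' the PDB dialect and raise an error suggesting mmCIF.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  if (any(nchar(a$chain) > 1)) {
    stop("chain id(s) longer than one character (",
         paste(unique(a$chain[nchar(a$chain) > 1]), collapse = ", "),
         ") cannot be written as fixed-column PDB; use mmCIF")
  }
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$atom, chain = a$chain,
    insert = ifelse(nzchar(a$ins), a$ins, NA),
    alt = ifelse(nzchar(a$altloc), a$altloc, NA),
    o = a$occ, b = a$b, elesy = a$element))
  invisible(path)
}
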