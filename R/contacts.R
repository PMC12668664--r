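# Heavy-atom inter-group contacts at a distance cutoff, classification,
# closest-contact reduction, and contact-map export.

.pair_columns <- function(a_atoms, b_atoms, ia, ib, d) {
  data.frame(chain_a = a_atoms$chain[ia], resno_a = a_atoms$resno[ia],
             ins_a = a_atoms$ins[ia], resid_a = a_atoms$resid[ia],
             atom_a = a_atoms$atom[ia], element_a = a_atoms$element[ia],
             chain_b = b_atoms$chain[ib], resno_b = b_atoms$resno[ib],
             ins_b = b_atoms$ins[ib], resid_b = b_atoms$resid[ib],
             atom_b = b_atoms$atom[ib], element_b = b_atoms$element[ib],
             distance = d, stringsAsFactors = FALSE)
}

.pairs_within <- function(a_xyz, b_xyz, cutoff, method) {
  na <- nrow(a_xyz); nb <- nrow(b_xyz)
  if (na == 0 || nb == 0)
    return(list(ia = integer(), ib = integer(), d = numeric()))
  if (method == "brute") {
    d2 <- outer(rowSums(a_xyz^2), rowSums(b_xyz^2), "+") -
      2 * tcrossprod(a_xyz, b_xyz)
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    return(list(ia = hit[, 1], ib = hit[, 2],
                d = sqrt(pmax(0, d2[hit]))))
  }
  # Spatial grid: bin both sets into cubic cells of edge `cutoff`; each A
  # atom is tested only against B atoms of the 27 surrounding cells.
  cell <- function(xyz) floor(sweep(xyz, 2, c(0, 0, 0)) / cutoff)
  ca <- cell(a_xyz); cb <- cell(b_xyz)
  key_b <- paste(cb[, 1], cb[, 2], cb[, 3])
  b_by_cell <- split(seq_len(nb), key_b)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ia_all <- integer(0); ib_all <- integer(0); d_all <- numeric(0)
  key_a_off <- lapply(seq_len(nrow(off)), function(k)
    paste(ca[, 1] + off[k, 1], ca[, 2] + off[k, 2], ca[, 3] + off[k, 3]))
  for (k in seq_len(nrow(off))) {
    cand <- b_by_cell[key_a_off[[k]]]
    len <- lengths(cand)
    if (!any(len)) next
    ia <- rep(seq_len(na), len)
    ib <- unlist(cand, use.names = FALSE)
    d2 <- rowSums((a_xyz[ia, , drop = FALSE] - b_xyz[ib, , drop = FALSE])^2)
    keep <- d2 <= cutoff^2 + 1e-12
    ia_all <- c(ia_all, ia[keep]); ib_all <- c(ib_all, ib[keep])
    d_all <- c(d_all, sqrt(d2[keep]))
  }
  list(ia = ia_all, ib = ib_all, d = d_all)
}

.empty_contact_table <- function(cutoff, reduction = "all") {
  tab <- .pair_columns(.atom_template(), .atom_template(),
                       integer(), integer(), numeric())
  tab$class <- character()
  structure(tab, class = c("contact_table", "data.frame"),
            cutoff = cutoff, reduction = reduction)
}

#' Find heavy-atom contacts between two atom groups
#'
#' All inter-group atom pairs within `cutoff` Angstrom (Euclidean), the
#' criterion used for interface contact tables.  The default spatial-grid
#' acceleration returns results identical to the brute-force all-pairs
#' scan (`method = "brute"`), which is retained as an oracle.
#'
#' @param a_atoms,b_atoms atom tables (heavy atoms; hydrogens are
#'   dropped).
#' @param cutoff distance cutoff, Angstrom (default 4.0).
#' @param method `"grid"` or `"brute"`.
#' @return A `contact_table`: data frame of contact records (residue and
#'   atom identities of both partners, `distance`, advisory `class`) with
#'   attributes `cutoff` and `reduction = "all"`.  Empty groups give an
#'   empty table, not an error.
#' @export
find_contacts <- function(a_atoms, b_atoms, cutoff = 4.0,
                          method = c("grid", "brute")) {
  method <- match.arg(method)
  a_atoms <- a_atoms[a_atoms$element != "H", , drop = FALSE]
  b_atoms <- b_atoms[b_atoms$element != "H", , drop = FALSE]
  if (nrow(a_atoms) == 0 || nrow(b_atoms) == 0)
    return(.empty_contact_table(cutoff))
  hits <- .pairs_within(as.matrix(a_atoms[, c("x", "y", "z")]),
                        as.matrix(b_atoms[, c("x", "y", "z")]),
                        cutoff, method)
  tab <- .pair_columns(a_atoms, b_atoms, hits$ia, hits$ib, hits$d)
  tab <- tab[order(tab$chain_a, tab$resno_a, tab$ins_a, tab$atom_a,
                   tab$chain_b, tab$resno_b, tab$ins_b, tab$atom_b), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab$class <- classify_contacts(tab)
  structure(tab, class = c("contact_table", "data.frame"),
            cutoff = cutoff, reduction = "all")
}

.CARBOXYLATE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.BASIC_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                 HIS = c("ND1", "NE2"))

.is_in <- function(resid, atom, table) {
  mapply(function(r, a) !is.null(table[[r]]) && a %in% table[[r]], resid, atom,
         USE.NAMES = FALSE)
}

#' Classify contacts by simple chemistry
#'
#' Advisory classification on top of the pure distance criterion: a
#' salt bridge when one atom belongs to an Asp/Glu carboxylate and the
#' other to a Lys/Arg/His basic nitrogen within 4.0 Angstrom; a hydrogen
#' bond when both atoms are N or O within 3.5 Angstrom; otherwise
#' nonbonded.  Salt bridge takes precedence over hydrogen bond.  No
#' angular criteria are applied (deposited models lack hydrogens).
#'
#' @param records a `contact_table` or compatible data frame.
#' @return character vector: `"salt_bridge"`, `"hbond"`, or
#'   `"nonbonded"`.
#' @export
classify_contacts <- function(records) {
  if (nrow(records) == 0) return(character(0))
  acid_a <- .is_in(records$resid_a, records$atom_a, .CARBOXYLATE)
  acid_b <- .is_in(records$resid_b, records$atom_b, .CARBOXYLATE)
  base_a <- .is_in(records$resid_a, records$atom_a, .BASIC_N)
  base_b <- .is_in(records$resid_b, records$atom_b, .BASIC_N)
  salt <- ((acid_a & base_b) | (acid_b & base_a)) & records$distance <= 4.0
  hb <- records$element_a %in% c("N", "O") &
    records$element_b %in% c("N", "O") & records$distance <= 3.5
  ifelse(salt, "salt_bridge", ifelse(hb, "hbond", "nonbonded"))
}

#' Reduce a contact table to the closest contact per residue pair
#'
#' Keeps the minimum-distance record for every (residue A, residue B)
#' pair, the presentation used in published interface tables.  Distance
#' ties break deterministically by (atom A name, atom B name).
#'
#' @param table a `contact_table`.
#' @return A `contact_table` with `reduction = "closest_per_residue_pair"`.
#' @export
reduce_closest <- function(table) {
  if (nrow(table) == 0) {
    attr(table, "reduction") <- "closest_per_residue_pair"
    return(table)
  }
  key <- paste(table$chain_a, table$resno_a, table$ins_a,
               table$chain_b, table$resno_b, table$ins_b, sep = "|")
  ord <- order(key, table$distance, table$atom_a, table$atom_b)
  out <- table[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  out <- out[order(out$chain_a, out$resno_a, out$ins_a,
                   out$chain_b, out$resno_b, out$ins_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(table), cutoff = attr(table, "cutoff"),
            reduction = "closest_per_residue_pair")
}

#' Distinct partner residues of a focal residue
#'
#' @param table a `contact_table`.
#' @param chain,resno,ins identity of the focal residue.
#' @param side which side of the table the focal residue lives on
#'   (`"a"` or `"b"`).
#' @param partner_chains optional restriction of partners to the given
#'   chain ids.
#' @return data frame of distinct partner residues with contact counts
#'   (`chain`, `resno`, `ins`, `resid`, `n_contacts`); empty when the
#'   focal residue is absent.
#' @export
contact_partners <- function(table, chain, resno, ins = "",
                             side = c("a", "b"), partner_chains = NULL) {
  side <- match.arg(side)
  fc <- paste0(c("chain_", "resno_", "ins_"), side)
  other <- if (side == "a") "b" else "a"
  oc <- paste0(c("chain_", "resno_", "ins_", "resid_"), other)
  sel <- table[[fc[1]]] == chain & table[[fc[2]]] == resno &
    table[[fc[3]]] == ins
  sub <- table[sel, , drop = FALSE]
  if (!is.null(partner_chains))
    sub <- sub[sub[[oc[1]]] %in% partner_chains, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(chain = character(), resno = integer(),
                      ins = character(), resid = character(),
                      n_contacts = integer(), stringsAsFactors = FALSE))
  key <- paste(sub[[oc[1]]], sub[[oc[2]]], sub[[oc[3]]], sep = "|")
  first <- !duplicated(key)
  out <- data.frame(chain = sub[[oc[1]]][first], resno = sub[[oc[2]]][first],
                    ins = sub[[oc[3]]][first], resid = sub[[oc[4]]][first],
                    n_contacts = as.integer(table(key)[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$chain, out$resno, out$ins), , drop = FALSE]
}

#' Residue-by-residue contact incidence matrix
#'
#' Rows are side-A residues in sequence order, columns side-B residues;
#' entries are 1 where the reduced table records a contact.  Row sums
#' therefore equal each A residue's distinct-partner count.
#'
#' @param table a `contact_table` (reduce with [reduce_closest()] first
#'   for a one-record-per-pair map).
#' @return integer matrix with dimnames `"chain:resno:resid"`.
#' @export
export_contact_map <- function(table) {
  lab <- function(ch, no, ins, res) paste0(ch, ":", no, ins, ":", res)
  if (nrow(table) == 0)
    return(matrix(0L, 0, 0))
  ra <- lab(table$chain_a, table$resno_a, table$ins_a, table$resid_a)
  rb <- lab(table$chain_b, table$resno_b, table$ins_b, table$resid_b)
  ord_a <- order(table$chain_a, table$resno_a, table$ins_a)
  ord_b <- order(table$chain_b, table$resno_b, table$ins_b)
  rows <- unique(ra[ord_a]); cols <- unique(rb[ord_b])
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(match(ra, rows), match(rb, cols))] <- 1L
  m
}
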