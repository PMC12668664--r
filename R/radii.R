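#' Van der Waals radius set
#'
#' A lookup from element symbol to van der Waals radius, plus the solvent
#' probe radius, used by the SASA and clash operators.  Defaults are the
#' Chothia-type values common in interface work: C 1.70, N 1.55, O 1.52,
#' S 1.80 Angstrom, with a 1.4 Angstrom water probe.
#'
#' @param lookup named numeric vector of radii (Angstrom) keyed by
#'   normalized element symbol.
#' @param default_radius radius assigned to elements absent from `lookup`
#'   when `strict = FALSE` lookups are performed.
#' @param probe_radius solvent probe radius in Angstrom.
#' @return An object of class `radius_set`.
#' @examples
#' rs <- radius_set()
#' vdw_radius(c("C", "N", "O"), rs)
#' @export
radius_set <- function(lookup = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                                  H = 1.20, P = 1.80, SE = 1.90),
                       default_radius = 1.70,
                       probe_radius = 1.4) {
  stopifnot(is.numeric(lookup), length(lookup) > 0, !is.null(names(lookup)))
  if (any(lookup <= 0)) stop("all van der Waals radii must be > 0")
  if (default_radius <= 0) stop("default_radius must be > 0")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  names(lookup) <- toupper(names(lookup))
  structure(list(lookup = lookup,
                 default_radius = default_radius,
                 probe_radius = probe_radius),
            class = "radius_set")
}

#' Look up van der Waals radii by element
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param rs a [radius_set()].
#' @param strict if `TRUE`, unknown elements are an error; otherwise they
#'   receive `rs$default_radius` with a warning.
#' @return numeric vector of radii, Angstrom.
#' @export
vdw_radius <- function(element, rs = radius_set(), strict = FALSE) {
  stopifnot(inherits(rs, "radius_set"))
  el <- toupper(trimws(element))
  r <- unname(rs$lookup[el])
  missing <- is.na(r)
  if (any(missing)) {
    unknown <- unique(el[missing])
    if (strict) {
      stop("unknown element(s) in radius set: ", paste(unknown, collapse = ", "))
    }
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using default radius ", rs$default_radius, " Angstrom")
    r[missing] <- rs$default_radius
  }
  r
}

#' @export
print.radius_set <- function(x, ...) {
  cat("Van der Waals radius set (", length(x$lookup), " elements, probe ",
      x$probe_radius, " A)\n", sep = "")
  print(x$lookup)
  invisible(x)
}
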