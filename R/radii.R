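#' Van der Waals radii tables
#'
#' Element-keyed heavy-atom radii (Angstrom) used for the contact-distance
#' rule and for SASA.  Two published sets are shipped: `"bondi"` (Bondi 1964
#' element radii, the default) and `"chothia"` (Chothia 1976 protein-atom
#' radii collapsed to elements).  The table used is recorded on every
#' structure so downstream numbers are reproducible.
#'
#' @param name `"bondi"` or `"chothia"`, or a named numeric vector of radii
#'   in Angstrom keyed by uppercase element symbol (used as-is).
#' @return Named numeric vector of radii with a `"radii_table"` attribute.
#' @export
#' @examples
#' radii_table("bondi")[["C"]]
radii_table <- function(name = "bondi") {
  if (is.numeric(name)) {
    if (is.null(names(name)) || any(name <= 0))
      stop("custom radii table must be a named numeric vector with positive values")
    tab <- name
    names(tab) <- toupper(names(tab))
    attr(tab, "radii_table") <- "custom"
    return(tab)
  }
  name <- match.arg(name, c("bondi", "chothia"))
  tab <- switch(name,
    bondi = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
              SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
              FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31, "NA" = 2.27,
              K = 2.75, MN = 2.00, CU = 1.40),
    chothia = c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
                SE = 1.90, F = 1.47, CL = 1.77, BR = 1.85, I = 1.98,
                FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31, "NA" = 2.27,
                K = 2.75, MN = 2.00, CU = 1.40))
  attr(tab, "radii_table") <- name
  tab
}

#' Assign van der Waals radii to every atom
#'
#' @param s A [read_structure()] structure.
#' @param table Radii table name or named numeric vector, see [radii_table()].
#' @param default Fallback radius (Angstrom) for elements missing from the
#'   table; `NA` (default) makes unknown elements an error.
#' @return The structure with its `radius` column filled; the table identity
#'   is stored in `s$radii_table`.
#' @export
assign_radii <- function(s, table = "bondi", default = NA_real_) {
  stopifnot(inherits(s, "wet_structure"))
  tab <- radii_table(table)
  el <- toupper(s$atoms$element)
  r <- unname(tab[el])
  if (anyNA(r)) {
    if (is.na(default)) {
      stop("no radius for element(s): ",
           paste(unique(el[is.na(r)]), collapse = ", "),
           " (supply `default` or extend the table)")
    }
    r[is.na(r)] <- default
  }
  s$atoms$radius <- r
  s$radii_table <- attr(tab, "radii_table")
  s
}
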