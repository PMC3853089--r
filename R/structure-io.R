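WATER_RESNAMES <- c("HOH", "WAT", "DOD")

new_structure <- function(atoms, id = NA_character_, resolution = NA_real_,
                          radii_table = NULL) {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id, resolution = resolution,
                 radii_table = radii_table),
            class = "wet_structure")
}

#' Build a structure object from an atom table
#'
#' Programmatic constructor used by the synthetic generators and by tests.
#' Minimal required columns: `chain`, `resno`, `resname`, `atom` (name),
#' `element`, `x`, `y`, `z`.  Optional: `ins`, `occ`, `b`, `radius`.
#' Hydrogens are rejected (the model is heavy-atom only).
#'
#' @param atoms data.frame of atom records.
#' @param id Structure identifier carried through reports.
#' @return A `wet_structure`.
#' @export
structure_from_atoms <- function(atoms, id = NA_character_) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(toupper(atoms$element) %in% c("H", "D")))
    stop("hydrogen atoms are not allowed (heavy-atom model)")
  n <- nrow(atoms)
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  atoms$element <- toupper(atoms$element)
  atoms$is_water <- atoms$resname %in% WATER_RESNAMES
  atoms$atom_id <- seq_len(n)
  cols <- c("atom_id", "chain", "resno", "ins", "resname", "atom", "element",
            "x", "y", "z", "occ", "b", "radius", "is_water")
  new_structure(atoms[, cols], id = id)
}

# ---------------------------------------------------------------------------
# PDB reading
# ---------------------------------------------------------------------------

read_input_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    return(readLines(x, warn = FALSE))
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

num_field <- function(txt, lineno, what) {
  v <- suppressWarnings(as.numeric(txt))
  bad <- is.na(v) & nzchar(trimws(txt))
  if (any(bad)) {
    stop(sprintf("malformed %s field in coordinate record at line %d: '%s'",
                 what, lineno[bad][1], trimws(txt[bad][1])))
  }
  v
}

element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  known2 <- c("FE", "ZN", "MG", "NA", "CL", "BR", "SE", "MN", "CU")
  ifelse(nchar(nm) >= 2 & two %in% known2, two, toupper(substr(nm, 1, 1)))
}

parse_pdb_atoms <- function(lines, linenos) {
  rec <- trimws(substr(lines, 1, 6))
  occ_txt <- substr(lines, 55, 60)
  b_txt <- substr(lines, 61, 66)
  el <- toupper(trimws(substr(lines, 77, 78)))
  name <- trimws(substr(lines, 13, 16))
  el[!nzchar(el)] <- element_from_name(name[!nzchar(el)])
  occ <- suppressWarnings(as.numeric(occ_txt))
  occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(b_txt))
  b[is.na(b)] <- 0
  data.frame(
    record = rec,
    serial = suppressWarnings(as.integer(substr(lines, 7, 11))),
    atom = name,
    altloc = trimws(substr(lines, 17, 17)),
    resname = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    resno = as.integer(num_field(substr(lines, 23, 26), linenos, "residue number")),
    ins = trimws(substr(lines, 27, 27)),
    x = num_field(substr(lines, 31, 38), linenos, "x"),
    y = num_field(substr(lines, 39, 46), linenos, "y"),
    z = num_field(substr(lines, 47, 54), linenos, "z"),
    occ = occ, b = b, element = el,
    stringsAsFactors = FALSE)
}

# keep, per (residue, atom name), the highest-occupancy altloc conformer;
# ties broken by altloc label order ("" sorts first)
resolve_altlocs <- function(a) {
  if (!any(nzchar(a$altloc))) return(a)
  key <- atom_key(a$chain, a$resno, a$ins, a$atom)
  ord <- order(key, -a$occ, a$altloc)
  a <- a[ord, , drop = FALSE]
  a[!duplicated(key[ord]), , drop = FALSE]
}

finalize_structure <- function(a, id, keep_hetero) {
  a <- a[!(toupper(a$element) %in% c("H", "D")), , drop = FALSE]
  a$is_water <- a$resname %in% WATER_RESNAMES
  if (!keep_hetero) a <- a[a$record != "HETATM" | a$is_water, , drop = FALSE]
  if (nrow(a) == 0) stop("model contains no atoms after filtering")
  a <- resolve_altlocs(a)
  a <- a[order(a$serial), , drop = FALSE]
  a$atom_id <- seq_len(nrow(a))
  a$radius <- NA_real_
  cols <- c("atom_id", "chain", "resno", "ins", "resname", "atom", "element",
            "x", "y", "z", "occ", "b", "radius", "is_water")
  new_structure(a[, cols], id = id)
}

split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(k) {
    idx <- seq(starts[k], ends[k])
    structure(lines[idx], lineno = idx)
  })
}

#' Read a crystal structure (PDB or mmCIF)
#'
#' Parses coordinate records into a heavy-atom structure.  Hydrogens are
#' always dropped; water molecules (HOH/WAT/DOD) are kept; other
#' heteroatoms (ligands, ions) are dropped unless `keep_hetero = TRUE`.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties by altloc label order).
#'
#' @param x File path or the file content as a character scalar/vector.
#' @param model Model number to read (1-based position among MODEL records;
#'   files without MODEL records have a single model 1).
#' @param keep_hetero Keep non-water HETATM records?
#' @param format `"auto"` (default; mmCIF is detected from an `_atom_site.`
#'   loop or a `.cif` extension), `"pdb"` or `"cif"`.
#' @param id Structure identifier; defaults to the HEADER id or file name.
#' @return A `wet_structure`: list with an `atoms` data.frame
#'   (`atom_id`, `chain`, `resno`, `ins`, `resname`, `atom`, `element`,
#'   `x`, `y`, `z`, `occ`, `b`, `radius`, `is_water`), plus `id`,
#'   `resolution` and `radii_table`.
#' @export
read_structure <- function(x, model = 1, keep_hetero = FALSE,
                           format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  lines <- read_input_lines(x)
  if (format == "auto") {
    is_cif <- any(grepl("^_atom_site\\.", lines)) ||
      (length(x) == 1 && grepl("\\.cif$", x, ignore.case = TRUE))
    format <- if (is_cif) "cif" else "pdb"
  }
  if (is.null(id)) {
    id <- if (length(x) == 1 && file.exists(x)) basename(x) else NA_character_
    hdr <- grep("^HEADER", lines, value = TRUE)
    if (length(hdr)) {
      code <- trimws(substr(hdr[1], 63, 66))
      if (nzchar(code)) id <- code
    }
  }
  if (format == "cif") return(read_cif_structure(lines, model, keep_hetero, id))

  models <- split_models(lines)
  if (model < 1 || model > length(models)) {
    stop(sprintf("model %d not found (file has %d model(s))",
                 model, length(models)))
  }
  mlines <- models[[model]]
  linenos <- attr(mlines, "lineno")
  if (is.null(linenos)) linenos <- seq_along(mlines)
  sel <- grepl("^(ATOM  |HETATM)", mlines)
  if (!any(sel)) stop(sprintf("model %d contains no coordinate records", model))
  a <- parse_pdb_atoms(mlines[sel], linenos[sel])
  s <- finalize_structure(a, id, keep_hetero)
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    v <- suppressWarnings(as.numeric(sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1", rl[1])))
    s$resolution <- v
  }
  s
}

#' Read all models of a multi-model coordinate file
#'
#' Convenience wrapper for trajectory-style multi-model PDB files; each
#' model becomes one structure (one frame).
#'
#' @inheritParams read_structure
#' @return List of `wet_structure` objects.
#' @export
read_models <- function(x, keep_hetero = FALSE) {
  lines <- read_input_lines(x)
  n <- max(1L, length(grep("^MODEL", lines)))
  lapply(seq_len(n), function(k) read_structure(lines, model = k,
                                                keep_hetero = keep_hetero))
}

# ---------------------------------------------------------------------------
# minimal mmCIF (_atom_site loop) reader
# ---------------------------------------------------------------------------

read_cif_structure <- function(lines, model, keep_hetero, id) {
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx)) stop("no _atom_site loop found in mmCIF input")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1
  body <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_")) break
    body <- c(body, lines[i])
  }
  if (!length(body)) stop("empty _atom_site loop")
  toks <- scan(text = body, what = character(), quote = "'\"", quiet = TRUE)
  if (length(toks) %% length(tags) != 0)
    stop("malformed _atom_site loop: token count is not a multiple of the field count")
  m <- matrix(toks, ncol = length(tags), byrow = TRUE)
  colnames(m) <- tags
  get <- function(nm, alt = NULL, default = NA_character_) {
    for (n2 in c(nm, alt)) if (!is.null(n2) && n2 %in% tags) return(m[, n2])
    rep(default, nrow(m))
  }
  clean <- function(v) ifelse(v %in% c(".", "?"), "", v)
  mdl <- get("pdbx_PDB_model_num", default = "1")
  mdl_levels <- unique(mdl)
  if (model < 1 || model > length(mdl_levels))
    stop(sprintf("model %d not found (file has %d model(s))", model,
                 length(mdl_levels)))
  keep <- mdl == mdl_levels[model]
  a <- data.frame(
    record = ifelse(get("group_PDB", default = "ATOM") == "HETATM", "HETATM", "ATOM"),
    serial = suppressWarnings(as.integer(get("id", default = NA))),
    atom = clean(get("auth_atom_id", "label_atom_id")),
    altloc = clean(get("label_alt_id")),
    resname = clean(get("auth_comp_id", "label_comp_id")),
    chain = clean(get("auth_asym_id", "label_asym_id")),
    resno = suppressWarnings(as.integer(get("auth_seq_id", "label_seq_id"))),
    ins = clean(get("pdbx_PDB_ins_code")),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    occ = suppressWarnings(as.numeric(get("occupancy", default = "1"))),
    b = suppressWarnings(as.numeric(get("B_iso_or_equiv", default = "0"))),
    element = toupper(clean(get("type_symbol"))),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (anyNA(a$x) || anyNA(a$y) || anyNA(a$z))
    stop("malformed _atom_site loop: non-numeric coordinates")
  blank_el <- !nzchar(a$element)
  a$element[blank_el] <- element_from_name(a$atom[blank_el])
  a$serial[is.na(a$serial)] <- seq_len(nrow(a))[is.na(a$serial)]
  a$occ[is.na(a$occ)] <- 1
  a$b[is.na(a$b)] <- 0
  finalize_structure(a, id, keep_hetero)
}

# ---------------------------------------------------------------------------
# PDB writing (synthetic fixtures, CLI output)
# ---------------------------------------------------------------------------

#' Write a structure as PDB-format text
#'
#' @param s A `wet_structure`.
#' @param file Optional path; if `NULL`, the text is returned invisibly.
#' @return Character vector of PDB lines (invisibly when writing to file).
#' @export
write_pdb <- function(s, file = NULL) {
  a <- s$atoms
  rec <- ifelse(a$is_water, "HETATM", "ATOM  ")
  nm <- ifelse(nchar(a$atom) >= 4 | nchar(a$element) >= 2,
               sprintf("%-4s", a$atom), sprintf(" %-3s", a$atom))
  lines <- sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$atom_id %% 100000L, nm, "", a$resname, a$chain,
                   a$resno, a$ins, a$x, a$y, a$z, a$occ, a$b,
                   sprintf("%2s", a$element))
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' @export
print.wet_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<wet_structure> %s: %d atoms (%d water) in %d chain(s): %s\n",
              ifelse(is.na(x$id), "unnamed", x$id), nrow(a), sum(a$is_water),
              length(unique(a$chain)), paste(sort(unique(a$chain)), collapse = ",")))
  if (!is.null(x$radii_table)) cat("  radii:", x$radii_table, "\n")
  invisible(x)
}

#' Subset a structure
#'
#' @param s A `wet_structure`.
#' @param chains Chains to keep (`NULL` = all).
#' @param keep_water Keep water molecules?
#' @param atom_ids Explicit atom ids to keep (applied after the other
#'   filters); `NULL` = no id filter.
#' @param reindex Renumber `atom_id` 1..n in the result (default `FALSE`,
#'   which preserves ids so subsets stay comparable with the parent).
#' @return A `wet_structure`.
#' @export
subset_structure <- function(s, chains = NULL, keep_water = TRUE,
                             atom_ids = NULL, reindex = FALSE) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & (a$chain %in% chains | (keep_water & a$is_water))
  if (!keep_water) keep <- keep & !a$is_water
  if (!is.null(atom_ids)) keep <- keep & a$atom_id %in% atom_ids
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("subset leaves no atoms")
  if (reindex) a$atom_id <- seq_len(nrow(a))
  new_structure(a, id = s$id, resolution = s$resolution,
                radii_table = s$radii_table)
}
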