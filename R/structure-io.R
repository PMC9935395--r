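#' Read a macromolecular structure with per-residue plDDT
#'
#' Parses a PDB or mmCIF coordinate file into a flat atom-table structure.
#' Per-residue model confidence (plDDT, 0-100 in AlphaFold-style models) is
#' taken from the B-factor column: when a residue's atoms carry differing
#' B-factors the Calpha value is used (first atom if no Calpha is present).
#' Hydrogens are excluded by default, heteroatoms (ligands) and waters are
#' dropped unless requested (waters are always dropped), the highest-occupancy
#' alternate location is kept (ties broken by altloc label order), and only
#' the first model of a multi-model file is read.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`. With `"auto"` the format
#'   is detected from the file extension, falling back to content sniffing.
#' @param keep_hydrogens Retain hydrogen/deuterium atoms (default `FALSE`).
#' @param keep_hetero Retain non-water HETATM records (default `FALSE`).
#' @return A `cf_structure`: a list with `id`, `atoms` (a tibble with columns
#'   `chain`, `resno`, `insert`, `resid`, `elety`, `element`, `x`, `y`, `z`,
#'   `b`, `plddt`), `source_path` and `format`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  CA  LYS A   1       0.000   0.000   0.000  1.00 85.30           C",
#'   "ATOM      2  CA  LYS A   2       3.800   0.000   0.000  1.00 90.00           C",
#'   "END"), pdb)
#' s <- read_structure(pdb)
#' s$atoms
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_hydrogens = FALSE, keep_hetero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") format <- detect_format(path)

  parsed <- tryCatch(
    if (format == "mmcif") {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) {
      abort(paste0("failed to parse ", format, " file '", path, "': ",
                   conditionMessage(e)))
    }
  )

  at <- as_tibble(parsed$atom)
  if (nrow(at) == 0) abort(paste0("no atoms parsed from '", path, "'"))

  at$chain <- as.character(at$chain)
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  at$insert <- as.character(at$insert)
  at$insert[is.na(at$insert)] <- ""
  at$elety <- as.character(at$elety)
  at$o <- suppressWarnings(as.numeric(at$o))
  at$o[is.na(at$o)] <- 1

  keep <- at$type == "ATOM"
  if (keep_hetero) keep <- keep | (at$type == "HETATM" & !at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) abort(paste0("no atoms parsed from '", path, "'"))

  at$element <- infer_element(at$elesy, at$elety)
  if (!keep_hydrogens) at <- at[!at$element %in% c("H", "D"), , drop = FALSE]
  if (nrow(at) == 0) abort(paste0("no heavy atoms parsed from '", path, "'"))

  # altloc: keep the highest-occupancy conformer per atom, ties by label order
  if (any(!is.na(at$alt) & at$alt != "")) {
    at$alt[is.na(at$alt)] <- ""
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(key, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(match(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r"),
                         unique(key))), , drop = FALSE]
  }

  atoms <- tibble(
    chain = at$chain, resno = as.integer(at$resno), insert = at$insert,
    resid = as.character(at$resid), elety = at$elety, element = at$element,
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    b = as.numeric(at$b)
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    abort(paste0("non-finite coordinates in '", path, "'"))
  atoms$plddt <- residue_plddt(atoms)

  new_structure(id = sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path)),
                atoms = atoms, source_path = path, format = format)
}

detect_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  first <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^(data_|loop_|_atom_site)", first))) "mmcif" else "pdb"
}

# element symbol from the PDB element column, falling back to the atom name
infer_element <- function(elesy, elety) {
  elesy <- toupper(trimws(as.character(elesy)))
  out <- elesy
  missing <- is.na(out) | out == ""
  if (any(missing)) {
    nm <- toupper(gsub("[^A-Za-z]", "", elety[missing]))
    first <- substr(nm, 1, 1)
    first[substr(nm, 1, 2) %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "SE", "NA", "CA") &
            nchar(nm) == 2] <- substr(nm, 1, 2)[substr(nm, 1, 2) %in%
            c("FE", "ZN", "MG", "MN", "CL", "BR", "SE", "NA", "CA") & nchar(nm) == 2]
    out[missing] <- first
  }
  out
}

# canonical per-residue plDDT: shared B-factor, else the Calpha's value
residue_plddt <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  split_idx <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  plddt <- numeric(nrow(atoms))
  for (idx in split_idx) {
    bs <- atoms$b[idx]
    val <- if (length(unique(bs)) == 1L) {
      bs[1]
    } else {
      ca <- idx[atoms$elety[idx] == "CA"]
      if (length(ca)) atoms$b[ca[1]] else bs[1]
    }
    plddt[idx] <- val
  }
  plddt
}

new_structure <- function(id, atoms, source_path = NA_character_,
                          format = NA_character_) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  structure(
    list(id = id, atoms = as_tibble(atoms), source_path = source_path,
         format = format),
    class = "cf_structure"
  )
}

#' @export
print.cf_structure <- function(x, ...) {
  ch <- chain_ids(x)
  cat("<cf_structure> ", x$id, ": ", length(ch), " chain(s) [",
      paste(ch, collapse = ","), "], ", nrow(x$atoms), " heavy atoms\n",
      sep = "")
  invisible(x)
}

#' Chain identifiers of a structure, in file order
#' @param structure A `cf_structure`.
#' @return Character vector of chain ids.
#' @export
chain_ids <- function(structure) unique(structure$atoms$chain)

#' Atoms of one chain
#'
#' @param structure A `cf_structure`.
#' @param chain A chain id present in the structure.
#' @param elety Optional atom-name filter (e.g. `"CA"` or `"NZ"`).
#' @return Tibble of atom records.
#' @export
chain_atoms <- function(structure, chain, elety = NULL) {
  if (!chain %in% chain_ids(structure)) {
    abort(paste0("chain '", chain, "' not found; available: ",
                 paste(chain_ids(structure), collapse = ", ")))
  }
  at <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  if (!is.null(elety)) at <- at[at$elety %in% elety, , drop = FALSE]
  at
}

#' Per-residue table of a chain
#' @inheritParams chain_atoms
#' @return Tibble with one row per residue: `resno`, `insert`, `resid`, `plddt`.
#' @export
chain_residues <- function(structure, chain) {
  at <- chain_atoms(structure, chain)
  distinct(at, .data$resno, .data$insert, .data$resid, .data$plddt)
}

#' Fraction of residues predicted disordered
#'
#' A residue counts as disordered when its plDDT lies strictly below the
#' threshold (default 50 on the 0-100 scale).
#'
#' @param structure A `cf_structure`.
#' @param chain Optional chain id; all chains pooled when `NULL`.
#' @param plddt_threshold Strict lower plDDT cutoff, default 50.
#' @return A fraction in \[0, 1\].
#' @export
disorder_fraction <- function(structure, chain = NULL, plddt_threshold = 50) {
  res <- if (is.null(chain)) {
    distinct(structure$atoms, .data$chain, .data$resno, .data$insert, .data$plddt)
  } else {
    chain_residues(structure, chain)
  }
  if (nrow(res) == 0) abort("chain has no residues")
  mean(res$plddt < plddt_threshold)
}

#' Write a structure to PDB or mmCIF
#'
#' Round-trip safe with [read_structure()]: chain order, residue numbering,
#' coordinates (3 decimals) and B-factors (2 decimals) are preserved. PDB
#' output refuses structures with more than 62 chains or multi-character
#' chain ids; use mmCIF for those.
#'
#' @param structure A `cf_structure`.
#' @param path Output path.
#' @param format `"auto"` (from extension), `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") format <- detect_format_out(path)
  at <- structure$atoms
  if (format == "pdb") {
    ch <- chain_ids(structure)
    if (length(ch) > 62)
      abort("more than 62 chains cannot be written as PDB; write mmCIF instead")
    if (any(nchar(ch) > 1))
      abort("multi-character chain ids cannot be written as PDB; write mmCIF instead")
    bio3d::write.pdb(
      pdb = NULL, file = path,
      xyz = as.numeric(t(coords_matrix(at))),
      type = rep("ATOM", nrow(at)),
      resno = at$resno, resid = at$resid,
      eleno = seq_len(nrow(at)), elety = at$elety,
      chain = at$chain,
      insert = ifelse(at$insert == "", NA, at$insert),
      o = rep(1, nrow(at)), b = at$plddt, elesy = at$element,
      end = TRUE
    )
  } else {
    write_mmcif(structure, path)
  }
  invisible(path)
}

detect_format_out <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
}

# minimal _atom_site loop, readable by standard mmCIF parsers
write_mmcif <- function(structure, path) {
  at <- structure$atoms
  ins <- ifelse(at$insert == "", "?", at$insert)
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_", structure$id)),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 %.2f %d %s 1",
            seq_len(nrow(at)), at$element, at$elety, at$resid, at$chain,
            at$resno, ins, at$x, at$y, at$z, at$plddt, at$resno, at$chain),
    "#"
  )
  writeLines(lines, path)
}

#' Relabel chains deterministically
#'
#' Assigns single-character labels `A, B, ..., Z, a, ..., z, 0, ..., 9` in
#' current chain order, e.g. to resolve chain-id collisions when merging
#' structures. The mapping is attached as attribute `chain_map`.
#'
#' @param structure A `cf_structure`.
#' @return The relabeled structure; `attr(, "chain_map")` is a tibble with
#'   columns `old`, `new`.
#' @export
relabel_chains <- function(structure) {
  pool <- c(LETTERS, letters, as.character(0:9))
  old <- chain_ids(structure)
  if (length(old) > length(pool))
    abort("more than 62 chains cannot be relabeled with single characters")
  new <- pool[seq_along(old)]
  structure$atoms$chain <- new[match(structure$atoms$chain, old)]
  attr(structure, "chain_map") <- tibble(old = old, new = new)
  structure
}
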