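# Antigen structure model: chains, residues, heavy atoms.
# PDB reading/writing is delegated to bio3d; everything downstream works on
# a flat atom table carried by the `antigen_structure` S3 class.

#' Standard amino-acid heavy-atom chemistry
#'
#' Internal tables: three-letter/one-letter codes for the 20 standard amino
#' acids, the heavy (non-hydrogen) atoms of each residue in PDB naming, and
#' the side-chain subset (backbone N, CA, C, O excluded).
#' @keywords internal
#' @name aa_chemistry
NULL

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(.AA1) <- .AA3
.AA3_FROM_1 <- stats::setNames(.AA3, .AA1)

.BACKBONE <- c("N", "CA", "C", "O")

# Heavy side-chain atoms per residue, standard PDB order.
.SIDE_CHAIN <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
          "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

# Bondi van der Waals radii (angstrom); unknown elements fall back to 1.7.
.VDW_DEFAULT <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52,
                  S = 1.80, P = 1.80, SE = 1.90)
.VDW_FALLBACK <- 1.7

# Non-standard residue mapping kept so pair statistics stay on 20 letters.
.RES_MAP <- c(MSE = "MET", SEC = "CYS")

.element_from_name <- function(name) {
  # PDB atom-name heuristic: strip digits/primes, first letter run;
  # two-letter elements we care about are SE (selenium) only.
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  el <- substr(nm, 1L, 1L)
  el[nm == "SE"] <- "SE"
  el
}

.new_structure <- function(atoms, pdb_id = "", chain_id = "") {
  rownames(atoms) <- NULL
  structure(list(pdb_id = pdb_id, chain_id = chain_id, atoms = atoms),
            class = "antigen_structure")
}

#' Parse a single chain of a PDB file into an antigen structure
#'
#' Reads `ATOM` records (plus amino-acid `HETATM` records such as MSE) for
#' one chain. Waters and non-amino-acid heteroatoms are excluded, only the
#' first model of multi-model files is used, and for alternate locations
#' only the first-listed conformer of each atom is kept. Hydrogens are
#' retained but flagged `is_heavy = FALSE`; all downstream geometry uses
#' heavy atoms only. MSE is mapped to MET and SEC to CYS; other
#' non-standard residues are dropped with a warning.
#'
#' @param text A character scalar holding PDB-format text, or a path to a
#'   PDB file.
#' @param chain_id Author chain identifier to extract.
#' @param pdb_id Optional structure identifier stored on the result.
#' @return An `antigen_structure`: a list with `pdb_id`, `chain_id` and an
#'   `atoms` data frame (serial, name, element, chain, resno, icode, aa,
#'   res_index, x, y, z, vdw, is_heavy, is_side_chain), residues ordered by
#'   (residue number, insertion code).
#' @export
parse_pdb <- function(text, chain_id, pdb_id = "") {
  stopifnot(is.character(text), length(text) == 1L)
  path <- text
  if (grepl("\n", text) || !file.exists(text)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(strsplit(text, "\n", fixed = TRUE)[[1L]], path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("malformed record in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[!is.na(at$chain) & at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain not found: '", chain_id, "'",
                           call. = FALSE)

  resid <- toupper(at$resid)
  mapped <- .RES_MAP[resid]
  resid[!is.na(mapped)] <- mapped[!is.na(mapped)]
  keep <- resid %in% .AA3
  dropped <- setdiff(unique(toupper(at$resid)[!keep]),
                     c("HOH", "WAT", "DOD"))
  if (length(dropped) > 0L)
    warning("dropping non-standard residues: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  at <- at[keep, , drop = FALSE]
  resid <- resid[keep]
  if (nrow(at) == 0L) stop("chain not found: '", chain_id,
                           "' (no amino-acid atoms)", call. = FALSE)

  icode <- ifelse(is.na(at$insert), "", at$insert)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  # First-listed altloc per (residue, atom name): records arrive in file
  # order, so keep the first occurrence of each key.
  key <- paste(at$resno, icode, at$elety, sep = "|")
  first <- !duplicated(key)
  at <- at[first, , drop = FALSE]
  resid <- resid[first]
  icode <- icode[first]

  element <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                            .element_from_name(at$elety), at$elesy))
  is_heavy <- !(element %in% c("H", "D"))

  ord <- order(at$resno, icode)
  at <- at[ord, , drop = FALSE]
  resid <- resid[ord]
  icode <- icode[ord]
  element <- element[ord]
  is_heavy <- is_heavy[ord]

  rkey <- paste(at$resno, icode, sep = "|")
  res_index <- match(rkey, unique(rkey))
  aa <- unname(.AA1[resid])
  is_side_chain <- is_heavy & !(at$elety %in% c(.BACKBONE, "OXT"))

  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = element,
    chain = at$chain, resno = at$resno, icode = icode, aa = aa,
    res_index = res_index, x = at$x, y = at$y, z = at$z,
    vdw = NA_real_, is_heavy = is_heavy, is_side_chain = is_side_chain,
    stringsAsFactors = FALSE
  )
  assign_vdw_radii(.new_structure(atoms, pdb_id = pdb_id,
                                  chain_id = chain_id))
}

#' @export
print.antigen_structure <- function(x, ...) {
  cat(sprintf("<antigen_structure> %s chain %s: %d residues, %d atoms (%d heavy)\n",
              if (nzchar(x$pdb_id)) x$pdb_id else "(unnamed)",
              x$chain_id, n_residues(x), nrow(x$atoms),
              sum(x$atoms$is_heavy)))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure An `antigen_structure`.
#' @return Integer count.
#' @export
n_residues <- function(structure) {
  if (nrow(structure$atoms) == 0L) return(0L)
  max(structure$atoms$res_index)
}

#' Residue-level summary table
#'
#' @param structure An `antigen_structure`.
#' @return Data frame with one row per residue: `res_index`, `chain`,
#'   `resno`, `icode`, `aa`, ordered by `res_index`.
#' @export
residue_table <- function(structure) {
  at <- structure$atoms
  first <- !duplicated(at$res_index)
  out <- at[first, c("res_index", "chain", "resno", "icode", "aa")]
  out[order(out$res_index), , drop = FALSE]
}

#' Alpha-carbon coordinates
#'
#' One row per residue (CA atom; falls back to the residue's first heavy
#' atom if CA is absent).
#' @param structure An `antigen_structure`.
#' @return Numeric matrix `n_residues x 3`.
#' @export
ca_coords <- function(structure) {
  at <- structure$atoms
  n <- n_residues(structure)
  out <- matrix(NA_real_, n, 3L)
  is_ca <- at$name == "CA" & at$is_heavy
  out[at$res_index[is_ca], ] <- as.matrix(at[is_ca, c("x", "y", "z")])
  miss <- which(is.na(out[, 1L]))
  for (r in miss) {
    i <- which(at$res_index == r & at$is_heavy)[1L]
    out[r, ] <- as.numeric(at[i, c("x", "y", "z")])
  }
  out
}

#' Side-chain heavy atoms of a residue
#'
#' Heavy atoms excluding the backbone (N, CA, C, O and terminal OXT).
#' Glycine has no heavy side-chain atom; its CA is returned as surrogate so
#' that side-chain-based surface rates stay defined.
#'
#' @param structure An `antigen_structure`.
#' @param res_index Residue index (row of [residue_table()]).
#' @return Data frame of atom rows.
#' @export
side_chain_atoms <- function(structure, res_index) {
  at <- structure$atoms
  rows <- at[at$res_index == res_index & at$is_side_chain, , drop = FALSE]
  if (nrow(rows) == 0L)
    rows <- at[at$res_index == res_index & at$name == "CA" & at$is_heavy, ,
               drop = FALSE]
  rows
}

#' Assign van der Waals radii
#'
#' Fills the `vdw` column from an element-indexed table (Bondi radii by
#' default); unknown elements get 1.7 angstrom.
#'
#' @param structure An `antigen_structure`.
#' @param radius_table Named numeric vector, element symbol to radius.
#' @return The structure with `vdw` set on every atom.
#' @export
assign_vdw_radii <- function(structure, radius_table = .VDW_DEFAULT) {
  at <- structure$atoms
  if (nrow(at) > 0L) {
    r <- radius_table[at$element]
    r[is.na(r)] <- .VDW_FALLBACK
    at$vdw <- unname(r)
    stopifnot(all(at$vdw > 0))
  }
  structure$atoms <- at
  structure
}

#' Write a structure (or chain pair) as PDB
#'
#' @param structure An `antigen_structure`.
#' @param path Output file path.
#' @param append Append to an existing file (used for complexes).
#' @param end Write the terminating END record (default: when not
#'   appending).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, append = FALSE, end = !append) {
  at <- structure$atoms
  aa3 <- unname(.AA3_FROM_1[at$aa])
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = aa3, eleno = at$serial,
                   elety = at$name, chain = at$chain,
                   insert = ifelse(at$icode == "", NA, at$icode),
                   elesy = at$element, o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)), append = append, end = end)
  invisible(path)
}
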