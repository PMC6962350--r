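# Macromolecular structure container and PDB/mmCIF IO.
#
# The container mirrors the atom-table idiom of structural-bioinformatics
# toolkits: a `protein_structure` is a list with an `atoms` data frame (one
# row per kept atom of the polymer), a `ligands` data frame (waters and
# heteroatoms), and the model number that was read.  Residues carry both a
# 1-based sequential index per chain (`res_index`) and the residue number of
# the source file (`auth_number`), because deposited numbering drifts between
# entries and design reports must print both.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"  # selenomethionine, routinely deposited as HETATM
)
AA1TO3 <- c(setNames(names(AA3TO1)[1:20], AA3TO1[1:20]), X = "UNK")

new_structure <- function(atoms, ligands = NULL, model = 1L, source = NA_character_) {
  if (is.null(ligands)) {
    ligands <- atoms[0L, , drop = FALSE]
  }
  structure(list(atoms = atoms, ligands = ligands, model = model,
                 source = source),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<protein_structure> %d chain(s) [%s], %d residues, %d atoms (model %d)\n",
              length(ch), paste(ch, collapse = ","),
              nrow(unique(x$atoms[, c("chain", "res_index")])),
              nrow(x$atoms), x$model))
  if (nrow(x$ligands)) cat(sprintf("  + %d ligand/water atoms\n", nrow(x$ligands)))
  invisible(x)
}

element_from_name <- function(name) {
  # PDB atom names encode the element in their leading characters; strip
  # digits/primes and take one letter, except recognized two-letter elements.
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1L, 2L)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "SE", "BR", "NI", "CA"),
         two, substr(nm, 1L, 1L))
}

finalize_atom_table <- function(df) {
  # first altloc kept per atom identity
  key <- paste(df$chain, df$auth_number, df$icode, df$atom)
  df <- df[!duplicated(key), , drop = FALSE]
  # sequential residue index per chain, in file order
  df$res_index <- NA_integer_
  for (ch in unique(df$chain)) {
    sel <- df$chain == ch
    rk <- paste(df$auth_number[sel], df$icode[sel])
    df$res_index[sel] <- match(rk, unique(rk))
  }
  rownames(df) <- NULL
  df
}

#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF file into a [protein_structure]. Standard (and
#' recognized modified) amino acids populate the polymer atom table; waters
#' and other heteroatoms are retained in a separate ligand table.  For atoms
#' with alternate locations only the first encountered altloc is kept, and
#' occupancy is carried but ignored by all geometry.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension: `.cif` /
#'   `.mmcif` are mmCIF, everything else PDB).
#' @param model model number to read (default 1; for files without MODEL
#'   records the single model is model 1).
#' @return a `protein_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), model = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (format == "pdb") read_pdb(path, model) else read_mmcif(path, model)
}

read_pdb <- function(path, model = 1L) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  model_ids <- cumsum(trimws(rec) == "MODEL")
  has_models <- any(model_ids > 0L)
  keep <- rec %in% c("ATOM  ", "HETATM")
  if (has_models) {
    present <- unique(model_ids[keep])
    if (!(model %in% present))
      stop("model ", model, " not present in ", path,
           " (models: ", paste(present, collapse = ","), ")")
    keep <- keep & model_ids == model
  } else if (model != 1L) {
    stop("model ", model, " not present in ", path, " (file has a single model)")
  }
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)

  fx <- function(from, to) substr(lines, from, to)
  xs <- suppressWarnings(as.numeric(fx(31L, 38L)))
  ys <- suppressWarnings(as.numeric(fx(39L, 46L)))
  zs <- suppressWarnings(as.numeric(fx(47L, 54L)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad))
    stop("parse error in ", path, ": malformed coordinates at line ",
         lineno[bad[1L]], ": ", lines[bad[1L]])
  occ <- suppressWarnings(as.numeric(fx(55L, 60L)))
  occ[is.na(occ)] <- 1
  el <- trimws(fx(77L, 78L))
  name <- trimws(fx(13L, 16L))
  el[el == ""] <- element_from_name(name[el == ""])

  df <- data.frame(
    record = trimws(fx(1L, 6L)),
    chain = fx(22L, 22L),
    auth_number = suppressWarnings(as.integer(trimws(fx(23L, 26L)))),
    icode = trimws(fx(27L, 27L)),
    resname = trimws(fx(18L, 20L)),
    atom = name,
    altloc = trimws(fx(17L, 17L)),
    x = xs, y = ys, z = zs,
    occupancy = occ,
    element = toupper(el),
    stringsAsFactors = FALSE
  )
  df$chain[df$chain == " "] <- "A"
  split_polymer_ligand(df, model, path)
}

split_polymer_ligand <- function(df, model, path) {
  df$aa <- unname(AA3TO1[df$resname])
  is_poly <- !is.na(df$aa) | (df$record == "ATOM" & !df$resname %in% "HOH")
  df$aa[is.na(df$aa)] <- "X"
  atoms <- finalize_atom_table(df[is_poly, , drop = FALSE])
  ligands <- df[!is_poly, , drop = FALSE]
  rownames(ligands) <- NULL
  cols <- c("chain", "res_index", "auth_number", "icode", "resname", "aa",
            "atom", "altloc", "x", "y", "z", "occupancy", "element")
  ligands$res_index <- rep(NA_integer_, nrow(ligands))
  new_structure(atoms[, cols], ligands[, cols], model = as.integer(model),
                source = path)
}

# Minimal tokenizer for one mmCIF atom_site loop.  Handles whitespace-
# separated values with single/double quoting; that covers atom_site loops
# as written by the PDB and by gemmi/biopython.
read_mmcif <- function(path, model = 1L) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  target <- NA_integer_
  for (ls in loop_starts) {
    j <- ls + 1L
    if (j <= length(lines) && startsWith(trimws(lines[j]), "_atom_site.")) {
      target <- ls
      break
    }
  }
  if (is.na(target)) stop("parse error in ", path, ": no _atom_site loop found")
  j <- target + 1L
  fields <- character()
  while (j <= length(lines) && startsWith(trimws(lines[j]), "_atom_site.")) {
    fields <- c(fields, sub("^_atom_site\\.", "", trimws(lines[j])))
    j <- j + 1L
  }
  rows <- list()
  while (j <= length(lines)) {
    ln <- trimws(lines[j])
    if (ln == "" || ln == "#" || startsWith(ln, "loop_") || startsWith(ln, "_") ||
        startsWith(ln, "data_"))
      break
    toks <- scan(text = lines[j], what = "character", quiet = TRUE,
                 quote = "'\"", strip.white = TRUE)
    if (length(toks) != length(fields))
      stop("parse error in ", path, ": atom_site row at line ", j,
           " has ", length(toks), " tokens, expected ", length(fields))
    rows[[length(rows) + 1L]] <- toks
    j <- j + 1L
  }
  if (!length(rows)) stop("parse error in ", path, ": empty atom_site loop")
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  getf <- function(nm, alt = NULL) {
    if (nm %in% fields) m[, nm]
    else if (!is.null(alt) && alt %in% fields) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  model_num <- getf("pdbx_PDB_model_num")
  if (!all(is.na(model_num))) {
    present <- unique(as.integer(model_num))
    if (!(model %in% present))
      stop("model ", model, " not present in ", path,
           " (models: ", paste(present, collapse = ","), ")")
    m <- m[as.integer(model_num) == model, , drop = FALSE]
  } else if (model != 1L) {
    stop("model ", model, " not present in ", path, " (file has a single model)")
  }
  getf2 <- function(nm, alt = NULL) {
    v <- if (nm %in% fields) m[, nm]
         else if (!is.null(alt) && alt %in% fields) m[, alt]
         else rep(NA_character_, nrow(m))
    v[v %in% c(".", "?")] <- ""
    v
  }
  occ <- suppressWarnings(as.numeric(getf2("occupancy")))
  occ[is.na(occ)] <- 1
  el <- toupper(getf2("type_symbol"))
  name <- getf2("auth_atom_id", "label_atom_id")
  if (all(name == "")) name <- getf2("label_atom_id")
  el[el == ""] <- element_from_name(name[el == ""])
  auth_seq <- suppressWarnings(as.integer(getf2("auth_seq_id")))
  if (all(is.na(auth_seq)))
    auth_seq <- suppressWarnings(as.integer(getf2("label_seq_id")))
  chain <- getf2("auth_asym_id")
  if (all(chain == "")) chain <- getf2("label_asym_id")

  df <- data.frame(
    record = getf2("group_PDB"),
    chain = chain,
    auth_number = auth_seq,
    icode = getf2("pdbx_PDB_ins_code"),
    resname = getf2("auth_comp_id", "label_comp_id"),
    atom = name,
    altloc = getf2("label_alt_id"),
    x = as.numeric(getf2("Cartn_x")),
    y = as.numeric(getf2("Cartn_y")),
    z = as.numeric(getf2("Cartn_z")),
    occupancy = occ,
    element = el,
    stringsAsFactors = FALSE
  )
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z))
    stop("parse error in ", path, ": non-numeric Cartesian coordinates")
  df$resname[df$resname == ""] <- "UNK"
  split_polymer_ligand(df, model, path)
}

#' Write a structure (optionally with a placed heme) as PDB
#'
#' @param structure a `protein_structure`.
#' @param path output file path.
#' @param heme optional data frame of heme atoms (columns `atom`, `element`,
#'   `x`, `y`, `z`), written as HETATM records with residue name `HEC`.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, heme = NULL) {
  a <- structure$atoms
  fmt <- function(record, serial, name, resname, chain, resno, x, y, z, occ, el) {
    nm <- ifelse(nchar(name) < 4L, sprintf(" %-3s", name), sprintf("%-4s", name))
    sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, nm, resname, substr(chain, 1L, 1L), resno,
            x, y, z, occ, 0, el)
  }
  lines <- fmt("ATOM", seq_len(nrow(a)), a$atom, a$resname, a$chain,
               a$auth_number, a$x, a$y, a$z, a$occupancy, a$element)
  if (!is.null(heme) && nrow(heme)) {
    hres <- max(a$auth_number, na.rm = TRUE) + 1L
    lines <- c(lines,
               fmt("HETATM", nrow(a) + seq_len(nrow(heme)), heme$atom, "HEC",
                   "X", hres, heme$x, heme$y, heme$z, 1, heme$element))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' One-letter sequence of a chain
#'
#' @param structure a `protein_structure`.
#' @param chain chain id; default first chain.
#' @return character scalar (one-letter codes, `X` for nonstandard residues).
#' @export
chain_sequence <- function(structure, chain = NULL) {
  a <- structure$atoms
  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain == chain, , drop = FALSE]
  a <- a[!duplicated(a$res_index), , drop = FALSE]
  paste(a$aa[order(a$res_index)], collapse = "")
}

residue_atom_xyz <- function(atoms, res_index, name) {
  sel <- which(atoms$res_index == res_index & atoms$atom == name)
  if (!length(sel)) return(NULL)
  as.numeric(atoms[sel[1L], c("x", "y", "z")])
}

#' Backbone phi/psi dihedrals
#'
#' Computes per-residue backbone torsions: `phi(i)` from
#' `C(i-1)-N(i)-CA(i)-C(i)` and `psi(i)` from `N(i)-CA(i)-C(i)-N(i+1)`,
#' in degrees on `(-180, 180]` (IUPAC convention).  Angles are `NA`
#' (undefined) at chain termini and wherever a required backbone atom is
#' missing; residues are never dropped, so rows align with source numbering.
#'
#' @param structure a `protein_structure`.
#' @return data frame of class `dihedral_table` with columns `chain`,
#'   `res_index`, `auth_number`, `aa`, `phi`, `psi`.
#' @export
compute_backbone_dihedrals <- function(structure) {
  out <- list()
  for (ch in unique(structure$atoms$chain)) {
    a <- structure$atoms[structure$atoms$chain == ch, , drop = FALSE]
    idx <- sort(unique(a$res_index))
    n <- length(idx)
    info <- a[!duplicated(a$res_index), , drop = FALSE]
    info <- info[order(info$res_index), , drop = FALSE]
    Nxyz <- lapply(idx, function(i) residue_atom_xyz(a, i, "N"))
    CAxyz <- lapply(idx, function(i) residue_atom_xyz(a, i, "CA"))
    Cxyz <- lapply(idx, function(i) residue_atom_xyz(a, i, "C"))
    phi <- psi <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      if (k > 1L && !is.null(Cxyz[[k - 1L]]) && !is.null(Nxyz[[k]]) &&
          !is.null(CAxyz[[k]]) && !is.null(Cxyz[[k]]))
        phi[k] <- dihedral_angle(Cxyz[[k - 1L]], Nxyz[[k]], CAxyz[[k]], Cxyz[[k]])
      if (k < n && !is.null(Nxyz[[k]]) && !is.null(CAxyz[[k]]) &&
          !is.null(Cxyz[[k]]) && !is.null(Nxyz[[k + 1L]]))
        psi[k] <- dihedral_angle(Nxyz[[k]], CAxyz[[k]], Cxyz[[k]], Nxyz[[k + 1L]])
    }
    out[[ch]] <- data.frame(chain = ch, res_index = idx,
                            auth_number = info$auth_number, aa = info$aa,
                            phi = phi, psi = psi, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("dihedral_table", "data.frame")
  res
}

#' Write a dihedral table as CSV
#'
#' @param dihedrals a `dihedral_table` from [compute_backbone_dihedrals()].
#' @param path output path.
#' @export
write_dihedral_csv <- function(dihedrals, path) {
  utils::write.csv(as.data.frame(dihedrals), path, row.names = FALSE)
  invisible(path)
}
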