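# Mining of x1-C1-x2-x3-C2-H heme-binding motifs from cytochrome structures
# and derivation of phi/psi gating windows from their torsion statistics.
#
# The motif is the canonical c-type heme attachment sequence CxxCH together
# with the residue immediately preceding it (x1), which is tracked because
# its backbone conformation constrains whether a rigid heme can be supported.

MOTIF_POSITIONS <- c("x1", "C1", "x2", "x3", "C2", "H")

#' Find CxxCH heme-binding motifs in a structure
#'
#' Scans every chain for 6-residue windows `x1 C1 x2 x3 C2 H`: cysteines at
#' window offsets 2 and 5, histidine at offset 6, any residue at the other
#' positions.  Overlapping motifs are all reported; motifs never span chains.
#' A CxxCH at the very start of a chain has no preceding x1 residue and is
#' not reported as a window.
#'
#' @param structure a `protein_structure`.
#' @return data frame of class `motif_table` with columns `source`, `chain`,
#'   `start_index` (sequential index of x1), `start_auth` (source-file number
#'   of x1) and `seq6` (the six residue letters).  Empty if no motif matches.
#' @export
#' @examples
#' s <- make_backbone(rep(-57, 11), rep(-47, 11), sequence = "AAACAACHAAA")
#' find_cxxch_motifs(s)  # one motif, x1 at index 3
find_cxxch_motifs <- function(structure) {
  out <- list()
  for (ch in unique(structure$atoms$chain)) {
    s <- chain_sequence(structure, ch)
    if (nchar(s) < 6L) next
    m <- gregexpr("(?=.C..CH)", s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    info <- structure$atoms[structure$atoms$chain == ch, , drop = FALSE]
    info <- info[!duplicated(info$res_index), , drop = FALSE]
    auth <- info$auth_number[match(starts, info$res_index)]
    out[[ch]] <- data.frame(
      source = structure$source, chain = ch, start_index = starts,
      start_auth = auth,
      seq6 = substring(s, starts, starts + 5L),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(source = character(), chain = character(),
               start_index = integer(), start_auth = integer(),
               seq6 = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("motif_table", "data.frame")
  res
}

#' Collect motif torsion angles into a Ramachandran table
#'
#' Joins each motif's six positions with the structure's dihedral table.
#' Positions whose phi or psi is undefined (chain termini, missing backbone
#' atoms) are excluded, so the table contains one row per fully defined motif
#' position -- at most six rows per motif, with equality exactly when no
#' motif touches a terminus.
#'
#' @param motifs a `motif_table` from [find_cxxch_motifs()].
#' @param dihedrals a `dihedral_table` for the same structure(s); when
#'   motifs come from several structures, row-bind their tables and make
#'   sure `source`/`chain` identify them unambiguously.
#' @return data frame of class `rama_table` with columns `source`, `chain`,
#'   `position` (one of x1, C1, x2, x3, C2, H), `res_index`, `phi`, `psi`.
#' @export
collect_motif_torsions <- function(motifs, dihedrals) {
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    ch <- motifs$chain[i]
    for (k in 0:5) {
      ri <- motifs$start_index[i] + k
      hit <- which(dihedrals$chain == ch & dihedrals$res_index == ri)
      if (!length(hit))
        stop("motif at ", ch, ":", motifs$start_index[i],
             " references residue ", ri, " absent from the dihedral table")
      rows[[length(rows) + 1L]] <- data.frame(
        source = motifs$source[i], chain = ch,
        position = MOTIF_POSITIONS[k + 1L], res_index = ri,
        phi = dihedrals$phi[hit[1L]], psi = dihedrals$psi[hit[1L]],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), chain = character(),
               position = character(), res_index = integer(),
               phi = numeric(), psi = numeric(), stringsAsFactors = FALSE)
  res <- res[!is.na(res$phi) & !is.na(res$psi), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("rama_table", "data.frame")
  res
}

new_gate_set <- function(df) {
  stopifnot(all(c("position", "angle", "min", "max", "gated") %in% names(df)))
  bad <- df$gated & !(df$min < df$max)
  if (any(bad)) stop("gate intervals must satisfy min < max")
  class(df) <- c("gate_set", "data.frame")
  df
}

#' The published torsion-angle gates
#'
#' Returns the fixed phi/psi acceptance windows used to search shell-protein
#' backbones for conformations compatible with heme attachment (degrees,
#' strict inequalities).  Position x1 is gated on phi only, and the motif
#' histidine carries no torsion gate at all (window existence only).
#'
#' @return a `gate_set` data frame: `position`, `angle` (phi/psi), `min`,
#'   `max`, `gated`.
#' @export
published_gates <- function() {
  g <- function(pos, angle, mn, mx, gated = TRUE)
    data.frame(position = pos, angle = angle, min = mn, max = mx,
               gated = gated, stringsAsFactors = FALSE)
  new_gate_set(rbind(
    g("x1", "phi", -100, -50),
    g("x1", "psi", -180, 180, FALSE),
    g("C1", "phi", -100, -50),
    g("C1", "psi", -100, 0),
    g("x2", "phi", -100, -25),
    g("x2", "psi", -75, 50),
    g("x3", "phi", -160, -50),
    g("x3", "psi", -75, 0),
    g("C2", "phi", -160, -50),
    g("C2", "psi", -75, 25),
    g("H", "phi", -180, 180, FALSE),
    g("H", "psi", -180, 180, FALSE)
  ))
}

#' Derive gates from a Ramachandran table
#'
#' Systematizes by-eye gate setting: for each gated position/angle the
#' interval is the central `coverage` quantile range of the observed angles,
#' rounded outward to a `rounding`-degree grid.  Quantiles are computed
#' linearly on `(-180, 180]` without circular statistics; this is adequate
#' because gated intervals in practice sit far from the +/-180 seam, and the
#' seam-adjacent position (psi of x1) is conventionally left ungated.
#'
#' @param table a `rama_table` from [collect_motif_torsions()].
#' @param coverage central quantile fraction in (0, 1]; 1 recovers the
#'   sample support.
#' @param rounding grid in degrees for outward rounding (default 5).
#' @param ungated character vector of `"position.angle"` entries to leave
#'   unrestricted; defaults to the conventions of the published set
#'   (`x1.psi`, `H.phi`, `H.psi`).
#' @param min_rows minimum observations required per gated position/angle.
#' @return a `gate_set`.
#' @export
derive_gates <- function(table, coverage = 0.95, rounding = 5,
                         ungated = c("x1.psi", "H.phi", "H.psi"),
                         min_rows = 10L) {
  stopifnot(coverage > 0, coverage <= 1, rounding > 0)
  rows <- list()
  for (pos in MOTIF_POSITIONS) {
    sub <- table[table$position == pos, , drop = FALSE]
    for (angle in c("phi", "psi")) {
      key <- paste0(pos, ".", angle)
      if (key %in% ungated) {
        rows[[key]] <- data.frame(position = pos, angle = angle,
                                  min = -180, max = 180, gated = FALSE,
                                  stringsAsFactors = FALSE)
        next
      }
      v <- sub[[angle]]
      v <- v[!is.na(v)]
      if (length(v) < min_rows)
        stop("insufficient rows to derive a gate for ", key, ": ",
             length(v), " < ", min_rows)
      lo <- (1 - coverage) / 2
      q <- stats::quantile(v, probs = c(lo, 1 - lo), names = FALSE, type = 7)
      rows[[key]] <- data.frame(
        position = pos, angle = angle,
        min = max(-180, floor(q[1L] / rounding) * rounding),
        max = min(180, ceiling(q[2L] / rounding) * rounding),
        gated = TRUE, stringsAsFactors = FALSE)
    }
  }
  new_gate_set(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Write / read a gate set as key-value text
#'
#' Plain-text format, one line per position/angle:
#' `position angle min max gated`.
#'
#' @param gates a `gate_set`.
#' @param path file path.
#' @return `path` (write) or a `gate_set` (read).
#' @export
write_gates <- function(gates, path) {
  utils::write.table(as.data.frame(gates), path, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_gates
#' @export
read_gates <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new_gate_set(df)
}
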