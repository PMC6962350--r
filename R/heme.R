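# Idealized c-type heme template, rigid placement onto CxxCH sites, and
# van der Waals steric clash screening.  This systematizes what is usually a
# manual modelling step: load a heme next to the motif, bond it to the two
# cysteines and the histidine, and inspect for clashes.

#' van der Waals radii (Angstrom)
#'
#' Bondi-type radii for the elements that occur in protein/heme systems;
#' unknown elements fall back to `default` with a warning.
#'
#' @param elements character vector of element symbols.
#' @param default fallback radius.
#' @return numeric vector of radii.
#' @export
vdw_radius <- function(elements, default = 1.70) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           FE = 2.00, ZN = 1.39, MG = 1.73, SE = 1.90, CL = 1.75, BR = 1.85)
  r <- unname(tab[toupper(elements)])
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(elements[is.na(r)]), collapse = ","),
            "; using default vdW radius ", default)
    r[is.na(r)] <- default
  }
  r
}

#' Idealized c-type heme template
#'
#' Builds a synthetic, idealized heme c coordinate set in a local frame:
#' a planar porphyrin core (Fe centered, four pyrrole nitrogens at 2.0 A),
#' the two thioether-forming substituent carbons of porphyrin rings A and B
#' with cysteine S-gamma stubs at the 1.81 A thioether bond length, an axial
#' histidine N-epsilon stub 2.0 A above the iron, and anchor stub atoms
#' (CYS1/CYS2 C-alpha + C-beta, HIS C-alpha) defining the frame that
#' [place_heme()] superposes onto a motif.  Geometry is idealized -- it
#' encodes bonding topology and bond lengths, not a crystallographic heme.
#'
#' @return data frame of class `heme_template`: `atom`, `element`, `x`,
#'   `y`, `z`, `role` (`"heme"` for atoms written to output models,
#'   `"anchor"` for the superposition stubs).
#' @export
heme_template <- function() {
  pol <- function(r, theta_deg, z = 0)
    c(r * cos(theta_deg * pi / 180), r * sin(theta_deg * pi / 180), z)
  rows <- list()
  add <- function(atom, element, xyz, role = "heme")
    rows[[length(rows) + 1L]] <<- data.frame(
      atom = atom, element = element, x = xyz[1L], y = xyz[2L], z = xyz[3L],
      role = role, stringsAsFactors = FALSE)

  add("FE", "FE", c(0, 0, 0))
  ring_theta <- c(A = 45, B = 135, C = 225, D = 315)
  for (rg in names(ring_theta)) {
    th <- ring_theta[[rg]]
    add(paste0("N", rg), "N", pol(2.00, th))
    add(paste0("C1", rg), "C", pol(3.06, th - 20))
    add(paste0("C4", rg), "C", pol(3.06, th + 20))
    add(paste0("C2", rg), "C", pol(4.25, th - 11))
    add(paste0("C3", rg), "C", pol(4.25, th + 11))
  }
  for (i in seq_along(ring_theta))
    add(paste0("CH", names(ring_theta)[i]), "C", pol(3.42, (i - 1) * 90))

  # thioether substituent carbons on rings A and B, with S-gamma stubs
  # rising out of plane; S-C bond fixed at 1.81 A
  thio <- function(suffix, ring_th) {
    cb <- pol(4.25, ring_th - 11)                  # ring beta-carbon C2x
    ca_sub <- cb + unit3(cb) * 1.50                # substituent carbon
    add(paste0("CA", suffix), "C", ca_sub)
    sdir <- unit3(c(unit3(cb)[1:2] * 0.6, 0.8))
    sg <- ca_sub + sdir * 1.81
    add(paste0("SG", suffix), "S", sg)
    sg
  }
  sg1 <- thio("B1", 45)    # ring A substituent -> Cys1
  sg2 <- thio("B2", 135)   # ring B substituent -> Cys2
  # axial His N-epsilon stub, 2.0 A above Fe
  ne <- c(0, 0, 2.0)
  add("NE2", "N", ne)

  # anchor stubs: continue each thioether outward to an idealized Cys
  # C-beta (S-C 1.81 A) and C-alpha (C-C 1.53 A); His C-alpha sits above
  # the ring plane roughly where a ligating histidine's backbone would be.
  anchor_cys <- function(sg, label) {
    dir <- unit3(c(unit3(sg[1:2]) * 0.5, 0.87))
    cb <- sg + dir * 1.81
    ca <- cb + unit3(c(unit3(sg[1:2]) * 0.8, 0.6)) * 1.53
    add(paste0(label, "_CB"), "C", cb, role = "anchor")
    add(paste0(label, "_CA"), "C", ca, role = "anchor")
  }
  anchor_cys(sg1, "CYS1")
  anchor_cys(sg2, "CYS2")
  add("HIS_CA", "C", c(2.6, -1.8, 4.4), role = "anchor")

  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("heme_template", "data.frame")
  df
}

template_xyz <- function(template, names) {
  m <- match(names, template$atom)
  if (anyNA(m)) stop("template lacks atom(s): ", paste(names[is.na(m)], collapse = ","))
  as.matrix(template[m, c("x", "y", "z")])
}

motif_site_residues <- function(start_index) {
  # C1, C2 and H positions of a window whose x1 sits at start_index
  c(C1 = start_index + 1L, C2 = start_index + 4L, H = start_index + 5L)
}

#' Rigidly place the heme template onto a candidate motif
#'
#' Superposes the template's anchor stubs onto the corresponding atoms of
#' the motif residues (default anchors: C-alpha and C-beta of both cysteine
#' positions plus C-alpha of the histidine position) and applies the rigid
#' transform to all heme atoms.  If a cysteine position lacks a C-beta
#' (glycine at a pre-mutation site), anchoring falls back to the three
#' C-alpha atoms with a warning.
#'
#' @param structure a `protein_structure`.
#' @param site list or one-row data frame with `chain` and `start_index`
#'   (the x1 window start, as reported by [gate_scan()] /
#'   [find_cxxch_motifs()]).
#' @param template a `heme_template` (default [heme_template()]).
#' @return object of class `heme_placement`: `site`, `atoms` (transformed
#'   heme atoms), `anchor_rmsd` (A), `fe` (Fe position), `fit`.
#' @export
place_heme <- function(structure, site, template = heme_template()) {
  ch <- site$chain[1L]
  start <- site$start_index[1L]
  a <- structure$atoms[structure$atoms$chain == ch, , drop = FALSE]
  res <- motif_site_residues(start)
  get <- function(ri, nm) residue_atom_xyz(a, ri, nm)

  ca <- list(C1 = get(res[["C1"]], "CA"), C2 = get(res[["C2"]], "CA"),
             H = get(res[["H"]], "CA"))
  missing_ca <- names(ca)[vapply(ca, is.null, logical(1L))]
  if (length(missing_ca))
    stop("missing anchor atom(s): CA of position ",
         paste(missing_ca, collapse = ","), " (residues ",
         paste(res[missing_ca], collapse = ","), ")")
  cb <- list(C1 = get(res[["C1"]], "CB"), C2 = get(res[["C2"]], "CB"))
  have_cb <- !vapply(cb, is.null, logical(1L))

  if (all(have_cb)) {
    anchor_names <- c("CYS1_CA", "CYS1_CB", "CYS2_CA", "CYS2_CB", "HIS_CA")
    target <- rbind(ca$C1, cb$C1, ca$C2, cb$C2, ca$H)
  } else {
    warning("C-beta missing at ", paste(names(cb)[!have_cb], collapse = ","),
            "; falling back to backbone-only (C-alpha) anchoring")
    anchor_names <- c("CYS1_CA", "CYS2_CA", "HIS_CA")
    target <- rbind(ca$C1, ca$C2, ca$H)
  }
  fit <- superpose(template_xyz(template, anchor_names), target)
  heme <- template[template$role == "heme", , drop = FALSE]
  xyz <- apply_transform(as.matrix(heme[, c("x", "y", "z")]), fit)
  heme$x <- xyz[, 1L]; heme$y <- xyz[, 2L]; heme$z <- xyz[, 3L]
  rownames(heme) <- NULL
  structure(list(site = list(chain = ch, start_index = start),
                 atoms = heme, anchor_rmsd = fit$rmsd,
                 fe = as.numeric(xyz[match("FE", heme$atom), ]),
                 fit = fit),
            class = "heme_placement")
}

#' @export
print.heme_placement <- function(x, ...) {
  cat(sprintf("Heme placed at %s:%d  anchor rmsd %.3f A, Fe = (%.2f, %.2f, %.2f)\n",
              x$site$chain, x$site$start_index, x$anchor_rmsd,
              x$fe[1L], x$fe[2L], x$fe[3L]))
  invisible(x)
}

#' Steric clash screen of a heme placement
#'
#' Flags every protein/heme atom pair closer than the sum of their van der
#' Waals radii minus `tolerance` (default 0.4 A, a conventional "serious
#' clash" margin).  Hydrogens are ignored, as are all atoms of the three
#' motif residues that become covalently joined to the heme (these side
#' chains are substituted in the design and would repack).  A uniform-grid
#' cell list keeps the search linear in atom count.
#'
#' @param structure a `protein_structure`.
#' @param placement a `heme_placement`.
#' @param tolerance allowed interpenetration below the vdW sum, Angstrom.
#' @param exclude_residues data frame (`chain`, `res_index`) of additional
#'   residues to exclude, beyond the motif's C1/C2/H positions.
#' @return object of class `clash_report`: `pairs` (protein atom, heme
#'   atom, distance, threshold), `n_clashes`, `pass`.
#' @export
clash_check <- function(structure, placement, tolerance = 0.4,
                        exclude_residues = NULL) {
  prot <- structure$atoms
  res <- motif_site_residues(placement$site$start_index)
  drop <- prot$chain == placement$site$chain & prot$res_index %in% res
  if (!is.null(exclude_residues) && nrow(exclude_residues)) {
    for (i in seq_len(nrow(exclude_residues)))
      drop <- drop | (prot$chain == exclude_residues$chain[i] &
                      prot$res_index == exclude_residues$res_index[i])
  }
  prot <- prot[!drop & prot$element != "H", , drop = FALSE]
  heme <- placement$atoms[placement$atoms$element != "H", , drop = FALSE]
  if (!all(is.finite(as.matrix(heme[, c("x", "y", "z")]))))
    stop("placement contains non-finite coordinates")

  rp <- vdw_radius(prot$element)
  rh <- vdw_radius(heme$element)
  cell <- max(rp) + max(rh)  # any clash threshold fits in one cell width
  key <- function(x, y, z) paste(floor(x / cell), floor(y / cell), floor(z / cell))
  grid <- split(seq_len(nrow(prot)), key(prot$x, prot$y, prot$z))

  pairs <- list()
  for (i in seq_len(nrow(heme))) {
    cx <- floor(heme$x[i] / cell); cy <- floor(heme$y[i] / cell)
    cz <- floor(heme$z[i] / cell)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      cand <- grid[[paste(cx + dx, cy + dy, cz + dz)]]
      if (is.null(cand)) next
      d <- sqrt((prot$x[cand] - heme$x[i])^2 + (prot$y[cand] - heme$y[i])^2 +
                (prot$z[cand] - heme$z[i])^2)
      thr <- rp[cand] + rh[i] - tolerance
      hit <- which(d < thr)
      for (h in hit) {
        j <- cand[h]
        pairs[[length(pairs) + 1L]] <- data.frame(
          chain = prot$chain[j], res_index = prot$res_index[j],
          resname = prot$resname[j], protein_atom = prot$atom[j],
          heme_atom = heme$atom[i], distance = d[h], threshold = thr[h],
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(chain = character(), res_index = integer(),
               resname = character(), protein_atom = character(),
               heme_atom = character(), distance = numeric(),
               threshold = numeric(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$distance), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_clashes = nrow(pairs),
                 pass = nrow(pairs) == 0L, tolerance = tolerance),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("Clash report (tolerance %.2f A): %d clash(es) -> %s\n",
              x$tolerance, x$n_clashes, if (x$pass) "PASS" else "FAIL"))
  if (x$n_clashes) print(utils::head(x$pairs, 10L), row.names = FALSE)
  invisible(x)
}

#' Pairwise Fe-Fe spacing of placed hemes
#'
#' @param placements list of `heme_placement` objects (>= 2).
#' @return symmetric matrix of Fe-Fe distances in nanometres, with
#'   attributes `min`, `median`, `max` over the off-diagonal entries.
#' @export
heme_spacing <- function(placements) {
  if (length(placements) < 2L)
    stop("need at least 2 placements to compute spacing")
  fe <- do.call(rbind, lapply(placements, function(p) p$fe))
  d <- as.matrix(stats::dist(fe)) / 10  # Angstrom -> nm
  off <- d[upper.tri(d)]
  attr(d, "min") <- min(off)
  attr(d, "median") <- stats::median(off)
  attr(d, "max") <- max(off)
  d
}
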