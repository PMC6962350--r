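# Deterministic synthetic-data generators.  Fixtures for every pipeline
# stage are built in code: parametric protein backbones with prescribed
# phi/psi, chains embedding CxxCH motifs at known positions, noisy Nernst
# titration curves, heme-like absorbance spectra and discrete particle-size
# distributions.  These emulate geometry and signal shape, not the fold
# topology or photophysics of real cytochromes.

# Ideal backbone internal coordinates (Engh-Huber-type values).
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.4, omega = 180
)

#' Build a backbone with prescribed phi/psi torsions
#'
#' Constructs N/CA/C/O (plus C-beta for non-glycine) atoms residue by
#' residue from fixed ideal bond lengths and angles, varying only the
#' requested phi/psi (omega fixed trans at 180 degrees).  Recomputing the
#' dihedrals of the built chain reproduces the prescription to well under
#' 0.5 degrees, which makes these chains exact oracles for the dihedral and
#' gate-scanning code.  Construction is fully deterministic.
#'
#' @param phi,psi numeric vectors of target torsions in degrees, one per
#'   residue, on `(-180, 180]`.  `phi[1]` and `psi[length(psi)]` have no
#'   geometric effect beyond carbonyl placement.
#' @param sequence one-letter sequence (default poly-alanine of matching
#'   length).
#' @param chain chain id.
#' @return a `protein_structure`.
#' @export
#' @examples
#' helix <- make_backbone(rep(-57, 20), rep(-47, 20))
#' summary(compute_backbone_dihedrals(helix)$phi[2:20])
make_backbone <- function(phi, psi, sequence = NULL, chain = "A") {
  n <- length(phi)
  if (length(psi) != n) stop("phi and psi must have equal length")
  if (n < 2L) stop("need at least 2 residues")
  if (any(phi < -180 | phi > 180 | psi < -180 | psi > 180, na.rm = TRUE))
    stop("angles must lie in [-180, 180]")
  if (is.null(sequence)) sequence <- strrep("A", n)
  if (nchar(sequence) != n) stop("sequence length must match angle vectors")
  aa <- strsplit(sequence, "")[[1L]]
  g <- BB_GEOM

  N <- CA <- C <- vector("list", n)
  N[[1L]] <- c(0, 0, 0)
  CA[[1L]] <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  C[[1L]] <- CA[[1L]] + g$ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    N[[i]] <- place_atom(N[[i - 1L]], CA[[i - 1L]], C[[i - 1L]],
                         g$c_n, g$ang_ca_c_n, psi[i - 1L])
    CA[[i]] <- place_atom(CA[[i - 1L]], C[[i - 1L]], N[[i]],
                          g$n_ca, g$ang_c_n_ca, g$omega)
    C[[i]] <- place_atom(C[[i - 1L]], N[[i]], CA[[i]],
                         g$ca_c, g$ang_n_ca_c, phi[i])
  }
  rows <- list()
  add <- function(i, name, element, xyz)
    rows[[length(rows) + 1L]] <<- data.frame(
      record = "ATOM", chain = chain, auth_number = i, icode = "",
      resname = unname(AA1TO3[aa[i]]), atom = name, altloc = "",
      x = xyz[1L], y = xyz[2L], z = xyz[3L], occupancy = 1,
      element = element, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    add(i, "N", "N", N[[i]])
    add(i, "CA", "C", CA[[i]])
    add(i, "C", "C", C[[i]])
    # carbonyl O: anti to the following N
    add(i, "O", "O", place_atom(N[[i]], CA[[i]], C[[i]],
                                g$c_o, g$ang_ca_c_o, wrap_angle(psi[i] + 180)))
    if (aa[i] != "G") {
      # C-beta from the C-N-CA frame; -122.6 deg branch gives L-chirality
      add(i, "CB", "C", place_atom(C[[i]], N[[i]], CA[[i]],
                                   g$ca_cb, g$ang_n_ca_cb, -122.6))
    }
  }
  df <- do.call(rbind, rows)
  df$aa <- aa[df$auth_number]
  atoms <- finalize_atom_table(df)
  cols <- c("chain", "res_index", "auth_number", "icode", "resname", "aa",
            "atom", "altloc", "x", "y", "z", "occupancy", "element")
  new_structure(atoms[, cols], model = 1L, source = "synthetic")
}

# uniform draw inside a gate interval, shrunk by `margin` degrees so that
# boundary values (which fail the strict gates) cannot be hit
draw_in_gate <- function(gates, pos, angle, margin = 2) {
  row <- gates[gates$position == pos & gates$angle == angle, ]
  if (!nrow(row) || !row$gated[1L]) return(stats::runif(1L, -60, -40))
  stats::runif(1L, row$min[1L] + margin, row$max[1L] - margin)
}

#' Generate a chain embedding CxxCH motifs at known positions
#'
#' Builds a single-chain structure whose backbone alternates between a
#' background conformation (ideal beta strand, which fails the x1 phi gate)
#' and embedded 6-residue `x1 C x x C H` motifs whose torsions are drawn
#' inside the given gates (or inside explicit per-position ranges).
#' Residues outside motif C/H positions are drawn from an alphabet without
#' C, H or G, so the ground-truth manifest lists every motif the chain
#' contains -- no incidental motifs, and C-beta anchors always exist.
#'
#' @param n_motifs number of motifs (>= 1).
#' @param spacing background residues between/around motifs.
#' @param gates gate set whose intervals the motif torsions are drawn from.
#' @param overrides named list of `c(min, max)` ranges keyed
#'   `"position.angle"` (e.g. `list("x1.phi" = c(-40, 0))`) that replace the
#'   gate-based draw, used to construct deliberately failing fixtures.
#' @param seed integer seed; generation is a pure function of the
#'   arguments.
#' @return list with `structure` (a `protein_structure`) and `manifest`
#'   (data frame `start_index`, `seq6`, plus the drawn torsions).
#' @export
make_motif_chain <- function(n_motifs = 5L, spacing = 10L,
                             gates = published_gates(), overrides = list(),
                             seed = 1L) {
  stopifnot(n_motifs >= 1L, spacing >= 1L)
  set.seed(seed)
  xal <- strsplit("ADEFIKLMNPQRSTVWY", "")[[1L]]  # no C, H, G
  phi <- psi <- numeric(0)
  aa <- character(0)
  manifest <- list()
  bg <- function(k) {
    list(phi = rep(-135, k), psi = rep(135, k),
         aa = sample(xal, k, replace = TRUE))
  }
  for (m in seq_len(n_motifs)) {
    b <- bg(spacing)
    phi <- c(phi, b$phi); psi <- c(psi, b$psi); aa <- c(aa, b$aa)
    start <- length(aa) + 1L
    maa <- c(sample(xal, 1L), "C", sample(xal, 1L), sample(xal, 1L), "C", "H")
    mphi <- mpsi <- numeric(6L)
    for (k in seq_len(6L)) {
      pos <- MOTIF_POSITIONS[k]
      kphi <- paste0(pos, ".phi"); kpsi <- paste0(pos, ".psi")
      mphi[k] <- if (!is.null(overrides[[kphi]]))
        stats::runif(1L, overrides[[kphi]][1L], overrides[[kphi]][2L])
      else draw_in_gate(gates, pos, "phi")
      mpsi[k] <- if (!is.null(overrides[[kpsi]]))
        stats::runif(1L, overrides[[kpsi]][1L], overrides[[kpsi]][2L])
      else draw_in_gate(gates, pos, "psi")
    }
    phi <- c(phi, mphi); psi <- c(psi, mpsi); aa <- c(aa, maa)
    manifest[[m]] <- data.frame(start_index = start,
                                seq6 = paste(maa, collapse = ""),
                                phi_x1 = mphi[1L], psi_x1 = mpsi[1L],
                                stringsAsFactors = FALSE)
  }
  b <- bg(spacing)
  phi <- c(phi, b$phi); psi <- c(psi, b$psi); aa <- c(aa, b$aa)
  list(structure = make_backbone(phi, psi, paste(aa, collapse = "")),
       manifest = do.call(rbind, manifest))
}

#' Generate a synthetic Nernst titration curve
#'
#' `A(E) = baseline + amplitude / (1 + 10^((E - Em) n / S))` plus seeded
#' Gaussian noise expressed as a fraction of the amplitude.  The reduced
#' (low-potential) branch carries the full amplitude, matching an
#' absorbance readout at the c-type heme alpha band (~550 nm) where the
#' reduced state absorbs more.
#'
#' @param Em midpoint potential, mV vs SHE.
#' @param n electrons per site.
#' @param amplitude,baseline absorbance scale and offset.
#' @param E potential grid, mV (>= 5 points).
#' @param sigma Gaussian noise s.d. as a fraction of `amplitude`.
#' @param temperature Kelvin.
#' @param seed integer seed; same seed, same curve.
#' @return data frame of class `titration_curve` with columns `E`, `A`.
#' @export
make_titration <- function(Em = -215, n = 1, amplitude = 1, baseline = 0,
                           E = seq(-350, -50, length.out = 25), sigma = 0,
                           temperature = 298.15, seed = 1L) {
  stopifnot(length(E) >= 5L, sigma >= 0)
  set.seed(seed)
  S <- nernst_slope(temperature)
  A <- baseline + amplitude / (1 + 10^((E - Em) * n / S))
  if (sigma > 0) A <- A + stats::rnorm(length(E), 0, sigma * amplitude)
  df <- data.frame(E = E, A = A)
  class(df) <- c("titration_curve", "data.frame")
  df
}

#' Generate a heme-like absorbance spectrum
#'
#' Sum of Gaussian bands: a dominant Soret band plus optional Q-band
#' features, on a wavelength grid.  Used to exercise Soret normalization
#' and peak reporting (oxidized ~407 nm vs reduced ~416 nm states).
#'
#' @param soret_nm Soret peak position, nm.
#' @param soret_height peak absorbance of the Soret band.
#' @param q_bands data frame `nm`, `height`, `width` of extra bands (NULL
#'   for none).
#' @param soret_width Gaussian s.d. of the Soret band, nm.
#' @param wavelengths grid, nm.
#' @return data frame `wavelength`, `absorbance`.
#' @export
make_spectrum <- function(soret_nm = 407, soret_height = 0.8,
                          q_bands = data.frame(nm = 530, height = 0.08,
                                               width = 18),
                          soret_width = 11, wavelengths = 350:700) {
  A <- soret_height * exp(-(wavelengths - soret_nm)^2 / (2 * soret_width^2))
  if (!is.null(q_bands) && nrow(q_bands)) {
    for (i in seq_len(nrow(q_bands)))
      A <- A + q_bands$height[i] *
        exp(-(wavelengths - q_bands$nm[i])^2 / (2 * q_bands$width[i]^2))
  }
  data.frame(wavelength = wavelengths, absorbance = A)
}

#' Generate a discrete particle-size mass distribution
#'
#' Mixture of log-normal-shaped mass peaks on a logarithmic radius grid,
#' emulating a dynamic-light-scattering regularization output (e.g. a
#' hexamer peak at ~3.5 nm plus a higher-order-assembly peak above 10 nm).
#'
#' @param components data frame `radius_nm`, `mass`, `width` (log10 s.d.).
#' @param radii radius grid in nm (default 64 log-spaced bins over
#'   0.5-200 nm, deliberately wider than the 1-100 nm averaging window).
#' @return data frame `radius`, `weight`.
#' @export
make_size_distribution <- function(components = data.frame(
                                     radius_nm = c(3.5, 20),
                                     mass = c(0.8, 0.2),
                                     width = c(0.08, 0.15)),
                                   radii = 10^seq(log10(0.5), log10(200),
                                                  length.out = 64)) {
  w <- rep(0, length(radii))
  for (i in seq_len(nrow(components)))
    w <- w + components$mass[i] *
      exp(-(log10(radii) - log10(components$radius_nm[i]))^2 /
            (2 * components$width[i]^2))
  data.frame(radius = radii, weight = w)
}
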