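# Independent oracle implementations.  These deliberately re-derive each
# quantity with a different formulation from the package code so that
# agreement is evidence, not tautology.

xprod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Dihedral via projection onto the plane normal to the central bond
# (praxeolitic formulation), IUPAC sign.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(xprod(b1, v) * w)
  atan2(y, x) * 180 / pi
}

# Optimal-superposition RMSD via Horn's quaternion eigenvalue method.
oracle_quat_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- t(Pc) %*% Qc
  S <- function(i, j) M[i, j]
  K <- matrix(c(
    S(1,1)+S(2,2)+S(3,3), S(2,3)-S(3,2),        S(3,1)-S(1,3),        S(1,2)-S(2,1),
    S(2,3)-S(3,2),        S(1,1)-S(2,2)-S(3,3), S(1,2)+S(2,1),        S(3,1)+S(1,3),
    S(3,1)-S(1,3),        S(1,2)+S(2,1),       -S(1,1)+S(2,2)-S(3,3), S(2,3)+S(3,2),
    S(1,2)-S(2,1),        S(3,1)+S(1,3),        S(2,3)+S(3,2),       -S(1,1)-S(2,2)+S(3,3)),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, (sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P)))
}

# All-pairs brute-force clash count/pairs between two atom tables.
oracle_clashes <- function(prot, heme, tolerance = 0.4) {
  hits <- 0L
  pairs <- character()
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(heme))) {
      d <- sqrt((prot$x[i] - heme$x[j])^2 + (prot$y[i] - heme$y[j])^2 +
                (prot$z[i] - heme$z[j])^2)
      thr <- hemesite::vdw_radius(prot$element[i]) +
        hemesite::vdw_radius(heme$element[j]) - tolerance
      if (d < thr) {
        hits <- hits + 1L
        pairs <- c(pairs, paste(i, j))
      }
    }
  }
  list(n = hits, pairs = sort(pairs))
}

# Exhaustive 6-mer window scan for x1-C-x-x-C-H motifs on a sequence.
oracle_motif_starts <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  if (n < 6) return(integer())
  starts <- integer()
  for (i in seq_len(n - 5)) {
    if (aa[i + 1] == "C" && aa[i + 4] == "C" && aa[i + 5] == "H")
      starts <- c(starts, i)
  }
  starts
}

# Type-7 sample quantile computed from first principles on the sorted sample.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Connected components of a set of integers (interval-merge oracle).
oracle_runs <- function(v) {
  v <- sort(unique(v))
  if (!length(v)) return(list())
  brk <- c(0L, which(diff(v) > 1L), length(v))
  lapply(seq_len(length(brk) - 1L),
         function(b) range(v[(brk[b] + 1L):brk[b + 1L]]))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2+b^2-c^2-d^2, 2*(b*c-a*d),     2*(b*d+a*c),
           2*(b*c+a*d),     a^2-b^2+c^2-d^2, 2*(c*d-a*b),
           2*(b*d-a*c),     2*(c*d+a*b),     a^2-b^2-c^2+d^2),
         3, 3, byrow = TRUE)
}

# Minimal hand-written 3-residue PDB fixture (sequence GAG), plus an
# altloc-bearing variant and the same content as mmCIF.
fixture_pdb_lines <- function() {
  c("HEADER    TEST FIXTURE",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.421   0.000  1.00  0.00           C",
    "ATOM      4  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  ALA A   2       4.042   2.803   0.100  1.00  0.00           C",
    "ATOM      6  C   ALA A   2       5.556   2.640   0.050  1.00  0.00           C",
    "ATOM      7  CB  ALA A   2       3.610   3.721   1.240  1.00  0.00           C",
    "ATOM      8  N   GLY A   3       6.281   3.751   0.120  1.00  0.00           N",
    "ATOM      9  CA  GLY A   3       7.732   3.721   0.080  1.00  0.00           C",
    "ATOM     10  C   GLY A   3       8.320   5.120   0.150  1.00  0.00           C",
    "HETATM   11  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END")
}

fixture_mmcif_lines <- function() {
  pdb <- fixture_pdb_lines()
  atom <- grep("^(ATOM|HETATM)", pdb, value = TRUE)
  hdr <- c("data_fixture", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
           "_atom_site.Cartn_z", "_atom_site.occupancy",
           "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(atom, function(l) {
    paste(trimws(substr(l, 1, 6)), trimws(substr(l, 7, 11)),
          trimws(substr(l, 77, 78)), trimws(substr(l, 13, 16)), ".",
          trimws(substr(l, 18, 20)), trimws(substr(l, 22, 22)),
          trimws(substr(l, 23, 26)), trimws(substr(l, 31, 38)),
          trimws(substr(l, 39, 46)), trimws(substr(l, 47, 54)),
          trimws(substr(l, 55, 60)), "1")
  }, character(1), USE.NAMES = FALSE)
  c(hdr, rows, "#")
}

write_fixture <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

random_coil <- function(n, seed) {
  set.seed(seed)
  make_backbone(runif(n, -179, 180), runif(n, -179, 180),
                sequence = paste(sample(strsplit("ADEFIKLMNPQRSTVWY", "")[[1]],
                                        n, replace = TRUE), collapse = ""))
}

random_clash_fixture <- function(seed, n_prot = 500, n_heme = 40) {
  set.seed(seed)
  prot <- data.frame(
    chain = "A", res_index = 100L + seq_len(n_prot), icode = "",
    auth_number = 100L + seq_len(n_prot), resname = "ALA", aa = "A",
    atom = "CA", altloc = "",
    x = runif(n_prot, 0, 30), y = runif(n_prot, 0, 30),
    z = runif(n_prot, 0, 30), occupancy = 1,
    element = sample(c("C", "N", "O", "S"), n_prot, replace = TRUE),
    stringsAsFactors = FALSE)
  heme <- data.frame(
    atom = paste0("X", seq_len(n_heme)),
    element = sample(c("C", "N", "FE"), n_heme, replace = TRUE),
    x = runif(n_heme, 0, 30), y = runif(n_heme, 0, 30),
    z = runif(n_heme, 0, 30), role = "heme", stringsAsFactors = FALSE)
  list(st = hemesite:::new_structure(prot),
       pl = structure(list(site = list(chain = "A", start_index = 1L),
                           atoms = heme), class = "heme_placement"))
}
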