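# CxxCH motif discovery, torsion aggregation, gate derivation

seq_structure <- function(seq) {
  n <- nchar(seq)
  make_backbone(rep(-57, n), rep(-47, n), sequence = seq)
}

test_that("motif discovery on constructed sequences", {
  m <- find_cxxch_motifs(seq_structure("AAACAACHAAA"))
  expect_equal(m$start_index, 3L)
  expect_equal(m$seq6, "ACAACH")

  # no histidine -> impossible motif
  expect_equal(nrow(find_cxxch_motifs(seq_structure("AAACAACAAACA"))), 0L)

  # overlapping motifs are all reported
  m2 <- find_cxxch_motifs(seq_structure("ACCAACHAACHA"))
  expect_equal(m2$start_index, oracle_motif_starts("ACCAACHAACHA"))
})

test_that("motif discovery equals the brute-force 6-mer scan on random chains", {
  set.seed(42)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:40) {
    seq <- paste(sample(alphabet, 200, replace = TRUE), collapse = "")
    # enrich C/H so motifs actually occur
    seq <- chartr("LM", "CH", seq)
    found <- find_cxxch_motifs(seq_structure(seq))$start_index
    expect_equal(found, oracle_motif_starts(seq))
  }
})

test_that("torsion aggregation: six rows per interior motif, termini excluded", {
  s <- seq_structure("AAACAACHAAA")
  d <- compute_backbone_dihedrals(s)
  m <- find_cxxch_motifs(s)
  tab <- collect_motif_torsions(m, d)
  expect_equal(nrow(tab), 6L)
  expect_setequal(tab$position, c("x1", "C1", "x2", "x3", "C2", "H"))

  # motif whose x1 is the first residue: phi(x1) undefined -> row excluded
  s2 <- seq_structure("ACAACHAAAA")
  tab2 <- collect_motif_torsions(find_cxxch_motifs(s2),
                                 compute_backbone_dihedrals(s2))
  expect_equal(nrow(tab2), 5L)
  expect_false("x1" %in% tab2$position)

  # inconsistent dihedral table -> error
  expect_error(collect_motif_torsions(m, d[d$res_index < 5, ]),
               "absent from the dihedral table")
})

test_that("row count is at most 6 x motifs, equality iff no terminus touched", {
  mc <- make_motif_chain(4, seed = 12)
  d <- compute_backbone_dihedrals(mc$structure)
  m <- find_cxxch_motifs(mc$structure)
  tab <- collect_motif_torsions(m, d)
  expect_equal(nrow(tab), 6L * nrow(m))  # generator pads both termini
})

test_that("published gates reproduce the printed constants", {
  g <- published_gates()
  gv <- function(pos, ang) {
    r <- g[g$position == pos & g$angle == ang, ]
    c(r$min, r$max, r$gated)
  }
  expect_equal(gv("C2", "phi"), c(-160, -50, 1))
  expect_equal(gv("x1", "phi"), c(-100, -50, 1))
  expect_equal(gv("C1", "psi"), c(-100, 0, 1))
  expect_equal(gv("x2", "phi"), c(-100, -25, 1))
  expect_equal(gv("x2", "psi"), c(-75, 50, 1))
  expect_equal(gv("x3", "phi"), c(-160, -50, 1))
  expect_equal(gv("x3", "psi"), c(-75, 0, 1))
  expect_equal(gv("C2", "psi"), c(-75, 25, 1))
  # psi of x1 and both histidine angles are unrestricted
  expect_false(gv("x1", "psi")[3] == 1)
  expect_false(gv("H", "phi")[3] == 1)
  expect_false(gv("H", "psi")[3] == 1)
})

make_rama_table <- function(phi, psi) {
  do.call(rbind, lapply(c("x1", "C1", "x2", "x3", "C2", "H"), function(p)
    data.frame(source = "synthetic", chain = "A", position = p,
               res_index = seq_along(phi), phi = phi, psi = psi,
               stringsAsFactors = FALSE)))
}

test_that("derive_gates recovers a uniform support at coverage 1", {
  set.seed(5)
  v <- runif(500, -100, -50)
  tab <- make_rama_table(v, v)
  g <- derive_gates(tab, coverage = 1, rounding = 5)
  r <- g[g$position == "C1" & g$angle == "phi", ]
  expect_equal(c(r$min, r$max), c(-100, -50))
})

test_that("derive_gates matches the sorted-sample quantile oracle", {
  set.seed(6)
  v <- rnorm(10000, -57, 5)
  w <- rnorm(10000, -47, 5)
  tab <- make_rama_table(v, w)
  g <- derive_gates(tab, coverage = 0.95, rounding = 5)
  r <- g[g$position == "x2" & g$angle == "phi", ]
  expect_equal(r$min, floor(oracle_quantile7(v, 0.025) / 5) * 5)
  expect_equal(r$max, ceiling(oracle_quantile7(v, 0.975) / 5) * 5)
  # roughly the generating distribution: interval near [-67, -47]
  expect_lt(abs(r$min + 67), 5 + 1e-9)
  expect_lt(abs(r$max + 47), 5 + 1e-9)
})

test_that("gates derived from in-gate data stay inside the published gates", {
  set.seed(7)
  pub <- published_gates()
  # draw 200 motifs with torsions strictly inside the published intervals
  rows <- list()
  for (pos in c("x1", "C1", "x2", "x3", "C2", "H")) {
    gphi <- pub[pub$position == pos & pub$angle == "phi", ]
    gpsi <- pub[pub$position == pos & pub$angle == "psi", ]
    rows[[pos]] <- data.frame(
      source = "synthetic", chain = "A", position = pos, res_index = 1:200,
      phi = runif(200, gphi$min + 1, gphi$max - 1),
      psi = runif(200, gpsi$min + 1, gpsi$max - 1), stringsAsFactors = FALSE)
  }
  g <- derive_gates(do.call(rbind, rows), coverage = 1, rounding = 5)
  for (i in seq_len(nrow(g))) {
    if (!g$gated[i]) next
    p <- pub[pub$position == g$position[i] & pub$angle == g$angle[i], ]
    expect_gte(g$min[i], p$min)
    expect_lte(g$max[i], p$max)
  }
})

test_that("derive_gates errors on insufficient rows, naming the position", {
  tab <- make_rama_table(rnorm(4, -57), rnorm(4, -47))
  expect_error(derive_gates(tab), "x1.phi")
})

test_that("gate sets round-trip through the key-value file", {
  p <- tempfile(fileext = ".tsv")
  write_gates(published_gates(), p)
  expect_equal(as.data.frame(read_gates(p)), as.data.frame(published_gates()))
})

test_that("training-set round trip: table quantiles recover generating torsions", {
  mc <- make_motif_chain(40, spacing = 6, seed = 33)
  tab <- collect_motif_torsions(find_cxxch_motifs(mc$structure),
                                compute_backbone_dihedrals(mc$structure))
  # x1 phi was drawn uniformly inside (-98, -52); sample quantiles must sit
  # inside the generating support and near its center
  v <- tab$phi[tab$position == "x1"]
  expect_equal(length(v), 40L)
  expect_true(all(v > -100 & v < -50))
  expect_lt(abs(median(v) + 75), 12)
})
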