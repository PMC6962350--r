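# heme template geometry, rigid placement, clash screening, Fe-Fe spacing

test_that("template satisfies its geometric invariants", {
  tpl <- heme_template()
  xyz <- function(nm) as.numeric(tpl[tpl$atom == nm, c("x", "y", "z")])
  expect_true("FE" %in% tpl$atom)
  # axial His N-epsilon 2.0 +/- 0.1 A from the iron
  expect_equal(sqrt(sum((xyz("FE") - xyz("NE2"))^2)), 2.0, tolerance = 0.05)
  # thioether S-C bond 1.81 +/- 0.05 A to the nearest heme carbon
  for (sg in c("SGB1", "SGB2")) {
    carbons <- tpl[tpl$element == "C" & tpl$role == "heme", c("x", "y", "z")]
    dmin <- min(sqrt(rowSums(sweep(as.matrix(carbons), 2, xyz(sg))^2)))
    expect_equal(dmin, 1.81, tolerance = 0.05)
  }
  # porphyrin core planar within 0.3 A
  core <- tpl[grepl("^(FE|N[A-D]|C[1-4][A-D]|CH[A-D])$", tpl$atom), ]
  expect_lt(diff(range(core$z)), 0.3)
})

motif_fixture <- function(seed = 1) {
  make_motif_chain(1, spacing = 8, seed = seed)
}

test_that("placement onto an exact copy of the template stubs has rmsd 0", {
  tpl <- heme_template()
  anchors <- tpl[tpl$role == "anchor", ]
  # fabricate a minimal structure whose motif anchor atoms coincide with
  # the template stubs (chain of 7 residues, window start at 1)
  rows <- list()
  put <- function(ri, nm, xyz)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = "A", res_index = ri, auth_number = ri, icode = "",
      resname = "ALA", aa = "A", atom = nm, altloc = "",
      x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1, element = "C",
      stringsAsFactors = FALSE)
  axyz <- function(nm) as.numeric(anchors[anchors$atom == nm, c("x", "y", "z")])
  put(2, "CA", axyz("CYS1_CA")); put(2, "CB", axyz("CYS1_CB"))
  put(5, "CA", axyz("CYS2_CA")); put(5, "CB", axyz("CYS2_CB"))
  put(6, "CA", axyz("HIS_CA"))
  st <- hemesite:::new_structure(do.call(rbind, rows))
  pl <- place_heme(st, list(chain = "A", start_index = 1))
  expect_lt(pl$anchor_rmsd, 1e-6)
  expect_equal(pl$fe, as.numeric(tpl[tpl$atom == "FE", c("x", "y", "z")]),
               tolerance = 1e-6)
})

test_that("placement is rigid and equivariant under global rotation", {
  mc <- motif_fixture(3)
  site <- list(chain = "A", start_index = mc$manifest$start_index[1])
  p0 <- place_heme(mc$structure, site)

  # intra-heme distances preserved by the rigid transform
  tpl <- heme_template()
  h0 <- as.matrix(tpl[tpl$role == "heme", c("x", "y", "z")])
  h1 <- as.matrix(p0$atoms[, c("x", "y", "z")])
  expect_equal(as.numeric(dist(h1)), as.numeric(dist(h0)), tolerance = 1e-9)

  set.seed(8)
  R <- random_rotation()
  tr <- c(5, -3, 12)
  s2 <- mc$structure
  xyz <- as.matrix(s2$atoms[, c("x", "y", "z")]) %*% t(R)
  s2$atoms$x <- xyz[, 1] + tr[1]
  s2$atoms$y <- xyz[, 2] + tr[2]
  s2$atoms$z <- xyz[, 3] + tr[3]
  p1 <- place_heme(s2, site)
  expect_equal(p1$fe, as.numeric(R %*% p0$fe + tr), tolerance = 1e-6)
  expect_equal(p1$anchor_rmsd, p0$anchor_rmsd, tolerance = 1e-9)
})

test_that("anchor rmsd equals the quaternion oracle on perturbed motifs", {
  tpl <- heme_template()
  anames <- c("CYS1_CA", "CYS1_CB", "CYS2_CA", "CYS2_CB", "HIS_CA")
  A <- as.matrix(tpl[match(anames, tpl$atom), c("x", "y", "z")])
  set.seed(19)
  for (rep in 1:20) {
    mc <- motif_fixture(rep)
    site <- list(chain = "A", start_index = mc$manifest$start_index[1])
    s <- mc$structure
    jit <- rnorm(nrow(s$atoms) * 3, sd = 0.1)
    s$atoms$x <- s$atoms$x + jit[seq_len(nrow(s$atoms))]
    pl <- place_heme(s, site)
    res <- hemesite:::motif_site_residues(site$start_index)
    a <- s$atoms
    g <- function(ri, nm) as.numeric(a[a$res_index == ri & a$atom == nm,
                                       c("x", "y", "z")])
    B <- rbind(g(res[["C1"]], "CA"), g(res[["C1"]], "CB"),
               g(res[["C2"]], "CA"), g(res[["C2"]], "CB"),
               g(res[["H"]], "CA"))
    expect_equal(pl$anchor_rmsd, oracle_quat_rmsd(A, B), tolerance = 1e-8)
  }
})

test_that("missing anchors: CA errors, CB falls back with warning", {
  mc <- motif_fixture(5)
  site <- list(chain = "A", start_index = mc$manifest$start_index[1])
  res <- hemesite:::motif_site_residues(site$start_index)
  s1 <- mc$structure
  s1$atoms <- s1$atoms[!(s1$atoms$res_index == res[["H"]] &
                           s1$atoms$atom == "CA"), ]
  expect_error(place_heme(s1, site), "missing anchor")
  s2 <- mc$structure
  s2$atoms <- s2$atoms[!(s2$atoms$res_index == res[["C1"]] &
                           s2$atoms$atom == "CB"), ]
  expect_warning(pl <- place_heme(s2, site), "backbone-only")
  expect_s3_class(pl, "heme_placement")
})

test_that("clash thresholds: two carbons at 10 A clear, at 2 A clash", {
  # r_C = 1.70, tolerance 0.4 -> threshold 3.0 A
  mk <- function(d) {
    prot <- data.frame(chain = "A", res_index = 50L, auth_number = 50L,
                       icode = "", resname = "ALA", aa = "A", atom = "CA",
                       altloc = "", x = d, y = 0, z = 0, occupancy = 1,
                       element = "C", stringsAsFactors = FALSE)
    st <- hemesite:::new_structure(prot)
    pl <- structure(list(site = list(chain = "A", start_index = 1L),
                         atoms = data.frame(atom = "C1A", element = "C",
                                            x = 0, y = 0, z = 0, role = "heme",
                                            stringsAsFactors = FALSE)),
                    class = "heme_placement")
    clash_check(st, pl, tolerance = 0.4)
  }
  expect_true(mk(10)$pass)
  r <- mk(2)
  expect_false(r$pass)
  expect_equal(r$n_clashes, 1L)
  expect_equal(r$pairs$threshold, 3.0)
  expect_equal(r$pairs$distance, 2.0)
})


test_that("grid-accelerated clash detection equals the all-pairs oracle", {
  for (seed in 1:3) {
    f <- random_clash_fixture(seed)
    got <- clash_check(f$st, f$pl, tolerance = 0.4)
    want <- oracle_clashes(f$st$atoms, f$pl$atoms, tolerance = 0.4)
    expect_equal(got$n_clashes, want$n)
  }
})

test_that("clash count is monotone in tolerance and in exclusions", {
  f <- random_clash_fixture(9)
  counts <- vapply(c(0, 0.2, 0.4, 0.8, 1.5),
                   function(tol) clash_check(f$st, f$pl, tolerance = tol)$n_clashes,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))

  base <- clash_check(f$st, f$pl, tolerance = 0)
  if (base$n_clashes > 0) {
    excl <- unique(base$pairs[, c("chain", "res_index")])
    fewer <- clash_check(f$st, f$pl, tolerance = 0, exclude_residues = excl)
    expect_lte(fewer$n_clashes, base$n_clashes)
    expect_equal(fewer$n_clashes, 0L)
  }
})

test_that("motif residues are excluded from the clash screen", {
  mc <- motif_fixture(4)
  site <- list(chain = "A", start_index = mc$manifest$start_index[1])
  pl <- place_heme(mc$structure, site)
  rep_ <- clash_check(mc$structure, pl, tolerance = 0.4)
  res <- hemesite:::motif_site_residues(site$start_index)
  expect_false(any(rep_$pairs$res_index %in% res))
})

test_that("unknown elements fall back to the default radius with a warning", {
  expect_warning(r <- vdw_radius(c("C", "XX")), "unknown element")
  expect_equal(r, c(1.70, 1.70))
})

test_that("Fe-Fe spacing: unit conversion, metric properties, hexagon", {
  mkpl <- function(fe) structure(list(fe = fe), class = "heme_placement")
  two <- list(mkpl(c(0, 0, 0)), mkpl(c(25, 0, 0)))
  d <- heme_spacing(two)
  expect_equal(d[1, 2], 2.5)
  expect_equal(d[2, 1], 2.5)
  expect_equal(diag(d), c(0, 0), ignore_attr = TRUE)

  # hexamer: six hemes at hexagon vertices, circumradius 30 A ->
  # nearest-neighbor spacing = side = 3.0 nm
  hex <- lapply(0:5, function(k)
    mkpl(30 * c(cos(k * pi / 3), sin(k * pi / 3), 0)))
  dh <- heme_spacing(hex)
  expect_equal(attr(dh, "min"), 3.0, tolerance = 1e-9)
  expect_equal(max(dh), 6.0, tolerance = 1e-9)

  expect_error(heme_spacing(two[1]), "at least 2")
})
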