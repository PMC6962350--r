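# gate scanning, region merging, mutation and insertion planning

test_that("ideal helix passes every gated position; ideal strand fails at x1", {
  helix <- make_backbone(rep(-57, 20), rep(-47, 20))
  sc <- gate_scan(compute_backbone_dihedrals(helix), published_gates())
  interior <- sc[sc$start_index >= 2 & sc$start_index <= 14, ]
  expect_true(all(interior$pass))
  # first window fails closed: phi(x1) is undefined at the N-terminus
  expect_false(sc$pass[sc$start_index == 1])
  expect_match(sc$reason[sc$start_index == 1], "undefined:x1.phi")

  strand <- make_backbone(rep(-135, 20), rep(135, 20))
  ss <- gate_scan(compute_backbone_dihedrals(strand), published_gates())
  expect_false(any(ss$pass))
  expect_true(all(grepl("x1.phi", ss$reason[ss$start_index > 1])))
})

test_that("one CandidateSite per possible window start; short chains give none", {
  d <- compute_backbone_dihedrals(make_backbone(rep(-57, 25), rep(-47, 25)))
  sc <- gate_scan(d, published_gates())
  expect_equal(nrow(sc), 25L - 5L)
  d5 <- compute_backbone_dihedrals(make_backbone(rep(-57, 5), rep(-47, 5)))
  expect_equal(nrow(gate_scan(d5, published_gates())), 0L)
})

test_that("widening any gate interval never turns a pass into a fail", {
  mc <- make_motif_chain(3, seed = 2)
  d <- compute_backbone_dihedrals(mc$structure)
  g <- published_gates()
  base <- gate_scan(d, g)
  set.seed(14)
  for (rep in 1:10) {
    g2 <- g
    i <- sample(which(g2$gated), 1)
    g2$min[i] <- g2$min[i] - runif(1, 0, 40)
    g2$max[i] <- min(180, g2$max[i] + runif(1, 0, 40))
    wide <- gate_scan(d, g2)
    expect_true(all(wide$pass[base$pass]))
  }
})

test_that("region merging: worked examples in both modes", {
  sites <- data.frame(chain = "A", start_index = c(5, 11, 12, 13, 40),
                      start_auth = c(5, 11, 12, 13, 40),
                      pass = c(FALSE, TRUE, TRUE, TRUE, TRUE),
                      reason = "", stringsAsFactors = FALSE)
  rs <- merge_regions(sites, "window-starts")
  expect_equal(rs$start_index, c(11, 40))
  expect_equal(rs$end_index, c(13, 40))
  rc <- merge_regions(sites, "covered-residues")
  expect_equal(rc$start_index, c(11, 40))
  expect_equal(rc$end_index, c(18, 45))

  sites2 <- sites
  sites2$pass <- sites2$start_index %in% c(5, 40)
  expect_equal(nrow(merge_regions(sites2, "window-starts")), 2L)
})

test_that("region merging equals connected-component labelling on random masks", {
  set.seed(31)
  for (rep in 1:50) {
    starts <- 1:60
    pass <- runif(60) < 0.3
    sites <- data.frame(chain = "A", start_index = starts, start_auth = starts,
                        pass = pass, reason = "", stringsAsFactors = FALSE)
    got <- merge_regions(sites, "window-starts")
    want <- oracle_runs(starts[pass])
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$start_index[k], want[[k]][1])
      expect_equal(got$end_index[k], want[[k]][2])
    }
    # covered mode against the same oracle on the unioned residue sets
    gotc <- merge_regions(sites, "covered-residues")
    wantc <- oracle_runs(unlist(lapply(starts[pass], function(s) s:(s + 5))))
    expect_equal(nrow(gotc), length(wantc))
    for (k in seq_along(wantc))
      expect_equal(c(gotc$start_index[k], gotc$end_index[k]), wantc[[k]],
                   ignore_attr = TRUE)
  }
})

test_that("mutation planning: worked examples", {
  # x1 = A, then KLEAH: substitutions K->C at C1 and A->C at C2
  p <- plan_mutations("AKLEAHAA", 1)
  expect_equal(p$n_substitutions, 2L)
  expect_equal(p$substitutions$from, c("K", "A"))
  expect_equal(p$substitutions$to, c("C", "C"))
  expect_equal(p$substitutions$position, c("C1", "C2"))
  expect_equal(p$window_after, "ACLECH")

  # window already a motif: empty plan
  p0 <- plan_mutations("ACLECHAA", 1)
  expect_equal(p0$n_substitutions, 0L)
  expect_equal(nrow(p0$substitutions), 0L)
  expect_equal(p0$mutated_sequence, "ACLECHAA")

  expect_error(plan_mutations("ACDEF", 1), "out of sequence bounds")
})

test_that("substitution count equals Hamming distance at the three fixed positions", {
  set.seed(77)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:200) {
    win <- sample(aa20, 6, replace = TRUE)
    seq <- paste(c("A", win, "A"), collapse = "")
    p <- plan_mutations(seq, 2)
    want <- sum(win[2] != "C", win[5] != "C", win[6] != "H")
    expect_equal(p$n_substitutions, want)
    expect_lte(p$n_substitutions, 3L)
    # x1, x2, x3 are never edited
    expect_false(any(p$substitutions$position %in% c("x1", "x2", "x3")))
    expect_equal(substr(p$window_after, 3, 4), paste(win[3:4], collapse = ""))
  }
})

test_that("insertion planning validates and round-trips", {
  seq <- strrep("A", 100)
  p <- plan_insertion(seq, 50, "ACAACH")
  expect_equal(nchar(p$sequence), 106L)
  expect_equal(substr(p$sequence, 51, 56), "ACAACH")
  expect_true(grepl("C[A-Z]{2}CH", p$sequence))
  # removing the inserted span restores the original
  restored <- paste0(substr(p$sequence, 1, 50), substr(p$sequence, 57, 106))
  expect_equal(restored, seq)

  expect_error(plan_insertion(seq, 50, "AAAAAA"), "CxxCH")
  expect_error(plan_insertion(seq, 50, "ACAACHX"), "6-mer")
  expect_error(plan_insertion(seq, 200, "ACAACH"), "outside sequence")
})

test_that("synthetic motif chains respect their construction contract", {
  mc <- make_motif_chain(5, seed = 10)
  d <- compute_backbone_dihedrals(mc$structure)
  sc <- gate_scan(d, published_gates())
  # motif windows drawn inside the gates all pass
  expect_true(all(sc$pass[match(mc$manifest$start_index, sc$start_index)]))

  # x1 phi forced outside its gate -> every motif window fails at x1
  bad <- make_motif_chain(5, overrides = list("x1.phi" = c(-40, 0)), seed = 10)
  scb <- gate_scan(compute_backbone_dihedrals(bad$structure), published_gates())
  hit <- scb[match(bad$manifest$start_index, scb$start_index), ]
  expect_false(any(hit$pass))
  expect_true(all(grepl("x1.phi", hit$reason)))
})
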