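test_that("a pristine sheet has the expected lattice counts", {
  set.seed(1)
  sh <- celluloseSheet(5, 5000)
  ct <- sheetCounts(sh)
  expect_equal(ct$n_units, 25000)
  expect_equal(ct$intact_glycosidic, 5 * 4999)
  expect_equal(ct$intact_hbonds, 4 * 5000)
  expect_equal(ct$soluble, 0)
  st <- unitStates(sh)
  expect_true(all(st$P2[, 1] == 1))      # nonreducing ends at column 0
  expect_true(all(st$P2[, 5000] == 2))   # reducing ends at column dp-1

  sh1 <- celluloseSheet(1, 4)
  ct1 <- sheetCounts(sh1)
  expect_equal(ct1$n_units, 4)
  expect_equal(ct1$intact_glycosidic, 3)
  expect_equal(ct1$intact_hbonds, 0)

  expect_error(celluloseSheet(0, 10), "positive integer")
  expect_error(celluloseSheet(2, 10.5), "positive integer")
  expect_error(celluloseSheet(2, 10, 1.2), "brokenFraction")
})

test_that("pre-cleaving cuts the deterministic rounded bond count", {
  set.seed(42)
  sh <- celluloseSheet(5, 5000, 0.05)
  ct <- sheetCounts(sh)
  n_oligo <- ct$g1 + ct$g2 + ct$g3
  # cuts = round(0.05 * 24995); dissolution of fragments shorter than 4
  # removes a further (soluble - oligomers) internal bonds
  expect_equal(24995 - ct$intact_glycosidic, 1250 + (ct$soluble - n_oligo))
  expect_equal(ct$g1 + 2 * ct$g2 + 3 * ct$g3, ct$soluble)
  # every cut carries fresh end flags on its nonsoluble incident units
  st <- unitStates(sh)
  for (c in 1:5) {
    cuts <- which(st$glycosidic[c, ] == 0)
    for (b in cuts) {
      if (st$P1[c, b] == 0) expect_equal(st$P2[c, b], 2)
      if (st$P1[c, b + 1] == 0) expect_equal(st$P2[c, b + 1], 1)
    }
  }
  # no nonsoluble fragment shorter than 4 survives
  for (c in 1:5) {
    runs <- rle(st$P1[c, ] == 0)
    frag <- integer(0); pos <- cumsum(c(1, runs$lengths))
    for (k in seq_along(runs$lengths)) if (runs$values[k]) {
      cols <- pos[k]:(pos[k] + runs$lengths[k] - 1)
      # split runs of nonsoluble units at cut bonds
      lens <- rle(cumsum(c(0, st$glycosidic[c, cols[-length(cols)]] == 0)))$lengths
      expect_true(all(lens >= 4))
    }
  }
})

test_that("cleaving a glycosidic bond creates ends and releases short fragments", {
  sh <- celluloseSheet(1, 5000)
  rel <- cleaveGlycosidic(sh, 0, 2499)
  expect_length(rel, 0)
  st <- unitStates(sh)
  expect_equal(st$P2[1, 2500], 2)  # new RE on the left unit
  expect_equal(st$P2[1, 2501], 1)  # new NE on the right unit
  expect_equal(nrow(exoSites(sh, "R")), 2)
  expect_equal(nrow(exoSites(sh, "N")), 2)

  # a fragment shorter than 4 dissolves as one oligomer
  sh2 <- celluloseSheet(1, 9)
  expect_equal(cleaveGlycosidic(sh2, 0, 5), 3L)    # 6 + 3 -> cellotriose out
  expect_equal(unname(sugarTally(sh2)["G3"]), 1)
  # splitting a short fragment into 1 + 3 gives glucose and cellotriose
  sh3 <- celluloseSheet(1, 7)
  expect_equal(cleaveGlycosidic(sh3, 0, 3), 3L)    # 4 | 3 -> G3 out, 4 stays
  rel3 <- cleaveGlycosidic(sh3, 0, 0)              # 1 + 3 from the 4-fragment
  expect_setequal(rel3, c(1L, 3L))
  expect_equal(sheetCounts(sh3)$soluble, 7)

  # cleaving one unit away from an existing cut releases one glucose
  sh4 <- celluloseSheet(1, 20)
  cleaveGlycosidic(sh4, 0, 9)
  rel4 <- cleaveGlycosidic(sh4, 0, 10)
  expect_equal(rel4, 1L)

  expect_error(cleaveGlycosidic(sh4, 0, 9), "already cleaved")
  expect_error(cleaveGlycosidic(sh4, 0, 5000), "out of range")
})

test_that("soluble units carry no bonds and conservation holds", {
  sh <- celluloseSheet(3, 12)
  # isolate a 3-unit fragment with intact flank hydrogen bonds
  cleaveGlycosidic(sh, 1, 3)  # chain 1: 4 | 8
  rel <- cleaveGlycosidic(sh, 1, 6)  # 4 | 3 | 5 -> cellotriose out
  expect_equal(rel, 3L)
  st <- unitStates(sh)
  expect_equal(st$P1[2, 5:7], c(1L, 1L, 1L))
  expect_true(all(st$hbonds[1, 5:7] == 0))  # bonds to chain 0 removed
  expect_true(all(st$hbonds[2, 5:7] == 0))  # bonds to chain 2 removed
  ct <- sheetCounts(sh)
  expect_equal(ct$soluble + sum(st$P1 == 0), 36)
  expect_equal(ct$g1 + 2 * ct$g2 + 3 * ct$g3, ct$soluble)
})

test_that("hydrogen-bond breaking is idempotent and exhaustive", {
  sh <- celluloseSheet(5, 50)
  expect_true(breakHydrogenBond(sh, 2, 10))
  expect_false(breakHydrogenBond(sh, 2, 10))
  for (p in 0:3) for (j in 0:49) breakHydrogenBond(sh, p, j)
  expect_equal(sheetCounts(sh)$intact_hbonds, 0)
  expect_error(breakHydrogenBond(sh, 4, 0), "out of range")
})

test_that("endo site enumeration matches the documented rule", {
  sh <- celluloseSheet(5, 5000)
  expect_equal(nrow(endoSites(sh)), 5 * (5000 - 8))
  expect_equal(nrow(endoSites(celluloseSheet(1, 9))), 1)
  # a connected 4..8-unit fragment is still degradable via one anchor
  sh6 <- celluloseSheet(1, 6)
  s6 <- endoSites(sh6)
  expect_equal(nrow(s6), 1)
  expect_true(s6$truncated)
  expect_equal(s6$coreStart, 1)

  # locking one core unit of every candidate removes all anchors
  shL <- celluloseSheet(1, 20)
  for (j in 3:18) CellulaseSim:::.sheet_mark(shL@ptr, 0L, as.integer(j), "lock")
  expect_equal(nrow(endoSites(shL)), 0)
})

test_that("exo site enumeration matches the documented rule", {
  sh <- celluloseSheet(5, 5000)
  expect_equal(nrow(exoSites(sh, "R")), 5)
  expect_equal(nrow(exoSites(sh, "N")), 5)
  cleaveGlycosidic(sh, 2, 2400)
  expect_equal(nrow(exoSites(sh, "R")), 6)  # each interior cut adds one RE
  expect_equal(nrow(exoSites(sh, "N")), 6)
  # a fragment of 8 units carrying an RE is not an anchor
  sh8 <- celluloseSheet(1, 30)
  cleaveGlycosidic(sh8, 0, 21)  # 22 | 8
  expect_equal(nrow(exoSites(sh8, "R")), 1)  # only the cut-created RE at 21
  expect_equal(exoSites(sh8, "R")$column, 21)
})

test_that("site enumeration equals a brute-force rescan on random sheets", {
  set.seed(99)
  for (case in 1:8) {
    nc <- sample(1:5, 1); dp <- sample(12:50, 1)
    sh <- celluloseSheet(nc, dp, runif(1, 0, 0.08))
    st <- unitStates(sh)
    # random extra cuts and fixture marks
    for (k in 1:6) {
      c <- sample(nc, 1) - 1; b <- sample(dp - 1, 1) - 1
      ok <- st$glycosidic[c + 1, b + 1] == 1 &&
        st$P1[c + 1, b + 1] == 0 && st$P1[c + 1, b + 2] == 0
      if (ok) cleaveGlycosidic(sh, c, b)
      st <- unitStates(sh)
    }
    for (k in 1:4) {
      c <- sample(nc, 1) - 1; j <- sample(dp, 1) - 1
      if (st$P1[c + 1, j + 1] == 0)
        CellulaseSim:::.sheet_mark(sh@ptr, as.integer(c), as.integer(j),
                                   sample(c("lock", "cover"), 1))
      st <- unitStates(sh)
    }
    got <- endoSites(sh)
    got <- got[order(got$chain, got$column, got$truncated), ]
    want <- as.data.frame(bf_endo_sites(st))
    want$truncated <- want$truncated == 1
    want <- want[order(want$chain, want$column, want$truncated), ]
    expect_equal(unname(as.matrix(got[, 1:3])), unname(as.matrix(want[, 1:3])))
    expect_equal(got$truncated, want$truncated)
    for (end in c("R", "N")) {
      gotx <- exoSites(sh, end)
      gotx <- gotx[order(gotx$chain, gotx$column), ]
      wantx <- as.data.frame(bf_exo_sites(st, end))
      expect_equal(unname(as.matrix(gotx)), unname(as.matrix(wantx)))
    }
  }
})

test_that("substrate metrics use the anhydroglucose mass and cellobiose area", {
  sh <- celluloseSheet(5, 5000)
  m <- substrateMetrics(sh)
  expect_equal(m$surface_area_m2, 12500 * 5.512e-19, tolerance = 1e-12)
  expect_equal(m$mass_g, 25000 * 162.1406 / 6.02214076e23, tolerance = 1e-12)
  expect_equal(unname(m$sites_per_gram["endo"]), 24960 / m$mass_g)
  # fully dissolved sheet reports zero mass and zero site density
  shd <- celluloseSheet(1, 4)
  cleaveGlycosidic(shd, 0, 1)
  md <- substrateMetrics(shd)
  expect_equal(md$mass_g, 0)
  expect_true(all(md$sites_per_gram == 0))
})

test_that("sheet snapshots round-trip through JSON", {
  set.seed(5)
  sh <- celluloseSheet(4, 40, 0.05)
  cleaveGlycosidic(sh, 1, 20)
  breakHydrogenBond(sh, 0, 7)
  path <- tempfile(fileext = ".json")
  writeSheetJSON(sh, path)
  sh2 <- readSheetJSON(path)
  expect_equal(unitStates(sh2), unitStates(sh))
  expect_equal(sheetCounts(sh2), sheetCounts(sh))
  unlink(path)
})
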