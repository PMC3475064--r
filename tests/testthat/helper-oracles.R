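# Independent oracles used by the tests.  These re-derive quantities from
# first principles (brute-force scans, closed-form Markov-chain algebra) and
# never call the engine code paths they check.

N_AVOGADRO <- 6.02214076e23
A_G2 <- 5.512e-19

# --- brute-force site enumeration over the raw state matrices --------------

# endo anchors: 9-column windows with a nonsoluble middle chain and an
# unblocked 4-column core on the three footprint chains, plus one anchor per
# connected fragment of 4..8 units (core centred on the fragment)
bf_endo_sites <- function(st) {
  nc <- nrow(st$P1); dp <- ncol(st$P1)
  blocked <- (st$P3 | st$P4 | st$P5 | st$P6 | st$P7)
  blk3 <- function(c, j) {
    any(blocked[max(1, c - 1):min(nc, c + 1), j])
  }
  out <- NULL
  for (c in seq_len(nc)) {
    if (dp >= 9) {
      for (j in seq_len(dp - 8)) {
        if (any(st$P1[c, j:(j + 8)] == 1)) next
        core <- (j + 3):(j + 6)
        if (any(vapply(core, function(m) blk3(c, m), logical(1)))) next
        out <- rbind(out, c(c - 1, j - 1, j + 2, 0))
      }
    }
    # maximal connected fragments
    j <- 1
    while (j <= dp) {
      if (st$P1[c, j] == 1) { j <- j + 1; next }
      a <- j
      while (j < dp && st$glycosidic[c, j] == 1 && st$P1[c, j + 1] == 0)
        j <- j + 1
      len <- j - a + 1
      if (len >= 4 && len <= 8) {
        core <- (a + (len - 4) %/% 2):(a + (len - 4) %/% 2 + 3)
        if (!any(vapply(core, function(m) blk3(c, m), logical(1))))
          out <- rbind(out, c(c - 1, a - 1, core[1] - 1, 1))
      }
      j <- j + 1
    }
  }
  if (is.null(out)) out <- matrix(integer(), 0, 4)
  colnames(out) <- c("chain", "column", "coreStart", "truncated")
  out[order(out[, 1], out[, 2], out[, 4]), , drop = FALSE]
}

# exo anchors: free chain ends with 9 intact terminal units and an
# unblocked up-to-27-unit footprint
bf_exo_sites <- function(st, end = "R") {
  nc <- nrow(st$P1); dp <- ncol(st$P1)
  blocked <- (st$P3 | st$P4 | st$P5 | st$P6 | st$P7)
  want <- if (end == "R") 2 else 1
  dir <- if (end == "R") -1 else 1
  out <- NULL
  for (c in seq_len(nc)) for (e in seq_len(dp)) {
    if (st$P1[c, e] == 1 || st$P2[c, e] != want) next
    inner <- e + 8 * dir
    if (inner < 1 || inner > dp) next
    win <- min(e, inner):max(e, inner)
    if (any(st$P1[c, win] == 1)) next
    bonds <- win[-length(win)]
    if (any(st$glycosidic[c, bonds] == 0)) next
    rows <- max(1, c - 1):min(nc, c + 1)
    if (any(blocked[rows, win])) next
    out <- rbind(out, c(c - 1, e - 1))
  }
  if (is.null(out)) out <- matrix(integer(), 0, 2)
  colnames(out) <- c("chain", "column")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# --- closed-form CTMC for the small-lattice first-cleavage oracle ----------

# One endo-cellulase on a pristine 3 x 9 sheet.  There are three sites (each
# chain can be the middle chain); the edge sites each use the 4 core
# hydrogen bonds of one chain pair, the middle site uses all 8.  Broken
# bonds persist across visits.  State: free/bound-at-site x (intact bonds in
# pair 1, intact bonds in pair 2).  Returns the expected time to the first
# glycosidic cleavage from the pristine free state.
ctmc_first_cleavage_mean <- function(kon, koff, kgly, khb, volumeL) {
  a <- kon * 1 * 3 / (N_AVOGADRO * volumeL)
  idx <- function(state, k0, k1) {
    # state: 1 free, 2 bound site0 (edge, pair 1), 3 bound site1 (middle),
    # 4 bound site2 (edge, pair 2)
    (state - 1) * 25 + k0 * 5 + k1 + 1
  }
  n <- 100
  A <- matrix(0, n, n); b <- numeric(n)
  for (k0 in 0:4) for (k1 in 0:4) {
    iF <- idx(1, k0, k1)
    A[iF, iF] <- 1
    b[iF] <- 1 / a
    for (s in 2:4) A[iF, idx(s, k0, k1)] <- -1 / 3
    # edge site on chain pair 1: its remaining bonds are k0
    for (s in c(2, 4)) {
      iB <- idx(s, k0, k1)
      k <- if (s == 2) k0 else k1
      A[iB, iB] <- 1
      if (k > 0) {
        r <- khb + koff
        b[iB] <- 1 / r
        tgt <- if (s == 2) idx(2, k0 - 1, k1) else idx(4, k0, k1 - 1)
        A[iB, tgt] <- A[iB, tgt] - khb / r
        A[iB, iF] <- A[iB, iF] - koff / r
      } else {
        r <- kgly + koff
        b[iB] <- 1 / r
        A[iB, iF] <- A[iB, iF] - koff / r   # cleavage absorbs
      }
    }
    iB <- idx(3, k0, k1)   # middle site sees both pairs
    A[iB, iB] <- 1
    k <- k0 + k1
    if (k > 0) {
      r <- khb + koff
      b[iB] <- 1 / r
      if (k0 > 0) A[iB, idx(3, k0 - 1, k1)] <- -khb / r * k0 / k
      if (k1 > 0) A[iB, idx(3, k0, k1 - 1)] <- -khb / r * k1 / k
      A[iB, iF] <- A[iB, iF] - koff / r
    } else {
      r <- kgly + koff
      b[iB] <- 1 / r
      A[iB, iF] <- A[iB, iF] - koff / r
    }
  }
  solve(A, b)[idx(1, 4, 4)]
}

# system volume used by the engine for a sheet of n units
sheet_volume_L <- function(n_units, d = 1e-6, aG2 = A_G2) {
  n_units / 2 * aG2 * d * 1000
}

# run one replica from simple arguments (test shorthand)
quick_run <- function(nChains, dp, species, seed, threshold = 1,
                      d = 1e-6, tMax = Inf, sampleInterval = 60,
                      brokenFraction = 0) {
  set.seed(seed)
  sys <- hydrolysisSystem(celluloseSheet(nChains, dp, brokenFraction),
                          species, d = d)
  runHydrolysis(sys, threshold = threshold, tMax = tMax,
                sampleInterval = sampleInterval)
}
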