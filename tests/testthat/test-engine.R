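test_that("adsorption propensity is mass-action in free enzymes and sites", {
  set.seed(1)
  sys <- hydrolysisSystem(celluloseSheet(5, 5000), endoCellulase(count = 8))
  a <- adsorptionPropensity(sys, "endo")
  v <- systemVolume(sys)
  expect_equal(v, 12500 * 5.512e-19 * 1e-6 * 1000, tolerance = 1e-12)
  expect_equal(a, 100 * 8 * 24960 / (6.02214076e23 * v), tolerance = 1e-12)
  expect_equal(round(a, 1), 4.8)

  # zero free enzymes or zero sites give zero propensity
  sys0 <- hydrolysisSystem(celluloseSheet(5, 5000), endoCellulase(count = 0))
  expect_equal(adsorptionPropensity(sys0, 1), 0)
  shd <- celluloseSheet(1, 4)
  cleaveGlycosidic(shd, 0, 1)
  sysd <- hydrolysisSystem(shd, endoCellulase(count = 5))
  expect_equal(adsorptionPropensity(sysd, 1), 0)
})

test_that("enzyme counts follow from molar concentration and volume", {
  expect_equal(enzymeCountFromConcentration(2e-6, 6.89e-18), 8L)
  expect_equal(enzymeCountFromConcentration(0, 1e-18), 0L)
  n1 <- enzymeCountFromConcentration(3e-6, 5e-18)
  n2 <- enzymeCountFromConcentration(3e-6, 1e-17)
  expect_equal(n2, 2L * n1)
  expect_error(enzymeCountFromConcentration(-1, 1e-18), ">= 0")
})

test_that("simulated time is nondecreasing and conservation holds at every event", {
  set.seed(2)
  sys <- hydrolysisSystem(celluloseSheet(3, 150),
                          list(endoCellulase(count = 2),
                               exoCellulase("R", count = 2)))
  t_prev <- 0
  for (k in 1:4000) {
    ev <- stepEvent(sys)
    if (!ev$fired) break
    expect_gte(ev$time, t_prev)
    t_prev <- ev$time
    ct <- sheetCounts(sys)
    # soluble + nonsoluble units conserved; tally matches soluble units
    expect_equal(ct$g1 + 2 * ct$g2 + 3 * ct$g3, ct$soluble)
  }
  expect_equal(sheetCounts(sys)$n_units, 450)
})

test_that("identical seeds reproduce identical runs", {
  run <- function() {
    set.seed(77)
    sys <- hydrolysisSystem(celluloseSheet(3, 200),
                            list(endoCellulase(count = 2),
                                 exoCellulase("R", count = 2)))
    runHydrolysis(sys, threshold = 1, sampleInterval = 30)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$finalTime, r2$finalTime)
  expect_identical(r1$tally, r2$tally)
})

test_that("runs without enzymes terminate immediately at the initial conversion", {
  cfg <- hydrolysisConfig(
    substrate = list(n_chains = 5, dp = 200, broken_fraction = 0.1),
    species = list(),
    system = list(allow_zero_enzymes = TRUE),
    rng = list(seed = 3, replicas = 1))
  res <- simulateHydrolysis(cfg)
  expect_equal(terminationReason(res), "exhausted")
  df <- trajectory(res)
  expect_equal(nrow(df), 1)
  expect_equal(df$time_s, 0)
  expect_gt(df$conversion, 0)
  expect_equal(df$conversion, sum(finalTally(res) * c(1, 2, 3)) / 1000)
})

test_that("a single exo-R converts a pristine even chain completely to cellobiose", {
  res <- quick_run(1, 300, exoCellulase("R", count = 1, alpha = 0), seed = 4)
  expect_equal(res$termination, "threshold")
  expect_equal(res$conversion, 1.0)
  expect_equal(unname(res$tally), c(0, 150, 0))
})

test_that("endo-only hydrolysis gives a monotone conversion curve reaching 1", {
  res <- quick_run(3, 200, endoCellulase(count = 3), seed = 5,
                   sampleInterval = 30)
  expect_equal(res$termination, "threshold")
  df <- res$trajectory
  expect_true(all(diff(df$conversion) >= 0))
  expect_equal(df$conversion[nrow(df)], 1.0)
  # first-passage grid is internally consistent with the trajectory
  expect_lte(res$firstPassage["p50"], res$firstPassage["p80"])
})

test_that("the hard time wall stops pathological runs", {
  res <- quick_run(5, 400, endoCellulase(count = 1, kOn = 1e-3), seed = 6,
                   tMax = 500)
  expect_equal(res$termination, "t_max")
  expect_equal(res$finalTime, 500)
})

test_that("post-cleavage desorption delays are Exponential(k_off)", {
  # collect desorb-after-cleave waiting times from a production run
  set.seed(8)
  sys <- hydrolysisSystem(celluloseSheet(5, 5000), endoCellulase(count = 8))
  cleave_t <- rep(NA_real_, 8)
  delays <- numeric(12000)
  nd <- 0
  while (nd < 1e4) {
    ev <- stepEvent(sys)
    if (!ev$fired) break
    if (ev$kind == "agent") {
      if (ev$action == "cleave") cleave_t[ev$who + 1] <- ev$time
      else if (ev$action == "desorb" && !is.na(cleave_t[ev$who + 1])) {
        nd <- nd + 1
        delays[nd] <- ev$time - cleave_t[ev$who + 1]
        cleave_t[ev$who + 1] <- NA_real_
      } else cleave_t[ev$who + 1] <- NA_real_
    }
  }
  delays <- delays[seq_len(nd)]
  expect_gte(length(delays), 1e4)
  ks <- stats::ks.test(delays, "pexp", rate = 0.1)
  expect_gt(ks$p.value, 0.01)
})

test_that("mean first-cleavage time matches the closed-form Markov chain", {
  # one endo on a 3 x 9 sheet: 3 overlapping sites sharing 8 core hydrogen
  # bonds; broken bonds persist across visits
  kon <- 100; koff <- 0.1; kgly <- 0.35; khb <- 1e12
  vol <- sheet_volume_L(27)
  expected <- ctmc_first_cleavage_mean(kon, koff, kgly, khb, vol)
  set.seed(9)
  n <- 1200
  times <- vapply(seq_len(n), function(i) {
    sys <- hydrolysisSystem(celluloseSheet(3, 9), endoCellulase(count = 1))
    repeat {
      ev <- stepEvent(sys)
      if (ev$kind == "agent" && ev$action == "cleave") return(ev$time)
    }
  }, numeric(1))
  se <- stats::sd(times) / sqrt(n)
  expect_lt(abs(mean(times) - expected), 3 * se)
})

test_that("enzyme loading saturates once sites are crowded", {
  # beyond saturation, extra enzymes do not speed up conversion
  t50 <- vapply(c(200, 400), function(n) {
    res <- quick_run(3, 200, endoCellulase(count = n), seed = 10,
                     threshold = 0.6, sampleInterval = 30)
    unname(res$firstPassage["p50"])
  }, numeric(1))
  expect_lt(abs(t50[2] - t50[1]) / t50[1], 0.25)
})
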