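# synthetic cohort generator: determinism, conservation, clock calibration,
# scar planting, signature draws, driver exclusivity

test_that("simulation is deterministic given the seed", {
  cc <- cohortConfig(n_patients = 3, seed = 17)
  a <- simulateCohort(cc)
  b <- simulateCohort(cc)
  expect_identical(a$variants, b$variants)
  expect_identical(a$alterations, b$alterations)
  expect_identical(lapply(a$profiles, lapply, segments),
                   lapply(b$profiles, lapply, segments))
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("per-sample variant counts equal ground-truth edge descent", {
  sim <- simulateCohort(cohortConfig(n_patients = 4, seed = 5))
  for (pt in names(sim$variants)) {
    v <- sim$variants[[pt]]
    gt <- sim$ground_truth[[pt]]
    # every variant appears in exactly one edge assignment
    expect_equal(sort(gt$assignment$variant), sort(variantKey(v)))
    for (sm in gt$samples) {
      edges_of_sm <- gt$edges$id[vapply(gt$edges$desc, function(d)
        sm %in% strsplit(d, "+", fixed = TRUE)[[1]], logical(1))]
      expect_equal(sum(v[[sm]]),
                   sum(gt$assignment$edge %in% edges_of_sm))
    }
  }
})

test_that("zero branch durations put every variant on the trunk", {
  cc <- cohortConfig(n_patients = 2, origin_months = 5,
                     divergence_months = 5, recurrence_months = c(0, 0),
                     seed = 3)
  sim <- simulateCohort(cc)
  for (pt in names(sim$ground_truth))
    expect_true(all(sim$ground_truth[[pt]]$assignment$class == "trunk"))
})

test_that("trunk clock counts match the Poisson mean over many patients", {
  r <- 8; t_div <- 3
  sim <- simulateCohort(cohortConfig(n_patients = 200, origin_months = 9,
                                     divergence_months = t_div,
                                     clock_rate = r, seed = 11))
  trunk_clock <- vapply(sim$ground_truth, function(gt)
    sum(gt$assignment$class == "trunk" &
          gt$assignment$signature == "AC1"), numeric(1))
  mu <- r * t_div
  se <- sqrt(mu / length(trunk_clock))
  expect_lt(abs(mean(trunk_clock) - mu), 3 * se)
})

test_that("driver genotypes always respect the exclusivity rules", {
  cc <- cohortConfig(n_patients = 50, seed = 23)
  sim <- simulateCohort(cc)
  alt <- sim$alterations != "none"
  for (rule in cc$driver_rules)
    expect_false(any(alt[rule[1], ] & alt[rule[2], ]))
})

test_that("scar planting closes the loop with the scoring module", {
  g <- toyGenomeBuild()
  zero <- plantScarProfile(c(0, 0, 0), g)
  expect_equal(unname(brute_hrd(zero, g)), c(0, 0, 0))
  expect_true(all(segments(zero)$total_cn == 2))

  p <- plantScarProfile(c(2, 1, 3), g)
  sc <- hrdScores(p, g)
  expect_equal(c(sc$loh, sc$tai, sc$lst), c(2, 1, 3))

  # sum-42 plant on the human-scale build classifies positive
  g37 <- grch37GenomeBuild()
  p42 <- plantScarProfile(c(14, 14, 14), g37)
  sc42 <- hrdScores(p42, g37)
  expect_equal(c(sc42$loh, sc42$tai, sc42$lst), c(14, 14, 14))
  expect_true(isHRDPositive(hrdClassify(sc42)))

  expect_error(plantScarProfile(c(0, 40, 0), g), "unachievable")
})

test_that("signature mutation draws follow the multinomial model", {
  ref <- referenceSignatures()
  mix <- setNames(c(1, 0, 0, 0, 0), colnames(ref))
  expect_equal(sum(simulateSignatureMutations(0, mix, ref)), 0)
  x <- simulateSignatureMutations(1000, mix, ref, seed = 7)
  expect_equal(sum(x), 1000)
  # multinomial 99% envelope around the AC1 channel probabilities
  pr <- ref[, "AC1"]
  z <- (x - 1000 * pr) / sqrt(pmax(1000 * pr * (1 - pr), 1e-9))
  expect_lt(max(abs(z)), qnorm(1 - 0.01 / (2 * 96)))

  # two disjoint-support toy signatures split mass 50/50
  toy <- matrix(0, 96, 2, dimnames = list(channels96(), c("a", "b")))
  toy[1:48, 1] <- 1 / 48; toy[49:96, 2] <- 1 / 48
  y <- simulateSignatureMutations(2000, c(a = .5, b = .5), toy, seed = 8)
  expect_lt(abs(sum(y[1:48]) - 1000) / 1000, 0.1)
  expect_error(simulateSignatureMutations(10, c(0.5, 0.5), ref), "mix length")
})

test_that("infeasible configs are rejected", {
  expect_error(cohortConfig(origin_months = 3, divergence_months = 5),
               "infeasible")
  expect_error(cohortConfig(clock_rate = 0))
  expect_error(cohortConfig(signature_mix = c(AC1 = 0.5, AC3 = 0.2)))
})
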