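test_that("panel generation is a pure function of parameters and seed", {
  a <- simulatePanel(30, 50, 2, 0.05, seed = 7)
  b <- simulatePanel(30, 50, 2, 0.05, seed = 7)
  expect_identical(dosages(a$genotypes), dosages(b$genotypes))
  expect_identical(a$population, b$population)
  c <- simulatePanel(30, 50, 2, 0.05, seed = 8)
  expect_false(identical(dosages(a$genotypes), dosages(c$genotypes)))
  # seeded generators do not disturb the caller's RNG stream
  set.seed(123); r1 <- rnorm(1)
  set.seed(123); invisible(simulatePanel(10, 20, 1, 0, seed = 3))
  expect_identical(rnorm(1), r1)
})

test_that("no differentiation at fst = 0; Balding-Nichols FST is recovered", {
  p0 <- simulatePanel(200, 10000, 2, 0, seed = 11)
  d <- dosages(p0$genotypes)
  sp <- p0$population$subpopulation
  f1 <- colMeans(d[sp == unique(sp)[1], ]) / 2
  f2 <- colMeans(d[sp == unique(sp)[2], ]) / 2
  expect_lt(mean(abs(f1 - f2)), 0.02 + 2 * sqrt(0.25 / 100))
  p <- simulatePanel(300, 5000, 3, 0.05, seed = 12)
  fst <- wcFst(dosages(p$genotypes), p$population$subpopulation)
  expect_lt(abs(fst - 0.05), 0.015)
})

test_that("parameter errors are raised", {
  expect_error(simulatePanel(10, 20, 2, fst = 1), "fst")
  expect_error(simulatePanel(10, 20, 2, fst = -0.1), "fst")
  expect_error(simulatePanel(10, 1, 2, fst = 0.1), "nMarkers")
  expect_error(simulatePanel(10, 20, 2, 0.1, subpopSizes = c(3, 3)),
               "sum")
})

test_that("meiosis respects Mendelian segregation at a single locus", {
  # parents: both heterozygous at M1, both ref-homozygous at M2,
  # opposite homozygotes at M3
  hapA <- rbind(c(1, 0, 1), c(1, 0, 0))
  hapB <- rbind(c(0, 0, 1), c(0, 0, 0))
  ph <- phasedFromHaps(hapA, hapB)
  off <- dosages(simulateCross(ph, "p01", "p02", 10000, seed = 5))
  expect_true(all(off[, 2] == 0))                  # monomorphic
  expect_true(all(off[, 3] == 1))                  # forced heterozygosity
  props <- table(factor(off[, 1], levels = 0:2)) / nrow(off)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 0.02))
})

test_that("offspring mean dosage converges to the parental average", {
  set.seed(31)
  hapA <- matrix(rbinom(2 * 10, 1, 0.5), 2)
  hapB <- matrix(rbinom(2 * 10, 1, 0.5), 2)
  ph <- phasedFromHaps(hapA, hapB)
  off <- dosages(simulateCross(ph, "p01", "p02", 10000, seed = 6))
  mid <- (hapA[1, ] + hapB[1, ] + hapA[2, ] + hapB[2, ]) / 2
  expect_true(all(abs(colMeans(off) - mid) < 0.02))
})

test_that("crossover counts scale with map length (Haldane model)", {
  # parent 1 heterozygous everywhere with hapA all-1; parent 2 null
  # homozygote, so each offspring dosage vector reads out one gamete of
  # parent 1 and phase switches count observable crossovers
  k <- 201
  countSwitches <- function(mapLen, seed) {
    ph <- phasedFromHaps(rbind(rep(1, k), rep(0, k)),
                         rbind(rep(0, k), rep(0, k)), mapLen = mapLen)
    off <- dosages(simulateCross(ph, "p01", "p02", 1000, seed = seed))
    mean(rowSums(abs(off[, -1] - off[, -k]) > 0))
  }
  s1 <- countSwitches(100, 7)
  s2 <- countSwitches(200, 8)
  expect_lt(abs(s1 - 1), 0.12)        # ~Poisson(1) mean, minus double-XO loss
  expect_gt(s2 / s1, 2 * 0.9)
  expect_lt(s2 / s1, 2 * 1.1)
})

test_that("unphased parents are rejected with guidance", {
  d <- dosageFromMatrix(matrix(c(0, 1, 2, 1), 2))
  expect_error(simulateCross(d, "i01", "i02", 5), "phase")
})

test_that("half-diallel enumerates all unordered parent pairs once", {
  set.seed(41)
  mk <- function(np) phasedFromHaps(matrix(rbinom(np * 20, 1, 0.5), np),
                                    matrix(rbinom(np * 20, 1, 0.5), np))
  expect_equal(nrow(makeHalfDiallel(mk(5), 2, seed = 1)$crosses), 10)
  expect_equal(nrow(makeHalfDiallel(mk(2), 2, seed = 1)$crosses), 1)
  expect_equal(nrow(makeHalfDiallel(mk(6), 2, seed = 1)$crosses), 15)
  hd <- makeHalfDiallel(mk(5), 3, seed = 2)
  pairs <- paste(pmin(hd$crosses$parent1, hd$crosses$parent2),
                 pmax(hd$crosses$parent1, hd$crosses$parent2))
  expect_false(anyDuplicated(pairs) > 0)
  expect_true(all(hd$crosses$parent1 != hd$crosses$parent2))
  ph <- mk(3)
  rownames(ph@hapA) <- rownames(ph@hapB) <- c("a", "a", "b")
  expect_error(makeHalfDiallel(ph, 2), "duplicate")
})

test_that("phenotype simulation calibrates the plug-in heritability", {
  st <- makeStudy(nPanel = 40, nMarkers = 150, nOff = 15, seed = 3)
  sim <- st$sims[[1]]
  expect_lt(abs(sim$pluginH2 - 0.8), 0.02)
  # noise-free: repeated plot values of a genotype identical
  arch0 <- st$archs[[1]]
  arch0@yearInteractionSd <- 0; arch0@spatialSd <- 0; arch0@residualSd <- 0
  arch0@targetH2 <- 1
  sim0 <- simulatePhenotypes(st$hd$genotypes, st$hd$population, arch0,
                             seed = 4)
  spread <- tapply(sim0$records$value, sim0$records$genotype,
                   function(v) diff(range(v)))
  # year and block main effects are fixed; within one year x block cell the
  # genotype value must be unique
  one <- sim0$records[sim0$records$year == "Y1" & sim0$records$block == "B1", ]
  expect_equal(length(unique(one$value)), length(unique(one$genotype)))
  # unattainable target: all non-genetic sds zero but target < 1
  archBad <- arch0
  archBad@targetH2 <- 0.8
  expect_error(simulatePhenotypes(st$hd$genotypes, st$hd$population,
                                  archBad, seed = 4), "implied H2 = 1")
})

test_that("cross-variance share calibration hits its target", {
  st <- makeStudy(nPanel = 40, nMarkers = 150, nOff = 20, seed = 5)
  ratios6 <- numeric(20); ratios3 <- numeric(20)
  archHigh <- calibrateCrossShare(st$hd$genotypes, st$hd$population,
                                  st$archs[[1]], 0.6)
  expect_gt(archHigh@crossDeviationSd, 0)   # additive share < 0.6: sd added
  archLow <- calibrateCrossShare(st$hd$genotypes, st$hd$population,
                                 st$archs[[1]], 0.3)
  for (s in seq_len(20)) {
    tc6 <- simulatePhenotypes(st$hd$genotypes, st$hd$population, archHigh,
                              seed = 100 + s)$trueComponents
    ratios6[s] <- tc6[["C"]] / (tc6[["C"]] + tc6[["G"]])
    tc3 <- simulatePhenotypes(st$hd$genotypes, st$hd$population, archLow,
                              seed = 200 + s)$trueComponents
    ratios3[s] <- tc3[["C"]] / (tc3[["C"]] + tc3[["G"]])
  }
  expect_lt(abs(mean(ratios6) - 0.6), 0.05)
  expect_lt(abs(mean(ratios3) - 0.3), 0.05)
})

test_that("trait architecture class constraints are enforced", {
  st <- makeStudy(nPanel = 30, nMarkers = 150, nOff = 10, seed = 6)
  expect_error(makeTraitArchitecture(st$hd$genotypes, "x", "oligogenic",
                                     50, 0.5), "oligogenic")
  expect_error(makeTraitArchitecture(st$hd$genotypes, "x", "polygenic",
                                     20, 0.5), "polygenic")
  a <- makeTraitArchitecture(st$hd$genotypes, "x", "oligogenic", 5, 0.5,
                             seed = 2)
  expect_s4_class(a, "TraitArchitecture")
  expect_true(all(a@qtlMarkerIds %in% markerIds(st$hd$genotypes)))
})
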