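test_that("10-fold assignment trains on 90% in every fold", {
  f <- cvFolds(650, 10, seed = 3)
  expect_equal(length(f), 650)
  expect_true(all(table(f) == 65))
  for (k in 1:10) expect_equal(sum(f != k), 585)
  expect_identical(cvFolds(650, 10, 3), f)
})

test_that("predictive-ability tables follow their definitions", {
  # hand-sized 5-pair correlation against the direct formula
  obs <- c(1.2, -0.5, 0.3, 2.0, -1.1)
  pred <- c(0.8, -0.2, 0.6, 1.5, -0.9)
  pa <- computePA(obs, pred, rep("C1", 5), rep("t1", 5), "per_cross")
  direct <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(pa$pa, direct, tolerance = 1e-12)
  expect_equal(computePA(obs, obs, rep("C1", 5), rep("t1", 5),
                         "per_cross")$pa, 1)
  expect_equal(computePA(obs, -obs, rep("C1", 5), rep("t1", 5),
                         "per_cross")$pa, -1)
  # groups under 3 pairs are dropped with a warning
  expect_warning(
    small <- computePA(c(obs, 1, 2), c(pred, 1, 2),
                       c(rep("C1", 5), "C2", "C2"),
                       rep("t1", 7), "per_cross"),
    "fewer than 3")
  expect_equal(nrow(small), 1)
  # zero variance in a group gives NA, never 0
  z <- computePA(rep(1, 5), pred, rep("C1", 5), rep("t1", 5), "per_cross")
  expect_true(is.na(z$pa))
})

test_that("best-method selection maximizes PA with ties to ridge", {
  expect_equal(bestMethod(0.3, 0.5), list(method = "LASSO", pa = 0.5))
  expect_equal(bestMethod(-0.1, -0.2), list(method = "RR", pa = -0.1))
  expect_equal(bestMethod(0.4, 0.4), list(method = "RR", pa = 0.4))
  expect_equal(bestMethod(NA, 0.2)$method, "LASSO")
  expect_equal(bestMethod(0.2, NA)$method, "RR")
  expect_true(is.na(bestMethod(NA_real_, NA_real_)$pa))
})

test_that("bias estimation recovers injected offsets and corrects them", {
  cm <- data.frame(trait = rep(c("t1", "t2"), each = 4),
                   cross = rep(sprintf("C%d", 1:4), 2),
                   observed = rnorm(8),
                   stringsAsFactors = FALSE)
  cm$predParental <- cm$observed + rep(c(0.5, -0.2), each = 4)
  b <- estimateBias(cm)
  expect_equal(unname(b["t1"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(b["t2"]), -0.2, tolerance = 1e-12)
  corr <- applyBias(cm$predParental[cm$trait == "t1"], b[["t1"]])
  expect_equal(mean(corr - cm$observed[cm$trait == "t1"]), 0,
               tolerance = 1e-12)
  # unbiased input: zero bias
  cm0 <- cm; cm0$predParental <- cm0$observed
  expect_true(all(abs(estimateBias(cm0)) < 1e-12))
  expect_warning(estimateBias(cm[c(1, 5), ]), "single cross")
})

test_that("all-pairs enumeration matches the parental-average prediction", {
  set.seed(44)
  n <- 30; p <- 40
  X <- matrix(sample(0:2, n * p, TRUE), n, p,
              dimnames = list(sprintf("g%03d", 1:n), sprintf("m%d", 1:p)))
  d <- dosageFromMatrix(X)
  m <- trainMarkerModel(d, setNames(rnorm(n), rownames(X)), "RR",
                        gridSize = 10, seed = 2)
  rk <- predictAllCrosses(d, m)
  expect_equal(nrow(rk), n * (n - 1) / 2)
  expect_true(all(diff(rk$predictedMean) <= 1e-12))
  # the linear shortcut equals explicit parental-average prediction
  for (i in c(1, 50, 200)) {
    pam <- matrix(parentalAverageGenotype(X[rk$parent1[i], ],
                                          X[rk$parent2[i], ]), 1,
                  dimnames = list("avg", colnames(X)))
    expect_equal(unname(predict(m, pam)), rk$predictedMean[i],
                 tolerance = 1e-10)
  }
  tiny <- predictAllCrosses(d[1:3, ], m)
  expect_equal(nrow(tiny), 3)
})

test_that("half-sib training sets contain the parent's other crosses only", {
  st <- makeStudy(nPanel = 40, nMarkers = 100, nOff = 8, seed = 21)
  hs <- halfSibTrainingSets(st$hd$crosses, st$hd$population)
  expect_equal(nrow(hs), 20)                 # 10 crosses x 2 parents
  expect_true(all(hs$nTsCrosses == 3))       # 5-parent half-diallel
  for (i in seq_len(nrow(hs))) {
    vs <- st$hd$population$individual[st$hd$population$cross == hs$cross[i]]
    expect_length(intersect(hs$tsIds[[i]], vs), 0)
  }
})

test_that("scenario outputs are structured and deterministic", {
  st <- makeStudy(nPanel = 60, nMarkers = 120, nOff = 12, seed = 22)
  s1a <- runScenario1a(st$hd$genotypes, st$values, st$hd$crosses,
                       st$parentsGeno, k = 4, reps = 2, methods = "RR",
                       seed = 5, gridSize = 8)
  expect_setequal(unique(s1a$pa$granularity),
                  c("per_cross", "per_trait", "overall"))
  cells <- s1a$pa[s1a$pa$component == "mendelian" &
                  s1a$pa$granularity == "per_cross", ]
  expect_equal(nrow(cells), 10)
  expect_true(all(is.finite(cells$se)))       # SE over replicates
  s1a2 <- runScenario1a(st$hd$genotypes, st$values, st$hd$crosses,
                        st$parentsGeno, k = 4, reps = 2, methods = "RR",
                        seed = 5, gridSize = 8)
  expect_identical(s1a$pa, s1a2$pa)
  # per-trait mendelian PA equals the mean over that trait's cells
  pt <- s1a$pa[s1a$pa$granularity == "per_trait" &
               s1a$pa$component == "mendelian", ]
  expect_equal(pt$pa, mean(cells$pa), tolerance = 1e-12)

  s2 <- runScenario2(st$panel$genotypes, st$panelValues, st$hd$genotypes,
                     st$values, st$hd$crosses, st$parentsGeno, "RR",
                     seed = 6, gridSize = 8)
  # TS and VS are disjoint by construction
  expect_length(intersect(st$panel$population$individual,
                          individualIds(st$hd$genotypes)), 0)
  expect_equal(nrow(s2$crossMeans), 10)
  expect_true(all(c("predOffspring", "predParental") %in%
                  names(s2$crossMeans)))
})

test_that("a noise-free realizable trait is predicted almost perfectly", {
  set.seed(23)
  st <- makeStudy(nPanel = 40, nMarkers = 120, nOff = 25, seed = 24)
  X <- dosages(st$hd$genotypes)
  beta <- rnorm(ncol(X), 0, 0.3)
  y <- as.numeric(X %*% beta)
  vals <- data.frame(genotype = rownames(X),
                     cross = st$hd$population$cross[
                       match(rownames(X), st$hd$population$individual)],
                     trait = "lin", total = (y - mean(y)) / sd(y),
                     stringsAsFactors = FALSE)
  s <- runScenario1a(st$hd$genotypes, vals, k = 5, reps = 1,
                     methods = "RR", seed = 7, gridSize = 25)
  ov <- s$pa$pa[s$pa$granularity == "overall" & s$pa$component == "mendelian"]
  expect_gt(ov, 0.98)
})

test_that("restricting the panel training set to one subpopulation lowers PA", {
  # panmictic panel: subsets carry equal relatedness to the progenies, so
  # the only systematic effect of the restriction is the smaller training
  # set (about a third of the panel)
  nSeeds <- 6
  d <- numeric(nSeeds)
  for (s in seq_len(nSeeds)) {
    st <- makeStudy(nPanel = 120, nMarkers = 200, nOff = 15, fst = 0,
                    seed = 500 + s)
    ovAll <- runScenario2(st$panel$genotypes, st$panelValues,
                          st$hd$genotypes, st$values, st$hd$crosses,
                          methods = "RR", tsFilter = "all",
                          seed = s, gridSize = 10)
    ovWW <- runScenario2(st$panel$genotypes, st$panelValues,
                         st$hd$genotypes, st$values, st$hd$crosses,
                         methods = "RR", tsFilter = "WW",
                         panelPopulation = st$panel$population,
                         seed = s, gridSize = 10)
    ov <- function(x) x$pa$pa[x$pa$component == "mendelian" &
                              x$pa$granularity == "overall"]
    d[s] <- ov(ovAll) - ov(ovWW)
  }
  expect_gt(mean(d), 0)
  expect_error(runScenario2(st$panel$genotypes, st$panelValues,
                            st$hd$genotypes, st$values, st$hd$crosses,
                            methods = "RR", tsFilter = "WW", seed = 1),
               "panelPopulation")
})
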