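test_that("MAF and missingness filters keep the right markers", {
  x <- rbind(c(0, 0, 2), c(0, 1, 2), c(0, 1, 2), c(0, 2, 1))
  d <- dosageFromMatrix(x)
  f <- filterMarkers(d, mafMin = 0.05)
  # hand-computed alternate-allele frequencies: 0, 0.5, 0.875
  expect_identical(markerIds(f), c("M002", "M003"))
  x2 <- x
  x2[c(1, 3, 4), 2] <- NA              # 75% missing, remaining call het:
  f2 <- filterMarkers(dosageFromMatrix(x2), 0.05, 0.8)
  expect_true("M002" %in% markerIds(f2))   # retained at maxMissing 0.8
  f3 <- filterMarkers(dosageFromMatrix(x2), 0.05, 0.5)
  expect_false("M002" %in% markerIds(f3))  # dropped at maxMissing 0.5
  # frequency 0.03 marker removed at 5%
  x4 <- matrix(0, 50, 2); x4[1:3, 1] <- 1; x4[, 2] <- rep(0:1, 25)
  expect_identical(markerIds(filterMarkers(dosageFromMatrix(x4))), "M002")
  expect_error(filterMarkers(dosageFromMatrix(matrix(0, 4, 2))),
               "stricter")
})

test_that("marker intersection aligns both matrices on shared ids", {
  a <- dosageFromMatrix(matrix(rep(0:2, 5)[1:15], 3, 5))
  b0 <- matrix(rep(0:2, 7)[1:21], 3, 7)
  colnames(b0) <- c("M003", "M004", "M005", "X1", "X2", "X3", "X4")
  b <- dosageFromMatrix(b0)
  both <- intersectMarkers(a, b)
  expect_identical(markerIds(both$a), c("M003", "M004", "M005"))
  expect_identical(markerIds(both$a), markerIds(both$b))
  same <- intersectMarkers(a, a)
  expect_identical(dosages(same$a), dosages(a))
  cz <- dosageFromMatrix(matrix(0:2, 3, 3,
                                dimnames = list(NULL, c("Z1", "Z2", "Z3"))))
  expect_error(intersectMarkers(a, cz), "common")
})

test_that("parental-average genotype equals the segregation-weighted mean", {
  expect_equal(parentalAverageGenotype(0, 0), 0)
  expect_equal(parentalAverageGenotype(1, 1), 1)
  expect_equal(parentalAverageGenotype(2, 1), 1.5)
  # exhaustive oracle over all 9 parent-dosage pairs: enumerate gamete
  # probabilities and offspring classes
  gam <- function(d) switch(as.character(d), "0" = c(1, 0), "1" = c(.5, .5),
                            "2" = c(0, 1))
  for (d1 in 0:2) for (d2 in 0:2) {
    g1 <- gam(d1); g2 <- gam(d2)
    classes <- outer(0:1, 0:1, "+")
    probs <- outer(g1, g2)
    expect_equal(parentalAverageGenotype(d1, d2), sum(classes * probs))
  }
  expect_error(parentalAverageGenotype(0.5, 1), "observed")
})

test_that("non-segregating proportion counts double-homozygous loci", {
  expect_equal(nonsegregatingProportion(0, 0), 1)
  expect_equal(nonsegregatingProportion(0, 2), 1)   # all offspring dosage 1
  expect_equal(nonsegregatingProportion(1, 0), 0)
  expect_equal(nonsegregatingProportion(c(0, 0, 1), c(0, 2, 0)), 2 / 3)
  # invariant to marker order and parent swap
  set.seed(2)
  d1 <- sample(0:2, 30, TRUE); d2 <- sample(0:2, 30, TRUE)
  expect_equal(nonsegregatingProportion(d1, d2),
               nonsegregatingProportion(d2, d1))
  o <- sample(30)
  expect_equal(nonsegregatingProportion(d1[o], d2[o]),
               nonsegregatingProportion(d1, d2))
})

test_that("VanRaden A matches hand algebra and a brute-force oracle", {
  d <- dosageFromMatrix(matrix(c(0, 2), 2, 1))
  # p = 0.5: Z = (-1, 1), denominator 2 * 0.5 * 0.5 * 2 markers... one
  # marker: 2 * 0.25 = 0.5
  A <- vanRadenA(d)
  expect_equal(unname(relValues(A)), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # identical rows give identical entries
  d2 <- dosageFromMatrix(rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 1, 0, 0)))
  A2 <- relValues(vanRadenA(d2))
  expect_equal(A2[1, 2], A2[1, 1])
  expect_equal(A2[2, 2], A2[1, 1])
  # brute-force double loop on a random matrix
  set.seed(5)
  x <- matrix(sample(0:2, 20 * 500, TRUE), 20, 500)
  d3 <- dosageFromMatrix(x)
  A3 <- vanRadenA(d3)
  p <- colMeans(x) / 2
  keep <- p > 0 & p < 1
  Z <- sweep(x[, keep], 2, 2 * p[keep])
  denom <- 2 * sum(p[keep] * (1 - p[keep]))
  brute <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    brute[i, j] <- sum(Z[i, ] * Z[j, ]) / denom
  expect_lt(max(abs(relValues(A3) - brute)), 1e-10)
  expect_equal(A3@nExcluded, sum(!keep))
  # all-heterozygote matrix: centered columns are zero -> zero matrix
  xc <- matrix(1, 3, 4)
  expect_lt(max(abs(relValues(vanRadenA(dosageFromMatrix(xc))))), 1e-12)
  expect_error(vanRadenA(dosageFromMatrix(matrix(2, 3, 2))), "fixed")
})

test_that("mean relationship averages the requested block", {
  v <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  v[lower.tri(v)] <- 1:10 / 10
  v <- v + t(v); diag(v) <- 2
  A <- new("RelationshipMatrix", values = v, scalingConstant = 1,
           freqSource = "self", nExcluded = 0)
  expect_equal(meanRelationship(A, "a", "b"), v["a", "b"])
  expect_equal(meanRelationship(A, c("a", "b"), c("a", "b")), v["a", "b"])
  s1 <- c("a", "b", "c"); s2 <- c("d", "e")
  expect_equal(meanRelationship(A, s1, s2), mean(v[s1, s2]))
  expect_error(meanRelationship(A, character(0), "a"), "non-empty")
  expect_error(meanRelationship(A, c("a", "b"), c("b", "c")), "overlap")
})

test_that("panel PCA projects others with panel centering and loadings", {
  set.seed(8)
  x <- matrix(sample(0:2, 40 * 60, TRUE), 40, 60)
  panel <- dosageFromMatrix(x)
  proj <- pcaProject(panel, nAxes = 3)
  # idempotence: projecting the panel itself reproduces its scores
  proj2 <- pcaProject(panel, panel, nAxes = 3)
  expect_lt(max(abs(pcaScores(proj2)[41:80, ] - pcaScores(proj))), 1e-8)
  # an individual at the panel means scores zero
  mid <- matrix(colMeans(x), 1, dimnames = list("mid", colnames(x)))
  pm <- pcaProject(panel, dosageFromMatrix(rbind(x[1, , drop = FALSE], mid)))
  expect_lt(max(abs(pcaScores(pm)["mid", ])), 1e-8)
  # parental-average genotype projects to the parents' midpoint
  avg <- (x[1, ] + x[2, ]) / 2
  others <- rbind(x[1:2, ], avg)
  rownames(others) <- c("pa", "pb", "avg")
  pp <- pcaScores(pcaProject(panel, dosageFromMatrix(others)))
  expect_lt(max(abs(pp["avg", ] - (pp["pa", ] + pp["pb", ]) / 2)), 1e-8)
  expect_warning(pcaProject(dosageFromMatrix(x[1:3, ]), nAxes = 10),
                 "truncated")
})

test_that("parent distances follow Pythagoras on the leading axes", {
  sc <- rbind(p1 = c(3, 0), p2 = c(0, 4), p3 = c(3, 0))
  proj <- new("PCAProjection", centers = numeric(2), loadings = diag(2),
              scores = sc, explained = c(0.6, 0.4), panelIds = "p1")
  expect_equal(parentAxisDistance(proj, "p1", "p2", 1), 3)
  expect_equal(parentAxisDistance(proj, "p1", "p2", 1:2), 5)
  expect_equal(parentAxisDistance(proj, "p1", "p3", 1:2), 0)
  expect_equal(parentAxisDistance(proj, "p2", "p1", 1:2),
               parentAxisDistance(proj, "p1", "p2", 1:2))
  expect_error(parentAxisDistance(proj, "p1", "zz", 1), "present")
})
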