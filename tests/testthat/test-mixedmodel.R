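test_that("balanced one-way REML equals the ANOVA closed form", {
  rec <- onewayRecords(10, 5, sigmaG = 1.5, sigmaE = 1, seed = 2)
  fit <- fitMixedModel(rec, fixed = character(0), random = "G",
                       tol = 1e-12, maxIter = 5000)
  anova <- onewayANOVA(rec)
  expect_lt(abs(fit$vc@components[["G"]] - anova[["G"]]), 1e-6)
  expect_lt(abs(fit$vc@components[["residual"]] - anova[["residual"]]),
            1e-6)
  # restricted likelihood is non-decreasing across EM iterations
  expect_true(all(diff(fit$logLikTrace) > -2e-6))
})

test_that("REML components agree with lme4 on an unbalanced two-factor design", {
  set.seed(17)
  ng <- 35
  g <- rep(sprintf("g%02d", 1:ng), times = sample(2:5, ng, TRUE))
  n <- length(g)
  b <- sample(c("B1", "B2"), n, TRUE)
  f <- sample(sprintf("f%02d", 1:12), n, TRUE)
  u <- rnorm(ng, 0, sqrt(2)); w <- rnorm(12, 0, 1)
  val <- 3 + (b == "B2") * 0.5 + u[as.integer(factor(g))] +
    w[as.integer(factor(f))] + rnorm(n)
  rec <- data.frame(genotype = g, cross = f, block = b, year = "Y1",
                    x = 1L, y = 1L, value = val, stringsAsFactors = FALSE)
  fit <- fitMixedModel(rec, fixed = "B", random = c("G", "C"),
                       tol = 1e-10, maxIter = 5000)
  lm4 <- lme4::lmer(value ~ block + (1 | genotype) + (1 | cross),
                    data = rec, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc4 <- as.data.frame(lme4::VarCorr(lm4))
  ours <- fit$vc@components
  for (k in seq_len(nrow(vc4))) {
    nm <- c(genotype = "G", cross = "C", Residual = "residual")[[vc4$grp[k]]]
    expect_lt(abs(ours[[nm]] - vc4$vcov[k]) / max(vc4$vcov[k], 0.01), 5e-3)
  }
})

test_that("a zero-variance term is shrunk to negligible or the floor", {
  # REML hits the boundary exactly only when the between-group mean square
  # falls below the within-group one (about half the seeds in a balanced
  # one-way design); the rest are tiny interior optima
  floorHits <- 0; negligible <- 0
  for (s in 1:50) {
    rec <- onewayRecords(200, 3, sigmaG = 0, sigmaE = 1, seed = 400 + s)
    fit <- fitMixedModel(rec, fixed = character(0), random = "G",
                         tol = 1e-8, maxIter = 500)
    g <- fit$vc@components[["G"]]
    if (g <= 1e-6 * var(rec$value)) floorHits <- floorHits + 1
    if (g <= 0.1 * var(rec$value)) negligible <- negligible + 1
  }
  expect_gte(negligible, 45)
  expect_gte(floorHits, 15)
})

test_that("duplicated records concentrate residual information coherently", {
  # duplicating every record creates zero-variance within-pair contrasts:
  # the residual component must shrink while the group component stays
  # stable, and the estimates must agree with lme4 on the duplicated data
  rec <- onewayRecords(12, 4, sigmaG = 1, sigmaE = 0.8, seed = 5)
  fit1 <- fitMixedModel(rec, fixed = character(0), random = "G",
                        tol = 1e-10, maxIter = 5000)
  dup <- rbind(rec, rec)
  fit2 <- fitMixedModel(dup, fixed = character(0), random = "G",
                        tol = 1e-10, maxIter = 5000)
  expect_lt(fit2$vc@components[["residual"]],
            fit1$vc@components[["residual"]])
  expect_lt(abs(fit2$vc@components[["G"]] - fit1$vc@components[["G"]]) /
              fit1$vc@components[["G"]], 0.15)
  lm4 <- lme4::lmer(value ~ (1 | genotype), data = dup, REML = TRUE)
  vc4 <- as.data.frame(lme4::VarCorr(lm4))$vcov
  expect_equal(unname(fit2$vc@components[c("G", "residual")]), vc4,
               tolerance = 1e-5)
})

test_that("BLUPs of random terms sum to approximately zero", {
  st <- makeStudy(nPanel = 40, nMarkers = 120, nOff = 12, seed = 8)
  sim <- st$sims[[1]]
  fit <- fitMixedModel(sim$records, random = c("G", "C", "G:Y", "C:Y"))
  for (term in names(fit$blups))
    expect_lt(abs(sum(fit$blups[[term]])) /
                max(1, length(fit$blups[[term]])), 1e-4)
  # genetic values carry C + G totals
  gv <- geneticValueTable(fit$geneticValues)
  expect_equal(gv$total, gv$C + gv$G)
})

test_that("singular fixed designs and bad inputs error clearly", {
  rec <- onewayRecords(6, 3, 1, 1, seed = 9)
  rec$block <- rec$genotype          # block aliased with genotype
  expect_error(fitMixedModel(rec, fixed = c("B", "G"), random = "G"),
               "aliased|singular")
  rec2 <- onewayRecords(6, 3, 1, 1, seed = 9)
  rec2$value[1] <- NA
  expect_error(fitMixedModel(rec2, fixed = character(0), random = "G"),
               "finite")
})

test_that("random-term selection keeps signal and drops noise", {
  makeRec <- function(sigmaF, seed) {
    set.seed(seed)
    ng <- 50; reps <- 4
    g <- rep(sprintf("g%02d", 1:ng), each = reps)
    f <- rep(sprintf("f%02d", 1:10), length.out = ng * reps)
    u <- rnorm(ng, 0, 1.2)
    w <- rnorm(10, 0, sigmaF)
    data.frame(genotype = g, cross = f, block = "B1", year = "Y1",
               x = 1L, y = 1L,
               value = u[as.integer(factor(g))] +
                 w[as.integer(factor(f))] + rnorm(ng * reps, 0, 0.5),
               stringsAsFactors = FALSE)
  }
  # the "cross" column here is just a second grouping factor under test;
  # run selection with C droppable by relabelling it x
  keep <- 0; drop <- 0
  for (s in 1:25) {
    recS <- makeRec(1.5, 600 + s)        # strong factor
    recS$x <- recS$cross
    selS <- dropRandomTerms(recS, fixed = character(0),
                            random = c("G", "x"), alpha = 0.05)
    if ("x" %in% selS$retained) keep <- keep + 1
    recN <- makeRec(0, 700 + s)          # pure-noise factor
    recN$x <- recN$cross
    selN <- dropRandomTerms(recN, fixed = character(0),
                            random = c("G", "x"), alpha = 0.05)
    if (!("x" %in% selN$retained)) drop <- drop + 1
  }
  expect_gte(keep, 24)                   # >= 95% power
  expect_gte(drop, 22)                   # >= 90% size control
})

test_that("selection order is deterministic and protects G and C", {
  st <- makeStudy(nPanel = 30, nMarkers = 100, nOff = 10, seed = 12)
  rec <- st$sims[[1]]$records
  sel1 <- dropRandomTerms(rec, random = c("G", "C", "G:Y", "C:Y"),
                          alpha = 0.9)   # aggressive dropping
  sel2 <- dropRandomTerms(rec, random = c("G", "C", "G:Y", "C:Y"),
                          alpha = 0.9)
  expect_identical(sel1$retained, sel2$retained)
  expect_identical(sel1$tests, sel2$tests)
  expect_true(all(c("G", "C") %in% sel1$retained))
})

test_that("the ML flavor matches lme4 maximum likelihood", {
  set.seed(19)
  ng <- 30
  g <- rep(sprintf("g%02d", 1:ng), each = 4)
  u <- rnorm(ng, 0, 1.1)
  rec <- data.frame(genotype = g, cross = NA_character_, block = "B1",
                    year = "Y1", x = 1L, y = 1L,
                    value = 4 + u[as.integer(factor(g))] +
                      rnorm(ng * 4, 0, 0.9),
                    stringsAsFactors = FALSE)
  fit <- fitMixedModel(rec, fixed = character(0), random = "G",
                       method = "ML", tol = 1e-12, maxIter = 9000)
  lm4 <- lme4::lmer(value ~ (1 | genotype), data = rec, REML = FALSE)
  vc4 <- as.data.frame(lme4::VarCorr(lm4))$vcov
  expect_equal(unname(fit$vc@components[c("G", "residual")]), vc4,
               tolerance = 1e-4)
})
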