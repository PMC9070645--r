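# Shared fixture builders: everything is generated in code at test time.

# A tiny DosageMatrix from an explicit matrix (map generated to match).
dosageFromMatrix <- function(x) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("i%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("M%03d", seq_len(ncol(x)))
  map <- data.frame(marker = colnames(x), chrom = "chr01",
                    pos_bp = seq_len(ncol(x)) * 1000,
                    pos_cM = seq_len(ncol(x)) * 0.01,
                    stringsAsFactors = FALSE)
  new("DosageMatrix", dosages = x, map = map)
}

# Phased parents with explicit haplotypes (markers in columns).
phasedFromHaps <- function(hapA, hapB, mapLen = 100) {
  if (is.null(rownames(hapA))) rownames(hapA) <- rownames(hapB) <-
    sprintf("p%02d", seq_len(nrow(hapA)))
  if (is.null(colnames(hapA))) colnames(hapA) <- colnames(hapB) <-
    sprintf("M%03d", seq_len(ncol(hapA)))
  k <- ncol(hapA)
  map <- data.frame(marker = colnames(hapA), chrom = "chr01",
                    pos_bp = seq_len(k) * 1000,
                    pos_cM = seq(0, mapLen, length.out = k),
                    stringsAsFactors = FALSE)
  new("PhasedGenotypes", hapA = hapA, hapB = hapB, map = map)
}

# A small structured panel + half-diallel + trait values used by several
# suites.  Values can be the true simulated genetic values (fast) so the
# prediction machinery is exercised without a mixed-model fit.
makeStudy <- function(nPanel = 120, nMarkers = 300, nOff = 25,
                      nTraits = 1, h2 = 0.8, ratio = 0.3, fst = 0.08,
                      seed = 1) {
  p <- simulatePanel(nPanel, nMarkers, 3, fst,
                     seed = deriveSeed(seed, "panel"))
  ids <- p$population$individual
  ww <- ids[p$population$subpopulation == "WW"]
  we <- ids[p$population$subpopulation == "WE"]
  parents <- c(ww[1:4], we[1])
  ph <- new("PhasedGenotypes", hapA = p$phased@hapA[parents, , drop = FALSE],
            hapB = p$phased@hapB[parents, , drop = FALSE],
            map = p$phased@map)
  hd <- makeHalfDiallel(ph, nOff, seed = deriveSeed(seed, "hd"))
  vals <- NULL; valsP <- NULL; archs <- list(); sims <- list()
  for (t in seq_len(nTraits)) {
    tr <- sprintf("t%d", t)
    arch <- makeTraitArchitecture(hd$genotypes, tr, "polygenic",
                                  max(100, nMarkers %/% 5), h2,
                                  seed = deriveSeed(seed, paste0("arch", t)))
    arch <- calibrateCrossShare(hd$genotypes, hd$population, arch, ratio)
    sim <- simulatePhenotypes(hd$genotypes, hd$population, arch,
                              seed = deriveSeed(seed, paste0("ph", t)))
    tv <- sim$trueValues
    vals <- rbind(vals, data.frame(genotype = tv$genotype, cross = tv$cross,
                                   trait = tr, total = tv$total / sd(tv$total),
                                   stringsAsFactors = FALSE))
    tvP <- simulatePhenotypes(p$genotypes, p$population, arch,
                              seed = deriveSeed(seed, paste0("pp", t)))$trueValues
    valsP <- rbind(valsP, data.frame(genotype = tvP$genotype, trait = tr,
                                     total = tvP$total / sd(tvP$total),
                                     stringsAsFactors = FALSE))
    archs[[tr]] <- arch
    sims[[tr]] <- sim
  }
  list(panel = p, parents = parents, parentsPhased = ph,
       parentsGeno = p$genotypes[parents, ], hd = hd, values = vals,
       panelValues = valsP, archs = archs, sims = sims)
}

# Balanced one-way records (single block/year so only the intercept is a
# fixed effect).
onewayRecords <- function(nGroups, reps, sigmaG, sigmaE, seed = 1,
                          mu = 10) {
  set.seed(seed)
  g <- rep(sprintf("g%03d", seq_len(nGroups)), each = reps)
  u <- rnorm(nGroups, 0, sigmaG)
  data.frame(genotype = g, cross = NA_character_, block = "B1",
             year = "Y1", x = 1L, y = 1L, trait = "t",
             value = mu + u[as.integer(factor(g))] +
               rnorm(nGroups * reps, 0, sigmaE),
             stringsAsFactors = FALSE)
}

# Closed-form balanced one-way REML (ANOVA estimators).
onewayANOVA <- function(records) {
  f <- factor(records$genotype)
  reps <- length(records$value) / nlevels(f)
  means <- tapply(records$value, f, mean)
  msb <- reps * var(means)
  msw <- sum((records$value - means[f])^2) /
    (length(records$value) - nlevels(f))
  c(G = max((msb - msw) / reps, 0), residual = msw)
}

# Multi-locus Weir & Cockerham-style FST estimate from subpopulation
# dosages (independent oracle for the Balding-Nichols generator).
wcFst <- function(dosages, subpop) {
  subpop <- factor(subpop)
  r <- nlevels(subpop)
  n <- as.numeric(table(subpop))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  p <- sapply(levels(subpop), function(s)
    colMeans(dosages[subpop == s, , drop = FALSE]) / 2)
  h <- sapply(levels(subpop), function(s)
    colMeans(dosages[subpop == s, , drop = FALSE] == 1))
  pbar <- as.numeric(p %*% n) / sum(n)
  s2 <- as.numeric(((p - pbar)^2) %*% n) / ((r - 1) * nbar)
  hbar <- as.numeric(h %*% n) / sum(n)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

# Fabricated per-cross / per-trait statistics for table assembly.
fakeStats <- function(nCross = 10, nTrait = 15, seed = 1) {
  set.seed(seed)
  crosses <- sprintf("C%02d", seq_len(nCross))
  traits <- sprintf("t%02d", seq_len(nTrait))
  list(
    pa = data.frame(trait = rep(traits, each = nCross),
                    cross = rep(crosses, nTrait),
                    component = "mendelian", method = "RR",
                    granularity = "per_cross",
                    pa = runif(nCross * nTrait, -0.2, 0.9),
                    se = NA_real_, ts_parent = NA_character_,
                    stringsAsFactors = FALSE),
    crossStats = data.frame(cross = crosses, nonseg = runif(nCross),
                            parentRel = rnorm(nCross),
                            parentDistPC12 = runif(nCross, 0, 5),
                            meanRelTsVs = rnorm(nCross, 0.1, 0.05),
                            stringsAsFactors = FALSE),
    traitStats = data.frame(trait = traits,
                            h2Overall = runif(nTrait, 0.4, 0.9),
                            crossRatio = runif(nTrait, 0.05, 0.5),
                            h2Panel = runif(nTrait, 0.4, 0.9),
                            subpopR2 = runif(nTrait, 0, 0.4),
                            stringsAsFactors = FALSE),
    perCrossH2 = data.frame(trait = rep(traits, each = nCross),
                            cross = rep(crosses, nTrait),
                            h2Cross = runif(nCross * nTrait, 0.1, 0.9),
                            stringsAsFactors = FALSE))
}
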