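#' Simulate a structured diversity panel
#'
#' Generates biallelic SNP genotypes for a panel subdivided into
#' subpopulations under the Balding-Nichols model: ancestral allele
#' frequencies are uniform on \code{[mafMin, 1 - mafMin]}, subpopulation
#' frequencies are Beta-distributed around them with differentiation
#' parameter \code{fst}, and haplotype alleles are Bernoulli draws, so
#' dosages are binomial with two draws.  Individuals are returned both as
#' dosages and as phased haplotypes (parents of simulated crosses must be
#' phased).
#'
#' @param nIndividuals total panel size.
#' @param nMarkers number of biallelic SNPs (>= 2).
#' @param nSubpops number of subpopulations (>= 1).
#' @param fst differentiation parameter in [0, 1); 0 gives a panmictic panel.
#' @param mafMin lower bound on the ancestral minor-allele frequency.
#' @param subpopSizes integer vector summing to \code{nIndividuals}; default
#'   an even split.
#' @param mapLengthCM genetic length per chromosome, in cM (one entry per
#'   chromosome).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return list with \code{genotypes} (\code{\linkS4class{DosageMatrix}}),
#'   \code{phased} (\code{\linkS4class{PhasedGenotypes}}) and
#'   \code{population} (data.frame: individual, role = "panel",
#'   subpopulation).  With three subpopulations they are labelled WW, WE and
#'   TE (wine-west, wine-east, table-east), the structure typical of
#'   cultivated grapevine diversity panels.
#' @export
simulatePanel <- function(nIndividuals, nMarkers, nSubpops = 3, fst = 0.05,
                          mafMin = 0.05, subpopSizes = NULL,
                          mapLengthCM = rep(70, 19), seed = 1) {
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (nMarkers < 2) stop("nMarkers must be at least 2")
  if (nSubpops < 1) stop("nSubpops must be at least 1")
  if (is.null(subpopSizes)) {
    subpopSizes <- rep(nIndividuals %/% nSubpops, nSubpops)
    subpopSizes[seq_len(nIndividuals %% nSubpops)] <-
      subpopSizes[seq_len(nIndividuals %% nSubpops)] + 1
  }
  if (sum(subpopSizes) != nIndividuals)
    stop("subpopSizes must sum to nIndividuals")
  subLabels <- if (nSubpops == 3) c("WW", "WE", "TE")
               else paste0("S", seq_len(nSubpops))
  withSeed(seed, {
    map <- makeMarkerMap(nMarkers, mapLengthCM)
    p0 <- runif(nMarkers, mafMin, 1 - mafMin)
    # Balding-Nichols: p_s ~ Beta(p0 (1-F)/F, (1-p0)(1-F)/F); fst = 0
    # collapses to the ancestral frequency.
    pSub <- matrix(NA_real_, nSubpops, nMarkers)
    for (s in seq_len(nSubpops)) {
      pSub[s, ] <- if (fst == 0) p0 else
        stats::rbeta(nMarkers, p0 * (1 - fst) / fst,
                     (1 - p0) * (1 - fst) / fst)
    }
    ids <- sprintf("P%03d", seq_len(nIndividuals))
    subpop <- rep(subLabels, subpopSizes)
    hapA <- matrix(0L, nIndividuals, nMarkers,
                   dimnames = list(ids, map$marker))
    hapB <- hapA
    for (s in seq_len(nSubpops)) {
      rows <- which(subpop == subLabels[s])
      n <- length(rows)
      hapA[rows, ] <- matrix(rbinom(n * nMarkers, 1,
                                    rep(pSub[s, ], each = n)), n, nMarkers)
      hapB[rows, ] <- matrix(rbinom(n * nMarkers, 1,
                                    rep(pSub[s, ], each = n)), n, nMarkers)
    }
    phased <- new("PhasedGenotypes", hapA = hapA, hapB = hapB, map = map)
    geno <- new("DosageMatrix", dosages = hapA + hapB, map = map)
    pop <- data.frame(individual = ids, role = "panel",
                      subpopulation = subpop, cross = NA_character_,
                      parent1 = NA_character_, parent2 = NA_character_,
                      stringsAsFactors = FALSE)
    list(genotypes = geno, phased = phased, population = pop)
  })
}

# Marker map: markers apportioned to chromosomes proportionally to genetic
# length, cM positions sorted uniforms, physical positions at ~200 kb / cM
# made strictly increasing.
makeMarkerMap <- function(nMarkers, mapLengthCM) {
  nChrom <- length(mapLengthCM)
  share <- mapLengthCM / sum(mapLengthCM)
  counts <- floor(share * nMarkers)
  rem <- nMarkers - sum(counts)
  if (rem > 0) counts[order(share * nMarkers - counts,
                            decreasing = TRUE)[seq_len(rem)]] <-
    counts[order(share * nMarkers - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  rows <- vector("list", nChrom)
  for (c in seq_len(nChrom)) {
    k <- counts[c]
    if (k == 0) next
    cm <- sort(runif(k, 0, mapLengthCM[c]))
    bp <- pmax(1, round(cm * 2e5)) + seq_len(k)  # strictly increasing
    rows[[c]] <- data.frame(chrom = sprintf("chr%02d", c), pos_bp = bp,
                            pos_cM = cm, stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  map$marker <- sprintf("M%05d", seq_len(nrow(map)))
  map[, c("marker", "chrom", "pos_bp", "pos_cM")]
}

# One recombinant gamete from a phased parent: crossover count per
# chromosome is Poisson with mean = length in Morgans, positions uniform on
# the cM scale (Haldane, no interference); starting haplotype is random.
meioseGamete <- function(hapA, hapB, map) {
  gam <- hapA
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    cm <- map$pos_cM[idx]
    L <- max(cm)
    nco <- rpois(1, L / 100)
    xo <- if (nco > 0) sort(runif(nco, 0, L)) else numeric(0)
    start <- sample(0:1, 1)
    phase <- (start + findInterval(cm, xo)) %% 2
    gam[idx] <- ifelse(phase == 0, hapA[idx], hapB[idx])
  }
  gam
}

#' Simulate offspring of a bi-parental cross
#'
#' Each offspring receives one recombinant gamete from each phased parent.
#' Recombination follows the Haldane model: crossover counts per chromosome
#' are Poisson with mean equal to the chromosome's genetic length in
#' Morgans, crossover positions are uniform on the cM scale, and there is no
#' interference.
#'
#' @param parents a \code{\linkS4class{PhasedGenotypes}} object containing
#'   (at least) the two parents.
#' @param parent1,parent2 individual ids of the parents.
#' @param nOffspring number of offspring to draw.
#' @param seed integer seed.
#' @param idPrefix prefix for offspring ids.
#' @return a \code{\linkS4class{DosageMatrix}} of offspring dosages.
#' @export
simulateCross <- function(parents, parent1, parent2, nOffspring, seed = 1,
                          idPrefix = "O") {
  if (!is(parents, "PhasedGenotypes"))
    stop("parents must be PhasedGenotypes: unphased dosages cannot be ",
         "transmitted through meiosis; phase them or simulate parents de novo")
  ids <- individualIds(parents)
  if (!all(c(parent1, parent2) %in% ids))
    stop("both parents must be present in the PhasedGenotypes object")
  map <- parents@map
  i1 <- match(parent1, ids); i2 <- match(parent2, ids)
  withSeed(seed, {
    off <- matrix(0L, nOffspring, ncol(parents@hapA),
                  dimnames = list(sprintf("%s%03d", idPrefix,
                                          seq_len(nOffspring)),
                                  colnames(parents@hapA)))
    for (k in seq_len(nOffspring)) {
      g1 <- meioseGamete(parents@hapA[i1, ], parents@hapB[i1, ], map)
      g2 <- meioseGamete(parents@hapA[i2, ], parents@hapB[i2, ], map)
      off[k, ] <- g1 + g2
    }
    new("DosageMatrix", dosages = off, map = map)
  })
}

#' Simulate a half-diallel progeny set
#'
#' Crosses every unordered pair of the given parents once (no selfs, no
#' reciprocals): p parents give p(p-1)/2 bi-parental families, e.g. 10
#' families from 5 parents.
#'
#' @param parents \code{\linkS4class{PhasedGenotypes}} holding the parents
#'   (all of them; ids must be unique).
#' @param nOffspringPerCross scalar or one count per cross.
#' @param seed integer seed.
#' @return list with \code{genotypes} (offspring
#'   \code{\linkS4class{DosageMatrix}}), \code{population} (data.frame with
#'   parent and offspring rows: individual, role, cross, parent1, parent2)
#'   and \code{crosses} (data.frame: cross, parent1, parent2, n_offspring).
#' @export
makeHalfDiallel <- function(parents, nOffspringPerCross = 65, seed = 1) {
  ids <- individualIds(parents)
  if (anyDuplicated(ids)) stop("duplicate parent ids")
  if (length(ids) < 2) stop("at least 2 parents are required")
  pairs <- combn(ids, 2)
  nCross <- ncol(pairs)
  nOff <- rep_len(nOffspringPerCross, nCross)
  crossIds <- sprintf("C%02d", seq_len(nCross))
  genoList <- vector("list", nCross)
  popList <- vector("list", nCross)
  for (k in seq_len(nCross)) {
    d <- simulateCross(parents, pairs[1, k], pairs[2, k], nOff[k],
                       seed = deriveSeed(seed, paste0("cross:", crossIds[k])),
                       idPrefix = paste0(crossIds[k], "_O"))
    genoList[[k]] <- dosages(d)
    popList[[k]] <- data.frame(individual = rownames(dosages(d)),
                               role = "offspring",
                               subpopulation = NA_character_,
                               cross = crossIds[k],
                               parent1 = pairs[1, k], parent2 = pairs[2, k],
                               stringsAsFactors = FALSE)
  }
  off <- do.call(rbind, genoList)
  pop <- rbind(
    data.frame(individual = ids, role = "parent",
               subpopulation = NA_character_, cross = NA_character_,
               parent1 = NA_character_, parent2 = NA_character_,
               stringsAsFactors = FALSE),
    do.call(rbind, popList))
  crosses <- data.frame(cross = crossIds, parent1 = pairs[1, ],
                        parent2 = pairs[2, ], n_offspring = nOff,
                        stringsAsFactors = FALSE)
  list(genotypes = new("DosageMatrix", dosages = off, map = parents@map),
       population = pop, crosses = crosses)
}

#' Construct a trait architecture
#'
#' Samples QTL positions and raw additive effects, then rescales the effects
#' so that the additive genetic variance in a reference population equals 1;
#' cross deviations and calibration in \code{\link{simulatePhenotypes}} are
#' expressed on that unit scale.
#'
#' @param genotypes reference \code{\linkS4class{DosageMatrix}} (typically
#'   the half-diallel offspring) used to normalize the effect scale.
#' @param traitId label.
#' @param architectureClass "polygenic" (nQtl >= 100) or "oligogenic"
#'   (nQtl <= 10).
#' @param nQtl number of causal markers.
#' @param targetH2 target entry-mean broad-sense heritability.
#' @param crossDeviationSd sd of the cross-specific non-additive deviation
#'   (unit-additive-variance scale); see
#'   \code{\link{crossDeviationSdForRatio}}.
#' @param yearInteractionSd,spatialSd,residualSd non-genetic sds, on the
#'   same scale.
#' @param seed integer seed.
#' @return a \code{\linkS4class{TraitArchitecture}}.
#' @export
makeTraitArchitecture <- function(genotypes, traitId, architectureClass,
                                  nQtl, targetH2, crossDeviationSd = 0,
                                  yearInteractionSd = 0.3, spatialSd = 0.2,
                                  residualSd = 0.7, seed = 1) {
  mk <- markerIds(genotypes)
  if (nQtl > length(mk)) stop("more QTLs requested than markers available")
  withSeed(seed, {
    qtl <- sort(sample(seq_along(mk), nQtl))
    eff <- rnorm(nQtl)
    a <- as.vector(dosages(genotypes)[, qtl, drop = FALSE] %*% eff)
    s <- sd(a)
    if (s == 0) stop("sampled QTLs are monomorphic in the reference; retry ",
                     "with another seed or more markers")
    new("TraitArchitecture", traitId = traitId,
        qtlMarkerIds = mk[qtl], qtlEffects = eff / s,
        architectureClass = architectureClass, targetH2 = targetH2,
        crossDeviationSd = crossDeviationSd, crossMeanScale = 1,
        yearInteractionSd = yearInteractionSd, spatialSd = spatialSd,
        residualSd = residualSd)
  })
}

#' Cross-deviation sd achieving a target cross-variance share
#'
#' The share of genetic variance between crosses is
#' \eqn{\sigma_C^2 / (\sigma_C^2 + \sigma_G^2)}.  Under pure additivity
#' \eqn{\sigma_C^2} is fixed by the parents' means; an explicit i.i.d.
#' cross deviation with the returned sd raises the share to \code{ratio}.
#'
#' @param genotypes offspring \code{\linkS4class{DosageMatrix}}.
#' @param population population table with a \code{cross} column.
#' @param arch a \code{\linkS4class{TraitArchitecture}} (its QTL effects
#'   define the additive values).
#' @param ratio target \eqn{\sigma_C^2 / (\sigma_C^2 + \sigma_G^2)} in
#'   [0, 1).
#' @return non-negative sd; errors if the additive between-cross variance
#'   already exceeds the target share.
#' @export
crossDeviationSdForRatio <- function(genotypes, population, arch, ratio) {
  stopifnot(ratio >= 0, ratio < 1)
  a <- additiveValues(genotypes, arch)
  cross <- population$cross[match(names(a), population$individual)]
  dec <- varBetweenWithin(a, cross)
  need <- ratio / (1 - ratio) * dec["within"] - dec["between"]
  if (need < 0)
    stop(sprintf(
      "additive between-cross variance already implies a share of %.3f > %.3f; use calibrateCrossShare() to shrink the additive cross-mean component",
      dec["between"] / sum(dec), ratio))
  sqrt(unname(need))
}

#' Calibrate an architecture to a target cross-variance share
#'
#' Sets \code{crossDeviationSd} and \code{crossMeanScale} so that the
#' between-cross share of genetic variance equals \code{ratio}.  When the
#' additive between-cross variance falls short of the target, an i.i.d.
#' cross deviation with the required sd is added (scale kept at 1); when
#' it exceeds the target — as it does for unrelated parents, whose
#' additive share sits near one half — the additive cross-mean component
#' is shrunk instead, emulating the non-additive and scale effects that
#' depress the fitted cross variance below its additive expectation.
#'
#' @inheritParams crossDeviationSdForRatio
#' @return the updated \code{\linkS4class{TraitArchitecture}}.
#' @export
calibrateCrossShare <- function(genotypes, population, arch, ratio) {
  stopifnot(ratio >= 0, ratio < 1)
  a <- additiveValues(genotypes, arch)
  cross <- population$cross[match(names(a), population$individual)]
  dec <- varBetweenWithin(a, cross)
  target <- ratio / (1 - ratio) * dec[["within"]]
  if (target >= dec[["between"]]) {
    arch@crossDeviationSd <- sqrt(target - dec[["between"]])
    arch@crossMeanScale <- 1
  } else {
    arch@crossDeviationSd <- 0
    arch@crossMeanScale <- sqrt(target / dec[["between"]])
  }
  arch
}

# Additive genetic values from a trait architecture.
additiveValues <- function(genotypes, arch) {
  d <- dosages(genotypes)[, arch@qtlMarkerIds, drop = FALSE]
  a <- as.vector(d %*% arch@qtlEffects)
  names(a) <- rownames(dosages(genotypes))
  a - mean(a)
}

# Between-cross (variance of cross means) and mean within-cross variance;
# a single cross has no between-cross component.
varBetweenWithin <- function(values, cross) {
  means <- tapply(values, cross, mean)
  within <- tapply(values, cross, var)
  b <- if (length(means) < 2) 0 else var(as.vector(means))
  c(between = b, within = mean(within, na.rm = TRUE))
}

#' Simulate multi-year field phenotypes
#'
#' Generates plot records under the same linear mixed model later used for
#' estimation: value = mu + genetic value (additive + cross deviation)
#' + year + block + genotype:year + cross:year + row + column + row:column
#' + row:year + column:year effects + residual, every random term i.i.d.
#' normal with the architecture's sd.  The genetic side (QTL effects and
#' cross deviations together) is rescaled by one factor so that plugging
#' the true simulated variance components into the entry-mean heritability
#' formula (\code{\link{heritabilityOverall}}) hits \code{targetH2} exactly;
#' the non-genetic sds are taken as fixed.  Plants are perennial: each
#' genotype-block pair keeps its field position across years.
#'
#' @param genotypes \code{\linkS4class{DosageMatrix}} of the phenotyped
#'   individuals.
#' @param population population table (rows for these individuals; panel
#'   individuals have no cross and receive no cross terms).
#' @param arch \code{\linkS4class{TraitArchitecture}}.
#' @param nYears,nBlocks numbers of years and of complete blocks.
#' @param fieldDims c(rows, cols); default a near-square grid holding all
#'   genotype-block plots.
#' @param seed integer seed.
#' @return list with \code{records} (data.frame: genotype, cross, block,
#'   year, x, y, trait, value), \code{trueValues} (data.frame: genotype,
#'   cross, additive, deviation, total — calibrated scale),
#'   \code{trueComponents} (named variances of the generating terms),
#'   \code{pluginH2} and \code{scalingFactor}.
#' @export
simulatePhenotypes <- function(genotypes, population, arch, nYears = 2,
                               nBlocks = 2, fieldDims = NULL, seed = 1) {
  ids <- individualIds(genotypes)
  pop <- population[match(ids, population$individual), , drop = FALSE]
  if (anyNA(pop$individual)) stop("every phenotyped individual needs a population row")
  hasCross <- !all(is.na(pop$cross))
  a <- additiveValues(genotypes, arch)
  nG <- length(ids)

  withSeed(seed, {
    cross <- if (hasCross) pop$cross else rep("none", nG)
    crossLevels <- unique(cross[!is.na(cross)])
    dev <- setNames(rnorm(length(crossLevels), 0, arch@crossDeviationSd),
                    crossLevels)
    if (!hasCross) dev[] <- 0
    if (hasCross) {
      bmean <- tapply(a, cross, mean)
      w <- a - bmean[cross]
      gRaw <- w + arch@crossMeanScale * bmean[cross] + dev[cross]
    } else {
      gRaw <- a + dev[cross]
    }

    # true genetic components on the raw (unit-additive) scale
    decRaw <- if (hasCross) varBetweenWithin(gRaw, cross)
              else c(between = 0, within = var(gRaw))
    ySd <- arch@yearInteractionSd; sSd <- arch@spatialSd; rSd <- arch@residualSd
    nYearTerms <- if (hasCross) 4 else 3     # G:Y, (C:Y), x:Y, y:Y
    A <- nYearTerms * ySd^2
    B <- 3 * sSd^2 + rSd^2                   # x, y, x:y, residual
    denomExtra <- A / nYears + B / (nYears * nBlocks)
    if (denomExtra == 0) {
      if (arch@targetH2 < 1)
        stop("targetH2 unattainable: all non-genetic sds are 0, implied H2 = 1")
      s2 <- 1
    } else {
      s2 <- arch@targetH2 / (1 - arch@targetH2) * denomExtra / sum(decRaw)
    }
    s <- sqrt(s2)
    g <- s * gRaw

    # field layout: genotype x block plots on a fixed grid, reused each year
    nPlot <- nG * nBlocks
    if (is.null(fieldDims)) {
      nr <- ceiling(sqrt(nPlot)); nc <- ceiling(nPlot / nr)
      fieldDims <- c(nr, nc)
    }
    if (prod(fieldDims) < nPlot)
      stop("fieldDims too small for genotype x block plots")
    cells <- cbind(x = rep(seq_len(fieldDims[1]), fieldDims[2]),
                   y = rep(seq_len(fieldDims[2]), each = fieldDims[1]))
    pos <- cells[sample(nrow(cells), nPlot), , drop = FALSE]

    years <- sprintf("Y%d", seq_len(nYears))
    blocks <- sprintf("B%d", seq_len(nBlocks))
    yearEff <- setNames(rnorm(nYears, 0, 0.5), years)
    blockEff <- setNames(rnorm(nBlocks, 0, 0.3), blocks)
    gy <- matrix(rnorm(nG * nYears, 0, ySd), nG, nYears,
                 dimnames = list(ids, years))
    cy <- matrix(rnorm(length(crossLevels) * nYears, 0, ySd),
                 length(crossLevels), nYears,
                 dimnames = list(crossLevels, years))
    if (!hasCross) cy[] <- 0
    rowEff <- rnorm(fieldDims[1], 0, sSd)
    colEff <- rnorm(fieldDims[2], 0, sSd)
    rcEff <- matrix(rnorm(prod(fieldDims), 0, sSd), fieldDims[1], fieldDims[2])
    rowYear <- matrix(rnorm(fieldDims[1] * nYears, 0, ySd), fieldDims[1], nYears)
    colYear <- matrix(rnorm(fieldDims[2] * nYears, 0, ySd), fieldDims[2], nYears)

    plotG <- rep(seq_len(nG), nBlocks)
    plotB <- rep(seq_len(nBlocks), each = nG)
    recs <- vector("list", nYears)
    mu <- 10
    for (l in seq_len(nYears)) {
      x <- pos[, "x"]; yc <- pos[, "y"]
      val <- mu + g[plotG] + yearEff[l] + blockEff[plotB] +
        gy[plotG, l] + cy[cross[plotG], l] +
        rowEff[x] + colEff[yc] + rcEff[cbind(x, yc)] +
        rowYear[x, l] + colYear[yc, l] +
        rnorm(nPlot, 0, rSd)
      recs[[l]] <- data.frame(genotype = ids[plotG],
                              cross = if (hasCross) cross[plotG] else NA_character_,
                              block = blocks[plotB], year = years[l],
                              x = x, y = yc, trait = arch@traitId,
                              value = as.numeric(val),
                              stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL

    trueComponents <- c(
      C = unname(s2 * decRaw["between"]), G = unname(s2 * decRaw["within"]),
      `C:Y` = if (hasCross) ySd^2 else 0, `G:Y` = ySd^2,
      `x:Y` = ySd^2, `y:Y` = ySd^2,
      x = sSd^2, y = sSd^2, `x:y` = sSd^2, residual = rSd^2)
    pluginH2 <- (trueComponents[["C"]] + trueComponents[["G"]]) /
      (trueComponents[["C"]] + trueComponents[["G"]] + A / nYears +
         B / (nYears * nBlocks))
    list(records = records,
         trueValues = data.frame(genotype = ids,
                                 cross = if (hasCross) cross else NA_character_,
                                 additive = if (hasCross)
                                   as.numeric(s * (gRaw - dev[cross])) else s * a,
                                 deviation = if (hasCross)
                                   as.numeric(s * dev[cross]) else 0,
                                 total = as.numeric(g),
                                 stringsAsFactors = FALSE),
         trueComponents = trueComponents, pluginH2 = pluginH2,
         scalingFactor = s)
  })
}

#' Default trait set for a synthetic study
#'
#' Builds a battery of trait architectures spanning the heritability range
#' (about 0.5 to 0.9) and cross-variance shares from under 10% up to about
#' 50%, alternating polygenic and oligogenic classes — the spread of
#' genetic architectures a multi-trait field study exhibits.
#'
#' @param genotypes offspring \code{\linkS4class{DosageMatrix}}.
#' @param population population table.
#' @param nTraits number of traits.
#' @param seed integer seed.
#' @return list of \code{\linkS4class{TraitArchitecture}} objects.
#' @export
defaultArchitectures <- function(genotypes, population, nTraits = 15,
                                 seed = 1) {
  h2 <- seq(0.5, 0.9, length.out = nTraits)
  ratio <- seq(0.05, 0.5, length.out = nTraits)
  out <- vector("list", nTraits)
  for (t in seq_len(nTraits)) {
    cls <- if (t %% 3 == 0) "oligogenic" else "polygenic"
    nQtl <- if (cls == "oligogenic") 5 else
      max(100, round(0.1 * length(markerIds(genotypes))))
    arch <- makeTraitArchitecture(
      genotypes, sprintf("trait%02d", t), cls, nQtl, h2[t],
      seed = deriveSeed(seed, paste0("arch:", t)))
    out[[t]] <- calibrateCrossShare(genotypes, population, arch, ratio[t])
  }
  names(out) <- vapply(out, function(a) a@traitId, character(1))
  out
}
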