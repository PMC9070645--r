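#' Default run configuration
#'
#' Desk-scale defaults for the end-to-end pipeline: a structured panel of
#' 300 individuals in 3 subpopulations, 5 parents drawn from the panel (4
#' from one subpopulation, 1 from another), 10 half-diallel crosses of 65
#' offspring, 2 000 markers on 19 chromosomes, and a reduced trait battery.
#' Every stochastic stage derives its seed from the master seed and a
#' stage label, so adding a stage never perturbs earlier stages.
#'
#' @param seed master seed.
#' @param outDir output directory.
#' @return nested configuration list understood by
#'   \code{\link{runPipeline}}.
#' @export
defaultRunConfig <- function(seed = 1, outDir = tempfile("diallelGP_run")) {
  list(
    seed = seed,
    outDir = outDir,
    simulation = list(
      nPanel = 300, nSubpops = 3, fst = 0.05, mafMin = 0.05,
      nMarkers = 2000, mapLengthCM = rep(70, 19),
      nParents = 5, parentSubpops = c(4, 1),
      nOffspringPerCross = 65,
      nTraits = 5, nYears = 2, nBlocks = 2),
    analysis = list(
      scenarios = c("1a", "1b", "2"),
      methods = c("RR", "LASSO"),
      useMixedModel = TRUE,
      selectTerms = FALSE,
      randomTerms = c("G", "C", "G:Y", "C:Y", "x", "y", "x:y",
                      "x:Y", "y:Y"),
      folds = 10, reps = 2, innerK = 5, gridSize = 30,
      tsSizes = c(50, 100, 150), tsCriteria = c("PEVmean", "CDmean",
                                                "MeanRel"),
      h2ForLambdaRatio = 0.5,
      wwOnly = FALSE))
}

#' Validate a genotype / pedigree / phenotype bundle
#'
#' Checks id cross-references, dosage ranges, marker-map ordering,
#' pedigree consistency (parents exist and differ) and phenotype factor
#' levels, distinguishing hard errors from warnings.
#'
#' @param genotypes a \code{\linkS4class{DosageMatrix}} (or matrix).
#' @param pedigree data.frame (offspring, cross, parent1, parent2), or
#'   NULL.
#' @param phenotypes long phenotype data.frame, or NULL.
#' @return list with \code{errors}, \code{warnings} and \code{ok}
#'   (TRUE when no hard error was found).
#' @export
validateInputs <- function(genotypes, pedigree = NULL, phenotypes = NULL) {
  errors <- character(0); warnings <- character(0)
  x <- if (is(genotypes, "DosageMatrix")) dosages(genotypes) else genotypes
  bad <- which(!is.na(x) & (x < 0 | x > 2), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[seq_len(min(20, nrow(bad))), , drop = FALSE]
    errors <- c(errors, sprintf(
      "dosage out of [0, 2] at (%s)",
      paste(sprintf("%s,%s", rownames(x)[b[, 1]], colnames(x)[b[, 2]]),
            collapse = "; ")))
  }
  if (is(genotypes, "DosageMatrix")) {
    m <- markerMap(genotypes)
    if (!identical(order(as.character(m$chrom), m$pos_bp),
                   seq_len(nrow(m))))
      errors <- c(errors, "marker map is not sorted by (chrom, pos_bp)")
  }
  if (!is.null(pedigree)) {
    same <- pedigree$parent1 == pedigree$parent2
    if (any(same))
      errors <- c(errors, sprintf(
        "offspring with identical parents: %s",
        paste(head(pedigree$offspring[same], 20), collapse = ", ")))
    known <- rownames(x)
    missPar <- setdiff(c(pedigree$parent1, pedigree$parent2), known)
    if (length(missPar))
      warnings <- c(warnings, sprintf(
        "parents without genotypes: %s",
        paste(head(missPar, 20), collapse = ", ")))
    missOff <- setdiff(pedigree$offspring, known)
    if (length(missOff))
      warnings <- c(warnings, sprintf(
        "offspring without genotypes: %s",
        paste(head(missOff, 20), collapse = ", ")))
    for (cid in unique(pedigree$cross)) {
      pp <- unique(pedigree[pedigree$cross == cid,
                            c("parent1", "parent2")])
      if (nrow(pp) > 1)
        errors <- c(errors, sprintf(
          "cross %s has inconsistent parent pairs", cid))
    }
  }
  if (!is.null(phenotypes)) {
    need <- c("genotype", "trait", "value")
    miss <- setdiff(need, names(phenotypes))
    if (length(miss))
      errors <- c(errors, paste("phenotype table lacks columns:",
                                paste(miss, collapse = ", ")))
    else {
      if (any(!is.finite(phenotypes$value)))
        errors <- c(errors, "non-finite phenotype values")
      unk <- setdiff(unique(phenotypes$genotype), rownames(x))
      if (length(unk))
        errors <- c(errors, sprintf(
          "phenotyped individuals without genotypes: %s",
          paste(head(unk, 20), collapse = ", ")))
    }
  }
  list(errors = errors, warnings = warnings, ok = !length(errors))
}

#' Run the full simulate - model - predict - optimize - explain pipeline
#'
#' Executes the requested stages in dependency order on a synthetic
#' structured panel plus half-diallel: simulation, per-trait mixed-model
#' analysis (or true simulated values when \code{useMixedModel} is FALSE),
#' the training scenarios with predictive-ability assessment, training-set
#' optimization against random baselines, and the determinants regression
#' of Mendelian-sampling PA.  All tabular outputs are written as CSV under
#' \code{config$outDir} together with a machine-readable manifest; two
#' runs with the same configuration produce byte-identical outputs.
#'
#' @param config configuration list, see \code{\link{defaultRunConfig}}.
#' @return (invisibly) list with all in-memory results plus
#'   \code{manifest}.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  cfg <- config
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  sim <- cfg$simulation
  ana <- cfg$analysis
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, name)
    p
  }

  ## -- simulate ------------------------------------------------------
  panel <- simulatePanel(sim$nPanel, sim$nMarkers, sim$nSubpops, sim$fst,
                         sim$mafMin, mapLengthCM = sim$mapLengthCM,
                         seed = deriveSeed(seed, "simulate:panel"))
  parentIds <- pickParents(panel$population, sim$nParents,
                           sim$parentSubpops,
                           deriveSeed(seed, "simulate:parents"))
  parentsPhased <- new("PhasedGenotypes",
                       hapA = panel$phased@hapA[parentIds, , drop = FALSE],
                       hapB = panel$phased@hapB[parentIds, , drop = FALSE],
                       map = panel$phased@map)
  hd <- makeHalfDiallel(parentsPhased, sim$nOffspringPerCross,
                        seed = deriveSeed(seed, "simulate:diallel"))
  if (nrow(hd$crosses) < 3 && "1b" %in% ana$scenarios) {
    warning("fewer than 3 crosses: scenario 1b has no half-sib training ",
            "sets and is skipped")
    ana$scenarios <- setdiff(ana$scenarios, "1b")
  }
  archs <- defaultArchitectures(hd$genotypes, hd$population, sim$nTraits,
                                deriveSeed(seed, "simulate:arch"))
  parentsGeno <- panel$genotypes[parentIds, ]

  phenoHD <- list(); phenoPanel <- list()
  for (tr in names(archs)) {
    phenoHD[[tr]] <- simulatePhenotypes(
      hd$genotypes, hd$population, archs[[tr]], sim$nYears, sim$nBlocks,
      seed = deriveSeed(seed, paste0("simulate:pheno:hd:", tr)))
    phenoPanel[[tr]] <- simulatePhenotypes(
      panel$genotypes, panel$population, archs[[tr]], sim$nYears,
      sim$nBlocks,
      seed = deriveSeed(seed, paste0("simulate:pheno:panel:", tr)))
  }
  emit(do.call(rbind, lapply(phenoHD, `[[`, "records")),
       "phenotypes_halfdiallel.csv")
  emit(do.call(rbind, lapply(phenoPanel, `[[`, "records")),
       "phenotypes_panel.csv")
  writeDosageCSV(hd$genotypes,
                 file.path(cfg$outDir, "genotypes_halfdiallel.csv"))
  written <- c(written, "genotypes_halfdiallel.csv",
               "genotypes_halfdiallel_map.csv")
  writePedigreeCSV(hd$population, file.path(cfg$outDir, "pedigree.csv"))
  written <- c(written, "pedigree.csv")

  ## -- phenomodel: genotypic values, H2, cross ratio -----------------
  valRows <- list(); panelValRows <- list(); traitStatRows <- list()
  perCrossH2Rows <- list()
  for (tr in names(archs)) {
    if (isTRUE(ana$useMixedModel)) {
      an <- analyzeTrait(phenoHD[[tr]]$records,
                         selectTerms = isTRUE(ana$selectTerms),
                         random = ana$randomTerms)
      gv <- geneticValueTable(an$values)
      h2 <- an$h2; ratio <- an$crossRatio
      anP <- analyzeTrait(phenoPanel[[tr]]$records,
                          selectTerms = isTRUE(ana$selectTerms),
                          random = ana$randomTerms)
      gvP <- geneticValueTable(anP$values)
      h2P <- anP$h2
      for (cid in hd$crosses$cross) {
        rc <- phenoHD[[tr]]$records[phenoHD[[tr]]$records$cross == cid, ]
        h2c <- tryCatch(
          heritabilityPerCross(rc, retained = setdiff(ana$randomTerms,
                                                      c("C", "C:Y")))$h2,
          error = function(e) NA_real_)
        perCrossH2Rows[[length(perCrossH2Rows) + 1]] <-
          data.frame(trait = tr, cross = cid, h2Cross = h2c,
                     stringsAsFactors = FALSE)
      }
    } else {
      tv <- phenoHD[[tr]]$trueValues
      gv <- data.frame(genotype = tv$genotype, cross = tv$cross,
                       C = tv$deviation, G = tv$additive,
                       total = tv$total / sd(tv$total),
                       stringsAsFactors = FALSE)
      tc <- phenoHD[[tr]]$trueComponents
      h2 <- phenoHD[[tr]]$pluginH2
      ratio <- tc[["C"]] / (tc[["C"]] + tc[["G"]])
      tvP <- phenoPanel[[tr]]$trueValues
      gvP <- data.frame(genotype = tvP$genotype, cross = NA_character_,
                        C = 0, G = tvP$additive,
                        total = tvP$total / sd(tvP$total),
                        stringsAsFactors = FALSE)
      h2P <- phenoPanel[[tr]]$pluginH2
      dec <- varBetweenWithin(
        phenoHD[[tr]]$trueValues$total, phenoHD[[tr]]$trueValues$cross)
      for (cid in hd$crosses$cross)
        perCrossH2Rows[[length(perCrossH2Rows) + 1]] <-
          data.frame(trait = tr, cross = cid, h2Cross = h2,
                     stringsAsFactors = FALSE)
    }
    off <- gv[gv$genotype %in% individualIds(hd$genotypes), ]
    valRows[[tr]] <- data.frame(genotype = off$genotype,
                                cross = off$cross, trait = tr,
                                total = off$total,
                                stringsAsFactors = FALSE)
    subR2 <- subpopulationR2(
      gvP$total[match(panel$population$individual, gvP$genotype)],
      panel$population$subpopulation)
    panelValRows[[tr]] <- data.frame(genotype = gvP$genotype, trait = tr,
                                     total = gvP$total,
                                     stringsAsFactors = FALSE)
    traitStatRows[[tr]] <- data.frame(trait = tr, h2Overall = h2,
                                      crossRatio = ratio, h2Panel = h2P,
                                      subpopR2 = subR2,
                                      stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, valRows); rownames(values) <- NULL
  panelValues <- do.call(rbind, panelValRows); rownames(panelValues) <- NULL
  traitStats <- do.call(rbind, traitStatRows); rownames(traitStats) <- NULL
  perCrossH2 <- do.call(rbind, perCrossH2Rows)
  emit(values, "genetic_values_halfdiallel.csv")
  emit(traitStats, "trait_statistics.csv")
  emit(perCrossH2, "h2_per_cross.csv")

  ## -- relationship, PCA, cross-level statistics ---------------------
  Apanel <- vanRadenA(panel$genotypes)
  proj <- pcaProject(panel$genotypes, hd$genotypes, nAxes = 2)
  Aall <- vanRadenA(
    new("DosageMatrix",
        dosages = rbind(dosages(panel$genotypes), dosages(hd$genotypes)),
        map = markerMap(panel$genotypes)),
    freqIndividuals = individualIds(panel$genotypes))
  P <- dosages(parentsGeno)
  crossStatRows <- lapply(seq_len(nrow(hd$crosses)), function(i) {
    p1 <- hd$crosses$parent1[i]; p2 <- hd$crosses$parent2[i]
    offIds <- hd$population$individual[
      hd$population$cross == hd$crosses$cross[i] &
      hd$population$role == "offspring"]
    data.frame(
      cross = hd$crosses$cross[i],
      nonseg = nonsegregatingProportion(P[p1, ], P[p2, ]),
      parentRel = relValues(Apanel)[p1, p2],
      parentDistPC12 = parentAxisDistance(proj, p1, p2, 1:2),
      meanRelTsVs = meanRelationship(Aall, individualIds(panel$genotypes),
                                     offIds),
      stringsAsFactors = FALSE)
  })
  crossStats <- do.call(rbind, crossStatRows)
  emit(crossStats, "cross_statistics.csv")
  scores <- pcaScores(proj)
  emit(data.frame(id = rownames(scores), scores, stringsAsFactors = FALSE),
       "pca_scores.csv")

  ## -- scenarios -----------------------------------------------------
  results <- list()
  if ("1a" %in% ana$scenarios)
    results$s1a <- runScenario1a(hd$genotypes, values, hd$crosses,
                                 parentsGeno, ana$folds, ana$reps,
                                 ana$methods,
                                 deriveSeed(seed, "scenario:1a"),
                                 ana$gridSize, ana$innerK)
  if ("1b" %in% ana$scenarios)
    results$s1b <- runScenario1b(hd$genotypes, values, hd$crosses,
                                 hd$population, parentsGeno, ana$methods,
                                 deriveSeed(seed, "scenario:1b"),
                                 ana$gridSize, ana$innerK)
  if ("2" %in% ana$scenarios)
    results$s2 <- runScenario2(panel$genotypes, panelValues, hd$genotypes,
                               values, hd$crosses, parentsGeno,
                               ana$methods, "all", panel$population,
                               deriveSeed(seed, "scenario:2"),
                               ana$gridSize, ana$innerK)
  if (isTRUE(ana$wwOnly) && "2" %in% ana$scenarios)
    results$s2ww <- runScenario2(panel$genotypes, panelValues,
                                 hd$genotypes, values, hd$crosses,
                                 parentsGeno, ana$methods,
                                 panel$population$subpopulation[1],
                                 panel$population,
                                 deriveSeed(seed, "scenario:2ww"),
                                 ana$gridSize, ana$innerK)
  paAll <- do.call(rbind, lapply(results, `[[`, "pa"))
  cmAll <- do.call(rbind, lapply(results, `[[`, "crossMeans"))
  if (!is.null(paAll)) { rownames(paAll) <- NULL; emit(paAll, "pa_results.csv") }
  if (!is.null(cmAll)) {
    rownames(cmAll) <- NULL
    emit(cmAll, "cross_means.csv")
  }

  ## -- bias-corrected all-pairs ranking ------------------------------
  if (!is.null(results$s2)) {
    cm2 <- results$s2$crossMeans
    m0 <- ana$methods[1]
    bias <- estimateBias(cm2[cm2$method == m0, ])
    tr0 <- names(archs)[1]
    rank <- predictAllCrosses(panel$genotypes,
                              results$s2$models[[tr0]][[m0]],
                              bias[[tr0]])
    emit(utils::head(rank, 1000), "all_crosses_ranked.csv")
  }

  ## -- training-set optimization -------------------------------------
  if (length(ana$tsSizes) && !is.null(results$s2)) {
    lambdaRatio <- (1 - ana$h2ForLambdaRatio) / ana$h2ForLambdaRatio
    vsIds <- hd$population$individual[
      hd$population$cross == hd$crosses$cross[1] &
      hd$population$role == "offspring"]
    tsRows <- list()
    for (crit in ana$tsCriteria) {
      for (sz in ana$tsSizes) {
        if (sz > length(individualIds(panel$genotypes))) next
        opt <- optimizeTS(Aall, individualIds(panel$genotypes), vsIds,
                          crit, sz, lambdaRatio,
                          seed = deriveSeed(seed, "tsopt"))
        rnd <- randomBaseline(Aall, individualIds(panel$genotypes), vsIds,
                              sz, crit, lambdaRatio, reps = 10,
                              seed = deriveSeed(seed, "tsopt:rand"))
        rvals <- vapply(rnd, function(s) s@criterionValue, numeric(1))
        tsRows[[length(tsRows) + 1]] <- data.frame(
          criterion = crit, size = sz, cross = hd$crosses$cross[1],
          optimized = opt@criterionValue, randomMean = mean(rvals),
          randomLo = quantile(rvals, 0.025), randomHi = quantile(rvals, 0.975),
          members = paste(opt@memberIds, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    tsTable <- do.call(rbind, tsRows); rownames(tsTable) <- NULL
    emit(tsTable, "ts_optimization.csv")
    results$tsopt <- tsTable
  }

  ## -- determinants of predictive ability ----------------------------
  if (!is.null(paAll)) {
    detRows <- list()
    for (sc in intersect(c("1a", "1b", "2"), unique(paAll$scenario))) {
      pam <- paAll[paAll$scenario == sc, ]
      best <- bestOfMethods(pam)
      tab <- tryCatch(
        assembleExplanatoryTable(best, crossStats, traitStats,
                                 perCrossH2, sc),
        error = function(e) NULL)
      if (is.null(tab)) next
      sw <- stepwiseAIC(tab)
      imp <- if (length(sw$selected))
        relativeImportance(tab, sw$selected, "pmvd") else
        list(shares = numeric(0), r2 = 0)
      detRows[[sc]] <- data.frame(
        scenario = sc,
        variable = c("(model R2)", names(imp$shares)),
        value = c(imp$r2, as.numeric(imp$shares)),
        stringsAsFactors = FALSE)
      results$determinants[[sc]] <-
        list(table = tab, stepwise = sw, importance = imp)
    }
    if (length(detRows))
      emit(do.call(rbind, detRows), "pa_determinants.csv")
  }

  ## -- manifest ------------------------------------------------------
  manifest <- list(
    package = "diallelGP",
    version = as.character(utils::packageVersion("diallelGP")),
    seed = seed,
    configHash = fnvHash(cfg[setdiff(names(cfg), "outDir")]),
    files = sort(unique(written)))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  results$config <- cfg
  invisible(results)
}

# Reduce method rows to the per-cell best of RR/LASSO.
bestOfMethods <- function(pa) {
  cells <- pa[pa$component == "mendelian" & pa$granularity == "per_cross" &
              pa$cross != "all", ]
  out <- list()
  for (key in unique(paste(cells$trait, cells$cross, cells$ts_parent))) {
    d <- cells[paste(cells$trait, cells$cross, cells$ts_parent) == key, ]
    rr <- d$pa[d$method == "RR"][1]
    la <- d$pa[d$method == "LASSO"][1]
    b <- bestMethod(if (is.null(rr)) NA_real_ else rr,
                    if (is.null(la)) NA_real_ else la)
    row <- d[1, ]
    row$method <- b$method
    row$pa <- b$pa
    out[[length(out) + 1]] <- row
  }
  res <- do.call(rbind, out)
  res[!is.na(res$pa), ]
}

# Parents sampled from the panel: `parentSubpops` gives how many parents
# come from each of the first subpopulations (e.g. c(4, 1)).
pickParents <- function(population, nParents, parentSubpops, seed) {
  subs <- unique(population$subpopulation)
  if (sum(parentSubpops) != nParents)
    parentSubpops <- c(nParents - 1, 1)
  withSeed(seed, {
    ids <- character(0)
    for (i in seq_along(parentSubpops)) {
      pool <- population$individual[population$subpopulation ==
                                    subs[min(i, length(subs))]]
      pool <- setdiff(pool, ids)
      ids <- c(ids, sample(pool, parentSubpops[i]))
    }
    ids
  })
}

# Polynomial hash of a configuration's deparsed text (manifest provenance).
fnvHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  sprintf("%08x", deriveSeed(7, s))
}
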