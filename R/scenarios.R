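#' Predictive-ability table from paired observations and predictions
#'
#' Pearson correlations between observed and predicted genotypic values at
#' the requested granularity: \code{per_cross} correlates within each
#' (trait, cross) cell over individuals; \code{per_trait} averages the
#' cell values of a trait over crosses; \code{overall} averages over all
#' cells.  Groups with fewer than 3 pairs are dropped with a warning;
#' zero-variance groups yield \code{NA} (missing, never 0).
#'
#' @param observed,predicted paired numeric vectors.
#' @param cross,trait grouping labels, one per pair.
#' @param granularity subset of c("per_cross", "per_trait", "overall").
#' @return data.frame with columns trait, cross, granularity, pa, n.
#' @export
computePA <- function(observed, predicted, cross, trait,
                      granularity = c("per_cross", "per_trait", "overall")) {
  stopifnot(length(observed) == length(predicted),
            length(cross) == length(observed),
            length(trait) == length(observed))
  granularity <- match.arg(granularity, several.ok = TRUE)
  key <- paste(trait, cross, sep = "\r")
  cells <- unique(data.frame(trait = trait, cross = cross, key = key,
                             stringsAsFactors = FALSE))
  pa <- numeric(nrow(cells)); n <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- key == cells$key[i]
    n[i] <- sum(sel)
    pa[i] <- if (n[i] < 3) NA_real_ else safeCor(observed[sel], predicted[sel])
  }
  if (any(n < 3))
    warning(sum(n < 3), " group(s) with fewer than 3 pairs dropped")
  cells <- cells[n >= 3, , drop = FALSE]
  pa <- pa[n >= 3]; n <- n[n >= 3]
  out <- list()
  if ("per_cross" %in% granularity)
    out$per_cross <- data.frame(trait = cells$trait, cross = cells$cross,
                                granularity = "per_cross", pa = pa, n = n,
                                stringsAsFactors = FALSE)
  if ("per_trait" %in% granularity) {
    agg <- tapply(pa, cells$trait, mean, na.rm = TRUE)
    out$per_trait <- data.frame(trait = names(agg), cross = "all",
                                granularity = "per_trait",
                                pa = as.numeric(agg),
                                n = as.integer(table(cells$trait)[names(agg)]),
                                stringsAsFactors = FALSE)
  }
  if ("overall" %in% granularity)
    out$overall <- data.frame(trait = "all", cross = "all",
                              granularity = "overall",
                              pa = mean(pa, na.rm = TRUE),
                              n = length(pa), stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-mean predictive ability from a cross-mean table
#'
#' Correlations between observed and predicted cross means: per trait
#' (across crosses), per cross (across traits) and overall (all cells
#' pooled, so the overall value equals the correlation over the
#' concatenated per-cell pairs).
#'
#' @param cm data.frame with columns trait, cross, observed, predicted.
#' @return data.frame with columns trait, cross, granularity, pa, n.
#' @export
crossMeanPA <- function(cm) {
  perTrait <- do.call(rbind, lapply(split(cm, cm$trait), function(d)
    data.frame(trait = d$trait[1], cross = "all", granularity = "per_trait",
               pa = safeCor(d$observed, d$predicted), n = nrow(d),
               stringsAsFactors = FALSE)))
  perCross <- do.call(rbind, lapply(split(cm, cm$cross), function(d)
    data.frame(trait = "all", cross = d$cross[1], granularity = "per_cross",
               pa = safeCor(d$observed, d$predicted), n = nrow(d),
               stringsAsFactors = FALSE)))
  overall <- data.frame(trait = "all", cross = "all",
                        granularity = "overall",
                        pa = safeCor(cm$observed, cm$predicted),
                        n = nrow(cm), stringsAsFactors = FALSE)
  res <- rbind(perTrait, perCross, overall)
  rownames(res) <- NULL
  res
}

#' Keep the better of the ridge and LASSO predictive abilities
#'
#' @param paRR,paLASSO predictive abilities (either may be NA).
#' @return list with \code{method} and \code{pa}; ties go to RR; both
#'   missing returns NA.
#' @export
bestMethod <- function(paRR, paLASSO) {
  stopifnot(length(paRR) == length(paLASSO))
  method <- ifelse(is.na(paRR) & is.na(paLASSO), NA_character_,
            ifelse(is.na(paLASSO), "RR",
            ifelse(is.na(paRR), "LASSO",
            ifelse(paLASSO > paRR, "LASSO", "RR"))))
  pa <- ifelse(is.na(method), NA_real_,
        ifelse(method == "LASSO", paLASSO, paRR))
  list(method = method, pa = pa)
}

#' Seeded k-fold assignment
#'
#' Random permutation of fold labels 1..k over n individuals (folds as
#' equal as possible), so each fold trains on (k-1)/k of the data — 90%
#' with the default 10 folds.
#'
#' @param n number of individuals; @param k folds; @param seed integer.
#' @return integer vector of fold labels.
#' @export
cvFolds <- function(n, k = 10, seed = 1) {
  withSeed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' Half-sib training sets for each cross and parent
#'
#' For a focal cross and one of its parents, the training set is the union
#' of the parent's other crosses (three half-sib crosses per parent in a
#' complete 5-parent half-diallel), never overlapping the focal cross.
#'
#' @param crosses cross table (cross, parent1, parent2).
#' @param population population table with offspring rows.
#' @return data.frame (cross, parent, tsCrosses) plus list-column
#'   \code{tsIds}; parents with no other cross are absent.
#' @export
halfSibTrainingSets <- function(crosses, population) {
  out <- list()
  for (ci in seq_len(nrow(crosses))) {
    cid <- crosses$cross[ci]
    for (par in c(crosses$parent1[ci], crosses$parent2[ci])) {
      others <- crosses$cross[crosses$cross != cid &
        (crosses$parent1 == par | crosses$parent2 == par)]
      if (!length(others)) next
      ids <- population$individual[population$cross %in% others &
                                   population$role == "offspring"]
      out[[length(out) + 1]] <-
        data.frame(cross = cid, parent = par,
                   tsCrosses = paste(others, collapse = ";"),
                   nTsCrosses = length(others),
                   tsIds = I(list(ids)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Parental-average dosage rows for every cross, as a plain matrix.
parentalAverageMatrix <- function(parents, crosses) {
  P <- if (is(parents, "DosageMatrix")) dosages(parents) else parents
  out <- t(vapply(seq_len(nrow(crosses)), function(i)
    parentalAverageGenotype(P[crosses$parent1[i], ], P[crosses$parent2[i], ]),
    numeric(ncol(P))))
  rownames(out) <- crosses$cross
  colnames(out) <- colnames(P)
  out
}

# Long values table -> named vector for one trait, restricted to ids.
traitValues <- function(values, traitId, ids) {
  v <- values[values$trait == traitId, ]
  v <- v[v$genotype %in% ids, ]
  setNames(v$total, v$genotype)
}

#' Scenario 1a: random 10-fold cross-validation within the half-diallel
#'
#' Outer k-fold cross-validation over all phenotyped offspring, replicated
#' \code{reps} times: per replicate every offspring is predicted exactly
#' once by a model trained on the other folds (shrinkage calibrated by
#' inner cross-validation within each training set).  Within-cross
#' (Mendelian-sampling) PA is computed per cross within each replicate and
#' averaged over replicates with its standard error.  Cross-mean
#' predictions come in two modalities: the per-offspring predictions
#' averaged over replicates and then over the cross, and the prediction at
#' the parental-average genotype from a model trained on all offspring.
#' Cross-mean PA rows use the parental-genotype modality (the two are
#' expected to agree closely; both columns are kept in the table).
#'
#' @param genotypes offspring \code{\linkS4class{DosageMatrix}}.
#' @param values long table (genotype, cross, trait, total) of scaled
#'   total genotypic values.
#' @param crosses cross table (cross, parent1, parent2); needed with
#'   \code{parents} for the parental modality.
#' @param parents parent \code{\linkS4class{DosageMatrix}} (integer
#'   dosages), or NULL to skip the parental modality.
#' @param k outer folds (default 10); \code{reps} replicates (default 10).
#' @param methods subset of c("RR", "LASSO").
#' @param seed master seed; all folds and calibrations derive from it.
#' @param gridSize,innerK shrinkage-calibration controls.
#' @return list with \code{pa} (PA rows: scenario, trait, cross,
#'   component, method, granularity, pa, se, ts_parent), \code{crossMeans}
#'   (trait, cross, method, observed, predOffspring, predParental) and
#'   \code{predictions} (per-individual averaged predictions).
#' @export
runScenario1a <- function(genotypes, values, crosses = NULL, parents = NULL,
                          k = 10, reps = 10, methods = c("RR", "LASSO"),
                          seed = 1, gridSize = 50, innerK = 5) {
  X <- dosages(genotypes)
  traits <- unique(values$trait)
  paRows <- list(); cmRows <- list(); predRows <- list()
  for (tr in traits) {
    y <- traitValues(values, tr, rownames(X))
    ids <- names(y)
    crossOf <- values$cross[match(ids, values$genotype)]
    n <- length(ids)
    Xt <- X[ids, , drop = FALSE]
    obsMean <- tapply(y, crossOf, mean)
    for (m in methods) {
      predMat <- matrix(NA_real_, n, reps, dimnames = list(ids, NULL))
      cellRep <- NULL
      for (r in seq_len(reps)) {
        folds <- cvFolds(n, k,
                         deriveSeed(seed, sprintf("1a:folds:%s:%d", tr, r)))
        for (f in seq_len(k)) {
          trIdx <- folds != f
          mod <- trainMarkerModel(
            Xt[trIdx, , drop = FALSE], y[trIdx], m, innerK, gridSize,
            deriveSeed(seed, sprintf("1a:cal:%s:%s:%d:%d", tr, m, r, f)), tr)
          predMat[!trIdx, r] <- predict(mod, Xt[!trIdx, , drop = FALSE])
        }
        paCell <- vapply(split(seq_len(n), crossOf), function(ii)
          safeCor(y[ii], predMat[ii, r]), numeric(1))
        cellRep <- cbind(cellRep, paCell)
      }
      paMend <- rowMeans(cellRep, na.rm = TRUE)
      seMend <- apply(cellRep, 1, function(v) sd(v, na.rm = TRUE)) /
        sqrt(rowSums(!is.na(cellRep)))
      avgPred <- rowMeans(predMat)
      predOffMean <- tapply(avgPred, crossOf, mean)

      predParental <- rep(NA_real_, length(obsMean))
      names(predParental) <- names(obsMean)
      if (!is.null(parents) && !is.null(crosses)) {
        full <- trainMarkerModel(
          Xt, y, m, innerK, gridSize,
          deriveSeed(seed, sprintf("1a:full:%s:%s", tr, m)), tr)
        pam <- parentalAverageMatrix(parents, crosses)
        pp <- predict(full, pam)
        predParental[crosses$cross] <- pp[crosses$cross]
      }
      cmRows[[length(cmRows) + 1]] <- data.frame(
        scenario = "1a", trait = tr, cross = names(obsMean), method = m,
        observed = as.numeric(obsMean),
        predOffspring = as.numeric(predOffMean[names(obsMean)]),
        predParental = as.numeric(predParental[names(obsMean)]),
        stringsAsFactors = FALSE)
      paRows[[length(paRows) + 1]] <- data.frame(
        scenario = "1a", trait = tr, cross = names(paMend),
        component = "mendelian", method = m, granularity = "per_cross",
        pa = as.numeric(paMend), se = as.numeric(seMend),
        ts_parent = NA_character_, stringsAsFactors = FALSE)
      predRows[[length(predRows) + 1]] <- data.frame(
        scenario = "1a", trait = tr, genotype = ids, cross = crossOf,
        method = m, predicted = as.numeric(avgPred), observed = as.numeric(y),
        stringsAsFactors = FALSE)
    }
  }
  finishScenario("1a", paRows, cmRows, do.call(rbind, predRows))
}

#' Scenario 1b: half-sib training within the half-diallel
#'
#' Each cross in turn is the validation set; for each of its two parents
#' the model is trained on the union of that parent's other crosses (three
#' half-sib crosses in a complete 5-parent half-diallel), so every cross
#' is predicted twice.  A parent with no other cross is skipped with a
#' warning.
#'
#' @inheritParams runScenario1a
#' @param population population table linking offspring to crosses.
#' @return as \code{\link{runScenario1a}}; PA rows carry \code{ts_parent}.
#' @export
runScenario1b <- function(genotypes, values, crosses, population,
                          parents = NULL, methods = c("RR", "LASSO"),
                          seed = 1, gridSize = 50, innerK = 5) {
  X <- dosages(genotypes)
  traits <- unique(values$trait)
  paRows <- list(); cmRows <- list(); predRows <- list()
  hs <- halfSibTrainingSets(crosses, population)
  nSlots <- 2 * nrow(crosses)
  if (is.null(hs) || nrow(hs) < nSlots)
    warning(nSlots - if (is.null(hs)) 0 else nrow(hs),
            " (cross, parent) slot(s) without half-sib crosses skipped")
  if (is.null(hs)) return(finishScenario("1b", paRows, cmRows, NULL))
  for (hi in seq_len(nrow(hs))) {
    {
      cid <- hs$cross[hi]
      par <- hs$parent[hi]
      ci <- match(cid, crosses$cross)
      tsIds <- hs$tsIds[[hi]]
      vsIds <- population$individual[population$cross == cid &
                                     population$role == "offspring"]
      for (tr in traits) {
        yts <- traitValues(values, tr, intersect(tsIds, rownames(X)))
        yvs <- traitValues(values, tr, intersect(vsIds, rownames(X)))
        if (length(yts) < 10 || length(yvs) < 3) next
        for (m in methods) {
          mod <- trainMarkerModel(
            X[names(yts), , drop = FALSE], yts, m, innerK, gridSize,
            deriveSeed(seed, sprintf("1b:%s:%s:%s:%s", cid, par, tr, m)), tr)
          pv <- predict(mod, X[names(yvs), , drop = FALSE])
          paRows[[length(paRows) + 1]] <- data.frame(
            scenario = "1b", trait = tr, cross = cid,
            component = "mendelian", method = m, granularity = "per_cross",
            pa = safeCor(yvs, pv), se = NA_real_, ts_parent = par,
            stringsAsFactors = FALSE)
          predParental <- NA_real_
          if (!is.null(parents)) {
            pam <- parentalAverageMatrix(parents, crosses[ci, , drop = FALSE])
            predParental <- as.numeric(predict(mod, pam))
          }
          cmRows[[length(cmRows) + 1]] <- data.frame(
            scenario = "1b", trait = tr, cross = cid, method = m,
            ts_parent = par, observed = mean(yvs),
            predOffspring = mean(pv), predParental = predParental,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  finishScenario("1b", paRows, cmRows, NULL)
}

#' Scenario 2: across-population prediction from a diversity panel
#'
#' One model per (trait, method) is trained on the diversity panel (its
#' genotypic values scaled within the panel) and used to predict every
#' half-diallel cross: within-cross individuals for Mendelian-sampling PA
#' and parental-average genotypes for cross-mean PA.  The training set may
#' be restricted to one subpopulation.
#'
#' @param panelGenotypes,panelValues panel dosages and long value table
#'   (genotype, trait, total), scaled within the panel.
#' @param genotypes,values offspring dosages and value table, scaled
#'   within the half-diallel.
#' @param crosses cross table; @param parents parent dosages.
#' @param tsFilter "all" or a subpopulation label; with a label,
#'   \code{panelPopulation} must give the subpopulation of each panel
#'   individual.
#' @param panelPopulation population table for the panel.
#' @inheritParams runScenario1a
#' @return as \code{\link{runScenario1a}}, plus \code{models} (per trait
#'   and method) for downstream reuse.
#' @export
runScenario2 <- function(panelGenotypes, panelValues, genotypes, values,
                         crosses, parents = NULL,
                         methods = c("RR", "LASSO"), tsFilter = "all",
                         panelPopulation = NULL, seed = 1,
                         gridSize = 50, innerK = 5) {
  Xp <- dosages(panelGenotypes)
  X <- dosages(genotypes)
  if (!identical(colnames(Xp), colnames(X)))
    stop("panel and progeny marker sets must be intersected and aligned first")
  tsPool <- rownames(Xp)
  if (!identical(tsFilter, "all")) {
    if (is.null(panelPopulation))
      stop("panelPopulation is required to filter the training set")
    tsPool <- panelPopulation$individual[
      panelPopulation$subpopulation %in% tsFilter]
  }
  traits <- unique(values$trait)
  paRows <- list(); cmRows <- list(); predRows <- list()
  models <- list()
  for (tr in traits) {
    yp <- traitValues(panelValues, tr, intersect(tsPool, rownames(Xp)))
    if (length(yp) < 10) {
      warning("trait ", tr, " has insufficient panel phenotypes; skipped")
      next
    }
    y <- traitValues(values, tr, rownames(X))
    crossOf <- values$cross[match(names(y), values$genotype)]
    obsMean <- tapply(y, crossOf, mean)
    for (m in methods) {
      mod <- trainMarkerModel(
        Xp[names(yp), , drop = FALSE], yp, m, innerK, gridSize,
        deriveSeed(seed, sprintf("2:%s:%s:%s", tr, m,
                                 paste(tsFilter, collapse = "+"))), tr)
      models[[tr]][[m]] <- mod
      pv <- predict(mod, X[names(y), , drop = FALSE])
      cells <- vapply(split(seq_along(y), crossOf), function(ii)
        safeCor(y[ii], pv[ii]), numeric(1))
      paRows[[length(paRows) + 1]] <- data.frame(
        scenario = "2", trait = tr, cross = names(cells),
        component = "mendelian", method = m, granularity = "per_cross",
        pa = as.numeric(cells), se = NA_real_, ts_parent = NA_character_,
        stringsAsFactors = FALSE)
      predParental <- rep(NA_real_, length(obsMean))
      names(predParental) <- names(obsMean)
      if (!is.null(parents)) {
        pam <- parentalAverageMatrix(parents, crosses)
        pp <- predict(mod, pam)
        predParental[crosses$cross] <- pp[crosses$cross]
      }
      predOffMean <- tapply(pv, crossOf, mean)
      cmRows[[length(cmRows) + 1]] <- data.frame(
        scenario = "2", trait = tr, cross = names(obsMean), method = m,
        observed = as.numeric(obsMean),
        predOffspring = as.numeric(predOffMean[names(obsMean)]),
        predParental = as.numeric(predParental[names(obsMean)]),
        stringsAsFactors = FALSE)
      predRows[[length(predRows) + 1]] <- data.frame(
        scenario = "2", trait = tr, genotype = names(y), cross = crossOf,
        method = m, predicted = as.numeric(pv), observed = as.numeric(y),
        stringsAsFactors = FALSE)
    }
  }
  out <- finishScenario("2", paRows, cmRows, do.call(rbind, predRows))
  out$models <- models
  out
}

# Shared tail: bind rows, add aggregated mendelian granularities and
# cross-mean PA rows computed from the parental modality.
finishScenario <- function(scenario, paRows, cmRows, predictions) {
  pa <- do.call(rbind, paRows)
  cmRows <- lapply(cmRows, function(d) {
    if (!"ts_parent" %in% names(d)) d$ts_parent <- NA_character_
    d[, c("scenario", "trait", "cross", "method", "ts_parent", "observed",
          "predOffspring", "predParental")]
  })
  cm <- do.call(rbind, cmRows)
  extra <- list()
  if (!is.null(pa) && nrow(pa)) {
    for (m in unique(pa$method)) {
      cells <- pa[pa$method == m & pa$component == "mendelian", ]
      agg <- tapply(cells$pa, cells$trait, mean, na.rm = TRUE)
      extra[[length(extra) + 1]] <- data.frame(
        scenario = scenario, trait = names(agg), cross = "all",
        component = "mendelian", method = m, granularity = "per_trait",
        pa = as.numeric(agg), se = NA_real_, ts_parent = NA_character_,
        stringsAsFactors = FALSE)
      extra[[length(extra) + 1]] <- data.frame(
        scenario = scenario, trait = "all", cross = "all",
        component = "mendelian", method = m, granularity = "overall",
        pa = mean(cells$pa, na.rm = TRUE), se = NA_real_,
        ts_parent = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(cm) && nrow(cm) && any(is.finite(cm$predParental))) {
    for (m in unique(cm$method)) {
      d <- cm[cm$method == m & is.finite(cm$predParental), ]
      d$predicted <- d$predParental
      rows <- crossMeanPA(d)
      extra[[length(extra) + 1]] <- data.frame(
        scenario = scenario, trait = rows$trait, cross = rows$cross,
        component = "cross_mean", method = m,
        granularity = rows$granularity, pa = rows$pa, se = NA_real_,
        ts_parent = NA_character_, stringsAsFactors = FALSE)
    }
  }
  pa <- rbind(pa, do.call(rbind, extra))
  rownames(pa) <- NULL
  list(pa = pa, crossMeans = cm, predictions = predictions)
}

#' Per-trait bias of predicted cross means
#'
#' Bias is the mean over crosses of (predicted - observed); subtracting it
#' gives bias-corrected predictions with zero mean error on the estimation
#' crosses.
#'
#' @param cm cross-mean table with columns trait, observed and a
#'   prediction column.
#' @param predictionColumn which prediction to use (default
#'   "predParental").
#' @return named numeric vector, one bias per trait.
#' @export
estimateBias <- function(cm, predictionColumn = "predParental") {
  stopifnot(predictionColumn %in% names(cm))
  ok <- is.finite(cm[[predictionColumn]])
  cm <- cm[ok, ]
  nPerTrait <- table(cm$trait)
  if (any(nPerTrait < 2))
    warning("bias estimated from a single cross for: ",
            paste(names(nPerTrait)[nPerTrait < 2], collapse = ", "))
  tapply(cm[[predictionColumn]] - cm$observed, cm$trait, mean)
}

#' @rdname estimateBias
#' @param prediction numeric predictions; @param bias scalar (or one value
#'   per prediction) from \code{estimateBias}.
#' @export
applyBias <- function(prediction, bias) prediction - bias

#' Rank all possible crosses of a panel by predicted cross mean
#'
#' Enumerates every unordered pair of panel individuals (no selfs;
#' n(n-1)/2 pairs, e.g. 38 781 for 279 genotypes) and predicts each cross
#' mean at the parental-average genotype.  Because the prediction map is
#' affine in dosages, the parental-average prediction equals the mean of
#' the two parents' own predictions, which is how the enumeration is
#' computed.
#'
#' @param panel panel \code{\linkS4class{DosageMatrix}}.
#' @param model a trained \code{\linkS4class{MarkerEffectsModel}}.
#' @param bias per-trait bias to subtract (default 0).
#' @return data.frame (parent1, parent2, predictedMean) sorted by
#'   decreasing corrected prediction.
#' @export
predictAllCrosses <- function(panel, model, bias = 0) {
  pred <- predict(model, panel)
  ids <- names(pred)
  pr <- combn(length(ids), 2)
  pm <- (pred[pr[1, ]] + pred[pr[2, ]]) / 2 - bias
  out <- data.frame(parent1 = ids[pr[1, ]], parent2 = ids[pr[2, ]],
                    predictedMean = as.numeric(pm),
                    stringsAsFactors = FALSE)
  out[order(-out$predictedMean), ]
}
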