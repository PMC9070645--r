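#' Prediction error variance of validation individuals given a training set
#'
#' Gaussian conditional variance of the validation genetic values given
#' training phenotypes, in units of the genetic variance:
#' \deqn{PEV = A_{VV} - A_{VT} (A_{TT} + \lambda_r I)^{-1} A_{TV}}
#' with \eqn{\lambda_r} the residual-to-genetic variance ratio.  An empty
#' training set returns the unconditional \eqn{diag(A_{VV})}.
#'
#' @param A a \code{\linkS4class{RelationshipMatrix}}.
#' @param tsIds training ids (may be empty), disjoint from \code{vsIds}.
#' @param vsIds validation ids.
#' @param lambdaRatio positive ratio \eqn{(1 - h^2)/h^2}.
#' @return named vector of PEV values (the diagonal), one per validation
#'   individual.
#' @export
pevMatrix <- function(A, tsIds, vsIds, lambdaRatio) {
  v <- relValues(A)
  if (lambdaRatio <= 0) stop("lambdaRatio must be positive")
  if (!length(vsIds)) stop("validation set must be non-empty")
  if (length(intersect(tsIds, vsIds)))
    stop("training and validation sets must be disjoint")
  if (!all(c(tsIds, vsIds) %in% rownames(v)))
    stop("ids missing from the relationship matrix")
  Avv <- diag(v)[vsIds]
  if (!length(tsIds)) return(Avv)
  Att <- v[tsIds, tsIds, drop = FALSE]
  Atv <- v[tsIds, vsIds, drop = FALSE]
  M <- Att + diag(lambdaRatio, length(tsIds))
  ch <- tryCatch(chol(M), error = function(e)
    stop("A_TT + lambda I is not positive definite; A may not be PSD"))
  W <- backsolve(ch, forwardsolve(t(ch), Atv))
  Avv - colSums(Atv * W)
}

#' Training-set quality criterion
#'
#' \code{PEVmean}: mean PEV over the validation set (lower is better).
#' \code{CDmean}: mean coefficient of determination
#' \eqn{1 - PEV_{ii} / A_{ii}} (higher is better).
#' \code{MeanRel}: mean additive relationship between training and
#' validation members (higher is better).
#'
#' @inheritParams pevMatrix
#' @param criterion one of "PEVmean", "CDmean", "MeanRel".
#' @return numeric scalar.
#' @export
criterionValue <- function(A, tsIds, vsIds, criterion = c("PEVmean",
                           "CDmean", "MeanRel"), lambdaRatio = 1) {
  criterion <- match.arg(criterion)
  if (!length(vsIds)) stop("validation set must be non-empty")
  switch(criterion,
    PEVmean = mean(pevMatrix(A, tsIds, vsIds, lambdaRatio)),
    CDmean = {
      pev <- pevMatrix(A, tsIds, vsIds, lambdaRatio)
      mean(1 - pev / diag(relValues(A))[vsIds])
    },
    MeanRel = if (!length(tsIds)) -Inf else
      meanRelationship(A, tsIds, vsIds))
}

# TRUE when `a` is better than `b` for the criterion's orientation.
criterionBetter <- function(criterion, a, b) {
  if (criterion == "PEVmean") a < b else a > b
}

#' Optimize a training set for a validation cross
#'
#' Greedy forward construction followed by steepest-ascent single-swap
#' exchanges until no swap improves the criterion; the best solution over
#' \code{restarts} seeded starts (the first greedy, the others random) is
#' returned.  Ties are broken by the id sort order, so the result is
#' invariant to candidate ordering and deterministic given the seed.
#' MeanRel is separable over training members, so its optimum is the
#' top-\code{size} candidates by mean relationship to the validation set;
#' the search reduces to that selection.
#'
#' @inheritParams criterionValue
#' @param candidateIds pool to select from (disjoint from the validation
#'   set).
#' @param size training-set size (<= number of candidates).
#' @param restarts number of search starts (default 1).
#' @param seed integer seed.
#' @return a \code{\linkS4class{TrainingSetSelection}}.
#' @export
optimizeTS <- function(A, candidateIds, vsIds, criterion = c("PEVmean",
                       "CDmean", "MeanRel"), size, lambdaRatio = 1,
                       restarts = 1, seed = 1) {
  criterion <- match.arg(criterion)
  candidateIds <- sort(setdiff(candidateIds, vsIds))
  if (size > length(candidateIds))
    stop("size exceeds the number of candidates")
  evalSet <- function(ts) criterionValue(A, ts, vsIds, criterion, lambdaRatio)
  if (size == length(candidateIds)) {
    ts <- candidateIds
    return(new("TrainingSetSelection", criterion = criterion, size = size,
               memberIds = ts, criterionValue = evalSet(ts), vsIds = vsIds,
               lambdaRatio = lambdaRatio, seed = seed))
  }
  if (criterion == "MeanRel") {
    mr <- vapply(candidateIds, function(id)
      meanRelationship(A, id, vsIds), numeric(1))
    ts <- candidateIds[order(-mr, candidateIds)][seq_len(size)]
    return(new("TrainingSetSelection", criterion = criterion, size = size,
               memberIds = sort(ts), criterionValue = evalSet(ts),
               vsIds = vsIds, lambdaRatio = lambdaRatio, seed = seed))
  }
  bestTs <- NULL; bestVal <- NULL
  for (r in seq_len(restarts)) {
    ts <- if (r == 1) greedyForward(A, candidateIds, vsIds, criterion,
                                    size, lambdaRatio)
          else withSeed(deriveSeed(seed, paste0("tsopt:restart:", r)),
                        sort(sample(candidateIds, size)))
    ts <- swapImprove(A, ts, candidateIds, vsIds, criterion, size,
                      lambdaRatio)
    val <- evalSet(ts)
    if (is.null(bestVal) || criterionBetter(criterion, val, bestVal)) {
      bestVal <- val; bestTs <- ts
    }
  }
  new("TrainingSetSelection", criterion = criterion, size = size,
      memberIds = sort(bestTs), criterionValue = bestVal, vsIds = vsIds,
      lambdaRatio = lambdaRatio, seed = seed)
}

greedyForward <- function(A, candidates, vsIds, criterion, size,
                          lambdaRatio) {
  ts <- character(0)
  for (step in seq_len(size)) {
    pool <- setdiff(candidates, ts)
    vals <- vapply(pool, function(id)
      criterionValue(A, c(ts, id), vsIds, criterion, lambdaRatio),
      numeric(1))
    ord <- if (criterion == "PEVmean") order(vals, pool)
           else order(-vals, pool)
    ts <- c(ts, pool[ord[1]])
  }
  sort(ts)
}

swapImprove <- function(A, ts, candidates, vsIds, criterion, size,
                        lambdaRatio, maxSweeps = 20) {
  cur <- criterionValue(A, ts, vsIds, criterion, lambdaRatio)
  for (sweep in seq_len(maxSweeps)) {
    bestGainTs <- NULL; bestGainVal <- cur
    outPool <- setdiff(candidates, ts)
    for (drop in ts) {
      base <- setdiff(ts, drop)
      for (add in outPool) {
        val <- criterionValue(A, c(base, add), vsIds, criterion,
                              lambdaRatio)
        if (criterionBetter(criterion, val, bestGainVal)) {
          bestGainVal <- val
          bestGainTs <- sort(c(base, add))
        }
      }
    }
    if (is.null(bestGainTs)) break
    ts <- bestGainTs
    cur <- bestGainVal
  }
  ts
}

#' Random training sets of a fixed size
#'
#' Seeded uniform samples without replacement from the candidate pool,
#' each scored with the requested criterion — the baseline against which
#' optimized training sets are compared.
#'
#' @inheritParams optimizeTS
#' @param reps number of random sets (default 10).
#' @return list of \code{\linkS4class{TrainingSetSelection}} objects.
#' @export
randomBaseline <- function(A, candidateIds, vsIds, size,
                           criterion = c("PEVmean", "CDmean", "MeanRel"),
                           lambdaRatio = 1, reps = 10, seed = 1) {
  criterion <- match.arg(criterion)
  candidateIds <- sort(setdiff(candidateIds, vsIds))
  if (size > length(candidateIds))
    stop("size exceeds the number of candidates")
  lapply(seq_len(reps), function(r) {
    ts <- withSeed(deriveSeed(seed, paste0("tsrand:", r)),
                   sort(sample(candidateIds, size)))
    new("TrainingSetSelection", criterion = criterion, size = size,
        memberIds = ts,
        criterionValue = criterionValue(A, ts, vsIds, criterion,
                                        lambdaRatio),
        vsIds = vsIds, lambdaRatio = lambdaRatio, seed = seed)
  })
}
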