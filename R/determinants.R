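#' Assemble the explanatory table for predictive-ability regression
#'
#' One row per (trait, cross) with the within-cross individual PA as the
#' response and the scenario-specific predictor set: six predictors common
#' to all scenarios (proportion of non-segregating markers, overall H2,
#' per-cross H2, cross-variance ratio, parent additive relationship,
#' parent PCA distance on the first two axes), plus the mean TS-VS
#' additive relationship for scenarios 1b and 2, plus panel H2 and
#' subpopulation R2 for scenario 2.  Rows with any missing value are
#' dropped with a message.
#'
#' @param pa PA rows (mendelian per_cross granularity; one row per trait x
#'   cross, e.g. the best-method values).
#' @param crossStats data.frame per cross: cross, nonseg, parentRel,
#'   parentDistPC12, and for 1b/2 meanRelTsVs.
#' @param traitStats data.frame per trait: trait, h2Overall, crossRatio,
#'   and for scenario 2, h2Panel, subpopR2.
#' @param perCrossH2 data.frame: trait, cross, h2Cross.
#' @param scenario "1a", "1b" or "2".
#' @return data.frame ready for \code{\link{stepwiseAIC}}.
#' @export
assembleExplanatoryTable <- function(pa, crossStats, traitStats,
                                     perCrossH2, scenario = c("1a", "1b", "2")) {
  scenario <- match.arg(scenario)
  d <- pa[pa$component == "mendelian" & pa$granularity == "per_cross" &
          pa$cross != "all", c("trait", "cross", "pa")]
  d <- merge(d, perCrossH2, by = c("trait", "cross"))
  d <- merge(d, crossStats, by = "cross")
  d <- merge(d, traitStats, by = "trait")
  common <- c("nonseg", "h2Overall", "h2Cross", "crossRatio",
              "parentRel", "parentDistPC12")
  extra <- switch(scenario, "1a" = character(0),
                  "1b" = "meanRelTsVs",
                  "2" = c("meanRelTsVs", "h2Panel", "subpopR2"))
  cols <- c("trait", "cross", "pa", common, extra)
  miss <- setdiff(cols, names(d))
  if (length(miss)) stop("missing predictor columns: ",
                         paste(miss, collapse = ", "))
  d <- d[, cols]
  complete <- stats::complete.cases(d)
  if (any(!complete))
    message(sum(!complete), " incomplete row(s) dropped")
  d <- d[complete, ]
  if (nrow(d) < 15)
    stop("fewer than 15 complete rows; the regression would be unstable")
  rownames(d) <- NULL
  d
}

#' Forward-backward stepwise regression under AIC
#'
#' Standardizes the predictors to unit variance (so AIC moves are
#' scale-free), fits the full linear model of PA on all predictors, then
#' alternates single-variable drops and adds until no move lowers the AIC.
#' Perfectly collinear predictors are removed (later-listed first) before
#' the search.
#'
#' @param table output of \code{\link{assembleExplanatoryTable}} (or any
#'   data.frame whose first columns are trait, cross, pa followed by
#'   predictors).
#' @return list with \code{model} (the selected \code{lm}, standardized
#'   predictors), \code{selected} predictor names, \code{aic}, and
#'   \code{coefficientsRaw} on the original predictor scale.
#' @export
stepwiseAIC <- function(table) {
  predictors <- setdiff(names(table), c("trait", "cross", "pa"))
  Xraw <- as.matrix(table[, predictors, drop = FALSE])
  sds <- apply(Xraw, 2, sd)
  keep <- sds > 0
  X <- scale(Xraw[, keep, drop = FALSE])
  # remove exactly collinear columns, later-listed first
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- sort(setdiff(seq_len(ncol(X)) + 1, qrX$pivot[seq_len(qrX$rank)])) - 1
    message("collinear predictor(s) removed: ",
            paste(colnames(X)[bad], collapse = ", "))
    X <- X[, -bad, drop = FALSE]
  }
  df <- data.frame(pa = table$pa, X)
  full <- lm(pa ~ ., data = df)
  sel <- step(full, direction = "both", trace = 0)
  selected <- setdiff(names(coef(sel)), "(Intercept)")
  co <- coef(sel)[selected]
  raw <- co / apply(Xraw[, selected, drop = FALSE], 2, sd)
  list(model = sel, selected = selected, aic = AIC(sel),
       coefficientsStd = co, coefficientsRaw = raw)
}

# R^2 of pa on a subset of predictor columns of a standardized matrix.
subsetR2 <- function(y, X, idx) {
  if (!length(idx)) return(0)
  f <- lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

# All permutations of 1..p (p <= 10).
allOrderings <- function(p) {
  if (p == 1) return(matrix(1L, 1, 1))
  sub <- allOrderings(p - 1)
  out <- matrix(0L, p * nrow(sub), p)
  r <- 0
  for (k in seq_len(p)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- k
    out[rows, -1] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Decompose a regression R-squared into per-predictor shares
#'
#' \code{lmg}: the sequential R2 increment of each variable averaged
#' uniformly over all orderings of the predictors.  \code{pmvd}
#' (proportional marginal variance decomposition): the same increments
#' averaged with data-dependent ordering weights proportional to
#' \eqn{\prod_{i=1}^{p-1} (R^2_{full} - R^2(\text{first } i))^{-1}}, so
#' that a variable with a zero marginal contribution given all others
#' receives exactly zero share.  Both sets of shares sum to the model R2.
#' Orderings are enumerated exhaustively, so at most 10 predictors are
#' supported.
#'
#' @param table the explanatory table (or any data.frame with a \code{pa}
#'   column).
#' @param variables predictor names to decompose (e.g. the stepwise
#'   selection).
#' @param method "pmvd" or "lmg".
#' @return list with \code{shares} (named, summing to \code{r2}),
#'   \code{r2} and \code{method}.
#' @export
relativeImportance <- function(table, variables,
                               method = c("pmvd", "lmg")) {
  method <- match.arg(method)
  p <- length(variables)
  if (p > 10)
    stop("more than 10 predictors: exhaustive enumeration of orderings is ",
         "infeasible; reduce the model (ordering sampling is not implemented)")
  y <- table$pa
  X <- scale(as.matrix(table[, variables, drop = FALSE]))
  if (p == 0) return(list(shares = numeric(0), r2 = 0, method = method))
  # cache R^2 for every subset, indexed by bitmask
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1))
    r2[mask + 1] <- subsetR2(y, X, which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0))
  r2full <- r2[2^p]

  if (method == "pmvd") {
    # zero-marginal variables: increment given all others is (numerically)
    # zero; in the weighting limit all mass concentrates on orderings that
    # place them last, so they get share 0 and drop from the enumeration
    margin <- vapply(seq_len(p), function(j)
      r2full - r2[bitwAnd(2^p - 1, bitwNot(2^(j - 1))) + 1], numeric(1))
    zero <- margin < 1e-12
    shares <- setNames(numeric(p), variables)
    act <- which(!zero)
    if (length(act)) {
      pa <- length(act)
      orders <- allOrderings(pa)
      wts <- numeric(nrow(orders))
      incs <- matrix(0, nrow(orders), pa)
      fullAct <- sum(2^(act - 1))
      for (o in seq_len(nrow(orders))) {
        mask <- 0
        w <- 1
        for (i in seq_len(pa)) {
          pre <- r2[mask + 1]
          mask <- mask + 2^(act[orders[o, i]] - 1)
          incs[o, i] <- r2[mask + 1] - pre
          if (i < pa) {
            rem <- r2[fullAct + 1] - r2[mask + 1]
            w <- w / max(rem, 1e-300)
          }
        }
        wts[o] <- w
      }
      wts <- wts / sum(wts)
      for (i in seq_len(pa))
        for (o in seq_len(nrow(orders)))
          shares[act[orders[o, i]]] <- shares[act[orders[o, i]]] +
            wts[o] * incs[o, i]
      # the zero-marginal variables contribute r2full - r2(active) = ~0;
      # rescale the active shares to sum exactly to the full R^2
      shares[act] <- shares[act] * r2full / sum(shares[act])
    }
  } else {
    shares <- setNames(numeric(p), variables)
    # lmg via subset averaging: weight of subset S (excluding j) is
    # |S|! (p - |S| - 1)! / p!
    for (j in seq_len(p)) {
      bitj <- 2^(j - 1)
      for (mask in 0:(2^p - 1)) {
        if (bitwAnd(mask, bitj) > 0) next
        k <- sum(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
        w <- exp(lfactorial(k) + lfactorial(p - k - 1) - lfactorial(p))
        shares[j] <- shares[j] + w * (r2[mask + bitj + 1] - r2[mask + 1])
      }
    }
  }
  list(shares = shares, r2 = r2full, method = method)
}

#' Correlation of a candidate variable with predictive ability
#'
#' Single-variable screen: plain Pearson correlation between a variable
#' (e.g. the parents' additive relationship per cross) and PA values.
#'
#' @param variable,pa paired numeric vectors (>= 3 pairs).
#' @return Pearson correlation, NA when either vector is degenerate.
#' @export
correlatePAWith <- function(variable, pa) {
  if (length(variable) != length(pa)) stop("inputs must be paired")
  if (length(variable) < 3) stop("at least 3 pairs are required")
  safeCor(variable, pa)
}
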