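#' Choose a variance-stabilizing transformation from sample skewness
#'
#' Raw phenotypes with skewed distributions are transformed before model
#' fitting: identity when |skewness| <= 1, square root for moderate
#' right-skew (skewness in (1, 2], non-negative values), log otherwise
#' (with a shift when the minimum is non-positive).  Falls back to identity
#' with a warning when a transform is inapplicable.
#'
#' @param values numeric vector (>= 10 finite values).
#' @return list with \code{name} ("identity", "sqrt" or "log"),
#'   \code{transform} (the function, shift included), \code{skewness} and
#'   \code{shift}.
#' @export
selectTransformation <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 10) stop("at least 10 finite values are required")
  sk <- sampleSkewness(v)
  shift <- 0
  if (abs(sk) <= 1) {
    name <- "identity"; f <- identity
  } else if (sk > 1 && sk <= 2 && all(v >= 0)) {
    name <- "sqrt"; f <- sqrt
  } else if (sk > 2 || sk < -1) {
    if (sk < -1) {
      warning("left-skewed distribution; no transform applied")
      name <- "identity"; f <- identity
    } else {
      if (min(v) <= 0) shift <- -min(v) + 1e-6 * diff(range(v)) + 1e-12
      name <- "log"
      f <- local({ s <- shift; function(x) log(x + s) })
    }
  } else {
    warning("skewed but negative-valued distribution; no transform applied")
    name <- "identity"; f <- identity
  }
  list(name = name, transform = f, skewness = sk, shift = shift)
}

#' Broad-sense heritability on a genotype-entry-mean basis
#'
#' \deqn{H^2 = \frac{\sigma_C^2 + \sigma_G^2}{\sigma_C^2 + \sigma_G^2 +
#'   \frac{\sigma_{C:Y}^2 + \sigma_{G:Y}^2 + \sigma_{x:Y}^2 +
#'   \sigma_{y:Y}^2}{n_{year}} + \frac{\sigma_x^2 + \sigma_y^2 +
#'   \sigma_{x:y}^2 + \sigma_\epsilon^2}{n_{year} \, n_{rep.year}}}}
#' Year-interaction components are averaged over the mean number of years
#' per genotype; spatial and residual components over years times
#' replicates per year.  Dropped terms contribute zero.
#'
#' @param vc a \code{\linkS4class{VarianceComponents}} object.
#' @return heritability in [0, 1].
#' @export
heritabilityOverall <- function(vc) {
  comp <- function(nm) if (nm %in% names(vc@components))
    vc@components[[nm]] else 0
  num <- comp("C") + comp("G")
  if (num + comp("C:Y") + comp("G:Y") + comp("x:Y") + comp("y:Y") +
      comp("x") + comp("y") + comp("x:y") + comp("residual") == 0)
    stop("all variance components are zero")
  if (vc@nYear <= 0 || vc@nRepYear <= 0)
    stop("n_year and n_rep.year must be positive")
  yearTerm <- (comp("C:Y") + comp("G:Y") + comp("x:Y") + comp("y:Y")) /
    vc@nYear
  plotTerm <- (comp("x") + comp("y") + comp("x:y") + comp("residual")) /
    (vc@nYear * vc@nRepYear)
  num / (num + yearTerm + plotTerm)
}

#' Per-cross broad-sense heritability
#'
#' Refits the globally selected model within one cross, with every term
#' involving cross removed, and evaluates the same entry-mean formula on
#' the within-cross components.
#'
#' @param records phenotype records restricted to one cross (>= 2
#'   genotypes).
#' @param retained random terms retained by the global selection (cross
#'   terms are stripped automatically).
#' @param fixed fixed terms; levels constant within the cross are dropped
#'   automatically.
#' @param tol,maxIter fitter controls.
#' @return list with \code{h2} and \code{fit}.
#' @export
heritabilityPerCross <- function(records,
                                 retained = c("G", "G:Y", "x", "y", "x:y",
                                              "x:Y", "y:Y"),
                                 fixed = c("B", "Y", "B:Y"),
                                 tol = 1e-6, maxIter = 1000) {
  # driver context: keep capped estimates rather than aborting
  if (length(unique(records$genotype)) < 2)
    stop("at least 2 genotypes are required within the cross")
  random <- setdiff(retained, c("C", "C:Y"))
  fixed <- Filter(function(tm) {
    nlevels(termFactor(records, tm)) > 1
  }, fixed)
  random <- Filter(function(tm) {
    nlevels(termFactor(records, tm)) > 1
  }, random)
  fit <- fitMixedModel(records, fixed = fixed, random = random,
                       method = "REML", tol = tol, maxIter = maxIter,
                       onNonconvergence = "warn")
  list(h2 = heritabilityOverall(fit$vc), fit = fit)
}

#' Share of genetic variance between crosses
#'
#' The ratio \eqn{\sigma_C^2 / (\sigma_C^2 + \sigma_G^2)}.
#'
#' @param vc a \code{\linkS4class{VarianceComponents}}; a dropped C term
#'   counts as zero.
#' @return ratio in [0, 1].
#' @export
crossVarianceRatio <- function(vc) {
  sC <- if ("C" %in% names(vc@components)) vc@components[["C"]] else 0
  sG <- if ("G" %in% names(vc@components)) vc@components[["G"]] else 0
  if (sC + sG <= 0) stop("total genetic variance is zero")
  sC / (sC + sG)
}

#' Scale genotypic values to unit variance
#'
#' Divides total genotypic values (and their C and G parts, by the same
#' factor) by the sample standard deviation (denominator n - 1) of the
#' totals, so that traits are comparable; Pearson correlations are
#' unaffected.
#'
#' @param gv a \code{\linkS4class{GeneticValues}} object (>= 2 genotypes).
#' @return the scaled \code{GeneticValues}, with the factor recorded.
#' @export
scaleGeneticValues <- function(gv) {
  v <- geneticValueTable(gv)
  if (nrow(v) < 2) stop("at least 2 genotypes are required")
  s <- sd(v$total)
  if (s == 0) stop("totals have zero variance; cannot scale")
  v$C <- v$C / s; v$G <- v$G / s; v$total <- v$total / s
  new("GeneticValues", values = v, scaled = TRUE,
      scalingFactor = gv@scalingFactor * s)
}

#' Trait variance explained by subpopulation
#'
#' Coefficient of determination of the one-way fixed-effect model
#' \eqn{G = P + \epsilon} regressing genotypic values on the subpopulation
#' factor.
#'
#' @param values genotypic values (one per individual).
#' @param subpopulation matching labels (>= 2 subpopulations with >= 2
#'   members each).
#' @return R-squared in [0, 1].
#' @export
subpopulationR2 <- function(values, subpopulation) {
  f <- factor(subpopulation)
  if (nlevels(f) < 2) stop("at least 2 subpopulations are required")
  if (any(table(f) < 2)) stop("every subpopulation needs >= 2 members")
  summary(lm(values ~ f))$r.squared
}

#' Full per-trait phenotype analysis
#'
#' Convenience wrapper chaining transformation choice, random-term
#' selection (optional), the REML fit, heritability, cross-variance ratio
#' and unit-variance scaling of the genotypic BLUPs.
#'
#' @param records phenotype records for one trait.
#' @param selectTerms logical: run \code{\link{dropRandomTerms}} first.
#' @param random starting random terms.
#' @param fixed fixed terms.
#' @param alpha LRT threshold when selecting.
#' @param tol,maxIter fitter controls.
#' @return list with \code{fit}, \code{h2}, \code{crossRatio},
#'   \code{values} (scaled \code{\linkS4class{GeneticValues}}),
#'   \code{transformation}.
#' @export
analyzeTrait <- function(records, selectTerms = FALSE,
                         random = c("G", "C", "G:Y", "C:Y", "x", "y",
                                    "x:y", "x:Y", "y:Y"),
                         fixed = c("B", "Y", "B:Y"),
                         alpha = 0.05, tol = 1e-6, maxIter = 1000) {
  tr <- selectTransformation(records$value)
  records$value <- tr$transform(records$value)
  hasCross <- !all(is.na(records$cross))
  if (!hasCross) random <- setdiff(random, c("C", "C:Y"))
  if (selectTerms) {
    sel <- dropRandomTerms(records, fixed, random, alpha, tol, maxIter)
    fit <- sel$fit
  } else {
    fit <- fitMixedModel(records, fixed, random, "REML", tol, maxIter,
                         onNonconvergence = "warn")
  }
  h2 <- heritabilityOverall(fit$vc)
  ratio <- if (hasCross && "C" %in% fit$random)
    crossVarianceRatio(fit$vc) else NA_real_
  gv <- scaleGeneticValues(fit$geneticValues)
  list(fit = fit, h2 = h2, crossRatio = ratio, values = gv,
       transformation = tr)
}
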