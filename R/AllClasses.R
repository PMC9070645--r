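#' @import methods
#' @importFrom stats var sd cor coef lm predict rnorm runif rbinom rpois
#'   model.matrix setNames quantile AIC as.formula pchisq step lm.fit
#' @importFrom utils combn head
NULL

#' Allelic dosage matrix with marker map
#'
#' Individuals-by-markers matrix of alternate-allele dosages together with a
#' marker map.  Dosages are in \code{[0, 2]}: integers \code{{0, 1, 2}} for
#' observed individuals, fractional values for expected (parental-average)
#' genotypes.  \code{NA} entries are permitted only upstream of
#' \code{\link{filterMarkers}}; all model-facing operations require complete
#' matrices.
#'
#' @slot dosages numeric matrix, rownames = individual ids, colnames = marker
#'   ids.
#' @slot map data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos_bp}, \code{pos_cM}, one row per marker in column order, sorted
#'   by (chrom, pos_bp) with non-decreasing \code{pos_cM} within chromosome.
#'
#' @aliases DosageMatrix-class
#' @exportClass DosageMatrix
setClass("DosageMatrix",
  representation(dosages = "matrix", map = "data.frame"))

setValidity("DosageMatrix", function(object) {
  d <- object@dosages
  m <- object@map
  msg <- character(0)
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosages must have individual (row) and marker (column) names")
  else {
    if (anyDuplicated(rownames(d))) msg <- c(msg, "individual ids must be unique")
    if (anyDuplicated(colnames(d))) msg <- c(msg, "marker ids must be unique")
  }
  rng <- range(d, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    msg <- c(msg, "dosage values must lie in [0, 2]")
  need <- c("marker", "chrom", "pos_bp", "pos_cM")
  if (!all(need %in% names(m)))
    msg <- c(msg, "map must have columns marker, chrom, pos_bp, pos_cM")
  else {
    if (nrow(m) != ncol(d) || !identical(as.character(m$marker), colnames(d)))
      msg <- c(msg, "map rows must match dosage columns (same markers, same order)")
    ord <- order(as.character(m$chrom), m$pos_bp)
    if (!identical(ord, seq_len(nrow(m))))
      msg <- c(msg, "map must be sorted by (chrom, pos_bp)")
    if (any(tapply(m$pos_cM, as.character(m$chrom),
                   function(x) any(diff(x) < 0))))
      msg <- c(msg, "pos_cM must be non-decreasing within chromosome")
    if (any(m$pos_cM < 0)) msg <- c(msg, "pos_cM must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Phased biallelic genotypes
#'
#' Two haplotype matrices (0/1 alternate-allele indicators) per individual,
#' needed to simulate meiosis.  The implied dosage matrix is
#' \code{hapA + hapB}.
#'
#' @slot hapA,hapB 0/1 matrices, individuals x markers, identical dimnames.
#' @slot map marker map as in \code{\linkS4class{DosageMatrix}}.
#'
#' @aliases PhasedGenotypes-class
#' @exportClass PhasedGenotypes
setClass("PhasedGenotypes",
  representation(hapA = "matrix", hapB = "matrix", map = "data.frame"))

setValidity("PhasedGenotypes", function(object) {
  msg <- character(0)
  if (!identical(dimnames(object@hapA), dimnames(object@hapB)))
    msg <- c(msg, "hapA and hapB must have identical dimnames")
  if (!all(object@hapA %in% c(0, 1)) || !all(object@hapB %in% c(0, 1)))
    msg <- c(msg, "haplotype entries must be 0/1")
  if (nrow(object@map) != ncol(object@hapA))
    msg <- c(msg, "map rows must match haplotype columns")
  if (length(msg)) msg else TRUE
})

#' Realized additive (genomic) relationship matrix
#'
#' VanRaden-type relationship matrix \eqn{A = Z Z' / (2 \sum p(1-p))} with
#' \eqn{Z} the allele-frequency-centered dosages.
#'
#' @slot values symmetric numeric matrix with individual ids as dimnames.
#' @slot scalingConstant the denominator \eqn{2 \sum p (1-p)}.
#' @slot freqSource label recording which individuals defined the allele
#'   frequencies.
#' @slot nExcluded number of markers dropped because they were fixed
#'   (p in {0,1}) in the frequency-defining set.
#'
#' @aliases RelationshipMatrix-class
#' @exportClass RelationshipMatrix
setClass("RelationshipMatrix",
  representation(values = "matrix", scalingConstant = "numeric",
                 freqSource = "character", nExcluded = "numeric"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-10)
    msg <- c(msg, "relationship matrix must be symmetric (tol 1e-10)")
  if (any(diag(v) < 0))
    msg <- c(msg, "diagonal must be non-negative (zero only for ",
             "individuals without any allelic variation)")
  if (length(msg)) msg else TRUE
})

#' Principal-component projection of genotypes
#'
#' PCA axes computed from a reference panel (columns centered by panel means,
#' unscaled); other individuals are projected with the panel centering and
#' loadings.
#'
#' @slot centers per-marker panel means used for centering.
#' @slot loadings markers x axes matrix, orthonormal columns.
#' @slot scores individuals x axes score matrix (panel and projected
#'   individuals).
#' @slot explained share of panel variance per axis.
#' @slot panelIds ids of the individuals that defined the axes.
#'
#' @aliases PCAProjection-class
#' @exportClass PCAProjection
setClass("PCAProjection",
  representation(centers = "numeric", loadings = "matrix", scores = "matrix",
                 explained = "numeric", panelIds = "character"))

setValidity("PCAProjection", function(object) {
  G <- crossprod(object@loadings)
  if (max(abs(G - diag(ncol(G)))) > 1e-8)
    "loadings must be orthonormal (tol 1e-8)" else TRUE
})

#' Penalized marker-effects model
#'
#' Intercept plus per-marker additive effects on the standardized-marker
#' scale, with the shrinkage parameter and the training standardization
#' needed to reproduce predictions exactly.
#'
#' @slot method "RR" or "LASSO".
#' @slot intercept numeric scalar.
#' @slot effects named numeric vector, one effect per marker (standardized
#'   scale).
#' @slot lambda shrinkage parameter (> 0).
#' @slot centers,sds per-marker training mean and sd (population convention,
#'   denominator n); zero-sd markers carry sd 0 and effect 0.
#' @slot traitId,trainingIds provenance.
#' @slot nZero count of exactly-zero effects (sparsity; meaningful for LASSO).
#'
#' @aliases MarkerEffectsModel-class
#' @exportClass MarkerEffectsModel
setClass("MarkerEffectsModel",
  representation(method = "character", intercept = "numeric",
                 effects = "numeric", lambda = "numeric",
                 centers = "numeric", sds = "numeric",
                 traitId = "character", trainingIds = "character",
                 nZero = "numeric"))

setValidity("MarkerEffectsModel", function(object) {
  msg <- character(0)
  if (!object@method %in% c("RR", "LASSO"))
    msg <- c(msg, "method must be 'RR' or 'LASSO'")
  if (length(object@lambda) != 1 || object@lambda <= 0)
    msg <- c(msg, "lambda must be a positive scalar")
  if (length(object@effects) != length(object@centers) ||
      length(object@effects) != length(object@sds))
    msg <- c(msg, "effects, centers and sds must have equal length")
  if (length(msg)) msg else TRUE
})

#' REML/ML variance components
#'
#' Named variance-component estimates from the mixed model, plus the design
#' averages entering the entry-mean heritability formula.
#'
#' @slot components named numeric vector of variance estimates (includes
#'   "residual"); dropped terms are absent.
#' @slot retained names of the retained random terms.
#' @slot nYear mean number of years with data per genotype.
#' @slot nRepYear mean number of replicates per genotype-year.
#' @slot logLik final (restricted) log-likelihood.
#' @slot method "REML" or "ML".
#' @slot nIter iterations used; @slot converged logical.
#'
#' @aliases VarianceComponents-class
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(components = "numeric", retained = "character",
                 nYear = "numeric", nRepYear = "numeric",
                 logLik = "numeric", method = "character",
                 nIter = "numeric", converged = "logical"))

setValidity("VarianceComponents", function(object) {
  msg <- character(0)
  if (!"residual" %in% names(object@components))
    msg <- c(msg, "components must include 'residual'")
  else if (object@components[["residual"]] <= 0)
    msg <- c(msg, "residual variance must be positive")
  if (any(object@components < 0))
    msg <- c(msg, "variance components must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Genotypic BLUPs (cross, within-cross, total)
#'
#' Per-genotype cross BLUP (C), genotype-within-cross BLUP (G) and their sum
#' C + G, the total genotypic value used for genomic prediction; optionally
#' scaled to unit variance of the totals.
#'
#' @slot values data.frame with columns genotype, cross, C, G, total.
#' @slot scaled logical; @slot scalingFactor the divisor applied.
#'
#' @aliases GeneticValues-class
#' @exportClass GeneticValues
setClass("GeneticValues",
  representation(values = "data.frame", scaled = "logical",
                 scalingFactor = "numeric"))

setValidity("GeneticValues", function(object) {
  v <- object@values
  msg <- character(0)
  if (!all(c("genotype", "cross", "C", "G", "total") %in% names(v)))
    msg <- c(msg, "values needs columns genotype, cross, C, G, total")
  else if (isTRUE(object@scaled) && nrow(v) > 1 &&
           abs(var(v$total) - 1) > 1e-8)
    msg <- c(msg, "scaled totals must have sample variance 1 (tol 1e-8)")
  if (length(msg)) msg else TRUE
})

#' Trait architecture for the phenotype simulator
#'
#' @slot traitId label.
#' @slot qtlMarkerIds markers carrying effects; @slot qtlEffects additive
#'   effect per QTL (trait units per alternate-allele copy, pre-calibration).
#' @slot architectureClass "polygenic" (>= 100 QTLs) or "oligogenic"
#'   (<= 10 QTLs).
#' @slot targetH2 target broad-sense entry-mean heritability in (0, 1].
#' @slot crossDeviationSd sd of the non-additive cross-specific deviation, on
#'   the scale of the unit-variance additive values.
#' @slot crossMeanScale multiplier in [0, 1] applied to the additive
#'   between-cross component; values below 1 emulate the non-additive and
#'   scale effects that make the fitted cross variance smaller than its
#'   additive expectation in real data.
#' @slot yearInteractionSd,spatialSd,residualSd sds of the non-genetic terms.
#'
#' @aliases TraitArchitecture-class
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  representation(traitId = "character", qtlMarkerIds = "character",
                 qtlEffects = "numeric", architectureClass = "character",
                 targetH2 = "numeric", crossDeviationSd = "numeric",
                 crossMeanScale = "numeric",
                 yearInteractionSd = "numeric", spatialSd = "numeric",
                 residualSd = "numeric"),
  prototype(crossMeanScale = 1))

setValidity("TraitArchitecture", function(object) {
  msg <- character(0)
  k <- length(object@qtlMarkerIds)
  if (length(object@qtlEffects) != k)
    msg <- c(msg, "qtlEffects must match qtlMarkerIds in length")
  if (object@architectureClass == "oligogenic" && k > 10)
    msg <- c(msg, "oligogenic architectures have at most 10 QTLs")
  if (object@architectureClass == "polygenic" && k < 100)
    msg <- c(msg, "polygenic architectures have at least 100 QTLs")
  if (object@targetH2 <= 0 || object@targetH2 > 1)
    msg <- c(msg, "targetH2 must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Optimized training-set selection
#'
#' @slot criterion one of "PEVmean", "CDmean", "MeanRel", "random".
#' @slot size requested training-set size.
#' @slot memberIds selected candidate ids (subset of the pool, disjoint from
#'   the validation set).
#' @slot criterionValue achieved criterion value.
#' @slot vsIds validation-set ids.
#' @slot lambdaRatio residual-to-genetic variance ratio used by PEV/CD.
#' @slot seed integer seed that produced the selection.
#'
#' @aliases TrainingSetSelection-class
#' @exportClass TrainingSetSelection
setClass("TrainingSetSelection",
  representation(criterion = "character", size = "numeric",
                 memberIds = "character", criterionValue = "numeric",
                 vsIds = "character", lambdaRatio = "numeric",
                 seed = "numeric"))

setValidity("TrainingSetSelection", function(object) {
  msg <- character(0)
  if (length(object@memberIds) != object@size)
    msg <- c(msg, "memberIds must have exactly 'size' elements")
  if (length(intersect(object@memberIds, object@vsIds)))
    msg <- c(msg, "training set must be disjoint from the validation set")
  if (length(msg)) msg else TRUE
})
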