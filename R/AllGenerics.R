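#' Accessors for dosage containers
#'
#' @param x a \code{\linkS4class{DosageMatrix}} or
#'   \code{\linkS4class{PhasedGenotypes}} object.
#' @return \code{dosages} returns the numeric matrix (individuals x markers);
#'   \code{markerMap} the map data.frame; \code{individualIds} and
#'   \code{markerIds} character vectors.
#' @name dosage-accessors
#' @aliases dosages markerMap individualIds markerIds
NULL

#' @rdname dosage-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname dosage-accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
#' @rdname dosage-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname dosage-accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname dosage-accessors
setMethod("dosages", "DosageMatrix", function(x) x@dosages)
#' @rdname dosage-accessors
setMethod("markerMap", "DosageMatrix", function(x) x@map)
#' @rdname dosage-accessors
setMethod("individualIds", "DosageMatrix", function(x) rownames(x@dosages))
#' @rdname dosage-accessors
setMethod("markerIds", "DosageMatrix", function(x) colnames(x@dosages))

#' @rdname dosage-accessors
setMethod("dosages", "PhasedGenotypes", function(x) {
  d <- x@hapA + x@hapB
  d
})
#' @rdname dosage-accessors
setMethod("markerMap", "PhasedGenotypes", function(x) x@map)
#' @rdname dosage-accessors
setMethod("individualIds", "PhasedGenotypes", function(x) rownames(x@hapA))
#' @rdname dosage-accessors
setMethod("markerIds", "PhasedGenotypes", function(x) colnames(x@hapA))

#' @describeIn DosageMatrix-class number of individuals and markers
#' @param object,x a \code{DosageMatrix}
#' @export
setMethod("dim", "DosageMatrix", function(x) dim(x@dosages))

#' @describeIn DosageMatrix-class subset by individuals (i) and markers (j);
#'   the map follows the marker subset
#' @param i,j,...,drop row (individual) and column (marker) indices; `drop`
#'   is ignored (always returns a DosageMatrix)
#' @export
setMethod("[", "DosageMatrix", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosages
  m <- x@map
  if (!missing(i)) d <- d[i, , drop = FALSE]
  if (!missing(j)) {
    d <- d[, j, drop = FALSE]
    m <- m[match(colnames(d), as.character(m$marker)), , drop = FALSE]
    rownames(m) <- NULL
  }
  new("DosageMatrix", dosages = d, map = m)
})

setMethod("show", "DosageMatrix", function(object) {
  d <- object@dosages
  cat("DosageMatrix:", nrow(d), "individuals x", ncol(d), "markers,",
      length(unique(object@map$chrom)), "chromosome(s)\n")
  if (anyNA(d)) cat("  contains missing calls (pre-filter matrix)\n")
})

setMethod("show", "PhasedGenotypes", function(object) {
  cat("PhasedGenotypes:", nrow(object@hapA), "individuals x",
      ncol(object@hapA), "markers (2 haplotypes each)\n")
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix:", nrow(object@values), "individuals",
      sprintf("(freq source: %s; 2*sum(p(1-p)) = %.3f; %d fixed markers excluded)\n",
              object@freqSource, object@scalingConstant, object@nExcluded))
})

setMethod("show", "PCAProjection", function(object) {
  cat("PCAProjection:", ncol(object@loadings), "axes from",
      length(object@panelIds), "panel individuals;",
      nrow(object@scores), "individuals scored\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * object@explained), collapse = ", "), "\n")
})

setMethod("show", "MarkerEffectsModel", function(object) {
  cat(sprintf("MarkerEffectsModel [%s] trait=%s: %d markers, lambda=%.4g, %d zero effects\n",
              object@method, object@traitId, length(object@effects),
              object@lambda, object@nZero))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents (%s, %s after %d iterations)\n",
              object@method,
              if (object@converged) "converged" else "NOT converged",
              object@nIter))
  print(round(object@components, 5))
  cat(sprintf("  n_year = %.2f, n_rep.year = %.2f, logLik = %.3f\n",
              object@nYear, object@nRepYear, object@logLik))
})

setMethod("show", "GeneticValues", function(object) {
  cat("GeneticValues:", nrow(object@values), "genotypes",
      if (isTRUE(object@scaled))
        sprintf("(scaled, factor %.4g)", object@scalingFactor)
      else "(unscaled)", "\n")
})

setMethod("show", "TrainingSetSelection", function(object) {
  cat(sprintf("TrainingSetSelection [%s] size=%d, criterion value %.4f (VS: %d ids)\n",
              object@criterion, as.integer(object@size),
              object@criterionValue, length(object@vsIds)))
})

setMethod("show", "TraitArchitecture", function(object) {
  cat(sprintf("TraitArchitecture '%s' (%s): %d QTLs, target H2 = %.2f\n",
              object@traitId, object@architectureClass,
              length(object@qtlMarkerIds), object@targetH2))
})

#' Extract the BLUP table from a GeneticValues object
#'
#' @param gv a \code{\linkS4class{GeneticValues}} object.
#' @return data.frame with columns genotype, cross, C, G, total.
#' @export
geneticValueTable <- function(gv) {
  stopifnot(is(gv, "GeneticValues"))
  gv@values
}

#' Extract the relationship values matrix
#'
#' @param A a \code{\linkS4class{RelationshipMatrix}}.
#' @return the symmetric numeric matrix of realized relationships.
#' @export
relValues <- function(A) {
  stopifnot(is(A, "RelationshipMatrix"))
  A@values
}

#' Extract PCA scores
#'
#' @param proj a \code{\linkS4class{PCAProjection}}.
#' @return individuals x axes score matrix.
#' @export
pcaScores <- function(proj) {
  stopifnot(is(proj, "PCAProjection"))
  proj@scores
}
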