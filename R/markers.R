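#' Filter markers on minor-allele frequency and missingness
#'
#' Retains markers whose minor-allele frequency among non-missing calls is
#' at least \code{mafMin} and whose missingness is at most
#' \code{maxMissing}; marker order is preserved.
#'
#' @param d a \code{\linkS4class{DosageMatrix}} (may contain \code{NA}
#'   calls).
#' @param mafMin minimum minor-allele frequency (default 0.05).
#' @param maxMissing maximum fraction of missing calls per marker (default
#'   0.8).
#' @return the filtered \code{DosageMatrix}.
#' @export
filterMarkers <- function(d, mafMin = 0.05, maxMissing = 0.8) {
  x <- dosages(d)
  miss <- colMeans(is.na(x))
  p <- colMeans(x, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keepMaf <- maf >= mafMin
  keepMiss <- miss <= maxMissing
  keep <- keepMaf & keepMiss
  if (!any(keep)) {
    stricter <- if (sum(keepMaf) <= sum(keepMiss)) "minor-allele frequency"
                else "missingness"
    stop("all markers removed; the ", stricter, " filter is the stricter one")
  }
  d[, which(keep)]
}

#' Restrict two dosage matrices to their common markers
#'
#' Both outputs contain exactly the shared marker ids, in the same (map)
#' order, mirroring the intersection of panel and progeny marker sets.
#'
#' @param a,b \code{\linkS4class{DosageMatrix}} objects.
#' @return list with elements \code{a} and \code{b}.
#' @export
intersectMarkers <- function(a, b) {
  common <- intersect(markerIds(a), markerIds(b))
  if (!length(common)) stop("no markers in common between the two matrices")
  ka <- which(markerIds(a) %in% common)
  list(a = a[, ka], b = b[, match(markerIds(a)[ka], markerIds(b))])
}

#' Expected offspring (parental-average) genotype
#'
#' Per-locus expected dosage of an offspring of two observed parents under
#' Mendelian segregation: the probability-weighted mean over offspring
#' genotype classes, which reduces to \code{(d1 + d2) / 2}.
#'
#' @param d1,d2 parent dosage vectors with values in {0, 1, 2}.
#' @return fractional dosage vector in [0, 2].
#' @export
parentalAverageGenotype <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("parent vectors must have equal length")
  if (!all(d1 %in% c(0, 1, 2)) || !all(d2 %in% c(0, 1, 2)))
    stop("parents must be observed genotypes with integer dosages {0, 1, 2}")
  (d1 + d2) / 2
}

#' Proportion of non-segregating markers in a cross
#'
#' A marker is non-segregating when the offspring dosage variance is zero,
#' i.e. both parents are homozygous (dosage 0 or 2) — whether for the same
#' allele (all offspring 0 or 2) or opposite alleles (all offspring 1).
#'
#' @param d1,d2 parent dosage vectors in {0, 1, 2}.
#' @return proportion in [0, 1].
#' @export
nonsegregatingProportion <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("parent vectors must have equal length")
  if (!all(d1 %in% c(0, 1, 2)) || !all(d2 %in% c(0, 1, 2)))
    stop("parents must be observed genotypes with integer dosages {0, 1, 2}")
  mean(d1 %in% c(0, 2) & d2 %in% c(0, 2))
}

#' VanRaden realized additive relationship matrix
#'
#' \eqn{A = Z Z' / (2 \sum_m p_m (1 - p_m))} with \eqn{Z} the dosages
#' centered by twice the allele frequencies.  Frequencies come either from
#' the individuals in the matrix itself (\code{freqIndividuals = "self"}) or
#' from a named subset (e.g. the panel, when relating panel and progenies).
#' Markers fixed in the frequency-defining set (p of 0 or 1) contribute
#' nothing to the denominator and are excluded, with the count recorded.
#'
#' @param d a complete \code{\linkS4class{DosageMatrix}}.
#' @param freqIndividuals "self" or a character vector of individual ids
#'   defining the allele frequencies.
#' @return a \code{\linkS4class{RelationshipMatrix}}.
#' @export
vanRadenA <- function(d, freqIndividuals = "self") {
  x <- dosages(d)
  if (anyNA(x)) stop("dosages must be complete (impute or filter first)")
  if (identical(freqIndividuals, "self")) {
    ref <- x
    src <- "self"
  } else {
    if (!all(freqIndividuals %in% rownames(x)))
      stop("freqIndividuals not all present in the matrix")
    ref <- x[freqIndividuals, , drop = FALSE]
    src <- sprintf("subset(%d ids)", length(freqIndividuals))
  }
  p <- colMeans(ref) / 2
  keep <- p > 0 & p < 1
  nExcluded <- sum(!keep)
  if (!any(keep))
    stop("all markers are fixed in the frequency-defining individuals")
  Z <- sweep(x[, keep, drop = FALSE], 2, 2 * p[keep])
  denom <- 2 * sum(p[keep] * (1 - p[keep]))
  A <- tcrossprod(Z) / denom
  A <- (A + t(A)) / 2
  new("RelationshipMatrix", values = A, scalingConstant = denom,
      freqSource = src, nExcluded = nExcluded)
}

#' Mean additive relationship between two sets
#'
#' Mean of the relationship matrix over all (i in set1, j in set2) pairs;
#' when the two sets coincide, diagonal entries are excluded.
#'
#' @param A a \code{\linkS4class{RelationshipMatrix}}.
#' @param set1,set2 non-empty id vectors within A.
#' @return numeric scalar.
#' @export
meanRelationship <- function(A, set1, set2) {
  v <- relValues(A)
  if (!length(set1) || !length(set2)) stop("both sets must be non-empty")
  if (!all(c(set1, set2) %in% rownames(v)))
    stop("ids missing from the relationship matrix")
  same <- setequal(set1, set2)
  if (!same && length(intersect(set1, set2)))
    stop("overlapping ids are allowed only when the two sets coincide")
  sub <- v[set1, set2, drop = FALSE]
  if (same) {
    offdiag <- outer(set1, set2, FUN = "!=")
    mean(sub[offdiag])
  } else mean(sub)
}

#' PCA of a panel with projection of other individuals
#'
#' Principal axes are computed from the panel only (markers centered by the
#' panel means, not scaled); parents and progenies are projected using the
#' panel centering and loadings, reproducing the standard diversity-panel
#' PCA on which bi-parental families are overlaid.
#'
#' @param panel \code{\linkS4class{DosageMatrix}} defining the axes.
#' @param others optional \code{DosageMatrix} (same markers, same order) to
#'   project; fractional dosages (parental averages) are accepted.
#' @param nAxes number of leading axes (truncated to the rank with a
#'   warning if too large).
#' @return a \code{\linkS4class{PCAProjection}}; scores contain the panel
#'   rows followed by the projected rows.
#' @export
pcaProject <- function(panel, others = NULL, nAxes = 2) {
  X <- dosages(panel)
  if (!is.null(others) &&
      !identical(markerIds(panel), markerIds(others)))
    stop("marker sets must be identical and aligned")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (nAxes > rank) {
    warning(sprintf("nAxes truncated from %d to rank %d", nAxes, rank))
    nAxes <- rank
  }
  loadings <- sv$v[, seq_len(nAxes), drop = FALSE]
  rownames(loadings) <- colnames(X)
  scoresPanel <- Xc %*% loadings
  explained <- (sv$d^2 / sum(sv$d^2))[seq_len(nAxes)]
  scores <- scoresPanel
  if (!is.null(others)) {
    Yc <- sweep(dosages(others), 2, ctr)
    scores <- rbind(scoresPanel, Yc %*% loadings)
  }
  colnames(scores) <- paste0("PC", seq_len(nAxes))
  new("PCAProjection", centers = ctr, loadings = loadings, scores = scores,
      explained = explained, panelIds = rownames(X))
}

#' Distance between two parents on the leading PCA axes
#'
#' Absolute score difference on axis 1, or Euclidean distance on the first
#' two axes.
#'
#' @param proj a \code{\linkS4class{PCAProjection}} with both parents
#'   scored.
#' @param parent1,parent2 individual ids.
#' @param axes \code{1} or \code{1:2}.
#' @return non-negative distance.
#' @export
parentAxisDistance <- function(proj, parent1, parent2, axes = 1:2) {
  s <- pcaScores(proj)
  if (!all(c(parent1, parent2) %in% rownames(s)))
    stop("both parents must be present in the projection")
  if (!identical(as.integer(axes), 1L) && !identical(as.integer(axes), 1:2))
    stop("axes must be 1 or 1:2")
  dif <- s[parent1, axes] - s[parent2, axes]
  sqrt(sum(dif^2))
}
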