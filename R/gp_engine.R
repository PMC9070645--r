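#' @useDynLib diallelGP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Standardize marker columns with training statistics
#'
#' Centers every marker to mean 0 and scales to sd 1, using the population
#' sd convention (denominator n) so that \eqn{x_j' x_j / n = 1} exactly.
#' Monomorphic (zero-sd) markers are set to all-zero and flagged; they
#' carry no information and receive zero effects.
#'
#' @param X dosage matrix (individuals x markers) or
#'   \code{\linkS4class{DosageMatrix}}.
#' @param centers,sds optional pre-computed training statistics, to apply a
#'   training standardization to validation data.
#' @return list with \code{X} (standardized matrix), \code{centers},
#'   \code{sds}, \code{zeroSd} (logical flags).
#' @export
standardizeDosages <- function(X, centers = NULL, sds = NULL) {
  if (is(X, "DosageMatrix")) X <- dosages(X)
  if (is.null(centers)) {
    centers <- colMeans(X)
    sds <- sqrt(colMeans(X^2) - centers^2)
  }
  zero <- sds <= 0
  s <- ifelse(zero, 1, sds)
  Xs <- sweep(sweep(X, 2, centers), 2, s, "/")
  if (any(zero)) Xs[, zero] <- 0
  list(X = Xs, centers = centers, sds = ifelse(zero, 0, sds),
       zeroSd = zero)
}

#' Fit a penalized marker-effect model at a fixed shrinkage
#'
#' Minimizes \eqn{(1/2n) \|y - \beta_0 - X\beta\|^2 + \lambda P(\beta)}
#' with \eqn{P = \tfrac12\|\beta\|^2} (ridge, "RR") or
#' \eqn{P = \|\beta\|_1} (LASSO) by cyclic coordinate descent with
#' covariance updates; the intercept is unpenalized.  Markers are expected
#' on the standardized scale from \code{\link{standardizeDosages}}.
#'
#' @param Xs standardized marker matrix.
#' @param y response vector (typically scaled total genotypic values).
#' @param method "RR" or "LASSO".
#' @param lambda positive shrinkage parameter.
#' @param std the standardization list (recorded in the model so
#'   predictions are exactly reproducible).
#' @param traitId,trainingIds provenance labels.
#' @param tol,maxIter coordinate-descent controls (convergence when the
#'   largest coefficient change is below \code{tol}).
#' @param onNonconvergence "error" (default) or "warn"; warning keeps the
#'   capped-sweep solution, which high-level drivers use for very slow
#'   ridge paths at the smallest grid values.
#' @return a \code{\linkS4class{MarkerEffectsModel}}; attribute
#'   \code{"objective"} carries the per-sweep objective values.
#' @export
fitPenalized <- function(Xs, y, method = c("RR", "LASSO"), lambda,
                         std = NULL, traitId = "trait",
                         trainingIds = rownames(Xs),
                         tol = 1e-7, maxIter = 10000,
                         onNonconvergence = c("error", "warn")) {
  method <- match.arg(method)
  onNonconvergence <- match.arg(onNonconvergence)
  if (length(lambda) != 1 || !is.finite(lambda) || lambda <= 0)
    stop("lambda must be a positive scalar")
  n <- nrow(Xs)
  if (n != length(y)) stop("rows of X must match length of y")
  if (n < 10) stop("at least 10 training individuals are required")
  ybar <- mean(y)
  XtX <- crossprod(Xs) / n
  Xty <- as.numeric(crossprod(Xs, y - ybar)) / n
  yc <- y - ybar
  res <- .cd_path(XtX, Xty, lambda, method == "LASSO", tol, maxIter,
                  sum(yc^2) / n)
  if (!res$converged[1]) {
    msg <- paste0("coordinate descent did not converge in ", maxIter,
                  " sweeps (last max change above ", tol, "); lambda = ",
                  lambda)
    if (onNonconvergence == "error") stop(msg) else warning(msg)
  }
  beta <- as.numeric(res$beta[, 1])
  names(beta) <- colnames(Xs)
  if (is.null(std))
    std <- list(centers = setNames(rep(0, ncol(Xs)), colnames(Xs)),
                sds = setNames(rep(1, ncol(Xs)), colnames(Xs)))
  m <- new("MarkerEffectsModel", method = method, intercept = ybar,
           effects = beta, lambda = lambda,
           centers = as.numeric(std$centers), sds = as.numeric(std$sds),
           traitId = traitId,
           trainingIds = as.character(trainingIds %||% character(0)),
           nZero = sum(beta == 0))
  attr(m, "objective") <- res$objective
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decreasing log-spaced lambda grid anchored at lambda_max =
# max_j |x_j'(y - ybar)| / n.
lambdaGrid <- function(Xs, y, gridSize = 100, ratio = 1e-4) {
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / nrow(Xs)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * ratio), length.out = gridSize))
}

#' Calibrate the shrinkage parameter by inner cross-validation
#'
#' k-fold cross-validation over a decreasing log-spaced grid from
#' \eqn{\lambda_{max}} (the smallest value nulling the LASSO) down to
#' \eqn{\lambda_{max} \times 10^{-4}}; folds are assigned by a seeded
#' random permutation; the \eqn{\lambda} minimizing the mean squared
#' prediction error is returned, ties resolved toward the larger value.
#'
#' @param Xs standardized marker matrix.
#' @param y response.
#' @param method "RR" or "LASSO".
#' @param k folds (default 5); requires n >= 2k.
#' @param gridSize grid resolution (default 100).
#' @param seed integer seed for the fold permutation.
#' @param tol,maxIter coordinate-descent controls for the fold path fits.
#'   These are looser than the final-fit defaults: the path fits only
#'   score prediction error, which is insensitive at this tolerance, and
#'   ridge paths on p > n designs converge very slowly at the smallest
#'   grid values, so sweeps are capped rather than raising an error.
#' @return list with \code{lambda}, \code{grid}, \code{cvError} (mean MSE
#'   per grid point) and \code{folds}.
#' @export
calibrateLambda <- function(Xs, y, method = c("RR", "LASSO"), k = 5,
                            gridSize = 100, seed = 1,
                            tol = 1e-4, maxIter = 50) {
  method <- match.arg(method)
  n <- nrow(Xs)
  if (n < 2 * k) stop("need at least 2k training individuals")
  grid <- lambdaGrid(Xs, y, gridSize)
  folds <- withSeed(seed, sample(rep(seq_len(k), length.out = n)))
  errs <- matrix(NA_real_, k, gridSize)
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- Xs[tr, , drop = FALSE]
    ytr <- y[tr]
    ybar <- mean(ytr)
    XtX <- crossprod(Xtr) / sum(tr)
    Xty <- as.numeric(crossprod(Xtr, ytr - ybar)) / sum(tr)
    res <- .cd_path(XtX, Xty, grid, method == "LASSO", tol, maxIter, 0)
    pred <- Xs[!tr, , drop = FALSE] %*% res$beta + ybar
    errs[f, ] <- colMeans((pred - y[!tr])^2)
  }
  cvm <- colMeans(errs)
  best <- which.min(cvm)   # grid is decreasing: first minimum = largest lambda
  list(lambda = grid[best], grid = grid, cvError = cvm, folds = folds)
}

#' Train a marker-effect model with inner-CV shrinkage calibration
#'
#' Standardizes the training dosages, calibrates \eqn{\lambda} by k-fold
#' inner cross-validation and fits the final model on the full training
#' set.
#'
#' @param genotypes training \code{\linkS4class{DosageMatrix}} or matrix.
#' @param y named response vector (names matched against individual ids
#'   when present).
#' @param method "RR" or "LASSO".
#' @param k,gridSize,seed calibration controls.
#' @param traitId provenance label.
#' @return a \code{\linkS4class{MarkerEffectsModel}}.
#' @export
trainMarkerModel <- function(genotypes, y, method = c("RR", "LASSO"),
                             k = 5, gridSize = 100, seed = 1,
                             traitId = "trait") {
  method <- match.arg(method)
  X <- if (is(genotypes, "DosageMatrix")) dosages(genotypes) else genotypes
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    common <- intersect(rownames(X), names(y))
    X <- X[common, , drop = FALSE]
    y <- y[common]
  }
  std <- standardizeDosages(X)
  cal <- calibrateLambda(std$X, y, method, k, gridSize, seed)
  m <- fitPenalized(std$X, y, method, cal$lambda, std, traitId,
                    rownames(X), tol = 1e-5, maxIter = 2000,
                    onNonconvergence = "warn")
  attr(m, "cv") <- cal[c("lambda", "grid", "cvError")]
  m
}

#' Predict genotypic values from a marker-effect model
#'
#' Applies the training standardization to the new dosages (fractional
#' dosages such as parental averages are accepted) and evaluates
#' \eqn{\beta_0 + X\beta}.  The map is affine in the dosages, so the
#' prediction at a parental-average genotype equals the
#' segregation-weighted mean of the predictions over offspring classes.
#'
#' @param object a \code{\linkS4class{MarkerEffectsModel}}.
#' @param newdata \code{\linkS4class{DosageMatrix}} or matrix whose columns
#'   cover the model's markers.
#' @return named numeric vector of predictions.
#' @export
setMethod("predict", "MarkerEffectsModel", function(object, newdata) {
  X <- if (is(newdata, "DosageMatrix")) dosages(newdata) else newdata
  need <- names(object@effects)
  missing <- setdiff(need, colnames(X))
  if (length(missing))
    stop("markers missing from newdata: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10))
  X <- X[, need, drop = FALSE]
  std <- standardizeDosages(X, setNames(object@centers, need),
                            setNames(object@sds, need))
  drop(std$X %*% object@effects) + object@intercept
})
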