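#' Fit a linear mixed model by EM on Henderson's equations
#'
#' Estimates variance components and BLUPs for the field model
#' \deqn{y = \mu + B + Y + B{:}Y + G + C + G{:}Y + C{:}Y + x + y + x{:}y +
#'   x{:}Y + y{:}Y + \epsilon}
#' with fixed block/year terms and i.i.d. random grouping factors (no
#' genomic covariance).  Variance components are estimated by EM iterations
#' on Henderson's mixed-model equations, in an ML or REML flavor, with an
#' Aitken-style acceleration step that is only accepted when it does not
#' decrease the (restricted) log-likelihood, so the likelihood is
#' non-decreasing across iterations.  Components are floored at
#' \code{1e-10 * var(y)}.
#'
#' Term labels use the field-model shorthand: \code{G} genotype, \code{C}
#' cross, \code{B} block, \code{Y} year, \code{x}/\code{y} row and column
#' (categorical), interactions with \code{:}.
#'
#' @param records data.frame with columns genotype, cross, block, year, x,
#'   y, value (a single trait).
#' @param fixed fixed-effect terms (besides the intercept); default
#'   \code{c("B", "Y", "B:Y")}.  Factors are coded sum-to-zero.
#' @param random random terms; default the full field model.  Terms absent
#'   from the data (e.g. \code{C} for a panel) must not be listed.
#' @param method "REML" (default) or "ML".
#' @param tol convergence tolerance on the maximum relative change of the
#'   variance components.
#' @param maxIter maximum EM iterations (default 1000).
#' @param onNonconvergence "error" (default) or "warn".  With "warn" the
#'   iteration-capped estimates are returned: near a variance boundary the
#'   likelihood can keep improving below any practical tolerance for
#'   thousands of iterations while every component is stable to several
#'   digits, and high-level drivers prefer the capped fit to an abort.
#' @return list with \code{vc} (\code{\linkS4class{VarianceComponents}}),
#'   \code{geneticValues} (\code{\linkS4class{GeneticValues}}, when a
#'   \code{G} term is present), \code{blups} (named list of per-term BLUP
#'   vectors), \code{logLik}, \code{logLikTrace}, \code{fixedEffects}.
#' @export
fitMixedModel <- function(records,
                          fixed = c("B", "Y", "B:Y"),
                          random = c("G", "C", "G:Y", "C:Y", "x", "y",
                                     "x:y", "x:Y", "y:Y"),
                          method = c("REML", "ML"),
                          tol = 1e-6, maxIter = 1000,
                          onNonconvergence = c("error", "warn")) {
  method <- match.arg(method)
  onNonconvergence <- match.arg(onNonconvergence)
  yv <- records$value
  if (anyNA(yv) || !all(is.finite(yv))) stop("phenotype values must be finite")
  n <- length(yv)

  X <- fixedDesign(records, fixed)
  if (qr(X)$rank < ncol(X)) {
    qrx <- qr(X)
    aliased <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("singular fixed design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  Zs <- lapply(random, function(tm) randomDesign(records, tm))
  names(Zs) <- random
  q <- vapply(Zs, ncol, integer(1))

  fit <- emVarComp(yv, X, Zs, method, tol, maxIter)
  if (!fit$converged) {
    msg <- paste0("EM did not converge in ", maxIter, " iterations; ",
                  "final components: ",
                  paste(sprintf("%s=%.4g", c(random, "residual"),
                                c(fit$sigma2, fit$sigma2e)),
                        collapse = ", "))
    if (onNonconvergence == "error") stop(msg)
    warning(msg)
  }

  comps <- c(setNames(fit$sigma2, random), residual = fit$sigma2e)
  ny <- meanYearsPerGenotype(records)
  nry <- meanRepsPerGenotypeYear(records)
  vc <- new("VarianceComponents", components = comps, retained = random,
            nYear = ny, nRepYear = nry, logLik = fit$logLik,
            method = method, nIter = fit$nIter, converged = fit$converged)
  gv <- NULL
  if ("G" %in% random) {
    gmap <- unique(records[, c("genotype", "cross")])
    gB <- fit$blups[["G"]][gmap$genotype]
    cB <- if ("C" %in% random) fit$blups[["C"]][as.character(gmap$cross)] else
      rep(0, nrow(gmap))
    cB[is.na(cB)] <- 0
    gv <- new("GeneticValues",
              values = data.frame(genotype = gmap$genotype,
                                  cross = as.character(gmap$cross),
                                  C = as.numeric(cB), G = as.numeric(gB),
                                  total = as.numeric(cB + gB),
                                  stringsAsFactors = FALSE),
              scaled = FALSE, scalingFactor = 1)
  }
  list(vc = vc, geneticValues = gv, blups = fit$blups, logLik = fit$logLik,
       logLikTrace = fit$trace, fixedEffects = fit$beta,
       fixed = fixed, random = random, method = method)
}

# Sum-to-zero-coded fixed design with intercept; interaction terms are
# coded through the formula so they stay orthogonal to the main effects.
fixedDesign <- function(records, fixed) {
  if (!length(fixed)) return(matrix(1, nrow(records), 1,
                                    dimnames = list(NULL, "(Intercept)")))
  colmap <- c(G = "genotype", C = "cross", B = "block", Y = "year",
              x = "x", y = "y")
  comps <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  df <- as.data.frame(lapply(comps, function(p)
    factor(records[[colmap[[p]]]])))
  names(df) <- comps
  # single-level factors (e.g. one year) cannot enter the design
  ok <- vapply(df, nlevels, integer(1)) > 1
  fixed <- Filter(function(tm)
    all(strsplit(tm, ":", fixed = TRUE)[[1]] %in% names(df)[ok]), fixed)
  if (!length(fixed)) return(matrix(1, nrow(records), 1,
                                    dimnames = list(NULL, "(Intercept)")))
  fml <- as.formula(paste("~", paste(fixed, collapse = " + ")))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  model.matrix(fml, df)
}

randomDesign <- function(records, term) {
  f <- termFactor(records, term)
  Z <- Matrix::sparse.model.matrix(~ 0 + f)
  colnames(Z) <- levels(f)
  Z
}

# A factor for a (possibly interaction) term over record columns.
termFactor <- function(records, term) {
  colmap <- c(G = "genotype", C = "cross", B = "block", Y = "year",
              x = "x", y = "y")
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  unknown <- setdiff(parts, names(colmap))
  if (length(unknown)) stop("unknown model term component: ",
                            paste(unknown, collapse = ", "))
  vals <- lapply(parts, function(p) {
    v <- records[[colmap[[p]]]]
    if (anyNA(v)) stop("term ", term, " has missing values in the records")
    as.character(v)
  })
  factor(do.call(paste, c(vals, sep = ":")))
}

# EM variance-component engine on Henderson's MME.  For REML the trace
# terms come from the inverse of the full coefficient matrix; for ML the
# fixed effects are profiled out as parameters (Hartley-Rao style) and the
# traces come from the random-only system.
emVarComp <- function(yv, X, Zs, method, tol, maxIter) {
  n <- length(yv)
  p <- ncol(X)
  K <- length(Zs)
  q <- vapply(Zs, ncol, integer(1))
  Z <- do.call(cbind, unname(Zs))
  W <- cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  WtW <- as.matrix(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, yv))
  yty <- sum(yv^2)
  vy <- var(yv)
  floorv <- 1e-10 * vy
  uIdx <- split(p + seq_len(sum(q)), rep(seq_len(K), q))

  s2 <- rep(vy / (K + 1), K)
  s2e <- vy / 2
  evalStep <- function(s2, s2e) {
    lam <- s2e / s2
    Cmat <- WtW
    for (k in seq_len(K)) {
      ii <- uIdx[[k]]
      diag(Cmat)[ii] <- diag(WtW)[ii] + lam[k]
    }
    ch <- tryCatch(chol(Cmat), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Cinv <- chol2inv(ch)
    sol <- Cinv %*% Wty
    quadres <- yty - sum(sol * Wty)          # y'y - b'X'y - u'Z'y
    logdetC <- 2 * sum(log(diag(ch)))
    if (method == "REML") {
      ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2e) +
                    logdetC - sum(q * log(lam)) + quadres / s2e)
      list(sol = sol, trDiag = diag(Cinv)[-seq_len(p)],
           quadres = quadres, ll = ll)
    } else {
      # ML: likelihood at the current (b, u) solve; the E-step conditions
      # on b, so the traces come from the random-only system Z'Z + Lambda
      b <- sol[seq_len(p)]
      r <- yv - as.numeric(X %*% b)
      Zu <- as.numeric(Z %*% sol[-seq_len(p)])
      ZtZ <- WtW[-seq_len(p), -seq_len(p), drop = FALSE]
      Dl <- ZtZ
      for (k in seq_len(K)) {
        ii <- uIdx[[k]] - p
        diag(Dl)[ii] <- diag(ZtZ)[ii] + lam[k]
      }
      chD <- chol(Dl)
      diagD <- diag(chol2inv(chD))
      logdetV <- n * log(s2e) + 2 * sum(log(diag(chD))) - sum(q * log(lam))
      quad <- sum(r * (r - Zu)) / s2e
      ll <- -0.5 * (n * log(2 * pi) + logdetV + quad)
      list(sol = sol, trDiag = diagD, ee = sum((r - Zu)^2), lam = lam,
           quadres = quadres, ll = ll)
    }
  }
  emUpdate <- function(s2, s2e, st) {
    s2new <- s2
    trSum <- numeric(K)
    for (k in seq_len(K)) {
      ii <- uIdx[[k]]
      uk <- st$sol[ii]
      trSum[k] <- sum(st$trDiag[ii - p])
      s2new[k] <- (sum(uk^2) + s2e * trSum[k]) / q[k]
    }
    if (method == "REML") {
      s2enew <- st$quadres / (n - p)
    } else {
      # E||y - Xb - Zu||^2 / n with tr((Z'Z+L)^{-1} Z'Z) expanded
      s2enew <- (st$ee + s2e * (sum(q) - sum(st$lam * trSum))) / n
    }
    list(s2 = pmax(s2new, floorv), s2e = max(s2enew, floorv))
  }

  st <- evalStep(s2, s2e)
  if (is.null(st)) stop("mixed-model equations are singular at the start")
  trace <- st$ll
  prev <- c(s2, s2e)
  prevDelta <- NULL
  converged <- FALSE
  it <- 0
  while (it < maxIter) {
    it <- it + 1
    up <- emUpdate(s2, s2e, st)
    cur <- c(up$s2, up$s2e)
    delta <- log(cur) - log(prev)
    # Aitken-style acceleration every 4 plain steps, accepted only if the
    # likelihood does not decrease
    if (it %% 4 == 0 && !is.null(prevDelta) && all(abs(prevDelta) > 0)) {
      r <- pmin(pmax(delta / prevDelta, 0), 0.995)
      acc <- exp(log(cur) + r / (1 - r) * delta)
      acc <- pmax(acc, floorv)
      stAcc <- evalStep(acc[seq_len(K)], acc[K + 1])
      if (!is.null(stAcc) && stAcc$ll >= st$ll - 1e-10) {
        cur <- acc
        stNew <- stAcc
      } else stNew <- evalStep(cur[seq_len(K)], cur[K + 1])
    } else stNew <- evalStep(cur[seq_len(K)], cur[K + 1])
    if (is.null(stNew)) stop("mixed-model equations became singular")
    # boundary handling: EM approaches a zero variance only sublinearly, so
    # periodically try snapping small, shrinking components to the floor,
    # keeping the move only if the likelihood does not decrease
    if (it %% 10 == 0 && K > 0) {
      small <- which((cur[seq_len(K)] < 1e-3 * vy |
                      (cur[seq_len(K)] < 1e-2 * vy &
                       cur[seq_len(K)] < prev[seq_len(K)])) &
                     cur[seq_len(K)] > floorv)
      for (k in small) {
        snap <- cur
        snap[k] <- floorv
        stSnap <- evalStep(snap[seq_len(K)], snap[K + 1])
        if (!is.null(stSnap) && stSnap$ll >= stNew$ll - 1e-6) {
          cur <- snap
          stNew <- stSnap
        }
      }
    }
    # hybrid relative/absolute change: components far below the
    # phenotypic variance cannot stall convergence by crawling
    free <- c(cur[seq_len(K)] > 1.5 * floorv, TRUE)
    relchg <- max(abs(cur[free] - prev[free]) /
                    pmax(prev[free], 1e-4 * vy))
    llchg <- stNew$ll - st$ll
    prevDelta <- log(cur) - log(prev)
    prev <- cur
    s2 <- cur[seq_len(K)]
    s2e <- cur[K + 1]
    st <- stNew
    trace <- c(trace, st$ll)
    if (relchg < tol || (it > 30 && abs(llchg) < 1e-8)) {
      converged <- TRUE
      break
    }
  }
  blups <- vector("list", K)
  names(blups) <- names(Zs)
  for (k in seq_len(K))
    blups[[k]] <- setNames(as.numeric(st$sol[uIdx[[k]]]),
                           colnames(Zs[[k]]))
  beta <- setNames(as.numeric(st$sol[seq_len(ncol(X))]), colnames(X))
  list(sigma2 = s2, sigma2e = s2e, blups = blups, beta = beta,
       logLik = st$ll, trace = trace, nIter = it, converged = converged)
}

meanYearsPerGenotype <- function(records) {
  mean(tapply(records$year, records$genotype,
              function(v) length(unique(v))))
}

meanRepsPerGenotypeYear <- function(records) {
  mean(tapply(records$value, paste(records$genotype, records$year),
              length))
}

#' Backward elimination of random terms by REML likelihood-ratio tests
#'
#' Starting from the full model, each candidate random term (never \code{G}
#' or \code{C}) is tested by a REML LRT against the boundary null
#' \eqn{0.5\chi^2_0 + 0.5\chi^2_1}; the term with the largest p-value
#' \eqn{\ge} alpha is dropped, and the procedure repeats until no term can
#' be removed.  The drop order is deterministic given the data.
#'
#' @param records phenotype records (one trait).
#' @param fixed,random as in \code{\link{fitMixedModel}}.
#' @param alpha retention threshold (default 0.05).
#' @param tol,maxIter passed to the fitter.
#' @return list with \code{fit} (the selected-model fit), \code{retained},
#'   \code{dropped} and \code{tests} (data.frame of per-round LRTs).
#' @export
dropRandomTerms <- function(records, fixed = c("B", "Y", "B:Y"),
                            random = c("G", "C", "G:Y", "C:Y", "x", "y",
                                       "x:y", "x:Y", "y:Y"),
                            alpha = 0.05, tol = 1e-6, maxIter = 1000) {
  protected <- intersect(c("G", "C"), random)
  current <- random
  full <- fitMixedModel(records, fixed, current, "REML", tol, maxIter,
                        onNonconvergence = "warn")
  tests <- list()
  repeat {
    cand <- setdiff(current, protected)
    if (!length(cand)) break
    ps <- numeric(length(cand))
    fits <- vector("list", length(cand))
    for (i in seq_along(cand)) {
      red <- fitMixedModel(records, fixed, setdiff(current, cand[i]),
                           "REML", tol, maxIter,
                           onNonconvergence = "warn")
      stat <- max(0, 2 * (full$logLik - red$logLik))
      ps[i] <- if (stat <= 0) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)
      fits[[i]] <- red
      tests[[length(tests) + 1]] <-
        data.frame(term = cand[i], stat = stat, p = ps[i],
                   model = paste(current, collapse = "+"),
                   stringsAsFactors = FALSE)
    }
    worst <- which.max(ps)
    if (ps[worst] >= alpha) {
      current <- setdiff(current, cand[worst])
      full <- fits[[worst]]
    } else break
  }
  list(fit = full, retained = current, dropped = setdiff(random, current),
       tests = do.call(rbind, tests))
}
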