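# Multifractal analysis by finite box covering: random-sequential covers,
# moment scaling tau(q) / D(q), and the Legendre transform to (alpha, f(alpha)).

largestComponentDistances <- function(net) {
  g <- graphOf(net)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  igraph::distances(g)
}

# One random-sequential cover on a precomputed distance matrix: pick an
# uncovered seed uniformly, claim all uncovered nodes within the ball radius,
# repeat. Returns the list of boxes (node index vectors).
sequentialCover <- function(D, radius) {
  n <- nrow(D)
  uncovered <- rep(TRUE, n)
  boxes <- list()
  left <- n
  while (left > 0) {
    cand <- which(uncovered)
    s <- cand[sample.int(length(cand), 1)]
    box <- cand[D[s, cand] <= radius]
    uncovered[box] <- FALSE
    left <- left - length(box)
    boxes[[length(boxes) + 1L]] <- box
  }
  boxes
}

# Compact a cover: greedily merge boxes (smallest first) into another box
# whenever the union still has shortest-path diameter <= r. Merging never
# invalidates a cover (boxes stay diameter-bounded and disjoint), strictly
# reduces the box count, and removes the residual 1-2 node fragments the
# sequential pass leaves between earlier boxes — those otherwise dominate
# the partition sum at strongly negative q.
compactCover <- function(D, boxes, r) {
  repeat {
    sizes <- vapply(boxes, length, integer(1))
    ord <- order(sizes)
    merged <- FALSE
    for (i in ord) {
      bi <- boxes[[i]]
      # both boxes already satisfy the diameter bound, so the union does iff
      # every cross pair does
      cross <- if (length(bi) == 1) D[bi, ] else apply(D[bi, , drop = FALSE], 2, max)
      for (j in seq_along(boxes)) {
        if (j == i) next
        if (max(cross[boxes[[j]]]) <= r) {
          boxes[[j]] <- c(bi, boxes[[j]])
          boxes[[i]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  boxes
}

#' Cover a graph with boxes of bounded shortest-path diameter
#'
#' Random-sequential finite box covering: an uncovered seed node is drawn
#' uniformly and claims every uncovered node within shortest-path distance
#' floor(r/2); this repeats until all nodes are covered. Among \code{nCovers}
#' restarts the cover with the fewest boxes is kept. Disconnected inputs are
#' reduced to their largest component.
#'
#' @param net a \linkS4class{SpatialNetwork} or igraph (r is interpreted as a
#'   box diameter; balls are grown to radius floor(r/2)).
#' @param r box diameter (>= 0).
#' @param nCovers restarts to minimize over.
#' @param seed integer seed.
#' @return a \linkS4class{BoxCover}.
#' @export
boxCover <- function(net, r, nCovers = 50, seed = 1) {
  if (r < 0) stop("r must be >= 0")
  D <- largestComponentDistances(net)
  radius <- floor(r / 2)
  withSeed(seed, {
    best <- NULL
    for (k in seq_len(nCovers)) {
      boxes <- compactCover(D, sequentialCover(D, radius), r)
      if (is.null(best) || length(boxes) < length(best)) best <- boxes
    }
    new("BoxCover", r = as.numeric(r), boxes = best,
        masses = vapply(best, length, integer(1)))
  })
}

defaultRGrid <- function(diam) {
  # smallest scale 4: at r = 2-3 a box holds <= 4 nodes and the discrete
  # (r+1) correction dominates, so those scales are excluded from the fit;
  # largest scale half the diameter keeps several boxes per cover
  top <- ceiling(diam / 2)
  if (top < 5) return(numeric(0))
  sort(unique(round(exp(seq(log(4), log(top), length.out = 8)))))
}

#' Mass exponents and generalized dimensions by finite box covering
#'
#' For each box diameter r in \code{rGrid}, \code{nCovers} random-sequential
#' covers are drawn; normalized box masses mu_i = M_i(r)/N give the partition
#' sum Z(q, r) = sum_i mu_i^q, and ln Z is averaged over the covers. The mass
#' exponent tau(q) is the slope of mean ln Z(q, r) against ln(r/d) (d = the
#' diameter), D(q) = tau(q)/(q - 1), and D(1) uses the limit form (slope of
#' the averaged sum_i mu_i ln mu_i). Fits with R^2 < 0.8 are flagged; an
#' unusable scaling range (fewer than 4 grid points below the diameter) marks
#' the whole result degenerate rather than erroring.
#'
#' @param net a \linkS4class{SpatialNetwork} or igraph (largest component).
#' @param qGrid distortion orders (default -10..10 in steps of 0.5).
#' @param rGrid box diameters; default log-spaced from 2 to ceiling(d/2).
#' @param nCovers covers averaged per r.
#' @param seed integer seed.
#' @return a \linkS4class{MassExponents}.
#' @export
massExponents <- function(net, qGrid = seq(-10, 10, by = 0.5), rGrid = NULL,
                          nCovers = 40, seed = 1) {
  D <- largestComponentDistances(net)
  N <- nrow(D)
  diam <- max(D)
  if (is.null(rGrid)) rGrid <- defaultRGrid(diam)
  rGrid <- sort(unique(rGrid[rGrid < diam & rGrid >= 1]))
  qGrid <- sort(qGrid)
  if (length(rGrid) < 4 || diam < 4) {
    nq <- length(qGrid)
    return(new("MassExponents", q = qGrid, tau = rep(NA_real_, nq),
               D = rep(NA_real_, nq), r2 = rep(NA_real_, nq),
               rGrid = as.numeric(rGrid), degenerate = TRUE,
               flagged = rep(TRUE, nq)))
  }
  qEff <- qGrid[abs(qGrid - 1) > 1e-8]
  lnZ <- matrix(0, length(qEff), length(rGrid))   # mean ln Z(q, r)
  lnM1 <- numeric(length(rGrid))                  # mean sum mu ln mu (q = 1 limit)
  withSeed(seed, {
    for (j in seq_along(rGrid)) {
      radius <- floor(rGrid[j] / 2)
      accZ <- matrix(0, length(qEff), nCovers)
      acc1 <- numeric(nCovers)
      for (k in seq_len(nCovers)) {
        boxes <- compactCover(D, sequentialCover(D, radius), rGrid[j])
        mu <- vapply(boxes, length, integer(1)) / N
        lmu <- log(mu)
        accZ[, k] <- vapply(qEff, function(q) {
          mx <- max(q * lmu)
          mx + log(sum(exp(q * lmu - mx)))
        }, numeric(1))
        acc1[k] <- sum(mu * lmu)
      }
      lnZ[, j] <- rowMeans(accZ)
      lnM1[j] <- mean(acc1)
    }
  })
  # box size in the ell_B convention: a box of shortest-path diameter r
  # spans ell = r + 1 nodes along a path, so ell is the scale variable
  # (removes the strong small-r discreteness bias of fitting against r)
  xs <- log((rGrid + 1) / (diam + 1))
  fitSlope <- function(y) {
    fit <- stats::lm.fit(cbind(1, xs), y)
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    c(slope = unname(fit$coefficients[2]),
      r2 = if (sst > 0) 1 - ssr / sst else 1)
  }
  tauEff <- t(apply(lnZ, 1, fitSlope))
  f1 <- fitSlope(lnM1)
  tau <- numeric(length(qGrid)); r2 <- numeric(length(qGrid)); Dq <- numeric(length(qGrid))
  iEff <- 1L
  for (i in seq_along(qGrid)) {
    q <- qGrid[i]
    if (abs(q - 1) <= 1e-8) {
      Dq[i] <- f1["slope"]; tau[i] <- 0; r2[i] <- f1["r2"]
    } else {
      tau[i] <- tauEff[iEff, "slope"]; r2[i] <- tauEff[iEff, "r2"]
      Dq[i] <- tau[i] / (q - 1)
      iEff <- iEff + 1L
    }
  }
  new("MassExponents", q = qGrid, tau = tau, D = Dq, r2 = r2,
      rGrid = as.numeric(rGrid), degenerate = FALSE, flagged = r2 < 0.8)
}

#' Legendre transform of mass exponents to the multifractal spectrum
#'
#' alpha(q) = d/dq [(q-1) D(q)] by central finite differences (one-sided at
#' the grid ends); f(alpha) = q alpha - (q-1) D(q). Summary parameters:
#' the spectrum height f_max = max f(alpha), the width alpha_max - alpha_min,
#' and the height range f_max - f_min. A warning is attached when alpha(q)
#' increases with q beyond tolerance (noisy estimate).
#'
#' @param me a \linkS4class{MassExponents} (dense enough q grid).
#' @param tol tolerance for the alpha monotonicity check.
#' @return a \linkS4class{MultifractalSpectrum}.
#' @export
legendreSpectrum <- function(me, tol = 0.05) {
  stopifnot(is(me, "MassExponents"))
  q <- me@q
  if (me@degenerate || any(!is.finite(me@D)))
    stop("mass exponents are degenerate; no spectrum can be computed")
  if (length(q) < 3) stop("q grid too sparse for central differences")
  tau <- (q - 1) * me@D
  n <- length(q)
  alpha <- numeric(n)
  alpha[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
  alpha[n] <- (tau[n] - tau[n - 1]) / (q[n] - q[n - 1])
  if (n > 2)
    alpha[2:(n - 1)] <- (tau[3:n] - tau[1:(n - 2)]) / (q[3:n] - q[1:(n - 2)])
  f <- q * alpha - tau
  warn <- character(0)
  if (any(diff(alpha) > tol))
    warn <- "alpha(q) is not nonincreasing beyond tolerance; noisy estimate"
  new("MultifractalSpectrum", q = q, alpha = alpha, f = f,
      fMax = max(f), alphaWidth = max(alpha) - min(alpha),
      fRange = max(f) - min(f), warnings = warn)
}

#' Mass exponents of an exact binomial cascade
#'
#' Closed-form multifractal reference: the measure that splits mass p / (1-p)
#' at every dyadic refinement. Partition sums are computed exactly at levels
#' \code{levels} and tau(q) is fitted against ln of the scale exactly as in
#' \code{\link{massExponents}}, giving a fixture whose Legendre spectrum has
#' known endpoints alpha in [-log2(max(p,1-p)), -log2(min(p,1-p))].
#'
#' @param p mass fraction in (0, 1), p != 0.5 for a genuinely multifractal case.
#' @param qGrid distortion orders.
#' @param levels dyadic refinement levels used for the fit.
#' @return a \linkS4class{MassExponents}.
#' @export
cascadeMassExponents <- function(p, qGrid = seq(-10, 10, by = 0.5), levels = 4:10) {
  stopifnot(p > 0, p < 1)
  qGrid <- sort(qGrid)
  lnEps <- -levels * log(2)
  lnZ <- matrix(0, length(qGrid), length(levels))
  lnM1 <- numeric(length(levels))
  for (j in seq_along(levels)) {
    n <- levels[j]
    k <- 0:n
    lw <- lchoose(n, k)
    lmass <- k * log(p) + (n - k) * log1p(-p)
    for (i in seq_along(qGrid)) {
      q <- qGrid[i]
      a <- lw + q * lmass
      mx <- max(a)
      lnZ[i, j] <- mx + log(sum(exp(a - mx)))
    }
    lnM1[j] <- sum(exp(lw + lmass) * lmass)
  }
  fitSlope <- function(y) {
    fit <- stats::lm.fit(cbind(1, lnEps), y)
    unname(fit$coefficients[2])
  }
  tau <- apply(lnZ, 1, fitSlope)
  D1 <- fitSlope(lnM1)
  Dq <- ifelse(abs(qGrid - 1) <= 1e-8, D1, tau / (qGrid - 1))
  tau[abs(qGrid - 1) <= 1e-8] <- 0
  new("MassExponents", q = qGrid, tau = tau, D = Dq,
      r2 = rep(1, length(qGrid)), rGrid = 2^(-levels), degenerate = FALSE,
      flagged = rep(FALSE, length(qGrid)))
}
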