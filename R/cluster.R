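## Gaussian-mixture clustering of the reduced space. The EM fitter is
## written out in full (it is the analytical core of the workflow and its
## contract -- full covariances, random restarts, covariance floor,
## likelihood tolerance -- is fixed here); silhouette widths come from the
## cluster package.

## log-density matrix (n x K) including log mixing weights
gmmLogDensity <- function(S, weights, means, covariances) {
  n <- nrow(S); m <- ncol(S); K <- length(weights)
  L <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    C <- chol(covariances[, , k])
    logdet <- 2 * sum(log(diag(C)))
    Xc <- S - matrix(means[k, ], n, m, byrow = TRUE)
    V <- Xc %*% backsolve(C, diag(m))
    L[, k] <- log(weights[k]) -
      0.5 * (m * log(2 * pi) + logdet + .rowSums(V * V, n, m))
  }
  L
}

## distance-weighted (kmeans++-style) random seeding: the first mean is a
## uniform draw, later means are drawn with probability proportional to the
## squared distance from the nearest chosen mean -- far better coverage of
## well-separated basins than uniform draws
seedMeans <- function(X, K) {
  n <- nrow(X)
  mu <- X[sample.int(n, 1), , drop = FALSE]
  if (K == 1L) return(mu)
  d2 <- rowSums((X - matrix(mu[1, ], n, ncol(X), byrow = TRUE))^2)
  for (k in 2:K) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1, prob = p)
    mu <- rbind(mu, X[i, ])
    d2 <- pmin(d2, rowSums((X - matrix(X[i, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  unname(mu) + matrix(stats::rnorm(K * ncol(X), sd = 1e-8), K, ncol(X))
}

runEM <- function(S, K, mu0, maxIter, tol, covFloor) {
  fit <- .cpp_run_em(S, mu0, maxIter, tol, covFloor)
  fit$weights <- fit$weights / sum(fit$weights)
  fit$covariances <- array(fit$covariances, dim = c(ncol(S), ncol(S), K))
  fit
}

#' Fit a full-covariance Gaussian mixture by EM
#'
#' Best of `nInit` random initializations (component means drawn from
#' distinct frames) by converged log-likelihood. Covariances carry a
#' diagonal floor of `covFloor`; EM stops when the log-likelihood gain
#' drops below `tol` or after `maxIter` iterations.
#'
#' @param x a [ReducedSpace-class] or frames x m score matrix.
#' @param K number of components (<= number of frames).
#' @param seed RNG seed (initialization is deterministic given it).
#' @param nInit random restarts (default 10).
#' @param maxIter EM iteration cap (default 500).
#' @param tol log-likelihood gain tolerance (default 1e-6).
#' @param covFloor diagonal covariance floor (default 1e-6).
#' @return A [GMMFit-class].
#' @export
fitGMM <- function(x, K, seed = 1L, nInit = 10L, maxIter = 500L,
                   tol = 1e-6, covFloor = 1e-6) {
  S <- if (is(x, "ReducedSpace")) scores(x) else as.matrix(x)
  n <- nrow(S)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of frames")
  uniq <- unique(S)
  if (K > 1L && nrow(uniq) == 1L)
    stop("all frames are identical; cannot fit K > 1 components")
  ## work on centered data (shift-invariant EM, numerically safer second
  ## moments); shift the means back afterwards
  cen <- colMeans(S)
  S <- S - matrix(cen, n, ncol(S), byrow = TRUE)
  uniq <- uniq - matrix(cen, nrow(uniq), ncol(S), byrow = TRUE)
  set.seed(seed)
  best <- NULL
  for (init in seq_len(nInit)) {
    mu0 <- seedMeans(uniq, K)
    fit <- runEM(S, K, mu0, maxIter, tol, covFloor)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  new("GMMFit", K = as.integer(K), weights = as.numeric(best$weights),
      means = unname(best$means) +
        matrix(cen, K, ncol(S), byrow = TRUE),
      covariances = best$covariances,
      logLik = best$logLik, logLikTrace = best$trace,
      seed = as.integer(seed), converged = best$converged)
}

#' Posterior responsibilities of frames under a mixture
#'
#' @param model a [GMMFit-class].
#' @param x [ReducedSpace-class] or score matrix.
#' @return n x K matrix of posterior probabilities (rows sum to 1).
#' @export
posteriorResponsibilities <- function(model, x) {
  S <- if (is(x, "ReducedSpace")) scores(x) else as.matrix(x)
  if (ncol(S) != ncol(model@means))
    stop("dimension mismatch between frames and model")
  L <- gmmLogDensity(S, model@weights, model@means, model@covariances)
  exp(L - logRowSumExp(L))
}

#' Hard frame assignment by maximum posterior
#'
#' Ties go to the lowest component index.
#'
#' @inheritParams posteriorResponsibilities
#' @return integer labels in 1..K.
#' @export
assignFrames <- function(model, x) {
  R <- posteriorResponsibilities(model, x)
  max.col(R, ties.method = "first")
}

#' Mean silhouette width of a hard partition
#'
#' Standard silhouette with Euclidean distance ([cluster::silhouette]);
#' members of singleton clusters score 0 by convention. Above `maxExact`
#' frames a seeded subsample is scored instead (the all-pairs distance
#' matrix is quadratic in frames).
#'
#' @param x [ReducedSpace-class] or frames x m matrix.
#' @param labels integer cluster labels (>= 2 distinct values).
#' @param maxExact exact-computation frame cap (default 20000).
#' @param seed subsample seed.
#' @param distances optional precomputed [stats::dist] over the rows of `x`
#'   (must match `maxExact` handling; used to share work across K scans).
#' @return list with `mean` and per-sample `widths`.
#' @export
silhouetteScore <- function(x, labels, maxExact = 20000L, seed = 1L,
                            distances = NULL) {
  S <- if (is(x, "ReducedSpace")) scores(x) else as.matrix(x)
  if (length(unique(labels)) < 2L)
    stop("silhouette needs at least 2 clusters")
  n <- nrow(S)
  idx <- seq_len(n)
  if (n > maxExact && is.null(distances)) {
    set.seed(seed)
    idx <- sort(sample.int(n, maxExact))
    S <- S[idx, , drop = FALSE]
    labels <- labels[idx]
    if (length(unique(labels)) < 2L)
      stop("subsample lost all but one cluster; lower maxExact or reseed")
  }
  if (is.null(distances)) distances <- stats::dist(S)
  w <- if (max(table(labels)) == 1L) {
    rep(0, length(labels))  # every cluster a singleton
  } else {
    as.numeric(cluster::silhouette(labels, distances)[, "sil_width"])
  }
  list(mean = mean(w), widths = w, frames = idx)
}

#' Scan cluster counts with elbow and silhouette diagnostics
#'
#' Fits a mixture for every K in `kMin..kMax` and reports, per K, the
#' negative log-likelihood, BIC and mean silhouette width. The elbow K
#' reads the scree curve the way practitioners do: it is the largest K
#' whose score improvement over K-1 still exceeds `elbowThreshold` times
#' the total drop of the curve -- the point where the curve flattens.
#' (The discrete second difference is a poor elbow statistic for
#' likelihood-based scores: their split gains shrink with K even far below
#' the true cluster count, because late splits affect few frames and enter
#' through a logarithm, so maximum curvature systematically lands below
#' the true K on well-separated data with unequal cluster masses.) The
#' silhouette ranking is reported alongside; nothing is auto-selected --
#' the two criteria can disagree and the caller weighs them.
#'
#' @param x [ReducedSpace-class] or score matrix.
#' @param kMin,kMax inclusive K range (kMin >= 2; kMax <= frames).
#' @param seed RNG seed for fits and silhouette subsampling.
#' @param nInit EM restarts per K.
#' @param metric elbow curve: "bic" (default) or "nll".
#' @param elbowThreshold fraction of the curve's total drop below which an
#'   improvement no longer counts (default 0.05).
#' @param maxExact silhouette exact-computation cap.
#' @return A [ModelSelectionReport-class].
#' @export
scanK <- function(x, kMin = 2L, kMax = 8L, seed = 1L, nInit = 10L,
                  metric = c("bic", "nll"), elbowThreshold = 0.05,
                  maxExact = 20000L) {
  metric <- match.arg(metric)
  S <- if (is(x, "ReducedSpace")) scores(x) else as.matrix(x)
  if (kMin > kMax) stop("empty K range")
  if (kMin < 2L) stop("kMin must be >= 2 (silhouette is undefined below)")
  if (kMax > nrow(S)) stop("kMax exceeds the number of frames")
  n <- nrow(S); m <- ncol(S)
  silIdx <- seq_len(n)
  if (n > maxExact) {
    set.seed(seed)
    silIdx <- sort(sample.int(n, maxExact))
  }
  sharedDist <- stats::dist(S[silIdx, , drop = FALSE])
  Ks <- seq.int(kMin, kMax)
  fits <- vector("list", length(Ks))
  nll <- bic <- sil <- numeric(length(Ks))
  for (i in seq_along(Ks)) {
    K <- Ks[i]
    fits[[i]] <- fitGMM(S, K, seed = seed, nInit = nInit)
    ll <- logLik(fits[[i]])
    nll[i] <- -ll
    p <- (K - 1) + K * m + K * m * (m + 1) / 2
    bic[i] <- -2 * ll + p * log(n)
    labs <- assignFrames(fits[[i]], S)[silIdx]
    sil[i] <- if (length(unique(labs)) >= 2L)
      mean(cluster::silhouette(labs, sharedDist)[, "sil_width"]) else NA_real_
  }
  curve <- if (metric == "bic") bic else nll
  elbow <- NA_integer_
  if (length(Ks) >= 2L) {
    drops <- -diff(curve)
    span <- curve[1] - min(curve)
    big <- which(drops > elbowThreshold * max(span, .Machine$double.eps))
    elbow <- if (length(big)) Ks[max(big) + 1L] else Ks[1]
  }  # a single-K scan makes no elbow claim (stays NA)
  ord <- order(sil, decreasing = TRUE, na.last = TRUE)
  new("ModelSelectionReport",
      table = data.frame(K = Ks, negLogLik = nll, BIC = bic,
                         silhouette = sil),
      elbowK = as.integer(elbow),
      bestSilhouetteK = as.integer(Ks[ord[1]]),
      secondBestSilhouetteK = as.integer(
        if (length(Ks) >= 2L) Ks[ord[2]] else NA),
      models = fits)
}

#' Cluster weights as frame fractions
#'
#' @param labels integer cluster labels.
#' @return named numeric vector of fractions (counts / total frames).
#' @export
clusterWeights <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  tab <- table(labels)
  out <- as.numeric(tab) / length(labels)
  names(out) <- names(tab)
  out
}

#' Per-condition cluster population table
#'
#' @param labels integer cluster labels.
#' @param meta per-frame metadata ([S4Vectors::DataFrame] or data.frame)
#'   with a `condition` column.
#' @return condition x cluster matrix of row-normalized fractions.
#' @export
populationsByCondition <- function(labels, meta) {
  cond <- as.character(meta$condition)
  if (length(cond) != length(labels))
    stop("one condition per frame required")
  if (any(is.na(cond) | cond == ""))
    stop("unknown (missing or empty) condition label")
  cond <- factor(cond, levels = unique(cond))  # keep input order
  tab <- table(condition = cond, cluster = labels)
  sweep(unclass(tab), 1, rowSums(tab), "/")
}

#' Representative frame per cluster
#'
#' Among frames assigned to a cluster, the one whose reduced-space score is
#' closest (Euclidean) to the component mean; ties go to the lowest frame
#' index.
#'
#' @param model a [GMMFit-class].
#' @param x [ReducedSpace-class] or score matrix.
#' @param labels hard assignments (defaults to [assignFrames()]).
#' @return integer frame index per cluster (named "1".."K").
#' @export
representativeFrames <- function(model, x, labels = NULL) {
  S <- if (is(x, "ReducedSpace")) scores(x) else as.matrix(x)
  if (is.null(labels)) labels <- assignFrames(model, S)
  out <- integer(model@K)
  for (k in seq_len(model@K)) {
    idx <- which(labels == k)
    if (!length(idx)) stop("cluster ", k, " is empty")
    d2 <- rowSums(sweep(S[idx, , drop = FALSE], 2, model@means[k, ])^2)
    out[k] <- idx[which.min(d2)]
  }
  names(out) <- seq_len(model@K)
  out
}

## ---------------------------------------------------------------------------
## Cluster report
## ---------------------------------------------------------------------------

#' ClusterReport: assignments, weights, populations, representatives
#'
#' @slot labels per-frame cluster labels (1-based).
#' @slot weights cluster weights (fraction of frames).
#' @slot populations condition x cluster row-normalized table.
#' @slot representatives frame index per cluster.
#' @slot model the fitted [GMMFit-class].
#' @slot frameMeta per-frame metadata.
#' @export
setClass("ClusterReport",
  representation(labels = "integer", weights = "numeric",
                 populations = "matrix", representatives = "integer",
                 model = "GMMFit", frameMeta = "DataFrame"))

setValidity("ClusterReport", function(object) {
  rs <- rowSums(object@populations)
  if (length(rs) && any(abs(rs - 1) > 1e-10))
    "population rows must sum to 1 per condition (within 1e-10)" else TRUE
})

#' Build a ClusterReport from a fitted mixture
#'
#' @param model a [GMMFit-class].
#' @param space the [ReducedSpace-class] the model was fit on.
#' @return A [ClusterReport-class].
#' @export
buildClusterReport <- function(model, space) {
  labels <- assignFrames(model, space)
  new("ClusterReport", labels = as.integer(labels),
      weights = clusterWeights(labels),
      populations = populationsByCondition(labels, frameMeta(space)),
      representatives = representativeFrames(model, space, labels),
      model = model, frameMeta = frameMeta(space))
}

setMethod("show", "ClusterReport", function(object) {
  cat("ClusterReport:", object@model@K, "clusters over",
      length(object@labels), "frames\n")
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "), "\n")
  cat("  representatives:",
      paste(object@representatives, collapse = " "), "\n")
})

#' Write a cluster report as CSV + JSON
#'
#' Frame table (`frame, run, condition, label`) to
#' `<prefix>_assignments.csv`; weights, populations and representative
#' frame indices to `<prefix>_summary.json`.
#'
#' @param report a [ClusterReport-class].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writeClusterReport <- function(report, prefix) {
  fm <- as.data.frame(report@frameMeta)
  utils::write.csv(
    data.frame(frame = seq_along(report@labels), run = fm$run,
               condition = fm$condition, label = report@labels),
    paste0(prefix, "_assignments.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(K = report@model@K,
         weights = as.list(report@weights),
         populations = apply(report@populations, 1, as.list),
         representatives = as.list(report@representatives),
         logLik = logLik(report@model)),
    paste0(prefix, "_summary.json"), digits = NA, auto_unbox = TRUE)
  invisible(prefix)
}
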