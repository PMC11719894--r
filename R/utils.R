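## Small numeric helpers shared across modules.

#' Rotation matrix from axis-angle
#'
#' Rodrigues' formula; the axis need not be normalized.
#'
#' @param axis 3-vector rotation axis (non-zero when `angle != 0`).
#' @param angle rotation angle, radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotationMatrix <- function(axis, angle) {
  if (angle == 0) return(diag(3))
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero when angle != 0")
  u <- axis / n
  Kx <- matrix(c(0, u[3], -u[2],
                 -u[3], 0, u[1],
                 u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * Kx + (1 - cos(angle)) * (Kx %*% Kx)
}

#' Stationary distribution of a Markov chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' sum to 1.
#'
#' @param P row-stochastic K x K transition matrix.
#' @return numeric K-vector.
#' @export
stationaryDistribution <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

## all pairwise Euclidean distances between two point sets (rows = points)
crossDistances <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  D2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(D2, 0))
}

## plain RMSD between two already-aligned coordinate sets (rows = points)
coordRMSD <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

## row-wise log(sum(exp(.))) with the usual max shift
logRowSumExp <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx + log(.rowSums(exp(M - mx), nrow(M), ncol(M)))
}

#' Match predicted cluster labels to reference labels
#'
#' Finds the cluster -> reference-state relabeling maximizing agreement
#' (exhaustive over permutations up to 8 clusters, greedy on the confusion
#' matrix beyond). Used to compare recovered partitions against planted
#' ground truth.
#'
#' @param labels integer cluster labels (1-based).
#' @param reference integer reference labels (1-based).
#' @return integer vector: `labels` relabeled into reference states.
#' @export
matchClusterLabels <- function(labels, reference) {
  ks <- sort(unique(labels))
  rs <- sort(unique(reference))
  C <- table(factor(labels, levels = ks), factor(reference, levels = rs))
  if (length(ks) <= 8L && length(ks) == length(rs)) {
    perms <- permuteAll(seq_along(rs))
    best <- NULL; bestScore <- -1
    for (p in perms) {
      sc <- sum(C[cbind(seq_along(ks), p)])
      if (sc > bestScore) { bestScore <- sc; best <- p }
    }
    map <- rs[best]
  } else {
    map <- integer(length(ks))
    Cw <- as.matrix(C)
    for (step in seq_along(ks)) {
      idx <- which(Cw == max(Cw), arr.ind = TRUE)[1, ]
      map[idx[1]] <- rs[idx[2]]
      Cw[idx[1], ] <- -1
      Cw[, idx[2]] <- -1
    }
  }
  map[match(labels, ks)]
}

## all permutations of a small integer vector (n! grows fast; callers cap n)
permuteAll <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permuteAll(v[-i]), function(p) c(v[i], p)))
  out
}
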