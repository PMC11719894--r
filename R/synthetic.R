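## Synthetic multidomain CA-only ensembles with planted conformational
## states. Each state is a set of per-domain rigid-body transforms applied
## to a reference topology; frames switch states along a Markov chain and
## receive per-domain isotropic Gaussian jitter. No force field is claimed:
## the generator exists so every downstream stage can be validated against
## known ground truth.

#' Build a toy CA-only multidomain topology
#'
#' Each domain is laid out as a helix-like curve (radius 5 A, rise 0.9 A per
#' residue, 40 degrees per residue) centered on a per-domain offset, with
#' consecutive 1-based residue numbering across domains. Offsets default to
#' a line along x with 14 A spacing; supply `centers` to control interdomain
#' distances.
#'
#' @param domainSizes named integer vector, residues per domain (>= 1 each).
#' @param centers optional named list of 3-vector domain centers (Angstrom).
#' @param identifier structure label.
#' @return A [ProteinStructure-class] with one CA atom per residue.
#' @examples
#' buildToyTopology(c(A = 10, B = 10))
#' @export
buildToyTopology <- function(domainSizes, centers = NULL,
                             identifier = "toy") {
  if (length(domainSizes) == 0) stop("at least one domain required")
  if (any(domainSizes < 1)) stop("each domain needs >= 1 residue")
  nms <- names(domainSizes)
  if (is.null(nms)) stop("domainSizes must be named")
  if (is.null(centers)) {
    centers <- lapply(seq_along(domainSizes),
                      function(i) c((i - 1) * 14, 0, 0))
    names(centers) <- nms
  }
  xyz <- NULL
  res <- integer(0)
  offset <- 0L
  for (d in nms) {
    n <- domainSizes[[d]]
    i <- seq_len(n)
    phi <- (i - 1) * (40 * pi / 180)
    local <- cbind(5 * cos(phi), 5 * sin(phi), 0.9 * (i - 1))
    local <- sweep(local, 2, colMeans(local))
    local <- sweep(local, 2, centers[[d]], "+")
    xyz <- rbind(xyz, local)
    res <- c(res, offset + i)
    offset <- offset + n
  }
  ProteinStructure(
    atoms = data.frame(residue_index = res,
                       residue_name = "ALA", atom_name = "CA"),
    coords = xyz, identifier = identifier)
}

#' Domain map matching a toy topology
#'
#' Contiguous residue intervals in the order of `domainSizes`, as produced
#' by [buildToyTopology()].
#'
#' @param domainSizes named integer vector, residues per domain.
#' @return A [DomainMap-class].
#' @export
toyDomainMap <- function(domainSizes) {
  en <- cumsum(domainSizes)
  st <- c(1L, utils::head(en, -1) + 1L)
  iv <- Map(function(s, e) c(s, e), st, en)
  names(iv) <- names(domainSizes)
  DomainMap(iv)
}

#' Sample a Markov state sequence
#'
#' @param transitionMatrix row-stochastic K x K matrix.
#' @param nFrames sequence length.
#' @param initialDistribution probability K-vector for the first frame
#'   (default uniform).
#' @param seed RNG seed; identical seeds give identical sequences.
#' @return integer vector of 1-based state labels.
#' @export
sampleStateSequence <- function(transitionMatrix, nFrames,
                                initialDistribution = NULL, seed = 1L) {
  P <- transitionMatrix
  K <- nrow(P)
  if (ncol(P) != K || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix rows must sum to 1")
  if (is.null(initialDistribution)) initialDistribution <- rep(1 / K, K)
  if (length(initialDistribution) != K || abs(sum(initialDistribution) - 1) > 1e-8)
    stop("initial distribution must be a K-vector summing to 1")
  set.seed(seed)
  s <- integer(nFrames)
  ## inverse-CDF draws so a degenerate (identity) chain is exact
  cumInit <- cumsum(initialDistribution)
  cumP <- t(apply(P, 1, cumsum))
  u <- stats::runif(nFrames)
  s[1] <- findInterval(u[1], cumInit, left.open = TRUE) + 1L
  for (t in seq_len(nFrames - 1L))
    s[t + 1L] <- findInterval(u[t + 1L], cumP[s[t], ], left.open = TRUE) + 1L
  s
}

## deterministic per-state coordinates: reference with each domain rotated
## about its own centroid and translated
stateCoordinates <- function(topology, map, state) {
  X <- coords(topology)
  for (d in names(state@transforms)) {
    tr <- state@transforms[[d]]
    idx <- domainAtomIndices(topology, map, d)
    if (length(idx) == 0L) next
    Xd <- X[idx, , drop = FALSE]
    cen <- colMeans(Xd)
    R <- rotationMatrix(tr$axis, tr$angle)
    X[idx, ] <- sweep(sweep(Xd, 2, cen) %*% t(R), 2, cen + tr$translation, "+")
  }
  X
}

## per-atom jitter sigma for one state
atomSigmas <- function(topology, map, state) {
  sig <- rep(0, nAtoms(topology))
  for (d in names(state@jitter)) {
    idx <- domainAtomIndices(topology, map, d)
    sig[idx] <- state@jitter[[d]]
  }
  sig
}

#' Generate a synthetic ensemble with planted ground truth
#'
#' For each run, a state sequence is drawn from the spec's Markov chain and
#' every frame is the reference topology with each domain rigidly
#' transformed by its state's [StateSpec-class] plus isotropic Gaussian
#' jitter. Run r (in generation order) uses seed `spec seed + r`, so runs
#' are independent yet bit-reproducible.
#'
#' @param spec an [EnsembleSpec-class].
#' @return A [SyntheticEnsemble-class] holding one [MDTrajectory-class] and
#'   one planted label vector per run.
#' @export
generateTrajectory <- function(spec) {
  methods::validObject(spec)
  topo <- spec@topology
  map <- spec@domainMap
  K <- length(spec@states)
  na <- nAtoms(topo)
  nf <- spec@framesPerRun
  stateX <- lapply(spec@states, function(s) stateCoordinates(topo, map, s))
  stateSig <- lapply(spec@states, function(s) atomSigmas(topo, map, s))
  trajs <- list()
  labs <- list()
  run <- 0L
  for (cond in names(spec@runsPerCondition)) {
    for (r in seq_len(spec@runsPerCondition[[cond]])) {
      run <- run + 1L
      runSeed <- spec@seed + run
      s <- sampleStateSequence(spec@transitionMatrix, nf,
                               spec@initialDistribution[[cond]], runSeed)
      arr <- array(0, dim = c(nf, na, 3))
      for (t in seq_len(nf)) arr[t, , ] <- stateX[[s[t]]]
      sigFrame <- do.call(rbind, stateSig)[s, , drop = FALSE]  # nf x na
      if (any(sigFrame > 0)) {
        set.seed(runSeed + 1000003L)
        noise <- array(stats::rnorm(nf * na * 3), dim = c(nf, na, 3))
        for (d in 1:3) arr[, , d] <- arr[, , d] + noise[, , d] * sigFrame
      }
      id <- paste0(cond, "-", r)
      trajs[[id]] <- MDTrajectory(topo, arr, runId = id, condition = cond,
                                  systemType = spec@systemType)
      labs[[id]] <- s
    }
  }
  new("SyntheticEnsemble", trajectories = trajs, labels = labs, spec = spec)
}

#' Write a synthetic ensemble to disk
#'
#' One multi-model PDB per run, a ground-truth CSV (`run, frame, state`) and
#' a YAML provenance summary of the spec.
#'
#' @param ensemble a [SyntheticEnsemble-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticEnsemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(ensemble@trajectories))
    writeTrajectory(ensemble@trajectories[[id]],
                    file.path(dir, paste0(id, ".pdb")))
  gt <- do.call(rbind, lapply(names(ensemble@labels), function(id)
    data.frame(run = id, frame = seq_along(ensemble@labels[[id]]),
               state = ensemble@labels[[id]])))
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  sp <- ensemble@spec
  yaml::write_yaml(list(
    states = length(sp@states),
    framesPerRun = sp@framesPerRun,
    runsPerCondition = as.list(sp@runsPerCondition),
    seed = sp@seed,
    systemType = sp@systemType,
    transitionMatrix = apply(sp@transitionMatrix, 1, as.list)),
    file.path(dir, "ensemble_spec.yaml"))
  invisible(dir)
}

## ---------------------------------------------------------------------------
## Preset study ensembles (miniature seven-domain systems)
## ---------------------------------------------------------------------------

## residues per domain: ORF2p proportions scaled ~1/5 (255 CA atoms)
miniatureDomainSizes <- function() {
  c(EN = 48L, tower = 40L, fingers = 24L, palm = 43L, thumb = 17L,
    wrist = 40L, CTD = 43L)
}

#' Miniature seven-domain reference topology
#'
#' 255 CA atoms laid out with a packed fingers-palm-thumb core, adjacent
#' wrist and tower, a peripheral EN, and a CTD placed so that the minimum
#' tower-CTD CA-CA distance in the reference conformation is 16 A (the
#' starting separation of the open-ring system).
#'
#' @return list with `topology` ([ProteinStructure-class]), `map`
#'   ([DomainMap-class]) and `contactShift` (the translation that brings the
#'   CTD to ~5 A minimum distance from the tower).
#' @export
miniatureTopology <- function() {
  sizes <- miniatureDomainSizes()
  centers <- list(EN = c(-22, -30, 0), tower = c(0, -18, 0),
                  fingers = c(0, 0, 0), palm = c(14, 0, 0),
                  thumb = c(28, 0, 0), wrist = c(14, 16, 0),
                  CTD = c(18, -20, 12))
  topo <- buildToyTopology(sizes, centers, identifier = "miniature-7dom")
  map <- toyDomainMap(sizes)
  ## place the CTD so the reference tower-CTD minimum distance is exactly 16 A
  iT <- domainAtomIndices(topo, map, "tower")
  iC <- domainAtomIndices(topo, map, "CTD")
  adj <- function(topo) {
    X <- coords(topo)
    D <- crossDistances(X[iC, , drop = FALSE], X[iT, , drop = FALSE])
    w <- which(D == min(D), arr.ind = TRUE)[1, ]
    u <- X[iT[w[2]], ] - X[iC[w[1]], ]
    u <- u / sqrt(sum(u^2))
    list(dmin = min(D), u = u)
  }
  a <- adj(topo)
  X <- coords(topo)
  X[iC, ] <- sweep(X[iC, , drop = FALSE], 2, (a$dmin - 16) * a$u, "+")
  topo <- ProteinStructure(atomData(topo), X, identifier(topo))
  a <- adj(topo)
  list(topology = topo, map = map, contactShift = (a$dmin - 5) * a$u)
}

## sticky chain with exact stationary distribution pi:
## P = s*I + (1-s) * 1 pi'
stickyChain <- function(pi, stay = 0.9) {
  K <- length(pi)
  P <- stay * diag(K) + (1 - stay) * matrix(pi, K, K, byrow = TRUE)
  P / rowSums(P)
}

## shared jitter sigmas (Angstrom): EN/CTD internally rigid but mobile,
## tower internally flexible, core stiff
miniatureJitter <- function() {
  c(EN = 0.8, tower = 1.5, fingers = 0.3, palm = 0.3, thumb = 0.3,
    wrist = 0.6, CTD = 0.6)
}

## in-plane radial/tangential unit vectors of a domain relative to the
## FPT-core centroid; state displacements are parameterized in this frame
## because distance features respond strongly to radial motion and more
## gently to tangential motion
domainAxes <- function(topology, map, domain) {
  core <- colMeans(coords(topology)[domainAtomIndices(topology, map, "FPT"),
                                    , drop = FALSE])
  cen <- colMeans(coords(topology)[domainAtomIndices(topology, map, domain),
                                   , drop = FALSE])
  u <- cen - core
  u[3] <- 0
  u <- u / sqrt(sum(u^2))
  list(rad = u, tang = c(-u[2], u[1], 0))
}

#' Planted five-state "open-like" study ensemble
#'
#' Miniature seven-domain system with five conformational basins: an
#' EN-extended near-start state, two CTD-tower contact states (minimum
#' tower-CTD distance ~5 A), and two elongated open states. The EN domain
#' is always displaced ~10 A radially outward and swings tangentially
#' between basins; the CTD moves along the dock/undock axis; the tower
#' takes small radial shifts and rotations. The stationary occupancies are
#' (0.40, 0.195, 0.12, 0.19, 0.095); the contact states (2 and 4) carry a
#' combined stationary mass of 0.385. Four conditions (apo, RNA, DNA,
#' ternary) start in different basins.
#'
#' @param seed base RNG seed.
#' @param framesPerRun frames per run (default 400).
#' @param runsPerCondition named integer vector (default 3 runs for each of
#'   apo, RNA, DNA, ternary).
#' @return An [EnsembleSpec-class] (pass to [generateTrajectory()]).
#' @export
openLikeSpec <- function(seed = 1L, framesPerRun = 400L,
                         runsPerCondition = c(apo = 3L, RNA = 3L,
                                              DNA = 3L, ternary = 3L)) {
  mt <- miniatureTopology()
  cs <- mt$contactShift
  jit <- miniatureJitter()
  axEN <- domainAxes(mt$topology, mt$map, "EN")
  axTW <- domainAxes(mt$topology, mt$map, "tower")
  enD <- function(t) domainTransform(0, c(0, 0, 1),
                                     10 * axEN$rad + t * axEN$tang)
  twD <- function(s, a) domainTransform(a * pi / 180, c(1, 0, 1),
                                        s * axTW$rad)
  ctd <- function(v, rot = 0, ax = c(0, 0, 1))
    domainTransform(rot * pi / 180, ax, v)
  states <- list(
    ## 1: EN extended, CTD at its 16 A starting separation
    StateSpec(list(EN = enD(0)), jit),
    ## 2: CTD docks on the tower, EN swings one way
    StateSpec(list(EN = enD(-14), CTD = ctd(cs, 10, c(1, 0, 0)),
                   tower = twD(3, 8)), jit),
    ## 3: elongated open, EN swung opposite, CTD pushed away
    StateSpec(list(EN = enD(14), CTD = ctd(-0.55 * cs),
                   tower = twD(-4, -8)), jit),
    ## 4: second contact state, different EN swing and CTD pose
    StateSpec(list(EN = enD(7), CTD = ctd(cs + c(0, 0, 2), 15),
                   tower = twD(-3, 5)), jit),
    ## 5: far open, CTD detached laterally
    StateSpec(list(EN = enD(7), CTD = ctd(-0.7 * cs + c(0, 6, 0)),
                   tower = twD(4, 6)), jit))
  pi0 <- c(0.40, 0.195, 0.12, 0.19, 0.095)
  delta <- function(k) { p <- rep(0, 5); p[k] <- 1; p }
  EnsembleSpec(mt$topology, mt$map, states, stickyChain(pi0),
               framesPerRun = framesPerRun,
               runsPerCondition = runsPerCondition,
               initialDistribution = list(apo = delta(3), RNA = delta(4),
                                          DNA = delta(2), ternary = delta(1)),
               systemType = "open", seed = seed)
}

#' Planted six-state "closed-like" study ensemble
#'
#' As [openLikeSpec()] but with six basins, three of which are CTD-tower
#' contact states; stationary occupancies (0.40, 0.13, 0.12, 0.13, 0.12,
#' 0.10) put a combined 0.65 stationary mass in contact states (1-3).
#'
#' @inheritParams openLikeSpec
#' @return An [EnsembleSpec-class].
#' @export
closedLikeSpec <- function(seed = 1L, framesPerRun = 400L,
                           runsPerCondition = c(apo = 3L, RNA = 3L,
                                                DNA = 3L, ternary = 3L)) {
  mt <- miniatureTopology()
  cs <- mt$contactShift
  jit <- miniatureJitter()
  axEN <- domainAxes(mt$topology, mt$map, "EN")
  axTW <- domainAxes(mt$topology, mt$map, "tower")
  enD <- function(r, t) domainTransform(0, c(0, 0, 1),
                                        r * axEN$rad + t * axEN$tang)
  twD <- function(s, a) domainTransform(a * pi / 180, c(1, 0, 1),
                                        s * axTW$rad)
  ctd <- function(v, rot = 0, ax = c(0, 0, 1))
    domainTransform(rot * pi / 180, ax, v)
  ## per-state dock vector: translate the CTD toward the (already shifted)
  ## tower until the minimum CA-CA distance reaches 5 A, so every contact
  ## state docks equally tightly whatever its tower pose
  dockFor <- function(towerTr) {
    X <- coords(mt$topology)
    iT <- domainAtomIndices(mt$topology, mt$map, "tower")
    cenT <- colMeans(X[iT, , drop = FALSE])
    R <- rotationMatrix(towerTr$axis, towerTr$angle)
    X[iT, ] <- sweep(sweep(X[iT, , drop = FALSE], 2, cenT) %*% t(R), 2,
                     cenT + towerTr$translation, "+")
    iC <- domainAtomIndices(mt$topology, mt$map, "CTD")
    D <- crossDistances(X[iC, , drop = FALSE], X[iT, , drop = FALSE])
    w <- which(D == min(D), arr.ind = TRUE)[1, ]
    u <- X[iT[w[2]], ] - X[iC[w[1]], ]
    (min(D) - 5) * u / sqrt(sum(u^2))
  }
  ## undock directions orthogonal to the dock axis (lateral drifts)
  u <- cs / sqrt(sum(cs^2))
  v1 <- c(u[2], -u[1], 0); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(u[2] * v1[3] - u[3] * v1[2], u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  ## EN poses (radial extension, tangential swing) chosen by maximizing
  ## the smallest mass-weighted squared basin separation of the noise-free
  ## feature centroids over a pose grid: every pairwise merge is then
  ## comparably costly, so the score-curve bend sits at the planted K
  ## rather than at a coarse docked/undocked split
  tws <- list(twD(0, 6), twD(6.7, -6), twD(-6.7, 8),     # docked 1-3
              twD(6.7, -8), twD(0, 4), twD(-6.7, -4))    # undocked 4-6
  states <- list(
    ## 1-3: contact states, CTD docked on the tower in distinct poses,
    ## EN swung to distinct poses
    StateSpec(list(EN = enD(14, 22), CTD = ctd(dockFor(tws[[1]])),
                   tower = tws[[1]]), jit),
    StateSpec(list(EN = enD(8, -16),
                   CTD = ctd(dockFor(tws[[2]]), 20, c(0, 1, 0)),
                   tower = tws[[2]]), jit),
    StateSpec(list(EN = enD(8, 5),
                   CTD = ctd(dockFor(tws[[3]]), -15, c(1, 0, 0)),
                   tower = tws[[3]]), jit),
    ## 4-6: open states, CTD undocked along and across the dock axis
    StateSpec(list(EN = enD(8, -22), CTD = ctd(-0.35 * cs),
                   tower = tws[[4]]), jit),
    StateSpec(list(EN = enD(8, 22), CTD = ctd(11 * v1),
                   tower = tws[[5]]), jit),
    StateSpec(list(EN = enD(14, -22), CTD = ctd(-0.35 * cs),
                   tower = tws[[6]]), jit))
  pi0 <- c(0.40, 0.13, 0.12, 0.13, 0.12, 0.10)
  delta <- function(k) { p <- rep(0, 6); p[k] <- 1; p }
  EnsembleSpec(mt$topology, mt$map, states, stickyChain(pi0),
               framesPerRun = framesPerRun,
               runsPerCondition = runsPerCondition,
               initialDistribution = list(apo = delta(5), RNA = delta(1),
                                          DNA = delta(2), ternary = delta(4)),
               systemType = "closed", seed = seed)
}

#' Planted three-motion-mode ensemble
#'
#' Four equally occupied states at the vertices of a regular tetrahedron
#' in a three-dimensional motion-mode space whose axes are carried by
#' three different domains (EN radial, CTD lateral, wrist radial), so the
#' modes excite disjoint feature columns and are mutually orthogonal by
#' construction. Amplitudes are scaled so each mode contributes equal
#' feature variance; with small jitter the between-state scatter spans
#' exactly three dominant motion modes.
#'
#' @inheritParams openLikeSpec
#' @param modeScale feature-space amplitude of each mode (Angstrom;
#'   default 25).
#' @return An [EnsembleSpec-class].
#' @export
threeModeSpec <- function(seed = 1L, framesPerRun = 400L,
                          runsPerCondition = c(apo = 3L),
                          modeScale = 25) {
  mt <- miniatureTopology()
  topo <- mt$topology
  map <- mt$map
  axEN <- domainAxes(topo, map, "EN")
  axWR <- domainAxes(topo, map, "wrist")
  cs <- mt$contactShift
  u <- cs / sqrt(sum(cs^2))
  v1 <- c(u[2], -u[1], 0); v1 <- v1 / sqrt(sum(v1^2))
  carriers <- list(EN = axEN$rad, CTD = v1, wrist = axWR$rad)
  ## measure the feature response of each carrier (the map from Cartesian
  ## displacement to pairwise distances is anisotropic and the three
  ## responses are correlated), then whiten: mode coefficients are mixed
  ## through C^(-1/2) so the three planted motion modes carry exactly
  ## equal, orthogonal feature variance
  fa <- pickFeatureAtoms(topo, 25)
  f0 <- as.numeric(stats::dist(coords(topo)[fa, , drop = FALSE]))
  resp <- function(domain, v) {
    st <- StateSpec(stats::setNames(
      list(domainTransform(0, c(0, 0, 1), v)), domain))
    X <- stateCoordinates(topo, map, st)
    as.numeric(stats::dist(X[fa, , drop = FALSE])) - f0
  }
  M <- sapply(seq_along(carriers), function(j)
    (resp(names(carriers)[j], 5 * carriers[[j]]) -
     resp(names(carriers)[j], -5 * carriers[[j]])) / 2)
  n <- sqrt(colSums(M^2))
  C <- stats::cov2cor(crossprod(M))
  e <- eigen(C, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  verts <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  states <- lapply(seq_len(nrow(verts)), function(k) {
    q <- modeScale * (W %*% verts[k, ]) / n  # Cartesian amplitude per carrier
    StateSpec(list(
      EN = domainTransform(0, c(0, 0, 1), q[1] * carriers$EN),
      CTD = domainTransform(0, c(0, 0, 1), q[2] * carriers$CTD),
      wrist = domainTransform(0, c(0, 0, 1), q[3] * carriers$wrist)),
      jitter = stats::setNames(rep(0.3, 7), names(miniatureDomainSizes())))
  })
  P <- matrix(1 / 8, 8, 8)
  EnsembleSpec(topo, map, states, P,
               framesPerRun = framesPerRun,
               runsPerCondition = runsPerCondition,
               systemType = "custom", seed = seed)
}

#' Planted two-state contact-switching ensemble
#'
#' One open state (reference, tower-CTD minimum distance 16 A) and one
#' contact state (CTD docked to ~5 A), switching along a two-state chain
#' with stationary contact occupancy 0.4.
#'
#' @inheritParams openLikeSpec
#' @return An [EnsembleSpec-class]; state 2 is the contact state.
#' @export
contactSwitchSpec <- function(seed = 1L, framesPerRun = 1000L,
                              runsPerCondition = c(apo = 3L)) {
  mt <- miniatureTopology()
  jit <- c(EN = 0.4, tower = 0.6, fingers = 0.3, palm = 0.3, thumb = 0.3,
           wrist = 0.4, CTD = 0.5)
  states <- list(
    StateSpec(jitter = jit),
    StateSpec(list(CTD = domainTransform(0, c(0, 0, 1), mt$contactShift)),
              jit))
  P <- rbind(c(0.96, 0.04), c(0.06, 0.94))  # stationary (0.6, 0.4)
  EnsembleSpec(mt$topology, mt$map, states, P,
               framesPerRun = framesPerRun,
               runsPerCondition = runsPerCondition,
               systemType = "open", seed = seed)
}
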