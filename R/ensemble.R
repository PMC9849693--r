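#' Construct a coordinate ensemble
#'
#' A set of frames (conformations) of the same labelled particle set, stored
#' as an `F x P x 3` array of coordinates in Angstrom. This is the container
#' on which superposition, RMSF, essential-dynamics PCA and subspace
#' comparisons operate.
#'
#' @param coords Numeric array `F x P x 3` (frames x particles x xyz), or a
#'   list of `P x 3` matrices.
#' @param particle_labels Character vector of particle identifiers, length
#'   `P` (e.g. `"A:CA:12"` or `"CA_12"`); defaults to `p1..pP`.
#' @param superposed Logical: have the frames already been least-squares
#'   fitted onto a common reference?
#' @return Object of class `"ensemble"`.
#' @export
ensemble <- function(coords, particle_labels = NULL, superposed = FALSE) {
  if (is.list(coords))
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[1] < 2) stop("an ensemble needs at least 2 frames")
  P <- dim(coords)[2]
  if (is.null(particle_labels)) particle_labels <- paste0("p", seq_len(P))
  stopifnot(length(particle_labels) == P)
  structure(list(coords = coords, particle_labels = as.character(particle_labels),
                 superposed = isTRUE(superposed), reference = NULL),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<ensemble> %d frames x %d particles%s\n", d[1], d[2],
              if (x$superposed) " (superposed)" else ""))
  invisible(x)
}

## Kabsch: proper rotation R minimising ||x R - y|| for centred row-vector
## coordinate matrices x, y.
.kabsch <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

.resolve_selection <- function(ens, selection) {
  if (is.null(selection)) return(seq_along(ens$particle_labels))
  if (is.character(selection)) {
    idx <- match(selection, ens$particle_labels)
    if (anyNA(idx)) stop("unknown particle labels in selection")
    return(idx)
  }
  as.integer(selection)
}

#' Superpose an ensemble onto its average structure
#'
#' Least-squares rigid-body fit of every frame onto the mean structure,
#' iteratively refined: after fitting, the mean is recomputed and the fit
#' repeated (`rounds` times, default 2). Rotations are proper
#' (determinant +1). The fit is computed on `selection` but applied to all
#' particles, so e.g. ions excluded from the fit still move with the frame.
#'
#' @param ens An [ensemble()].
#' @param selection Particle indices or labels used for fitting (default:
#'   all); at least 3 particles.
#' @param rounds Refinement rounds.
#' @return Superposed `"ensemble"` with the final reference (mean structure
#'   over the selection) stored in `$reference`.
#' @export
superpose <- function(ens, selection = NULL, rounds = 2) {
  stopifnot(inherits(ens, "ensemble"))
  sel <- .resolve_selection(ens, selection)
  if (length(sel) < 3)
    stop("superposition is underdetermined with fewer than 3 particles")
  co <- ens$coords
  FF <- dim(co)[1]
  ref <- apply(co[, sel, , drop = FALSE], c(2, 3), mean)
  for (r in seq_len(rounds + 1)) {
    ref_c <- scale(ref, scale = FALSE)
    ref_centroid <- attr(ref_c, "scaled:center")
    for (f in seq_len(FF)) {
      frame <- co[f, , ]
      fsel <- frame[sel, , drop = FALSE]
      cen <- colMeans(fsel)
      rot <- .kabsch(sweep(fsel, 2, cen), ref_c)
      co[f, , ] <- sweep(sweep(frame, 2, cen) %*% rot, 2, ref_centroid, `+`)
    }
    new_ref <- apply(co[, sel, , drop = FALSE], c(2, 3), mean)
    if (r <= rounds) ref <- new_ref
  }
  out <- ens
  out$coords <- co
  out$superposed <- TRUE
  out$reference <- ref
  out
}

#' Per-particle root-mean-square fluctuation
#'
#' RMSF of each selected particle about its time-average position:
#' `sqrt(mean_f |r_f - <r>|^2)`, in Angstrom. The ensemble must be
#' superposed first so that rigid-body motion does not inflate the
#' fluctuations.
#'
#' @param ens A superposed [ensemble()].
#' @param selection Particle indices or labels (default all).
#' @param selection_tag Free-text tag recorded in the profile (e.g.
#'   `"calpha"`, `"calcium_ion"`).
#' @return Object of class `"flex_profile"`: data.frame with `particle` and
#'   `rmsf` columns plus a `selection_tag` attribute.
#' @export
rmsf <- function(ens, selection = NULL, selection_tag = "custom") {
  stopifnot(inherits(ens, "ensemble"))
  if (!ens$superposed)
    stop("ensemble must be superposed before computing RMSF")
  sel <- .resolve_selection(ens, selection)
  co <- ens$coords[, sel, , drop = FALSE]
  mu <- apply(co, c(2, 3), mean)
  dev2 <- sweep(co, c(2, 3), mu)^2
  val <- sqrt(apply(dev2, 2, mean) * 3)   # mean over frames & xyz, times 3
  out <- data.frame(particle = ens$particle_labels[sel], rmsf = val,
                    stringsAsFactors = FALSE)
  attr(out, "selection_tag") <- selection_tag
  class(out) <- c("flex_profile", "data.frame")
  out
}

#' Essential-dynamics principal component analysis
#'
#' Diagonalises the `3P x 3P` covariance matrix of the selected particle
#' coordinates across frames. Eigenvectors are the collective modes of
#' motion, eigenvalues their variances (Angstrom^2, descending). The sum of
#' eigenvalues equals the total coordinate variance.
#'
#' @param ens A superposed [ensemble()].
#' @param selection Particle indices or labels (default all).
#' @param warn_rank Warn when frames < 3P + 1 (covariance rank-deficient).
#' @return Object of class `"essential_subspace"`: list with `eigenvectors`
#'   (`3P x 3P`, columns orthonormal), `eigenvalues`, `mean` (flattened mean
#'   coordinates), `n_particles`, `selection`.
#' @export
pca_ensemble <- function(ens, selection = NULL, warn_rank = TRUE) {
  stopifnot(inherits(ens, "ensemble"))
  if (!ens$superposed) stop("ensemble must be superposed before PCA")
  sel <- .resolve_selection(ens, selection)
  co <- ens$coords[, sel, , drop = FALSE]
  FF <- dim(co)[1]
  X <- matrix(co, nrow = FF)                  # F x 3P (all x, all y, all z)
  if (warn_rank && FF <= ncol(X))
    warning("fewer frames than coordinates: covariance is rank-deficient")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / (FF - 1)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)                   # clip tiny negative round-off
  structure(list(eigenvectors = eig$vectors, eigenvalues = ev, mean = mu,
                 n_particles = length(sel), selection = sel),
            class = "essential_subspace")
}

#' Project frames onto principal components
#'
#' Mean-centred frame coordinates dotted with the first `k` eigenvectors of
#' an essential subspace, giving per-frame scores.
#'
#' @param ens A superposed [ensemble()] over the same selection that defined
#'   `subspace`.
#' @param subspace An `"essential_subspace"`.
#' @param k Number of components (default 2).
#' @return `F x k` matrix of scores.
#' @export
project_frames <- function(ens, subspace, k = 2) {
  stopifnot(inherits(ens, "ensemble"), inherits(subspace, "essential_subspace"))
  co <- ens$coords[, subspace$selection, , drop = FALSE]
  X <- matrix(co, nrow = dim(co)[1])
  if (ncol(X) != length(subspace$mean))
    stop("ensemble selection does not match the subspace dimensionality")
  sweep(X, 2, subspace$mean) %*% subspace$eigenvectors[, seq_len(k), drop = FALSE]
}

#' Root-mean-square inner product between two essential subspaces
#'
#' `RMSIP = sqrt( (1/S) * sum_{n,m<=S} (v_n^i . v_m^j)^2 )` over the first
#' `S` principal components of each subspace. 1 means identical essential
#' subspaces, and for random S-dimensional subspaces of a D-dimensional
#' space the expectation is `sqrt(S/D)`.
#'
#' @param sub_a,sub_b `"essential_subspace"` objects (or bare matrices whose
#'   columns are orthonormal modes) over the same particle selection.
#' @param S Number of components compared (default 20).
#' @return RMSIP in \[0, 1\].
#' @export
rmsip <- function(sub_a, sub_b, S = 20) {
  va <- if (inherits(sub_a, "essential_subspace")) sub_a$eigenvectors else sub_a
  vb <- if (inherits(sub_b, "essential_subspace")) sub_b$eigenvectors else sub_b
  if (nrow(va) != nrow(vb))
    stop("subspaces live in spaces of different dimensionality")
  if (ncol(va) < S || ncol(vb) < S)
    stop("both subspaces need at least S components")
  M <- crossprod(va[, seq_len(S), drop = FALSE], vb[, seq_len(S), drop = FALSE])
  sqrt(sum(M^2) / S)
}

## Bhattacharyya coefficient of two Gaussians fitted to 2D score clouds.
.bhattacharyya_gauss <- function(x1, x2) {
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  s1 <- stats::cov(x1); s2 <- stats::cov(x2)
  s <- (s1 + s2) / 2
  dm <- m1 - m2
  db <- 0.125 * drop(t(dm) %*% solve(s, dm)) +
    0.5 * log(det(s) / sqrt(det(s1) * det(s2)))
  exp(-db)
}

#' Replica-consistency report from PCA projections
#'
#' Assesses whether trajectory replicas sampled the same region of the
#' essential plane. Frames' scores are classified by linear discriminant
#' analysis with the replica label as the class: when replicas are
#' consistent the classifier cannot do better than chance. A pairwise
#' density-overlap coefficient (Bhattacharyya coefficient of per-replica
#' Gaussian fits) is reported alongside; overlap near 1 means consistent
#' replicas, near 0 means disjoint sampling.
#'
#' @param scores `F x k` matrix of projection scores (k >= 2).
#' @param replica_labels Factor or character vector, one label per frame,
#'   >= 2 distinct replicas.
#' @return List with `accuracy` (LDA resubstitution accuracy), `confusion`
#'   (table), `overlap` (symmetric matrix of pairwise Bhattacharyya
#'   coefficients), `n_replicas`.
#' @export
replica_consistency <- function(scores, replica_labels) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("need at least 2 score dimensions")
  lab <- factor(replica_labels)
  if (nlevels(lab) < 2) stop("nothing to classify with a single replica")
  stopifnot(nrow(scores) == length(lab))

  ## identical per-replica distributions (e.g. a duplicated replica) leave
  ## LDA nothing to separate: that is chance-level accuracy, not an error
  fit <- tryCatch(MASS::lda(scores, grouping = lab), error = function(e) NULL)
  if (is.null(fit)) {
    acc <- 1 / nlevels(lab)
    conf <- table(truth = lab, predicted = lab)  # placeholder: no separation
  } else {
    pred <- stats::predict(fit, scores)$class
    conf <- table(truth = lab, predicted = pred)
    acc <- sum(diag(conf)) / sum(conf)
  }

  lev <- levels(lab)
  ov <- matrix(1, nlevels(lab), nlevels(lab), dimnames = list(lev, lev))
  for (i in seq_along(lev)) for (j in seq_along(lev)) if (i < j) {
    bc <- .bhattacharyya_gauss(scores[lab == lev[i], 1:2, drop = FALSE],
                               scores[lab == lev[j], 1:2, drop = FALSE])
    ov[i, j] <- ov[j, i] <- min(bc, 1)
  }
  list(accuracy = acc, confusion = conf, overlap = ov, n_replicas = nlevels(lab))
}
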