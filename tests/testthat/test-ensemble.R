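test_that("superposition removes rigid-body motion and refines monotonically", {
  ## frames differing only by rotation + translation collapse onto each other
  g <- gen_ensemble(n_frames = 40, n_particles = 15, mode_vars = numeric(0),
                    jitter_sd = 0, rigid_motion = TRUE, seed = 11)
  sup <- superpose(g$ens)
  expect_true(sup$superposed)
  ref <- sup$reference
  rmsds <- apply(sup$coords, 1, function(fr) sqrt(mean((fr - ref)^2) * 3))
  expect_lt(max(rmsds), 1e-8)

  ## identical frames: zero displacement everywhere
  co <- array(rep(g$ens$coords[1, , ], each = 5), dim = c(5, 15, 3))
  sup2 <- superpose(ensemble(co))
  expect_lt(max(abs(sweep(sup2$coords, c(2, 3), sup2$reference))), 1e-8)

  ## random ensemble: mean RMSD to the reference non-increasing in rounds
  g2 <- gen_ensemble(n_frames = 30, n_particles = 12, mode_vars = c(2),
                     jitter_sd = 0.5, rigid_motion = TRUE, seed = 12)
  mean_rmsd <- function(rounds) {
    s <- superpose(g2$ens, rounds = rounds)
    ref <- apply(s$coords, c(2, 3), mean)
    mean(apply(s$coords, 1, function(fr)
      sqrt(mean((fr - ref)^2) * 3)))
  }
  m <- vapply(0:3, mean_rmsd, numeric(1))
  expect_true(all(diff(m) <= 1e-8))

  expect_error(superpose(g$ens, selection = 1:2), "underdetermined")
})

test_that("RMSF reproduces closed-form and sampling expectations", {
  ## static ensemble: all zeros
  base <- gen_ensemble(2, 10, numeric(0), 0, seed = 1)$ens$coords[1, , ]
  co <- array(rep(base, each = 4), dim = c(4, 10, 3))
  ens0 <- ensemble(co, superposed = TRUE)
  expect_equal(rmsf(ens0)$rmsf, rep(0, 10))

  ## two-state oscillation +/- a along x with equal occupancy: RMSF = a
  a <- 0.7
  co2 <- co
  co2[c(1, 3), 1, 1] <- co2[c(1, 3), 1, 1] + a
  co2[c(2, 4), 1, 1] <- co2[c(2, 4), 1, 1] - a
  prof <- rmsf(ensemble(co2, superposed = TRUE))
  expect_equal(prof$rmsf[1], a)
  expect_equal(prof$rmsf[-1], rep(0, 9))

  ## isotropic jitter sigma per axis converges to sigma * sqrt(3)
  g <- gen_ensemble(n_frames = 5000, n_particles = 50,
                    mode_vars = numeric(0), jitter_sd = 0.3, seed = 13)
  prof2 <- rmsf(superpose(g$ens), selection_tag = "calpha")
  expect_equal(mean(prof2$rmsf), 0.3 * sqrt(3), tolerance = 0.05)
  expect_identical(attr(prof2, "selection_tag"), "calpha")

  ## unsuperposed input is a state error
  expect_error(rmsf(g$ens), "superposed")
})

test_that("RMSF is invariant under a global rigid transform of the input", {
  g <- gen_ensemble(n_frames = 100, n_particles = 20, mode_vars = c(2, 1),
                    jitter_sd = 0.2, seed = 14)
  r1 <- rmsf(superpose(g$ens))$rmsf
  th <- 0.9
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  co <- g$ens$coords
  for (f in seq_len(dim(co)[1]))
    co[f, , ] <- co[f, , ] %*% rot + matrix(c(5, -3, 10), 20, 3, byrow = TRUE)
  r2 <- rmsf(superpose(ensemble(co)))$rmsf
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("PCA recovers planted modes and conserves total variance", {
  ## single planted mode, no jitter: first eigenvector collinear with it
  g <- gen_ensemble(n_frames = 300, n_particles = 20, mode_vars = c(4),
                    jitter_sd = 0, seed = 15)
  ens <- ensemble(g$ens$coords, superposed = TRUE)  # planted frame, no refit
  sub <- pca_ensemble(ens, warn_rank = FALSE)
  expect_gt(abs(sum(sub$eigenvectors[, 1] * g$truth$modes[, 1])), 0.999)
  expect_lt(sub$eigenvalues[2] / sub$eigenvalues[1], 1e-10)

  ## orthonormality of the eigenvector set
  VtV <- crossprod(sub$eigenvectors)
  expect_lt(max(abs(VtV - diag(nrow(VtV)))), 1e-8)

  ## trace identity: sum of eigenvalues = total coordinate variance
  X <- matrix(ens$coords, nrow = 300)
  expect_equal(sum(sub$eigenvalues), sum(apply(X, 2, var)),
               tolerance = 1e-6)

  ## two orthogonal planted modes with 4:1 variances
  g2 <- gen_ensemble(n_frames = 4000, n_particles = 15, mode_vars = c(4, 1),
                     jitter_sd = 0, seed = 16)
  sub2 <- pca_ensemble(ensemble(g2$ens$coords, superposed = TRUE),
                       warn_rank = FALSE)
  expect_equal(sub2$eigenvalues[1] / sub2$eigenvalues[2], 4, tolerance = 0.15)

  expect_warning(
    pca_ensemble(ensemble(g$ens$coords[1:10, , ], superposed = TRUE)),
    "rank-deficient")
})

test_that("projections satisfy the PCA identities", {
  g <- gen_ensemble(n_frames = 200, n_particles = 10, mode_vars = c(3, 1),
                    jitter_sd = 0.1, seed = 17)
  ens <- superpose(g$ens)
  sub <- pca_ensemble(ens, warn_rank = FALSE)
  sc <- project_frames(ens, sub, k = 5)
  ## score variance along each component equals its eigenvalue
  expect_equal(apply(sc, 2, var), sub$eigenvalues[1:5], tolerance = 1e-8)
  ## the average structure projects to the origin
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  ## full-rank reconstruction returns the original coordinates
  all_sc <- project_frames(ens, sub, k = length(sub$eigenvalues))
  X <- matrix(ens$coords, nrow = 200)
  Xrec <- sweep(all_sc %*% t(sub$eigenvectors), 2, sub$mean, `+`)
  expect_lt(max(abs(X - Xrec)), 1e-8)
})

test_that("RMSIP matches its analytic values and symmetry", {
  set.seed(18)
  q <- random_orthobasis(300, 40)
  a <- q[, 1:20]; b <- q[, 21:40]
  expect_equal(rmsip(a, a), 1, tolerance = 1e-12)
  expect_lt(rmsip(a, b), 1e-12)
  r <- random_orthobasis(300, 20)
  expect_equal(rmsip(a, r), rmsip(r, a), tolerance = 1e-12)
  expect_gte(rmsip(a, r), 0)
  expect_lte(rmsip(a, r), 1)
  ## random-overlap expectation sqrt(S / D)
  m <- mean(replicate(200, rmsip(a, random_orthobasis(300, 20))))
  expect_equal(m, sqrt(20 / 300), tolerance = 0.10)
  expect_error(rmsip(a, random_orthobasis(200, 20)), "dimensionality")
  expect_error(rmsip(a[, 1:5], a, S = 20), "at least S")
})

test_that("RMSIP agrees with the bio3d reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(19)
  a <- random_orthobasis(90, 20)
  b <- random_orthobasis(90, 20)
  ref <- bio3d::rmsip(a, b, subset = 20)$rmsip
  expect_equal(rmsip(a, b), ref, tolerance = 1e-10)
})

test_that("replica consistency separates planted clusters and not null draws", {
  set.seed(20)
  ## same-distribution replicas: near-chance accuracy, high overlap
  sc <- matrix(rnorm(2 * 2000 * 2), ncol = 2)
  lab <- rep(c("r1", "r2"), each = 2000)
  null <- replica_consistency(sc, lab)
  expect_lte(null$accuracy, 0.5 + 0.1)
  expect_gt(null$overlap["r1", "r2"], 0.95)

  ## fully separated clusters: accuracy ~ 1, overlap ~ 0
  sep <- rbind(matrix(rnorm(2000), ncol = 2),
               matrix(rnorm(2000) + 30, ncol = 2))
  lsep <- rep(c("r1", "r2"), each = 1000)
  s <- replica_consistency(sep, lsep)
  expect_gt(s$accuracy, 0.999)
  expect_lt(s$overlap["r1", "r2"], 1e-6)

  ## duplicated replica: overlap exactly 1 between the copies
  dup <- replica_consistency(rbind(sc[1:500, ], sc[1:500, ]),
                             rep(c("a", "b"), each = 500))
  expect_equal(dup$overlap["a", "b"], 1)

  expect_error(replica_consistency(sc, rep("only", 4000)), "single replica")
  expect_error(replica_consistency(sc[, 1, drop = FALSE], lab), "2 score")
})
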