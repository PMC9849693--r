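## Seeded generators emulating each experimental input of the pipeline.
## Every generator is a pure function of its arguments: the same seed gives
## bit-identical output, and the generating truth is returned next to the
## data so recovery tests are self-describing.

## Run code under a local RNG state so generators do not disturb the
## caller's random stream.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a fluorescence titration replicate
#'
#' Emulates titrating 1 uM of a tryptophan-bearing peptide with increasing
#' protein concentrations (default grid 0-4 uM): the noise-free signal
#' follows the exact ligand-depletion isotherm between the endpoints, and
#' Gaussian noise (default sigma = 2% of the signal span) is added.
#'
#' @param kd True dissociation constant, M.
#' @param seed Integer seed.
#' @param titrant_total Concentration grid, M.
#' @param ligand_total Fixed peptide concentration, M.
#' @param y0,ymax Signal endpoints (free / saturated), e.g. emission-peak
#'   wavelengths in nm.
#' @param noise_sd Gaussian signal noise, same unit as the signal; default
#'   2% of `|ymax - y0|`.
#' @param replicate_id Label.
#' @return List with `series` (a [titration_series()]) and `truth`.
#' @export
gen_titration <- function(kd, seed = 1,
                          titrant_total = c(0, 0.1, 0.25, 0.5, 0.75, 1, 1.5,
                                            2, 3, 4) * 1e-6,
                          ligand_total = 1e-6,
                          y0 = 332, ymax = 322,
                          noise_sd = 0.02 * abs(ymax - y0),
                          replicate_id = "rep1") {
  fb <- one_site_model(titrant_total, kd, ligand_total, "quadratic_depletion")
  signal <- .with_seed(seed, y0 + (ymax - y0) * fb +
                         stats::rnorm(length(fb), 0, noise_sd))
  list(series = titration_series(titrant_total, signal, ligand_total,
                                 replicate_id = replicate_id),
       truth = list(kd = kd, y0 = y0, ymax = ymax, noise_sd = noise_sd,
                    seed = seed))
}

#' Simulate an ITC thermogram
#'
#' One-set-of-sites forward heats for the given protocol plus Gaussian
#' heat noise (default sigma = 2% of the largest |heat|) and an optional
#' constant heat-of-dilution offset.
#'
#' @param kd,dh,n_sites True binding parameters (M, kcal/mol, sites).
#' @param seed Integer seed.
#' @param protocol An [itc_protocol()].
#' @param noise_frac Noise sigma as a fraction of `max(|heats|)`.
#' @param dilution_offset Constant added to every injection heat (same unit
#'   as the heats); the matching blank is returned for subtraction.
#' @return List with `thermogram`, `blank` (constant-offset thermogram),
#'   `protocol`, `truth`.
#' @export
gen_itc <- function(kd, dh, n_sites = 1, seed = 1,
                    protocol = itc_protocol(),
                    noise_frac = 0.02, dilution_offset = 0) {
  clean <- itc_forward(protocol, n_sites, kd, dh)
  sdv <- noise_frac * max(abs(clean$heats))
  noisy <- clean
  noisy$heats <- .with_seed(seed, clean$heats + dilution_offset +
                              stats::rnorm(length(clean$heats), 0, sdv))
  blank <- clean
  blank$heats <- rep(dilution_offset, length(clean$heats))
  list(thermogram = noisy, blank = blank, protocol = protocol,
       truth = list(kd = kd, dh = dh, n_sites = n_sites, noise_sd = sdv,
                    dilution_offset = dilution_offset, seed = seed))
}

#' Simulate a set of SPR sensorgrams
#'
#' Pseudo-first-order association (60 s) followed by single-exponential
#' dissociation (300 s) for each analyte concentration, with Gaussian RU
#' noise (default 1 RU). The association amplitude follows the Langmuir
#' steady state `Req = Rmax * C / (C + koff/kon)`.
#'
#' @param kon,koff True rate constants (1/(M s), 1/s).
#' @param concentrations Analyte concentrations, M (one curve each).
#' @param seed Integer seed.
#' @param rmax Saturating response, RU.
#' @param noise_sd RU noise sigma.
#' @param t_assoc,t_dissoc Phase durations, s.
#' @param dt Sampling interval, s.
#' @return List with `curves` (list of [sensorgram()]) and `truth`.
#' @export
gen_sensorgrams <- function(kon, koff,
                            concentrations = c(0.25, 0.5, 1, 2) * 1e-6,
                            seed = 1, rmax = 120, noise_sd = 1,
                            t_assoc = 60, t_dissoc = 300, dt = 0.5) {
  t_a <- seq(0, t_assoc, by = dt)
  t_d <- seq(t_assoc + dt, t_assoc + t_dissoc, by = dt)
  curves <- .with_seed(seed, lapply(concentrations, function(C) {
    kobs <- kon * C + koff
    req <- rmax * C / (C + koff / kon)
    r_a <- req * (1 - exp(-kobs * t_a))
    r0 <- r_a[length(r_a)]
    r_d <- r0 * exp(-koff * (t_d - t_assoc))
    resp <- c(r_a, r_d) + stats::rnorm(length(t_a) + length(t_d), 0, noise_sd)
    sensorgram(c(t_a, t_d), resp, C,
               assoc_window = c(0, t_assoc),
               dissoc_window = c(t_assoc, t_assoc + t_dissoc))
  }))
  list(curves = curves,
       truth = list(kon = kon, koff = koff, rmax = rmax,
                    concentrations = concentrations, noise_sd = noise_sd,
                    seed = seed))
}

## Random orthonormal set of k vectors in n dimensions.
.random_orthonormal <- function(n, k) {
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))[, seq_len(k), drop = FALSE]
}

#' Simulate a fluctuating coordinate ensemble with planted modes
#'
#' Frames are built as `base + sum_m a_m(f) * mode_m + jitter`, with
#' `a_m ~ N(0, var_m)` along planted orthonormal 3P-dimensional modes and
#' isotropic Gaussian jitter on every coordinate. Optionally each frame is
#' additionally rotated/translated rigidly (nuisance motion that
#' superposition must remove).
#'
#' @param n_frames,n_particles Dimensions of the ensemble.
#' @param mode_vars Variances (Angstrom^2) of the planted modes; may be
#'   empty for pure jitter.
#' @param jitter_sd Isotropic per-coordinate jitter sigma, Angstrom
#'   (default 0.3).
#' @param rigid_motion Apply a random rigid-body motion per frame.
#' @param seed Integer seed.
#' @return List with `ens` (an [ensemble()], not superposed) and `truth`
#'   (`modes`: 3P x M orthonormal matrix, `mode_vars`, `base`).
#' @export
gen_ensemble <- function(n_frames = 200, n_particles = 30,
                         mode_vars = c(4, 1), jitter_sd = 0.3,
                         rigid_motion = FALSE, seed = 1) {
  P <- n_particles
  D <- 3 * P
  .with_seed(seed, {
    ## base geometry: loose helix so the structure is not degenerate
    t <- seq_len(P)
    base <- cbind(3 * cos(t / 2), 3 * sin(t / 2), 0.8 * t)
    M <- length(mode_vars)
    modes <- if (M > 0) .random_orthonormal(D, M) else matrix(0, D, 0)
    amps <- if (M > 0)
      matrix(stats::rnorm(n_frames * M), n_frames, M) %*%
        diag(sqrt(mode_vars), M) else matrix(0, n_frames, 0)
    co <- array(0, dim = c(n_frames, P, 3))
    for (f in seq_len(n_frames)) {
      disp <- if (M > 0) matrix(amps[f, , drop = FALSE] %*% t(modes), P, 3)
        else matrix(0, P, 3)
      frame <- base + disp +
        matrix(stats::rnorm(D, 0, jitter_sd), P, 3)
      if (rigid_motion) {
        rot <- .random_rotation()
        frame <- frame %*% rot +
          matrix(stats::rnorm(3, 0, 5), P, 3, byrow = TRUE)
      }
      co[f, , ] <- frame
    }
    list(ens = ensemble(co), truth = list(modes = modes,
                                          mode_vars = mode_vars,
                                          jitter_sd = jitter_sd,
                                          base = base, seed = seed))
  })
}

## Uniform random proper rotation (QR of a Gaussian matrix, det fixed).
.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Simulate frame-wise interaction records with planted structure
#'
#' Each planted pair is present in every frame independently with its
#' specified persistence probability (Bernoulli occupancy). The planted
#' table may include a hydrophobic cluster whose persistence sets the
#' threshold knee, robust communication routes between EF-hand
#' representative residues, and transient distractor pairs.
#'
#' @param pairs `data.frame` with columns `residue_i`, `residue_j`,
#'   `interaction_class`, `persistence` (the per-frame presence
#'   probability).
#' @param n_frames Number of frames to simulate.
#' @param seed Integer seed.
#' @return List with `records` (an [interaction_records()] table),
#'   `n_frames` and `truth` (the planted table).
#' @export
gen_interaction_records <- function(pairs, n_frames = 100, seed = 1) {
  if (nrow(pairs) == 0) {
    rec <- interaction_records(integer(), character(), character(), character())
    return(list(records = rec, n_frames = n_frames, truth = pairs))
  }
  stopifnot(all(pairs$persistence >= 0), all(pairs$persistence <= 1))
  rows <- .with_seed(seed, lapply(seq_len(nrow(pairs)), function(i) {
    present <- which(stats::runif(n_frames) < pairs$persistence[i]) - 1L
    if (length(present) == 0) return(NULL)
    data.frame(frame = present,
               residue_i = pairs$residue_i[i],
               residue_j = pairs$residue_j[i],
               interaction_class = pairs$interaction_class[i],
               stringsAsFactors = FALSE)
  }))
  rows <- do.call(rbind, rows)
  rec <- if (is.null(rows))
    interaction_records(integer(), character(), character(), character())
  else interaction_records(rows$frame, rows$residue_i, rows$residue_j,
                           rows$interaction_class)
  list(records = rec, n_frames = n_frames, truth = pairs)
}

#' Planted EF-hand communication network template
#'
#' Builds the planted-pair table consumed by [gen_interaction_records()]
#' for the discrimination experiments: a persistent hydrophobic cluster
#' (sets the threshold knee at `cluster_persistence`), two node-disjoint
#' two-step communication routes between EF3 (E104) and EF4 (E140), a
#' matching route pair between EF1 (E31) and EF3 that is present in the
#' `"wt"` condition and absent in the `"mutant"` condition, and low-
#' persistence distractor contacts among filler residues.
#'
#' @param condition `"wt"` (both routes) or `"mutant"` (EF1-EF3 route
#'   removed).
#' @param route_persistence Occupancy of route edges.
#' @param cluster_persistence Occupancy of the hydrophobic-cluster edges.
#' @param distractor_persistence Occupancy of transient contacts.
#' @param n_distractors Number of transient filler contacts.
#' @return `data.frame` suitable for [gen_interaction_records()].
#' @export
ef_route_template <- function(condition = c("wt", "mutant"),
                              route_persistence = 0.85,
                              cluster_persistence = 0.45,
                              distractor_persistence = 0.15,
                              n_distractors = 12) {
  condition <- match.arg(condition)
  route <- function(a, b, via1, via2)
    data.frame(residue_i = c(a, via1, a, via2),
               residue_j = c(via1, b, via2, b),
               interaction_class = "hbond",
               persistence = route_persistence,
               stringsAsFactors = FALSE)
  ## hydrophobic core: 6-node clique dissolving together at its persistence
  core <- t(utils::combn(paste0("L", 1:6), 2))
  cluster <- data.frame(residue_i = core[, 1], residue_j = core[, 2],
                        interaction_class = "hydrophobic",
                        persistence = cluster_persistence,
                        stringsAsFactors = FALSE)
  ef34 <- route("E104", "E140", "F92", "M124")
  pairs <- rbind(cluster, ef34)
  if (condition == "wt")
    pairs <- rbind(pairs, route("E31", "E104", "F19", "M51"))
  filler <- paste0("X", seq_len(n_distractors + 1))
  distract <- data.frame(residue_i = filler[seq_len(n_distractors)],
                         residue_j = filler[seq_len(n_distractors) + 1],
                         interaction_class = "electrostatic",
                         persistence = distractor_persistence,
                         stringsAsFactors = FALSE)
  out <- rbind(pairs, distract)
  ## representatives outside any planted route still need to appear in the
  ## record stream: anchor them through transient contacts (below any
  ## plausible threshold, so they stay isolated in the filtered network)
  anchors <- data.frame(residue_i = c("E67", "E31"),
                        residue_j = c("X1", "X3"),
                        interaction_class = "electrostatic",
                        persistence = distractor_persistence,
                        stringsAsFactors = FALSE)
  if (condition == "wt") anchors <- anchors[1, , drop = FALSE]
  rbind(out, anchors)
}
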