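#' @importFrom stats coef sd setNames var
NULL

## Gas constant in kcal mol^-1 K^-1; KD standard state is 1 M throughout.
.R_KCAL <- 1.9872e-3

#' Construct a fluorescence titration series
#'
#' Bundles one replicate of an equilibrium titration in which a fixed
#' concentration of peptide (the fluorophore carrier) is titrated with
#' increasing concentrations of protein, and a scalar spectroscopic
#' observable (here, the emission-peak wavelength of the peptide's single
#' tryptophan) is recorded at each point.
#'
#' @param titrant_total Numeric vector of total titrant (protein)
#'   concentrations in M, non-negative and strictly increasing, at least 5
#'   points.
#' @param signal Numeric vector of the observable at each point (same length).
#' @param ligand_total Fixed total concentration of the observed species (M),
#'   > 0.
#' @param temperature Temperature in K.
#' @param replicate_id Label identifying the replicate.
#' @return An object of class `"titration_series"`.
#' @export
titration_series <- function(titrant_total, signal, ligand_total,
                             temperature = 298.15, replicate_id = "rep1") {
  stopifnot(is.numeric(titrant_total), is.numeric(signal),
            length(titrant_total) == length(signal))
  if (length(titrant_total) < 5)
    stop("a titration series needs at least 5 points")
  if (any(titrant_total < 0))
    stop("titrant concentrations must be non-negative")
  if (any(diff(titrant_total) <= 0))
    stop("titrant concentrations must be strictly increasing")
  if (!is.numeric(ligand_total) || length(ligand_total) != 1 || ligand_total <= 0)
    stop("ligand_total must be a single positive concentration (M)")
  structure(
    list(titrant_total = as.numeric(titrant_total),
         signal = as.numeric(signal),
         ligand_total = as.numeric(ligand_total),
         temperature = as.numeric(temperature),
         replicate_id = as.character(replicate_id)),
    class = "titration_series")
}

#' Fraction of ligand bound from a spectroscopic observable
#'
#' Linear rescaling of a signal between its free-state endpoint `y0` and its
#' saturated-complex endpoint `ymax`: `fb = (signal - y0) / (ymax - y0)`.
#' Values slightly outside \[0, 1\] arising from noise are returned as-is.
#'
#' @param signal Observed signal (scalar or vector).
#' @param y0 Signal of the free species.
#' @param ymax Signal of the saturated complex.
#' @return Fraction bound (dimensionless, unclamped).
#' @export
fraction_bound <- function(signal, y0, ymax) {
  if (!is.finite(y0) || !is.finite(ymax) || ymax == y0)
    stop("degenerate signal span: ymax must differ from y0")
  (signal - y0) / (ymax - y0)
}

#' One-site binding isotherm
#'
#' Predicted fraction of ligand bound at total titrant concentration `x` for
#' a single class of sites with dissociation constant `kd`. Two forms are
#' available:
#' \describe{
#'   \item{`"hyperbolic"`}{`x / (kd + x)` on the *total* titrant
#'     concentration, i.e. titrant depletion by complex formation is
#'     neglected.}
#'   \item{`"quadratic_depletion"`}{the exact 1:1 mass-balance root
#'     `((x + L + kd) - sqrt((x + L + kd)^2 - 4 x L)) / (2 L)`, appropriate
#'     when the fixed ligand concentration `L` is comparable to `kd`.}
#' }
#'
#' @param titrant_total Total titrant concentration(s), M, >= 0.
#' @param kd Dissociation constant, M, > 0.
#' @param ligand_total Fixed ligand concentration, M (used only by the
#'   depletion form).
#' @param model_tag `"hyperbolic"` or `"quadratic_depletion"`.
#' @return Predicted fraction bound in \[0, 1\].
#' @export
one_site_model <- function(titrant_total, kd, ligand_total = NULL,
                           model_tag = c("hyperbolic", "quadratic_depletion")) {
  model_tag <- match.arg(model_tag)
  if (!is.numeric(kd) || any(kd <= 0)) stop("kd must be positive")
  if (any(titrant_total < 0)) stop("concentrations must be non-negative")
  if (model_tag == "hyperbolic")
    return(titrant_total / (kd + titrant_total))
  if (is.null(ligand_total) || ligand_total <= 0)
    stop("quadratic_depletion form needs ligand_total > 0")
  x <- titrant_total
  L <- ligand_total
  s <- x + L + kd
  disc <- pmax(s^2 - 4 * x * L, 0)
  (s - sqrt(disc)) / (2 * L)
}

#' Fit a one-site binding model to a fluorescence titration
#'
#' Nonlinear least-squares estimate of the dissociation constant from one
#' titration replicate (replicates are always fitted individually, never
#' pooled). The signal model is
#' `signal = y0 + (ymax - y0) * fb(x; kd)`, with `fb` given by
#' [one_site_model()]. Endpoints `y0`/`ymax` are free parameters by default
#' (`endpoints = "free"`), or pinned to the first/last observed points
#' (`endpoints = "pinned"`).
#'
#' @param series A [titration_series()].
#' @param model_tag Isotherm form, see [one_site_model()].
#' @param endpoints `"free"` or `"pinned"`.
#' @return An object of class `"binding_fit"`: list with `kd`, `kd_stderr`,
#'   `amplitude` (span of fraction bound covered by the data), `model_tag`,
#'   `residual_norm`, `y0`, `ymax`, `convergence`, `boundary_warning`.
#' @export
fit_fluorescence_titration <- function(series,
                                       model_tag = c("hyperbolic",
                                                     "quadratic_depletion"),
                                       endpoints = c("free", "pinned")) {
  stopifnot(inherits(series, "titration_series"))
  model_tag <- match.arg(model_tag)
  endpoints <- match.arg(endpoints)
  x <- series$titrant_total
  y <- series$signal
  L <- series$ligand_total

  span <- diff(range(y))
  if (span == 0 || span < 1e-12 * max(abs(y), 1))
    stop("fit failure: signal is constant, no binding transition to fit")

  ## crude start: kd at the half-transition point
  fb0 <- (y - y[1]) / (y[length(y)] - y[1])
  i_half <- which.min(abs(fb0 - 0.5))
  kd0 <- max(x[i_half], max(x) * 1e-3, 1e-12)

  pred <- function(x, kd, y0, ymax)
    y0 + (ymax - y0) * one_site_model(x, kd, L, model_tag)

  lower_kd <- max(x[x > 0][1], 1e-15) * 1e-4
  upper_kd <- max(x) * 1e4

  fit <- if (endpoints == "free") {
    try(minpack.lm::nlsLM(
      y ~ pred(x, kd, y0, ymax),
      start = list(kd = kd0, y0 = y[1], ymax = y[length(y)]),
      lower = c(kd = lower_kd, y0 = -Inf, ymax = -Inf),
      upper = c(kd = upper_kd, y0 = Inf, ymax = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  } else {
    y0_pin <- y[1]; ymax_pin <- y[length(y)]
    try(minpack.lm::nlsLM(
      y ~ pred(x, kd, y0_pin, ymax_pin),
      start = list(kd = kd0),
      lower = c(kd = lower_kd), upper = c(kd = upper_kd),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (inherits(fit, "try-error"))
    stop("fit failure: nonlinear least squares did not converge (",
         attr(fit, "condition")$message, ")")

  cf <- coef(fit)
  kd_hat <- unname(cf["kd"])
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))["kd"], error = function(e) NA_real_)
  y0_hat <- if (endpoints == "free") unname(cf["y0"]) else y[1]
  ymax_hat <- if (endpoints == "free") unname(cf["ymax"]) else y[length(y)]
  boundary <- kd_hat <= lower_kd * (1 + 1e-6) || kd_hat >= upper_kd * (1 - 1e-6)
  if (boundary)
    warning("kd estimate at parameter boundary; data may not constrain the fit")

  fb_range <- range(one_site_model(x, kd_hat, L, model_tag))
  structure(
    list(kd = kd_hat,
         kd_stderr = unname(se),
         amplitude = diff(fb_range),
         model_tag = model_tag,
         residual_norm = sqrt(sum(stats::resid(fit)^2)) / abs(ymax_hat - y0_hat),
         y0 = y0_hat, ymax = ymax_hat,
         endpoints = endpoints,
         replicate_id = series$replicate_id,
         convergence = TRUE,
         boundary_warning = boundary),
    class = "binding_fit")
}

#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(KD / 1 M)` with `R = 1.9872e-3` kcal/(mol K); negative for
#' sub-molar dissociation constants.
#'
#' @param kd Dissociation constant, M, > 0.
#' @param temperature Temperature, K, > 0.
#' @return Free energy of binding, kcal/mol.
#' @export
delta_g_from_kd <- function(kd, temperature = 298.15) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("kd must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive")
  .R_KCAL * temperature * log(kd)
}

#' Assemble a thermodynamic record for one variant/peptide pair
#'
#' Combines a measured dissociation constant and binding enthalpy into the
#' full free-energy decomposition `dG = dH - T dS`, storing the entropic term
#' as `minus_tds = -T dS = dG - dH`.
#'
#' @param kd Dissociation constant, M.
#' @param dh Binding enthalpy, kcal/mol.
#' @param temperature Temperature, K.
#' @param n_sites Stoichiometry (sites per molecule), default 1.
#' @param variant Protein variant label (e.g. `"WT"`, `"N97I"`).
#' @param peptide Target peptide label (e.g. `"RyR1"`).
#' @return Object of class `"thermo_record"` with fields `kd`, `dh`, `dg`,
#'   `minus_tds`, `temperature`, `n_sites`, `variant`, `peptide`.
#' @export
make_thermo_record <- function(kd, dh, temperature = 298.15, n_sites = 1,
                               variant = "WT", peptide = "pep") {
  dg <- delta_g_from_kd(kd, temperature)
  structure(
    list(kd = kd, dh = dh, dg = dg, minus_tds = dg - dh,
         temperature = temperature, n_sites = n_sites,
         variant = as.character(variant), peptide = as.character(peptide)),
    class = "thermo_record")
}

#' Relative binding free energy of a variant
#'
#' `ddG = dG(mutant) - dG(wild type)`. Both records must refer to the same
#' peptide and temperature.
#'
#' @param mutant,wildtype Objects of class `"thermo_record"`.
#' @return ddG in kcal/mol; positive means the mutant binds more weakly.
#' @export
ddg <- function(mutant, wildtype) {
  stopifnot(inherits(mutant, "thermo_record"), inherits(wildtype, "thermo_record"))
  if (!identical(mutant$peptide, wildtype$peptide))
    stop("cannot pair records for different peptides: ",
         mutant$peptide, " vs ", wildtype$peptide)
  if (abs(mutant$temperature - wildtype$temperature) > 1e-9)
    stop("cannot pair records at different temperatures")
  mutant$dg - wildtype$dg
}

#' Aggregate per-replicate dissociation constants
#'
#' Summarises individually fitted replicate `kd` values as mean +/- sd
#' (the convention used for reporting apparent affinities), and optionally
#' compares two groups with a Welch t-test.
#'
#' @param kds Numeric vector of per-replicate dissociation constants (M).
#' @param kds_other Optional second group for comparison.
#' @return List with `mean`, `sd`, `n`, and, when `kds_other` is given,
#'   `p_value` from a two-sided Welch t-test.
#' @export
aggregate_kd <- function(kds, kds_other = NULL) {
  out <- list(mean = mean(kds), sd = sd(kds), n = length(kds))
  if (!is.null(kds_other))
    out$p_value <- stats::t.test(kds, kds_other, var.equal = FALSE)$p.value
  out
}

#' @export
print.thermo_record <- function(x, ...) {
  cat(sprintf(
    "<thermo_record> %s-%s  KD = %.3g M  N = %.2f\n  dG = %.2f  dH = %.2f  -TdS = %.2f kcal/mol  (T = %.2f K)\n",
    x$variant, x$peptide, x$kd, x$n_sites, x$dg, x$dh, x$minus_tds,
    x$temperature))
  invisible(x)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> [%s] kd = %.4g M (s.e. %.2g), residual norm %.3g\n",
              x$model_tag, x$kd, x$kd_stderr, x$residual_norm))
  invisible(x)
}
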