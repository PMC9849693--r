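#' Isothermal titration calorimetry protocol
#'
#' Describes one ITC run: a perfusion cell of fixed volume pre-loaded with
#' the binding partner, titrated by a series of syringe injections.
#' Defaults mirror a typical peptide-into-protein experiment: a 200 uL cell
#' with 10 uM protein titrated by thirty 1-uL injections of 125 uM peptide
#' at 25 C.
#'
#' @param cell_volume Cell volume, L.
#' @param cell_conc Concentration of the species in the cell, M.
#' @param syringe_conc Titrant concentration in the syringe, M.
#' @param injection_volumes Vector of injection volumes, L (>= 5 injections).
#' @param temperature Temperature, K.
#' @return Object of class `"itc_protocol"`.
#' @export
itc_protocol <- function(cell_volume = 200e-6, cell_conc = 10e-6,
                         syringe_conc = 125e-6,
                         injection_volumes = rep(1e-6, 30),
                         temperature = 298.15) {
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > 0,
            all(injection_volumes > 0))
  if (length(injection_volumes) < 5)
    stop("an ITC protocol needs at least 5 injections")
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = as.numeric(injection_volumes),
                 temperature = temperature),
            class = "itc_protocol")
}

## Cumulative cell concentrations under the displacement model: each
## injection of volume v instantaneously displaces a fraction v/V0 of the
## (well-mixed) cell content. M = species pre-loaded in cell, X = titrant.
.itc_concentrations <- function(protocol) {
  v <- protocol$injection_volumes
  V0 <- protocol$cell_volume
  d <- 1 - v / V0
  n <- length(v)
  M <- numeric(n)
  X <- numeric(n)
  m_prev <- protocol$cell_conc
  x_prev <- 0
  for (i in seq_len(n)) {
    m_prev <- m_prev * d[i]
    x_prev <- x_prev * d[i] + protocol$syringe_conc * (v[i] / V0)
    M[i] <- m_prev
    X[i] <- x_prev
  }
  list(M = M, X = X, d = d)
}

## Equilibrium complex concentration for N identical independent sites:
## binding-site concentration N*M, quadratic mass-balance root.
.complex_conc <- function(M, X, kd, n_sites) {
  s <- n_sites * M + X + kd
  disc <- pmax(s^2 - 4 * n_sites * M * X, 0)
  (s - sqrt(disc)) / 2
}

#' One-set-of-sites ITC forward model
#'
#' Computes the heat evolved at each injection for a single class of
#' `n_sites` identical independent sites with dissociation constant `kd` and
#' molar binding enthalpy `dh`. Concentrations in the perfusion cell account
#' for displacement: each injection dilutes the existing cell content by
#' `(1 - v/V0)` before adding titrant, and the heat of injection `i` is
#' `V0 * dh * ([MX]_i - [MX]_{i-1} * (1 - v_i/V0))`, i.e. the change in
#' complex moles net of the complex carried out with the displaced volume.
#'
#' @param protocol An [itc_protocol()].
#' @param n_sites Stoichiometry N.
#' @param kd Dissociation constant, M.
#' @param dh Binding enthalpy, kcal per mol of complex.
#' @param unit `"kcal_per_mol_injectant"` (heats normalised to moles of
#'   titrant injected; the scale on which fitting is done) or `"ucal"`
#'   (raw integrated heats).
#' @return Object of class `"thermogram"`: list with `heats`, `unit`,
#'   `n_injections`.
#' @export
itc_forward <- function(protocol, n_sites = 1, kd, dh,
                        unit = c("kcal_per_mol_injectant", "ucal")) {
  stopifnot(inherits(protocol, "itc_protocol"))
  unit <- match.arg(unit)
  if (kd <= 0) stop("kd must be positive")
  cc <- .itc_concentrations(protocol)
  mx <- .complex_conc(cc$M, cc$X, kd, n_sites)
  mx_prev <- c(0, mx[-length(mx)])
  V0 <- protocol$cell_volume
  q_kcal <- V0 * dh * (mx - mx_prev * cc$d)      # kcal per injection
  inj_mol <- protocol$syringe_conc * protocol$injection_volumes
  heats <- switch(unit,
                  kcal_per_mol_injectant = q_kcal / inj_mol,
                  ucal = q_kcal * 1e9)
  structure(list(heats = heats, unit = unit,
                 n_injections = length(heats)),
            class = "thermogram")
}

#' Subtract a dilution blank from a thermogram
#'
#' Element-wise subtraction of the heats measured when titrating into buffer
#' alone (heat of dilution) from the binding thermogram.
#'
#' @param thermogram,blank Objects of class `"thermogram"` (or bare numeric
#'   heat vectors) of equal length and unit.
#' @return Corrected `"thermogram"`.
#' @export
subtract_dilution <- function(thermogram, blank) {
  h <- if (inherits(thermogram, "thermogram")) thermogram$heats else thermogram
  b <- if (inherits(blank, "thermogram")) blank$heats else blank
  if (length(h) != length(b))
    stop("thermogram and blank have different numbers of injections")
  out <- if (inherits(thermogram, "thermogram")) thermogram else
    structure(list(heats = h, unit = "kcal_per_mol_injectant",
                   n_injections = length(h)), class = "thermogram")
  out$heats <- h - b
  out
}

#' Fit a one-set-of-sites model to an ITC thermogram
#'
#' Least-squares estimation of the stoichiometry `N`, dissociation constant
#' `kd` and binding enthalpy `dh` from integrated injection heats, using the
#' forward model of [itc_forward()]. The derived free-energy decomposition
#' is returned as a [make_thermo_record()].
#'
#' The Wiseman `c`-parameter (`cell_conc / kd`) is reported; estimates with
#' `c` outside roughly 1-1000 carry a reliability warning.
#'
#' @param thermogram A `"thermogram"` in kcal per mol of injectant (heats in
#'   `"ucal"` are converted using the protocol).
#' @param protocol The matching [itc_protocol()].
#' @param variant,peptide Labels stored in the resulting record.
#' @param discard_first Drop the first injection before fitting (common
#'   practice for diffusion across the syringe tip); default `FALSE`.
#' @return A `"thermo_record"` with an extra `c_parameter` field and fit
#'   diagnostics (`kd_stderr`, `dh_stderr`, `residual_norm`).
#' @export
fit_itc <- function(thermogram, protocol, variant = "WT", peptide = "pep",
                    discard_first = FALSE) {
  stopifnot(inherits(thermogram, "thermogram"), inherits(protocol, "itc_protocol"))
  h <- thermogram$heats
  if (thermogram$unit == "ucal")
    h <- h * 1e-9 / (protocol$syringe_conc * protocol$injection_volumes)
  keep <- seq_along(h)
  if (discard_first) keep <- keep[-1]
  if (length(keep) < 10)
    stop("need at least 10 informative injections")
  if (all(abs(h) < 1e-12))
    stop("fit failure: all heats are zero")

  obs <- h[keep]
  ## kd spans orders of magnitude: fit log10(kd) for conditioning
  fwd <- function(n_sites, lkd, dh)
    itc_forward(protocol, n_sites, 10^lkd, dh)$heats[keep]

  ## starts: dh from the initial plateau, N from the equivalence point,
  ## kd from the cell concentration (c ~ 10)
  dh0 <- h[1]
  molar_ratio <- cumsum(protocol$syringe_conc * protocol$injection_volumes) /
    (protocol$cell_conc * protocol$cell_volume)
  i_eq <- which.min(abs(abs(h) - abs(dh0) / 2))
  n0 <- max(molar_ratio[i_eq], 0.2)
  starts <- expand.grid(lkd0 = log10(protocol$cell_conc) - c(0.5, 1.5, 2.5, 3.5),
                        n0 = n0, dh0 = dh0)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nlsLM(
      obs ~ fwd(n_sites, lkd, dh),
      start = list(n_sites = starts$n0[s], lkd = starts$lkd0[s],
                   dh = starts$dh0[s]),
      lower = c(n_sites = 0.05, lkd = -13, dh = -1e3),
      upper = c(n_sites = 20, lkd = 0, dh = 1e3),
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("fit failure: ITC model did not converge from any start")
  fit <- best$fit

  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    setNames(rep(NA_real_, 3), names(cf)))
  ## delta-method s.e. for kd from the log-scale fit
  se["kd"] <- 10^cf["lkd"] * log(10) * se["lkd"]
  rec <- make_thermo_record(kd = unname(10^cf["lkd"]), dh = unname(cf["dh"]),
                            temperature = protocol$temperature,
                            n_sites = unname(cf["n_sites"]),
                            variant = variant, peptide = peptide)
  rec$kd_stderr <- unname(se["kd"])
  rec$dh_stderr <- unname(se["dh"])
  rec$residual_norm <- sqrt(sum(stats::resid(fit)^2)) / max(abs(obs))
  rec$c_parameter <- protocol$cell_conc / rec$kd
  if (rec$c_parameter < 1 || rec$c_parameter > 1000)
    warning(sprintf(
      "c-parameter %.3g outside 1-1000: kd estimate may be unreliable",
      rec$c_parameter))
  rec
}
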