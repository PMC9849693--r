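#' Construct an SPR sensorgram
#'
#' One binding curve from a surface plasmon resonance experiment: response
#' units (RU, 1 RU = 1 pg/mm^2) versus time, collected while a fixed
#' concentration of analyte flows over the immobilised partner
#' (association phase) and then while buffer alone flows (dissociation
#' phase). Default windows follow a 60 s association / 300 s dissociation
#' protocol.
#'
#' @param time Time, s, strictly increasing.
#' @param response Response, RU.
#' @param analyte_conc Analyte concentration during association, M.
#' @param assoc_window Numeric `c(t_start, t_end)` of the association phase.
#' @param dissoc_window Numeric `c(t_start, t_end)` of the dissociation
#'   phase; must start at or after the association window ends.
#' @return Object of class `"sensorgram"`.
#' @export
sensorgram <- function(time, response, analyte_conc,
                       assoc_window = c(0, 60),
                       dissoc_window = c(60, 360)) {
  stopifnot(is.numeric(time), is.numeric(response),
            length(time) == length(response))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (assoc_window[2] > dissoc_window[1])
    stop("association window must precede the dissociation window")
  structure(list(time = as.numeric(time), response = as.numeric(response),
                 analyte_conc = analyte_conc,
                 assoc_window = assoc_window, dissoc_window = dissoc_window),
            class = "sensorgram")
}

#' Fit the dissociation phase of a sensorgram
#'
#' Single-exponential decay `R(t) = R0 * exp(-koff * (t - t0))` fitted to the
#' dissociation window by nonlinear least squares; `t0` is the window start.
#' An optional constant drift offset can be floated.
#'
#' @param sgram A [sensorgram()].
#' @param offset Float a constant baseline offset (default `FALSE`).
#' @return List with `koff` (1/s), `koff_stderr`, `r0` (RU at the start of
#'   dissociation), and `residual_norm`.
#' @export
fit_dissociation <- function(sgram, offset = FALSE) {
  stopifnot(inherits(sgram, "sensorgram"))
  w <- sgram$dissoc_window
  sel <- sgram$time >= w[1] & sgram$time <= w[2]
  if (sum(sel) < 20) stop("need at least 20 points in the dissociation window")
  t <- sgram$time[sel] - w[1]
  r <- sgram$response[sel]
  if (r[1] <= 0) stop("dissociation phase must start from a positive response")
  n <- length(r)
  if (mean(r[t > max(t) / 2]) >= mean(r[t <= max(t) / 2]))
    stop("fit failure: dissociation signal does not decay")

  ## log-linear start (guard against non-positive responses)
  pos <- r > max(r) * 1e-6
  lf <- stats::lm(log(r[pos]) ~ t[pos])
  koff0 <- unname(max(-coef(lf)[2], 1e-6))
  r00 <- unname(exp(coef(lf)[1]))

  fit <- if (offset) {
    try(minpack.lm::nlsLM(r ~ r0 * exp(-koff * t) + c0,
                          start = list(r0 = r00, koff = koff0, c0 = 0),
                          lower = c(r0 = 0, koff = 1e-8, c0 = -Inf)),
        silent = TRUE)
  } else {
    try(minpack.lm::nlsLM(r ~ r0 * exp(-koff * t),
                          start = list(r0 = r00, koff = koff0),
                          lower = c(r0 = 0, koff = 1e-8)),
        silent = TRUE)
  }
  if (inherits(fit, "try-error"))
    stop("fit failure: dissociation fit did not converge")
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(cf)), names(cf)))
  list(koff = unname(cf["koff"]), koff_stderr = unname(se["koff"]),
       r0 = unname(cf["r0"]),
       residual_norm = sqrt(mean(stats::resid(fit)^2)))
}

#' Fit the association phase of a sensorgram given koff
#'
#' Pseudo-first-order association: `R(t) = Req * (1 - exp(-kobs * t))` with
#' `kobs = kon * C + koff`. The dissociation rate comes first (from
#' [fit_dissociation()]); `kon` is then `(kobs - koff) / C`.
#'
#' @param sgram A [sensorgram()] with `analyte_conc > 0`.
#' @param koff Dissociation rate constant, 1/s.
#' @return List with `kobs`, `kon` (1/(M s)), `req` (RU), `kobs_stderr`.
#' @export
fit_association <- function(sgram, koff) {
  stopifnot(inherits(sgram, "sensorgram"))
  C <- sgram$analyte_conc
  if (is.null(C) || !is.finite(C) || C <= 0)
    stop("association fit needs a positive analyte concentration")
  w <- sgram$assoc_window
  sel <- sgram$time >= w[1] & sgram$time <= w[2]
  t <- sgram$time[sel] - w[1]
  r <- sgram$response[sel]

  req0 <- max(r[length(r)], max(r) * 0.5, 1e-3)
  kobs0 <- max(koff * 2, 3 / max(t))
  fit <- try(minpack.lm::nlsLM(r ~ req * (1 - exp(-kobs * t)),
                               start = list(req = req0, kobs = kobs0),
                               lower = c(req = 0, kobs = 1e-8)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("fit failure: association fit did not converge")
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(cf)), names(cf)))
  kobs <- unname(cf["kobs"])
  if (kobs <= koff)
    stop("negative kon: fitted kobs <= koff ",
         "(check analyte concentration labels or the koff estimate)")
  list(kobs = kobs, kon = (kobs - koff) / C, req = unname(cf["req"]),
       kobs_stderr = unname(se["kobs"]))
}

#' Two-stage 1:1 Langmuir analysis of a sensorgram series
#'
#' Applies the sequential procedure to a concentration series: the
#' single-exponential dissociation of each curve is fitted first to obtain
#' `koff`, then the pseudo-first-order association is fitted with `koff`
#' fixed to obtain `kon`. Per-curve rate constants are aggregated as
#' mean +/- s.e.m., and the kinetic dissociation constant is reported as
#' `kd_kinetic = koff / kon` of the means.
#'
#' @param curves List of [sensorgram()] objects (>= 3 usable concentrations).
#' @param koff_mode `"per_curve"` (default, each curve contributes its own
#'   dissociation fit) or `"global"` (a single koff, the mean of per-curve
#'   estimates, is fixed for every association fit).
#' @return Object of class `"kinetic_fit"`: `kon`, `kon_sem`, `koff`,
#'   `koff_sem`, `kd_kinetic`, `n_curves`, and the per-curve table
#'   `per_curve`.
#' @export
fit_langmuir_series <- function(curves, koff_mode = c("per_curve", "global")) {
  koff_mode <- match.arg(koff_mode)
  stopifnot(length(curves) >= 3)
  dis <- lapply(curves, fit_dissociation)
  koffs <- vapply(dis, `[[`, numeric(1), "koff")
  koff_fixed <- mean(koffs)
  kons <- vapply(seq_along(curves), function(i) {
    kf <- if (koff_mode == "global") koff_fixed else koffs[i]
    fit_association(curves[[i]], kf)$kon
  }, numeric(1))

  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  kon_m <- mean(kons); koff_m <- mean(koffs)
  structure(
    list(kon = kon_m, kon_sem = sem(kons),
         koff = koff_m, koff_sem = sem(koffs),
         kd_kinetic = koff_m / kon_m,
         n_curves = length(curves),
         per_curve = data.frame(
           conc_M = vapply(curves, `[[`, numeric(1), "analyte_conc"),
           kon = kons, koff = koffs)),
    class = "kinetic_fit")
}

#' Fold-change between two kinetic fits
#'
#' Ratio of mean rate constants (variant over reference) with first-order
#' error propagation of the s.e.m.s, plus Welch t-tests on the per-curve
#' rate constants.
#'
#' @param variant,reference Objects of class `"kinetic_fit"`.
#' @return List with `kon_ratio`, `kon_ratio_se`, `koff_ratio`,
#'   `koff_ratio_se`, `p_kon`, `p_koff`.
#' @export
kinetic_fold_change <- function(variant, reference) {
  stopifnot(inherits(variant, "kinetic_fit"), inherits(reference, "kinetic_fit"))
  ratio_se <- function(a, sa, b, sb) {
    r <- a / b
    list(ratio = r, se = abs(r) * sqrt((sa / a)^2 + (sb / b)^2))
  }
  kon <- ratio_se(variant$kon, variant$kon_sem, reference$kon, reference$kon_sem)
  koff <- ratio_se(variant$koff, variant$koff_sem,
                   reference$koff, reference$koff_sem)
  list(kon_ratio = kon$ratio, kon_ratio_se = kon$se,
       koff_ratio = koff$ratio, koff_ratio_se = koff$se,
       p_kon = stats::t.test(variant$per_curve$kon,
                             reference$per_curve$kon)$p.value,
       p_koff = stats::t.test(variant$per_curve$koff,
                              reference$per_curve$koff)$p.value)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> n = %d curves\n  kon  = %.3g +/- %.2g 1/(M s)\n  koff = %.3g +/- %.2g 1/s\n  kinetic KD = %.3g M\n",
    x$n_curves, x$kon, x$kon_sem, x$koff, x$koff_sem, x$kd_kinetic))
  invisible(x)
}
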