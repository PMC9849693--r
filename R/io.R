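## File-format layer and end-to-end drivers. All tables are plain CSV/TSV
## with concentrations in molar, energies in kcal/mol, temperatures in K.

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Read fluorescence titration replicates from CSV
#'
#' Expects columns `titrant_M`, `signal` and optionally `replicate`;
#' returns one [titration_series()] per replicate.
#'
#' @param path CSV path.
#' @param ligand_total Fixed ligand concentration, M.
#' @param temperature Temperature, K.
#' @return Named list of `"titration_series"`.
#' @export
read_titration_csv <- function(path, ligand_total = 1e-6,
                               temperature = 298.15) {
  df <- .read_csv_checked(path, c("titrant_M", "signal"))
  if (is.null(df$replicate)) df$replicate <- "rep1"
  lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$titrant_M), ]
    titration_series(d$titrant_M, d$signal, ligand_total, temperature,
                     replicate_id = d$replicate[1])
  })
}

#' Write a titration series (or list of them) to CSV
#' @param series A `"titration_series"` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(titrant_M = s$titrant_total, signal = s$signal,
               replicate = s$replicate_id)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an ITC injection table from CSV
#'
#' Expects columns `inj_vol_uL` and `heat_ucal` (integrated heat per
#' injection, microcalories).
#'
#' @param path CSV path.
#' @param cell_volume,cell_conc,syringe_conc,temperature Protocol fields
#'   (see [itc_protocol()]); may also be supplied via `protocol_json`.
#' @param protocol_json Optional JSON file with the protocol fields.
#' @return List with `thermogram` (unit `"ucal"`) and `protocol`.
#' @export
read_itc_csv <- function(path, cell_volume = 200e-6, cell_conc = 10e-6,
                         syringe_conc = 125e-6, temperature = 298.15,
                         protocol_json = NULL) {
  df <- .read_csv_checked(path, c("inj_vol_uL", "heat_ucal"))
  if (!is.null(protocol_json)) {
    pj <- jsonlite::read_json(protocol_json, simplifyVector = TRUE)
    known <- c("cell_volume", "cell_conc", "syringe_conc", "temperature")
    bad <- setdiff(names(pj), known)
    if (length(bad))
      stop("unknown protocol key(s): ", paste(bad, collapse = ", "))
    for (k in names(pj)) assign(k, pj[[k]])
  }
  proto <- itc_protocol(cell_volume, cell_conc, syringe_conc,
                        injection_volumes = df$inj_vol_uL * 1e-6,
                        temperature = temperature)
  tg <- structure(list(heats = df$heat_ucal, unit = "ucal",
                       n_injections = nrow(df)), class = "thermogram")
  list(thermogram = tg, protocol = proto)
}

#' Read SPR sensorgrams from CSV
#'
#' Expects columns `time_s`, `RU`, `conc_M` and `phase`
#' (`"association"`/`"dissociation"`); one curve per concentration.
#'
#' @param path CSV path.
#' @return List of [sensorgram()] objects.
#' @export
read_sensorgram_csv <- function(path) {
  df <- .read_csv_checked(path, c("time_s", "RU", "conc_M", "phase"))
  bad <- setdiff(unique(df$phase), c("association", "dissociation"))
  if (length(bad))
    stop("schema error: unknown phase label(s) ", paste(bad, collapse = ", "))
  lapply(split(df, df$conc_M), function(d) {
    d <- d[order(d$time_s), ]
    t_switch <- if (any(d$phase == "association"))
      max(d$time_s[d$phase == "association"])
    else min(d$time_s[d$phase == "dissociation"])
    sensorgram(d$time_s, d$RU, d$conc_M[1],
               assoc_window = c(min(d$time_s), t_switch),
               dissoc_window = c(t_switch, max(d$time_s)))
  })
}

#' Write sensorgrams to CSV
#' @param curves List of `"sensorgram"` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensorgram_csv <- function(curves, path) {
  if (inherits(curves, "sensorgram")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(s)
    data.frame(time_s = s$time, RU = s$response, conc_M = s$analyte_conc,
               phase = ifelse(s$time <= s$assoc_window[2],
                              "association", "dissociation"))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read frame-wise interaction records from CSV
#'
#' Expects columns `frame`, `residue_i`, `residue_j`, `interaction_class`.
#'
#' @param path CSV path.
#' @return An [interaction_records()] table.
#' @export
read_interaction_csv <- function(path) {
  df <- .read_csv_checked(path,
                          c("frame", "residue_i", "residue_j",
                            "interaction_class"))
  bad <- which(is.na(suppressWarnings(as.integer(df$frame))))
  if (length(bad))
    stop("malformed row(s) in ", basename(path), " at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": frame is not an integer")
  interaction_records(df$frame, df$residue_i, df$residue_j,
                      df$interaction_class)
}

#' Read a coordinate ensemble from a per-frame XYZ table
#'
#' Expects columns `frame`, `particle`, `x`, `y`, `z` (Angstrom); every
#' frame must list the same particles.
#'
#' @param path CSV path.
#' @return An [ensemble()].
#' @export
read_xyz_csv <- function(path) {
  df <- .read_csv_checked(path, c("frame", "particle", "x", "y", "z"))
  frames <- split(df, df$frame)
  labels <- frames[[1]]$particle
  co <- array(NA_real_, dim = c(length(frames), length(labels), 3))
  for (f in seq_along(frames)) {
    d <- frames[[f]]
    idx <- match(labels, d$particle)
    if (anyNA(idx) || nrow(d) != length(labels))
      stop("frame ", names(frames)[f], " does not list the same particles")
    co[f, , ] <- as.matrix(d[idx, c("x", "y", "z")])
  }
  ensemble(co, particle_labels = as.character(labels))
}

#' Write an ensemble to a per-frame XYZ table
#' @param ens An [ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_csv <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  d <- dim(ens$coords)
  df <- do.call(rbind, lapply(seq_len(d[1]), function(f)
    data.frame(frame = f, particle = ens$particle_labels,
               x = ens$coords[f, , 1], y = ens$coords[f, , 2],
               z = ens$coords[f, , 3])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-model PDB into an ensemble
#'
#' Thin adapter over `bio3d::read.pdb(..., multi = TRUE)`; tolerant of
#' missing occupancy/B-factor fields. Selects alpha-carbons by default.
#'
#' @param path PDB path.
#' @param atom_names Atom names to keep (default `"CA"`; `NULL` keeps all).
#' @return An [ensemble()] with labels `chain:resno:atom`.
#' @export
read_ensemble_pdb <- function(path, atom_names = "CA") {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB ensembles requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  sel <- if (is.null(atom_names)) seq_len(nrow(pdb$atom))
    else which(pdb$atom$elety %in% atom_names)
  if (length(sel) == 0) stop("no atoms match the requested names")
  xyz <- pdb$xyz[, as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel)),
                 drop = FALSE]
  FF <- nrow(xyz)
  P <- length(sel)
  co <- array(NA_real_, dim = c(FF, P, 3))
  for (f in seq_len(FF))
    co[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  labels <- paste(pdb$atom$chain[sel], pdb$atom$resno[sel],
                  pdb$atom$elety[sel], sep = ":")
  ensemble(co, particle_labels = labels)
}

#' Thermodynamic table from measured dissociation constants and enthalpies
#'
#' Applies the free-energy decomposition to a table of per-variant,
#' per-peptide calorimetric measurements: computes `dG = RT ln KD`,
#' `-T dS = dG - dH`, and `ddG = dG(variant) - dG(WT)` within each peptide.
#'
#' @param measurements `data.frame` with columns `variant`, `peptide`,
#'   `kd_nM`, `dh_kcal_mol`. Defaults to the packaged table of published
#'   ITC measurements for CaM wild type and the arrhythmia-associated N97I
#'   and Q135P variants binding the RyR1/RyR2 CaMBD2 peptides.
#' @param temperature Temperature, K.
#' @param reference Variant used as the ddG reference (default `"WT"`).
#' @return `data.frame` with `variant`, `peptide`, `kd_nM`, `dh`, `dg`,
#'   `minus_tds`, `ddg` (NA for the reference rows).
#' @export
thermo_table <- function(measurements = NULL, temperature = 298.15,
                         reference = "WT") {
  if (is.null(measurements)) {
    path <- system.file("extdata", "itc_thermo.csv", package = "camryr")
    measurements <- .read_csv_checked(path,
                                      c("variant", "peptide", "kd_nM",
                                        "dh_kcal_mol"))
  }
  recs <- lapply(seq_len(nrow(measurements)), function(i)
    make_thermo_record(kd = measurements$kd_nM[i] * 1e-9,
                       dh = measurements$dh_kcal_mol[i],
                       temperature = temperature,
                       variant = measurements$variant[i],
                       peptide = measurements$peptide[i]))
  out <- data.frame(
    variant = measurements$variant, peptide = measurements$peptide,
    kd_nM = measurements$kd_nM,
    dh = vapply(recs, `[[`, numeric(1), "dh"),
    dg = vapply(recs, `[[`, numeric(1), "dg"),
    minus_tds = vapply(recs, `[[`, numeric(1), "minus_tds"),
    ddg = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    if (out$variant[i] == reference) next
    j <- which(measurements$variant == reference &
                 measurements$peptide == out$peptide[i])
    if (length(j) == 1) out$ddg[i] <- ddg(recs[[i]], recs[[j]])
  }
  out
}

#' End-to-end EF-hand communication discrimination trial
#'
#' One seeded pass through the full structure-network pipeline on synthetic
#' interaction records: plant the network template for the given condition,
#' sample Bernoulli frame occupancy, compute persistences, select the
#' persistence threshold from the hydrophobic-cluster curve, build the PSN
#' (EF-hand representatives forced in as nodes), and score EF-hand
#' communication robustness.
#'
#' @param condition `"wt"` (robust EF1-EF3 and EF3-EF4 routes) or
#'   `"mutant"` (EF1-EF3 route broken).
#' @param seed Integer seed.
#' @param n_frames Frames of simulated occupancy.
#' @param ... Passed to [ef_route_template()].
#' @return The `"cr_matrix"` with extra fields `pt_selection` and
#'   `condition`.
#' @export
run_ef_discrimination <- function(condition = c("wt", "mutant"), seed = 1,
                                  n_frames = 100, ...) {
  condition <- match.arg(condition)
  ef_map <- c(EF1 = "E31", EF2 = "E67", EF3 = "E104", EF4 = "E140")
  tpl <- ef_route_template(condition, ...)
  sim <- gen_interaction_records(tpl, n_frames = n_frames, seed = seed)
  pm <- persistence_from_records(sim$records, n_frames = sim$n_frames)
  pt_sel <- select_pt(pm)
  psn <- build_psn(pm, pt = pt_sel$pt, nodes = unname(ef_map))
  cr <- ef_hand_cr(psn, ef_map = ef_map)
  cr$pt_selection <- pt_sel
  cr$condition <- condition
  cr
}

#' Write a result bundle as JSON
#'
#' Serialises a named list of results together with the configuration and
#' seed that produced it, so every run is reproducible from its output.
#'
#' @param results Named list.
#' @param path Output JSON path.
#' @param config Named list echoed verbatim into the bundle.
#' @param seed Seed used for the run.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(results, path, config = list(), seed = NA) {
  bundle <- list(package = "camryr",
                 version = as.character(utils::packageVersion("camryr")),
                 seed = seed, config = config, results = results)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
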