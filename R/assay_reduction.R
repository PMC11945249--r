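# Reduction of fluorimetric microplate readings to enzyme activities.
#
# Sediment suspensions quench 4-MUB / 7-AMC fluorescence to a degree that
# varies between samples, so every sample carries its own quenched standard
# (sample + buffer + fluorophore). The reduction is the standard
# fluorimetric-assay algebra: net RFU corrected by the per-sample quench
# coefficient and the substrate control, scaled by the emission coefficient
# of the reference standard, then converted to nmol per g dry sediment per
# hour from the suspension geometry and incubation time.

WELL_ROLES <- c("assay", "quench_standard", "substrate_control",
                "reference_standard", "homogenate_control", "abiotic_control")
ENZYMES <- c("bg", "cbh", "nag", "lap", "ap")

#' Assay parameters
#'
#' Physical constants of one plate run. Defaults follow the common
#' lake-sediment protocol: 1 g dry sediment in 10 mL autoclaved in-situ
#' water, 200 uL of suspension per well, 30 min dark incubation, substrates
#' at a final concentration of 0.2 mM.
#'
#' @param sediment_dry_mass Dry sediment mass, g.
#' @param suspension_volume Suspension volume, mL.
#' @param well_aliquot_volume Suspension aliquot per well, mL.
#' @param incubation_time Incubation time, h.
#' @param substrate_final_conc Substrate concentration in the well, mM
#'   (metadata; not used in the unit conversion).
#' @param standard_amount nmol of 4-MUB or 7-AMC in a standard well.
#' @param temperature_c Incubation temperature, degrees C (metadata).
#' @param fluorophore `"MUB"` or `"AMC"` (metadata).
#' @param excitation_emission Length-2 numeric, nm (metadata;
#'   364/445 for AMC, 365/455 for MUB).
#' @return A list of class `assay_params`.
#' @export
assay_params <- function(sediment_dry_mass = 1, suspension_volume = 10,
                         well_aliquot_volume = 0.2, incubation_time = 0.5,
                         substrate_final_conc = 0.2, standard_amount = 0.5,
                         temperature_c = 15, fluorophore = c("MUB", "AMC"),
                         excitation_emission = c(365, 455)) {
  fluorophore <- match.arg(fluorophore)
  p <- list(sediment_dry_mass = sediment_dry_mass,
            suspension_volume = suspension_volume,
            well_aliquot_volume = well_aliquot_volume,
            incubation_time = incubation_time,
            substrate_final_conc = substrate_final_conc,
            standard_amount = standard_amount,
            temperature_c = temperature_c,
            fluorophore = fluorophore,
            excitation_emission = excitation_emission)
  for (nm in c("sediment_dry_mass", "suspension_volume",
               "well_aliquot_volume", "incubation_time",
               "substrate_final_conc", "standard_amount")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      ev_config_error(sprintf("assay parameter '%s' must be a single positive number", nm))
  }
  structure(p, class = "assay_params")
}

#' One plate reading (a sample x enzyme block of wells)
#'
#' @param sample_id Sample label.
#' @param enzyme One of `"bg"`, `"cbh"`, `"nag"`, `"lap"`, `"ap"`.
#' @param assay >= 3 RFU readings, sample + buffer + substrate.
#' @param quench_standard RFU, sample + buffer + fluorophore standard.
#' @param substrate_control RFU, water + buffer + substrate.
#' @param reference_standard RFU, water + buffer + fluorophore standard.
#' @param homogenate_control Optional RFU, sample + buffer (no substrate);
#'   treated as 0 when absent.
#' @param abiotic_control Optional RFU, autoclaved sediment + buffer +
#'   substrate.
#' @param params An [assay_params()] object.
#' @return A list of class `plate_reading`.
#' @export
plate_reading <- function(sample_id, enzyme, assay, quench_standard,
                          substrate_control, reference_standard,
                          homogenate_control = NULL, abiotic_control = NULL,
                          params = assay_params()) {
  enzyme <- match.arg(tolower(enzyme), ENZYMES)
  if (!inherits(params, "assay_params"))
    ev_config_error("'params' must come from assay_params()")
  if (length(assay) < 3L)
    ev_data_error("at least three assay replicate wells are required")
  for (nm in c("assay", "quench_standard", "substrate_control",
               "reference_standard")) {
    check_numeric(get(nm), nm, nonnegative = TRUE)
  }
  if (!is.null(homogenate_control))
    check_numeric(homogenate_control, "homogenate_control", nonnegative = TRUE)
  if (!is.null(abiotic_control))
    check_numeric(abiotic_control, "abiotic_control", nonnegative = TRUE)
  structure(list(sample_id = as.character(sample_id), enzyme = enzyme,
                 assay = assay, quench_standard = quench_standard,
                 substrate_control = substrate_control,
                 reference_standard = reference_standard,
                 homogenate_control = homogenate_control,
                 abiotic_control = abiotic_control, params = params),
            class = "plate_reading")
}

.homog_mean <- function(reading) {
  if (is.null(reading$homogenate_control)) 0 else mean(reading$homogenate_control)
}

#' Per-sample quench coefficient
#'
#' `q = (mean(quench standard) - mean(homogenate control)) /
#' mean(reference standard)`: the fraction of standard fluorescence
#' surviving the sediment matrix. Values near 1 mean no quenching.
#'
#' @param reading A [plate_reading()].
#' @return A single number in (0, Inf); errors (class `ev_assay_error`) if
#'   the coefficient is not positive (fully quenched or mislabelled wells).
#' @export
quench_coefficient <- function(reading) {
  stopifnot(inherits(reading, "plate_reading"))
  ref <- mean(reading$reference_standard)
  if (ref <= 0) ev_assay_error("reference standard mean must be > 0")
  q <- (mean(reading$quench_standard) - .homog_mean(reading)) / ref
  if (q <= 0)
    ev_assay_error(sprintf(
      "quench coefficient <= 0 for sample '%s' enzyme '%s': standard fully quenched or wells mislabelled",
      reading$sample_id, reading$enzyme))
  q
}

#' Emission coefficient (RFU per nmol)
#'
#' Mean reference-standard fluorescence divided by the nmol of fluorophore
#' in a standard well.
#'
#' @param reading A [plate_reading()].
#' @return RFU per nmol.
#' @export
emission_coefficient <- function(reading) {
  stopifnot(inherits(reading, "plate_reading"))
  ref <- mean(reading$reference_standard)
  if (ref <= 0) ev_assay_error("reference standard mean must be > 0")
  ref / reading$params$standard_amount
}

#' Net quench-corrected fluorescence
#'
#' `(mean(assay) - mean(homogenate control)) / q - mean(substrate control)`,
#' with the abiotic hydrolysis signal
#' `mean(abiotic control) - mean(substrate control)` additionally removed
#' when abiotic-control wells are present. May be negative at this stage;
#' clamping happens in [plate_activity()].
#'
#' @param reading A [plate_reading()].
#' @return Net RFU.
#' @export
net_fluorescence <- function(reading) {
  q <- quench_coefficient(reading)
  net <- (mean(reading$assay) - .homog_mean(reading)) / q -
    mean(reading$substrate_control)
  if (!is.null(reading$abiotic_control))
    net <- net - (mean(reading$abiotic_control) - mean(reading$substrate_control))
  net
}

#' Enzyme activity from one plate reading
#'
#' Converts net fluorescence to nmol g^-1 h^-1:
#' `net / emission_coefficient * (suspension_volume / well_aliquot_volume) /
#' (sediment_dry_mass * incubation_time)`. Negative activities are clamped
#' to 0 and flagged `NEGATIVE_CLAMPED`; assay-replicate coefficients of
#' variation above `cv_threshold` are flagged `HIGH_CV`; quench
#' coefficients below `low_quench` are flagged `LOW_QUENCH`.
#'
#' @param reading A [plate_reading()].
#' @param cv_threshold QC threshold on the replicate CV (default 0.3).
#' @param low_quench QC threshold on the quench coefficient (default 0.2).
#' @return One-row data.frame: `sample_id`, `enzyme`, `activity`,
#'   `quench_coefficient`, `replicate_cv`, `qc_flags` (`;`-separated).
#' @export
plate_activity <- function(reading, cv_threshold = 0.3, low_quench = 0.2) {
  q <- quench_coefficient(reading)
  e <- emission_coefficient(reading)
  p <- reading$params
  net <- net_fluorescence(reading)
  act <- net / e * (p$suspension_volume / p$well_aliquot_volume) /
    (p$sediment_dry_mass * p$incubation_time)
  m <- mean(reading$assay)
  cv <- if (m > 0) stats::sd(reading$assay) / m else NA_real_
  flags <- character()
  if (act < 0) { act <- 0; flags <- c(flags, "NEGATIVE_CLAMPED") }
  if (is.finite(cv) && cv > cv_threshold) flags <- c(flags, "HIGH_CV")
  if (q < low_quench) flags <- c(flags, "LOW_QUENCH")
  data.frame(sample_id = reading$sample_id, enzyme = reading$enzyme,
             activity = act, quench_coefficient = q,
             replicate_cv = cv,
             qc_flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Read a long-format plate table
#'
#' Schema: `sample_id,enzyme,well_role,rfu` with `well_role` one of
#' assay, quench_standard, substrate_control, reference_standard,
#' homogenate_control, abiotic_control.
#'
#' @param path CSV path.
#' @return data.frame; errors (class `ev_data_error`) on schema violations.
#' @export
read_plate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "enzyme", "well_role", "rfu")
  if (!all(need %in% names(df)))
    ev_data_error(sprintf("plate table must have columns %s",
                          paste(need, collapse = ", ")))
  df$enzyme <- tolower(df$enzyme)
  bad <- setdiff(unique(df$well_role), WELL_ROLES)
  if (length(bad))
    ev_data_error(sprintf("unknown well_role value(s): %s",
                          paste(bad, collapse = ", ")))
  bad_e <- setdiff(unique(df$enzyme), ENZYMES)
  if (length(bad_e))
    ev_data_error(sprintf("unknown enzyme value(s): %s",
                          paste(bad_e, collapse = ", ")))
  df
}

#' Reduce a set of plate readings to activities
#'
#' Accepts either a list of [plate_reading()] objects or a long-format
#' plate data.frame (`sample_id,enzyme,well_role,rfu`). Produces the QC
#' table (one row per reading) and the wide activity table for samples with
#' all five enzymes; samples with missing enzymes are excluded with a
#' warning.
#'
#' @param readings List of `plate_reading` objects, or a long plate
#'   data.frame.
#' @param params [assay_params()] used when `readings` is a data.frame.
#' @param ... Passed to [plate_activity()].
#' @return A list with elements `qc` (long QC data.frame), `activities`
#'   (wide `sample_id,bg,cbh,nag,lap,ap` data.frame) and `excluded`
#'   (character vector of incomplete samples).
#' @export
reduce_plate_set <- function(readings, params = assay_params(), ...) {
  if (is.data.frame(readings))
    readings <- .plate_df_to_readings(readings, params)
  if (length(readings) == 0L)
    return(list(qc = data.frame(),
                activities = data.frame(sample_id = character(), bg = numeric(),
                                        cbh = numeric(), nag = numeric(),
                                        lap = numeric(), ap = numeric()),
                excluded = character()))
  keys <- vapply(readings, function(r) paste(r$sample_id, r$enzyme, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys))
    ev_data_error(sprintf("duplicate (sample, enzyme) reading(s): %s",
                          paste(unique(sub("\r", "/", keys[duplicated(keys)])),
                                collapse = ", ")))
  qc <- do.call(rbind, lapply(readings, plate_activity, ...))
  wide <- stats::reshape(qc[c("sample_id", "enzyme", "activity")],
                         idvar = "sample_id", timevar = "enzyme",
                         direction = "wide")
  names(wide) <- sub("^activity\\.", "", names(wide))
  complete <- wide$sample_id[stats::complete.cases(wide[intersect(ENZYMES, names(wide))])]
  has_all <- all(ENZYMES %in% names(wide))
  if (!has_all) complete <- character()
  excluded <- setdiff(wide$sample_id, complete)
  if (length(excluded))
    warning(sprintf("sample(s) missing one or more enzymes, excluded from activity table: %s",
                    paste(excluded, collapse = ", ")), call. = FALSE)
  act <- wide[wide$sample_id %in% complete, , drop = FALSE]
  for (e in ENZYMES) if (!e %in% names(act)) act[[e]] <- numeric(nrow(act))
  act <- act[c("sample_id", ENZYMES)]
  rownames(act) <- NULL
  list(qc = qc, activities = act, excluded = excluded)
}

.plate_df_to_readings <- function(df, params) {
  need <- c("sample_id", "enzyme", "well_role", "rfu")
  if (!all(need %in% names(df)))
    ev_data_error(sprintf("plate table must have columns %s",
                          paste(need, collapse = ", ")))
  bad <- setdiff(unique(df$well_role), WELL_ROLES)
  if (length(bad))
    ev_data_error(sprintf("unknown well_role value(s): %s",
                          paste(bad, collapse = ", ")))
  if (nrow(df) == 0L) return(list())
  pieces <- split(df, list(df$sample_id, df$enzyme), drop = TRUE)
  lapply(unname(pieces), function(p) {
    grab <- function(role) {
      v <- p$rfu[p$well_role == role]
      if (length(v)) v else NULL
    }
    plate_reading(sample_id = p$sample_id[1], enzyme = p$enzyme[1],
                  assay = grab("assay") %||% numeric(),
                  quench_standard = grab("quench_standard") %||% numeric(),
                  substrate_control = grab("substrate_control") %||% numeric(),
                  reference_standard = grab("reference_standard") %||% numeric(),
                  homogenate_control = grab("homogenate_control"),
                  abiotic_control = grab("abiotic_control"),
                  params = params)
  })
}
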