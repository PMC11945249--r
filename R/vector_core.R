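# Ecoenzymatic vector analysis.
#
# Microbial investment in carbon-, nitrogen- and phosphorus-acquiring
# hydrolases is summarised by two proportions,
#   x = C / (C + P)   and   y = C / (C + N),
# where C = BG + CBH, N = NAG + LAP, P = AP. The point (x, y) deviates from
# the global 1:1:1 reference (0.5, 0.5); its distance from the origin
# (vector length) indexes relative C limitation and its angle from the
# x-axis separates N limitation (< 45 deg) from P limitation (> 45 deg).

#' Enzyme group totals
#'
#' Sums the five terminal hydrolase activities into C-, N- and
#' P-acquisition groups. By default the C group is BG + CBH (both act on
#' cellulose); set `c_enzymes = "bg"` for the single-enzyme convention used
#' in part of the literature. The N group is NAG + LAP and the P group AP.
#'
#' @param bg,cbh,nag,lap,ap Nonnegative enzyme activities
#'   (nmol g^-1 h^-1): beta-1,4-glucosidase, cellobiohydrolase,
#'   beta-1,4-N-acetylglucosaminidase, leucine aminopeptidase, alkaline
#'   phosphatase. Vectors are recycled to a common length by the usual
#'   rules only if scalar.
#' @param c_enzymes Character subset of `c("bg", "cbh")` forming the
#'   C-acquisition numerator.
#' @return A data.frame with columns `c_total`, `n_total`, `p_total`.
#'   Errors (class `ev_domain_error`) if any group total is zero, naming
#'   the zero group.
#' @examples
#' group_activities(bg = 2, cbh = 1, nag = 1, lap = 2, ap = 3)
#' @export
group_activities <- function(bg, cbh, nag, lap, ap,
                             c_enzymes = c("bg", "cbh")) {
  c_enzymes <- match.arg(c_enzymes, c("bg", "cbh"), several.ok = TRUE)
  for (nm in c("bg", "cbh", "nag", "lap", "ap"))
    check_numeric(get(nm), nm, nonnegative = TRUE)
  c_total <- if (identical(c_enzymes, "bg")) bg + 0 * cbh else
             if (identical(c_enzymes, "cbh")) cbh + 0 * bg else bg + cbh
  n_total <- nag + lap
  p_total <- ap + 0 * c_total # recycle to common length
  if (any(c_total <= 0)) ev_domain_error("C group zero: bg + cbh must be > 0")
  if (any(n_total <= 0)) ev_domain_error("N group zero: nag + lap must be > 0")
  if (any(p_total <= 0)) ev_domain_error("P group zero: ap must be > 0")
  data.frame(c_total = c_total, n_total = n_total, p_total = p_total)
}

#' Stoichiometric enzyme ratios
#'
#' @param c_total,n_total,p_total Strictly positive group totals, e.g. from
#'   [group_activities()].
#' @return A data.frame with columns `x = c/(c+p)` and `y = c/(c+n)`, both
#'   in (0, 1).
#' @export
enzyme_ratios <- function(c_total, n_total, p_total) {
  check_numeric(c_total, "c_total", positive = TRUE)
  check_numeric(n_total, "n_total", positive = TRUE)
  check_numeric(p_total, "p_total", positive = TRUE)
  data.frame(x = c_total / (c_total + p_total),
             y = c_total / (c_total + n_total))
}

#' Vector length (microbial C limitation)
#'
#' `sqrt(x^2 + y^2)`: distance of the enzyme-ratio point from the origin.
#' Longer vectors mean relatively larger investment in C acquisition,
#' i.e. stronger microbial carbon limitation.
#'
#' @param x,y Enzyme ratios in (0, 1).
#' @return Numeric vector in (0, sqrt(2)).
#' @export
vector_length <- function(x, y) {
  .check_ratio(x, "x"); .check_ratio(y, "y")
  sqrt(x^2 + y^2)
}

#' Vector angle in degrees (microbial N vs P limitation)
#'
#' The angle of the point (x, y) measured from the positive x-axis,
#' `atan2(y, x) * 180 / pi`, in (0, 90) for valid ratios. Angles above 45
#' degrees indicate P limitation (severity grows with the angle), below 45
#' N limitation (severity grows as the angle shrinks): a high phosphatase
#' investment depresses x and pushes the point above the 1:1 line.
#'
#' @param x,y Enzyme ratios in (0, 1).
#' @return Angle in degrees.
#' @export
vector_angle <- function(x, y) {
  check_numeric(x, "x"); check_numeric(y, "y")
  if (any(x <= 0)) ev_domain_error("vector angle undefined for x <= 0")
  .check_ratio(x, "x"); .check_ratio(y, "y")
  atan2(y, x) * 180 / pi
}

.check_ratio <- function(v, name) {
  check_numeric(v, name)
  if (any(v <= 0) || any(v >= 1))
    ev_domain_error(sprintf("ratio '%s' must lie strictly in (0, 1)", name))
  invisible(v)
}

#' Classify N vs P limitation from the vector angle
#'
#' @param angle_deg Angle in degrees, strictly inside (0, 90).
#' @param note If `TRUE`, return a data.frame with a per-sample severity
#'   note instead of a bare character vector.
#' @return Character vector with values `"N_LIMITED"` (angle < 45),
#'   `"P_LIMITED"` (> 45) or `"BALANCED"` (exactly 45).
#' @export
classify_limitation <- function(angle_deg, note = FALSE) {
  check_numeric(angle_deg, "angle_deg")
  if (any(angle_deg <= 0) || any(angle_deg >= 90))
    ev_domain_error("angle_deg must lie strictly in (0, 90)")
  cls <- ifelse(angle_deg > 45, "P_LIMITED",
         ifelse(angle_deg < 45, "N_LIMITED", "BALANCED"))
  if (!note) return(cls)
  sev <- ifelse(cls == "P_LIMITED",
                sprintf("P limitation, severity increases with angle (+%.2f deg above 45)",
                        angle_deg - 45),
         ifelse(cls == "N_LIMITED",
                sprintf("N limitation, severity increases as angle decreases (-%.2f deg below 45)",
                        45 - angle_deg),
                "balanced N/P investment at exactly 45 deg"))
  data.frame(angle_deg = angle_deg, limitation_class = cls, severity = sev)
}

#' Metabolic-limitation vector statistics from enzyme activities
#'
#' Composes [group_activities()], [enzyme_ratios()], [vector_length()],
#' [vector_angle()] and [classify_limitation()] over a per-sample activity
#' table.
#'
#' @param activities A data.frame with columns `bg`, `cbh`, `nag`, `lap`,
#'   `ap` and optionally `sample_id`.
#' @param c_enzymes Passed to [group_activities()].
#' @param ln_ratios If `TRUE`, ratios are computed on natural-log
#'   transformed activities (an alternative convention; all activities must
#'   then exceed 1 so the logs are positive). Default `FALSE`: plain
#'   proportions of untransformed activities.
#' @return A data.frame with columns `sample_id`, `x`, `y`,
#'   `vector_length`, `vector_angle_deg`, `limitation_class`.
#' @examples
#' mml_from_activities(data.frame(bg = 2, cbh = 1, nag = 1, lap = 2, ap = 3))
#' @export
mml_from_activities <- function(activities, c_enzymes = c("bg", "cbh"),
                                ln_ratios = FALSE) {
  need <- c("bg", "cbh", "nag", "lap", "ap")
  if (!is.data.frame(activities) || !all(need %in% names(activities)))
    ev_data_error("'activities' must be a data.frame with columns bg, cbh, nag, lap, ap")
  if (nrow(activities) == 0L)
    return(data.frame(sample_id = character(), x = numeric(), y = numeric(),
                      vector_length = numeric(), vector_angle_deg = numeric(),
                      limitation_class = character()))
  id <- activities$sample_id %||% paste0("S", seq_len(nrow(activities)))
  g <- group_activities(activities$bg, activities$cbh, activities$nag,
                        activities$lap, activities$ap, c_enzymes = c_enzymes)
  if (ln_ratios) {
    if (any(g <= 1))
      ev_domain_error("ln_ratios = TRUE needs all group totals > 1")
    g <- log(g)
  }
  r <- enzyme_ratios(g$c_total, g$n_total, g$p_total)
  ang <- vector_angle(r$x, r$y)
  data.frame(sample_id = as.character(id), x = r$x, y = r$y,
             vector_length = vector_length(r$x, r$y),
             vector_angle_deg = ang,
             limitation_class = classify_limitation(ang),
             stringsAsFactors = FALSE)
}

#' Read a per-sample activity table
#'
#' Expects the CSV schema `sample_id,bg,cbh,nag,lap,ap` with activities in
#' nmol g^-1 h^-1.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_activity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "bg", "cbh", "nag", "lap", "ap")
  if (!all(need %in% names(df)))
    ev_data_error(sprintf("activity table must have columns %s",
                          paste(need, collapse = ", ")))
  df
}
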