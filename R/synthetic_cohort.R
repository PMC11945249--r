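# Synthetic lake-sediment cohorts.
#
# The generator emulates a high-altitude lake survey: 25 lakes in four
# salinity classes (9 freshwater / 8 subsaline / 6 hyposaline /
# 2 mesosaline) sampled at 1-4 sites each for 44 sites in total, spanning
# 0.13-31.06 permil. A standardized Gaussian latent system ties ln
# salinity (s), vector length, vector angle and SOC together so that the
# published effect sizes are reproduced by construction:
#
#   ln length ~ alpha s + sqrt(1 - alpha^2) u,  alpha = sqrt(R2_sal_len)
#   angle     = mean_angle - sqrt(R2_sal_ang) sd (s) + sqrt(1-R2) sd (eps)
#   SOC latent S = beta s + gamma u + delta v
#
# with (beta, gamma) solved numerically so that the marginal SOC-length
# R-squared and the partial R-squared controlling salinity match their
# configured targets (negative branch: SOC falls as C limitation rises).

#' Cohort generator configuration
#'
#' All knobs of the synthetic lake-sediment cohort, with defaults matching
#' the published survey structure and effect sizes. Feasibility is
#' validated here (class `ev_config_error` on violation).
#'
#' @param lakes_per_class Named counts of lakes per salinity class
#'   (must sum to 25 with the default site allocation to keep the default
#'   cohort at 44 sites; other structures are allowed).
#' @param sites_per_lake Named list; for each class, an integer vector of
#'   sites per lake (each 1-4), one entry per lake.
#' @param salinity_anchor Length-2 numeric: cohort minimum and maximum site
#'   salinity (permil) enforced when `anchor = TRUE`.
#' @param anchor Logical; monotonically rescale (in log space) the
#'   freshwater and mesosaline tails so the cohort spans exactly
#'   `salinity_anchor`.
#' @param r2_salinity_length,r2_salinity_angle,r2_soc_length_marginal,r2_soc_length_partial
#'   Calibration targets in `[0, 1)`; the partial target must not exceed
#'   the marginal one.
#' @param mean_angle_deg,angle_sd_deg Cohort mean and SD of the vector
#'   angle (degrees). The mean is the published cohort-level mean; the SD
#'   is a realism choice (8 deg keeps nearly all angles well inside the
#'   5-85 deg truncation window).
#' @param mean_length,length_sd_ln Mean vector length and SD of ln length.
#'   The survey's own cohort mean is not published; 0.9 sits inside the
#'   span of published cross-lake means (0.68-1.13) and, together with the
#'   ~10% ln spread, keeps nearly all draws inside the geometric
#'   admissibility cap `length < 1/cos(angle)` so truncation-resampling
#'   stays immaterial (see the methods vignette).
#' @param soc_mean,soc_sd_ln SOC mean (g kg^-1) and lognormal spread.
#' @param ph_mean,ph_sd,ph_salinity_corr Sediment pH model: Gaussian with
#'   the given mean/SD, correlated with standardized ln salinity.
#' @param c_activity_meanlog,c_activity_sdlog,c_activity_salinity_slope
#'   Lognormal model of total C-acquisition activity (nmol g^-1 h^-1);
#'   the slope on s makes C-acquiring activity rise with salinity.
#' @param bg_share_shape,nag_share_shape Beta shape pairs splitting the C
#'   group into BG/CBH and the N group into NAG/LAP.
#' @param nutrient_trends Named list of `c(mean, slope, sdlog)` rows for
#'   the lognormal nutrient/diversity covariates (slope is on standardized
#'   ln salinity).
#' @param site_jitter_sdlog SD of the lognormal site-within-lake salinity
#'   jitter (kept small so sites stay within their lake's class band).
#' @param angle_bounds Truncation window for generated angles (degrees).
#' @param plate_noise_sd Default RFU noise for [simulate_plate()].
#' @param quench_range Range from which per-sample quench coefficients are
#'   drawn when simulating plates.
#' @return List of class `gradient_config`.
#' @export
gradient_config <- function(
    lakes_per_class = c(FRESHWATER = 9, SUBSALINE = 8, HYPOSALINE = 6,
                        MESOSALINE = 2),
    sites_per_lake = list(FRESHWATER = c(4, 3, 2, 2, 1, 1, 1, 1, 1),
                          SUBSALINE  = c(3, 2, 2, 2, 1, 1, 1, 1),
                          HYPOSALINE = c(3, 2, 2, 1, 1, 1),
                          MESOSALINE = c(3, 2)),
    salinity_anchor = c(0.13, 31.06), anchor = TRUE,
    r2_salinity_length = 0.23, r2_salinity_angle = 0.44,
    r2_soc_length_marginal = 0.21, r2_soc_length_partial = 0.09,
    mean_angle_deg = 39.40, angle_sd_deg = 8,
    mean_length = 0.9, length_sd_ln = 0.10,
    soc_mean = 42.7, soc_sd_ln = 0.5,
    ph_mean = 9.0, ph_sd = 0.5, ph_salinity_corr = 0.7,
    c_activity_meanlog = log(100), c_activity_sdlog = 0.8,
    c_activity_salinity_slope = 0.3,
    bg_share_shape = c(6, 4), nag_share_shape = c(5, 5),
    nutrient_trends = list(
      tn        = c(mean = 4.81,  slope = -0.10, sdlog = 0.30),
      tp        = c(mean = 0.56,  slope =  0.10, sdlog = 0.30),
      doc       = c(mean = 0.50,  slope =  0.00, sdlog = 0.40),
      nh4       = c(mean = 10.0,  slope =  0.40, sdlog = 0.40),
      no3       = c(mean = 5.0,   slope =  0.40, sdlog = 0.40),
      no2       = c(mean = 0.50,  slope =  0.30, sdlog = 0.40),
      dip       = c(mean = 2.0,   slope =  0.40, sdlog = 0.40),
      water_tn  = c(mean = 1.05,  slope =  0.30, sdlog = 0.30),
      water_tp  = c(mean = 0.368, slope =  0.50, sdlog = 0.30),
      water_chla = c(mean = 1.33, slope =  0.00, sdlog = 0.50),
      bacterial_richness = c(mean = 3000, slope = -0.30, sdlog = 0.25),
      fungal_richness    = c(mean = 300,  slope = -0.30, sdlog = 0.30)),
    site_jitter_sdlog = 0.04, angle_bounds = c(5, 85),
    plate_noise_sd = 20, quench_range = c(0.5, 0.9)) {
  cfg <- mget(names(formals()))
  cls <- names(cfg$lakes_per_class)
  if (!setequal(cls, SALINITY_LEVELS))
    ev_config_error("lakes_per_class must name the four salinity classes")
  for (k in cls) {
    spl <- cfg$sites_per_lake[[k]]
    if (length(spl) != cfg$lakes_per_class[[k]])
      ev_config_error(sprintf("sites_per_lake[['%s']] must have one entry per lake", k))
    if (any(spl < 1 | spl > 4))
      ev_config_error("sites per lake must be between 1 and 4")
  }
  for (nm in c("r2_salinity_length", "r2_salinity_angle",
               "r2_soc_length_marginal", "r2_soc_length_partial")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v >= 1)
      ev_config_error(sprintf("'%s' must lie in [0, 1)", nm))
  }
  if (cfg$r2_soc_length_partial > cfg$r2_soc_length_marginal)
    ev_config_error("infeasible targets: r2_soc_length_partial exceeds r2_soc_length_marginal")
  if (cfg$salinity_anchor[1] >= cfg$salinity_anchor[2] ||
      cfg$salinity_anchor[1] <= 0)
    ev_config_error("salinity_anchor must be an increasing positive pair")
  if (abs(cfg$ph_salinity_corr) > 1)
    ev_config_error("ph_salinity_corr must lie in [-1, 1]")
  structure(cfg, class = "gradient_config")
}

#' Solve the latent covariance coefficients
#'
#' With standardized iid latents s, u, v the generator uses
#' `L = alpha s + sqrt(1 - alpha^2) u` for ln vector length and
#' `S = beta s + gamma u + delta v` for the SOC latent. `alpha` is
#' `sqrt(r2_salinity_length)` in closed form; `(beta, gamma)` (both
#' negative: SOC decreases with both salinity and C limitation) solve
#'
#'   `cor(S, L)^2   = r2_soc_length_marginal`
#'   `gamma^2 / (1 - beta^2) = r2_soc_length_partial`
#'
#' by a univariate root search, and `delta = sqrt(1 - beta^2 - gamma^2)`.
#'
#' @param config A [gradient_config()].
#' @return List with `alpha`, `beta`, `gamma`, `delta`.
#' @export
solve_covariance <- function(config = gradient_config()) {
  stopifnot(inherits(config, "gradient_config"))
  alpha <- sqrt(config$r2_salinity_length)
  m <- config$r2_soc_length_marginal
  p <- config$r2_soc_length_partial
  if (m == 0) {
    if (p > 0) ev_config_error("infeasible targets: zero marginal but positive partial R2")
    return(list(alpha = alpha, beta = 0, gamma = 0, delta = 1))
  }
  ca <- sqrt(1 - alpha^2)
  # gamma(beta) on the negative branch; cor(S, L) = alpha beta + ca gamma
  g_of_b <- function(beta) -sqrt(p * (1 - beta^2))
  f <- function(beta) alpha * beta + ca * g_of_b(beta) + sqrt(m)
  lo <- -1 + 1e-12
  if (f(lo) * f(0) > 0)
    ev_config_error(paste("infeasible targets: no (beta, gamma) solves the",
                          "marginal/partial SOC moment equations on the negative branch"))
  beta <- stats::uniroot(f, c(lo, 0), tol = 1e-12)$root
  gamma <- g_of_b(beta)
  rest <- 1 - beta^2 - gamma^2
  if (rest < 0)
    ev_config_error("infeasible targets: beta^2 + gamma^2 exceeds 1")
  list(alpha = alpha, beta = beta, gamma = gamma, delta = sqrt(rest))
}

# Class bands in permil (left-closed).
.class_bands <- function(anchor) {
  list(FRESHWATER = c(anchor[1], 0.5), SUBSALINE = c(0.5, 3),
       HYPOSALINE = c(3, 20), MESOSALINE = c(20, anchor[2]))
}

# Monotone log-linear rescale of v so min(v) = lo (keep max) or
# max(v) = hi (keep min).
.rescale_log <- function(v, lo = NULL, hi = NULL) {
  lv <- log(v)
  if (length(v) == 1L) return(exp(log(lo %||% hi)))
  a <- min(lv); b <- max(lv)
  if (a == b) return(v)
  target_a <- if (is.null(lo)) a else log(lo)
  target_b <- if (is.null(hi)) b else log(hi)
  exp(target_a + (lv - a) * (target_b - target_a) / (b - a))
}

#' Generate a synthetic lake-sediment cohort
#'
#' Draws lake salinities per class (log-uniform within the class band),
#' jitters them to site level, optionally anchors the cohort span, then
#' generates the coupled latent system (pH, vector length, vector angle,
#' SOC), nutrient and diversity covariates, and per-site enzyme activities
#' that invert exactly to the drawn vector statistics.
#'
#' @param config A [gradient_config()].
#' @param seed Integer seed; the cohort is deterministic given
#'   (config, seed).
#' @param n_sites Optional total number of sites. When given, class site
#'   proportions of the default allocation are preserved (largest-remainder
#'   rounding) and lakes of 1-4 sites are created per class as needed; when
#'   `NULL` (default) the configured 25-lake / 44-site structure is used.
#' @return A data.frame with one row per site: identifiers, salinity and
#'   class, pH, nutrients (incl. derived ratios), diversity covariates,
#'   the five enzyme activities and the derived vector statistics.
#'   Attribute `resample_count` records how many latent draws were rejected
#'   by the (0,1) ratio / angle-window truncation contract.
#' @export
generate_cohort <- function(config = gradient_config(), seed = 1,
                            n_sites = NULL) {
  stopifnot(inherits(config, "gradient_config"))
  set.seed(as.integer(seed))
  coefs <- solve_covariance(config)
  bands <- .class_bands(config$salinity_anchor)

  # --- structure: lakes and sites ----------------------------------------
  if (is.null(n_sites)) {
    sites_per_lake <- config$sites_per_lake[SALINITY_LEVELS]
  } else {
    base <- vapply(config$sites_per_lake[SALINITY_LEVELS], sum, 0)
    quota <- base / sum(base) * n_sites
    cnt <- floor(quota)
    rem <- n_sites - sum(cnt)
    if (rem > 0) {
      up <- order(quota - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[up] <- cnt[up] + 1
    }
    sites_per_lake <- lapply(stats::setNames(SALINITY_LEVELS, SALINITY_LEVELS),
                             function(k) {
      left <- cnt[[k]]; sizes <- integer()
      pat <- c(4L, 3L, 2L, 1L)
      i <- 1L
      while (left > 0) {
        take <- min(pat[(i - 1L) %% 4L + 1L], left)
        sizes <- c(sizes, take); left <- left - take; i <- i + 1L
      }
      sizes
    })
  }
  lake_class <- rep(SALINITY_LEVELS, vapply(sites_per_lake, length, 0L))
  lake_sizes <- unlist(sites_per_lake, use.names = FALSE)
  n_lakes <- length(lake_sizes)
  lake_id <- sprintf("L%02d", seq_len(n_lakes))

  # --- salinity: lake draws, site jitter, anchoring ----------------------
  lake_sal <- numeric(n_lakes)
  for (k in SALINITY_LEVELS) {
    idx <- which(lake_class == k)
    b <- bands[[k]]
    lake_sal[idx] <- exp(stats::runif(length(idx), log(b[1]), log(b[2])))
  }
  site_lake <- rep(seq_len(n_lakes), lake_sizes)
  n <- length(site_lake)
  sal <- lake_sal[site_lake] *
    exp(stats::rnorm(n, 0, config$site_jitter_sdlog))
  site_class <- lake_class[site_lake]
  # clamp jitter back inside the class band (margin keeps bands left-closed)
  for (k in SALINITY_LEVELS) {
    idx <- which(site_class == k)
    b <- bands[[k]]
    sal[idx] <- pmin(pmax(sal[idx], b[1]), b[2] * 0.9999)
  }
  if (isTRUE(config$anchor)) {
    fw <- which(site_class == "FRESHWATER")
    ms <- which(site_class == "MESOSALINE")
    if (length(fw)) sal[fw] <- .rescale_log(sal[fw], lo = config$salinity_anchor[1])
    if (length(ms)) sal[ms] <- .rescale_log(sal[ms], hi = config$salinity_anchor[2])
  }
  s <- as.numeric(scale(log(sal)))

  # --- coupled latent system with truncation-by-resampling ---------------
  r2a <- config$r2_salinity_angle
  draw <- function(idx) {
    u <- stats::rnorm(length(idx))
    eps <- stats::rnorm(length(idx))
    angle <- config$mean_angle_deg - sqrt(r2a) * config$angle_sd_deg * s[idx] +
      sqrt(1 - r2a) * config$angle_sd_deg * eps
    L <- coefs$alpha * s[idx] + sqrt(1 - coefs$alpha^2) * u
    len <- config$mean_length *
      exp(config$length_sd_ln * L - config$length_sd_ln^2 / 2)
    list(u = u, angle = angle, len = len)
  }
  u <- numeric(n); angle <- numeric(n); len <- numeric(n)
  todo <- seq_len(n); resamples <- 0L; iter <- 0L
  while (length(todo)) {
    d <- draw(todo)
    x <- d$len * cos(d$angle * pi / 180)
    y <- d$len * sin(d$angle * pi / 180)
    ok <- d$angle > config$angle_bounds[1] & d$angle < config$angle_bounds[2] &
      x > 0 & x < 1 & y > 0 & y < 1
    u[todo[ok]] <- d$u[ok]; angle[todo[ok]] <- d$angle[ok]
    len[todo[ok]] <- d$len[ok]
    resamples <- resamples + sum(!ok)
    todo <- todo[!ok]
    iter <- iter + 1L
    if (iter > 1000L)
      ev_config_error("latent truncation rejected > 1000 rounds; widen angle/length settings")
  }
  v <- stats::rnorm(n)
  S <- coefs$beta * s + coefs$gamma * u + coefs$delta * v
  soc <- config$soc_mean * exp(config$soc_sd_ln * S - config$soc_sd_ln^2 / 2)

  # --- pH, nutrients, diversity ------------------------------------------
  ph <- config$ph_mean + config$ph_sd *
    (config$ph_salinity_corr * s +
       sqrt(1 - config$ph_salinity_corr^2) * stats::rnorm(n))
  ln_trend <- function(row) {
    row[["mean"]] * exp(row[["slope"]] * s +
                          row[["sdlog"]] * stats::rnorm(n) -
                          row[["sdlog"]]^2 / 2)
  }
  nut <- lapply(config$nutrient_trends, ln_trend)

  # --- activities ---------------------------------------------------------
  c_total <- exp(config$c_activity_meanlog +
                   config$c_activity_salinity_slope * s +
                   config$c_activity_sdlog * stats::rnorm(n))
  bg_share <- stats::rbeta(n, config$bg_share_shape[1], config$bg_share_shape[2])
  nag_share <- stats::rbeta(n, config$nag_share_shape[1], config$nag_share_shape[2])
  acts <- latent_to_activities(len, angle, c_total, bg_share, nag_share)

  # DCA1 stand-ins: community turnover driven by pH and salinity
  zph <- as.numeric(scale(ph))
  bacterial_dca1 <- 0.6 * zph + 0.4 * s + 0.6 * stats::rnorm(n)
  fungal_dca1 <- 0.4 * zph + 0.5 * s + 0.7 * stats::rnorm(n)

  out <- data.frame(
    sample_id = sprintf("%s_S%02d", lake_id[site_lake],
                        unlist(lapply(lake_sizes, seq_len))),
    lake_id = lake_id[site_lake],
    salinity = sal,
    salinity_class = factor(site_class, levels = SALINITY_LEVELS,
                            ordered = TRUE),
    ph = ph,
    soc = soc,
    tn = nut$tn, tp = nut$tp, doc = nut$doc,
    nh4 = nut$nh4, no3 = nut$no3, no2 = nut$no2, dip = nut$dip,
    soc_tn = soc / nut$tn, soc_tp = soc / nut$tp, tn_tp = nut$tn / nut$tp,
    water_tn = nut$water_tn, water_tp = nut$water_tp,
    water_tn_tp = nut$water_tn / nut$water_tp,
    water_chla = nut$water_chla,
    bacterial_richness = nut$bacterial_richness,
    fungal_richness = nut$fungal_richness,
    bacterial_dca1 = bacterial_dca1, fungal_dca1 = fungal_dca1,
    stringsAsFactors = FALSE)
  out <- cbind(out, acts)
  mml <- mml_from_activities(cbind(sample_id = out$sample_id, acts))
  out$x <- mml$x; out$y <- mml$y
  out$vector_length <- mml$vector_length
  out$vector_angle_deg <- mml$vector_angle_deg
  out$limitation_class <- mml$limitation_class
  attr(out, "resample_count") <- resamples
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Invert vector statistics to enzyme activities
#'
#' Given a target vector length and angle plus a total C-acquisition
#' activity and group split shares, constructs the five activities whose
#' stoichiometric ratios reproduce (length, angle) exactly:
#' `x = length cos(angle)`, `y = length sin(angle)`,
#' `AP = C (1 - x) / x`, `N = C (1 - y) / y`, with
#' `BG = bg_share C`, `CBH = (1 - bg_share) C`, `NAG = nag_share N`,
#' `LAP = (1 - nag_share) N`.
#'
#' @param length,angle_deg Target vector statistics; the implied ratios
#'   `x`, `y` must fall strictly inside (0, 1) or an `ev_domain_error`
#'   signals the caller to resample.
#' @param c_total Total C-acquisition activity (nmol g^-1 h^-1).
#' @param bg_share,nag_share Shares in (0, 1) splitting the C and N groups.
#' @return data.frame with columns `bg`, `cbh`, `nag`, `lap`, `ap`.
#' @export
latent_to_activities <- function(length, angle_deg, c_total,
                                 bg_share = 0.5, nag_share = 0.5) {
  check_numeric(length, "length", positive = TRUE)
  check_numeric(angle_deg, "angle_deg")
  check_numeric(c_total, "c_total", positive = TRUE)
  if (any(angle_deg <= 0) || any(angle_deg >= 90))
    ev_domain_error("angle_deg must lie strictly in (0, 90)")
  if (any(bg_share <= 0 | bg_share >= 1) || any(nag_share <= 0 | nag_share >= 1))
    ev_domain_error("shares must lie strictly in (0, 1)")
  x <- length * cos(angle_deg * pi / 180)
  y <- length * sin(angle_deg * pi / 180)
  if (any(x <= 0 | x >= 1) || any(y <= 0 | y >= 1))
    ev_domain_error("implied ratios fall outside (0, 1): resample the latent draw")
  ap <- c_total * (1 - x) / x
  n_total <- c_total * (1 - y) / y
  data.frame(bg = bg_share * c_total, cbh = (1 - bg_share) * c_total,
             nag = nag_share * n_total, lap = (1 - nag_share) * n_total,
             ap = ap)
}

#' Simulate fluorimetric plates for known activities
#'
#' Constructs, for every sample x enzyme pair, reference standards, quench
#' standards (reference x q), substrate controls and assay wells whose
#' noise-free reduction by [reduce_plate_set()] reproduces the input
#' activities exactly. Gaussian RFU noise (SD `noise_sd`) is added to every
#' well when positive.
#'
#' @param activities Wide activity data.frame (`sample_id`, `bg`, `cbh`,
#'   `nag`, `lap`, `ap`).
#' @param params An [assay_params()].
#' @param quench_q Per-sample quench coefficient(s) in (0.2, 1]; recycled
#'   across samples.
#' @param noise_sd RFU noise standard deviation, >= 0.
#' @param seed Optional integer seed (only used when `noise_sd > 0`).
#' @param n_replicates Assay replicate wells per enzyme (>= 3).
#' @param reference_rfu Mean reference-standard fluorescence (RFU).
#' @param substrate_control_rfu Mean substrate-control fluorescence (RFU).
#' @return Long plate data.frame (`sample_id,enzyme,well_role,rfu`).
#' @export
simulate_plate <- function(activities, params = assay_params(),
                           quench_q = 0.8, noise_sd = 0, seed = NULL,
                           n_replicates = 3, reference_rfu = 1000,
                           substrate_control_rfu = 50) {
  need <- c("sample_id", ENZYMES)
  if (!is.data.frame(activities) || !all(need %in% names(activities)))
    ev_data_error("'activities' must have columns sample_id, bg, cbh, nag, lap, ap")
  if (any(quench_q <= 0.2 | quench_q > 1))
    ev_config_error("quench_q must lie in (0.2, 1]")
  if (noise_sd < 0) ev_config_error("noise_sd must be >= 0")
  if (n_replicates < 3) ev_config_error("need >= 3 assay replicates")
  if (!is.null(seed)) set.seed(as.integer(seed))
  q <- rep_len(quench_q, nrow(activities))
  e <- reference_rfu / params$standard_amount
  rows <- list()
  for (i in seq_len(nrow(activities))) {
    for (enz in ENZYMES) {
      a <- activities[[enz]][i]
      net <- a * e * params$sediment_dry_mass * params$incubation_time *
        params$well_aliquot_volume / params$suspension_volume
      assay_mean <- (net + substrate_control_rfu) * q[i]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = activities$sample_id[i], enzyme = enz,
        well_role = c(rep("assay", n_replicates),
                      rep("quench_standard", 3),
                      rep("substrate_control", 3),
                      rep("reference_standard", 3)),
        rfu = c(rep(assay_mean, n_replicates),
                rep(reference_rfu * q[i], 3),
                rep(substrate_control_rfu, 3),
                rep(reference_rfu, 3)),
        stringsAsFactors = FALSE)
    }
  }
  plate <- do.call(rbind, rows)
  if (noise_sd > 0)
    plate$rfu <- pmax(plate$rfu + stats::rnorm(nrow(plate), 0, noise_sd), 0)
  plate
}
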