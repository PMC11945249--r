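# Gradient statistics: log-linear fits, salinity-class ANOVA with compact
# letters, partial regression, three-block variance partitioning,
# distance-matrix regression with permutation inference, and VIF-based
# collinearity filtering. "log" means the natural log throughout.

SALINITY_LEVELS <- c("FRESHWATER", "SUBSALINE", "HYPOSALINE", "MESOSALINE")

#' Classify water salinity
#'
#' Left-closed bands: freshwater < 0.5 permil, subsaline \[0.5, 3),
#' hyposaline \[3, 20), mesosaline >= 20 permil.
#'
#' @param salinity Positive salinity in permil.
#' @return Ordered factor with levels FRESHWATER < SUBSALINE < HYPOSALINE <
#'   MESOSALINE.
#' @export
classify_salinity <- function(salinity) {
  check_numeric(salinity, "salinity", positive = TRUE)
  cut(salinity, breaks = c(0, 0.5, 3, 20, Inf), labels = SALINITY_LEVELS,
      right = FALSE, ordered_result = TRUE)
}

#' Log-log linear regression
#'
#' OLS of `ln(y)` on `ln(x)`; both variables must be strictly positive.
#'
#' @param x,y Positive numeric vectors of equal length, n >= 3.
#' @return An object of class `ev_regression`: a list with `slope`,
#'   `intercept`, `r2`, `adj_r2`, `p_value` (two-sided slope test), `n`,
#'   and the underlying `lm` fit.
#' @export
loglinear_fit <- function(x, y) {
  check_numeric(x, "x", positive = TRUE)
  check_numeric(y, "y", positive = TRUE)
  if (length(x) != length(y)) ev_domain_error("x and y lengths differ")
  if (length(x) < 3L) ev_domain_error("need at least 3 observations")
  lx <- log(x); ly <- log(y)
  if (stats::var(lx) == 0) ev_domain_error("zero variance in x after log transform")
  .ols_result(stats::lm(ly ~ lx))
}

.ols_result <- function(fit) {
  s <- summary(fit)
  co <- s$coefficients
  p <- if (nrow(co) >= 2) co[2, 4] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = s$r.squared, adj_r2 = s$adj.r.squared,
                 p_value = p, n = length(stats::fitted(fit)), fit = fit),
            class = "ev_regression")
}

#' @export
print.ev_regression <- function(x, ...) {
  cat(sprintf("log-log OLS (n = %d): slope = %.4f, adj R2 = %.4f, p = %.3g\n",
              x$n, x$slope, x$adj_r2, x$p_value))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Compares a response between groups (e.g. salinity classes); classes
#' sharing a letter are not significantly different under Tukey's HSD at
#' level `alpha`. Groups with fewer than 2 observations are dropped with a
#' warning.
#'
#' @param values Numeric response.
#' @param classes Grouping vector (coerced to factor).
#' @param alpha Familywise level for the HSD letters (default 0.05).
#' @return List of class `ev_anova`: `f`, `p`, `means` (named), `letters`
#'   (named), `tukey` (data.frame of pairwise comparisons), `n` (named
#'   group sizes).
#' @export
class_anova <- function(values, classes, alpha = 0.05) {
  check_numeric(values, "values")
  classes <- factor(classes)
  if (length(values) != length(classes))
    ev_domain_error("values and classes lengths differ")
  sizes <- table(classes)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("dropping class(es) with < 2 observations: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !(classes %in% small)
    values <- values[keep]; classes <- droplevels(classes[keep])
  }
  if (nlevels(classes) < 2) ev_domain_error("need >= 2 classes with >= 2 observations")
  fit <- stats::aov(values ~ classes)
  an <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$classes
  means <- tapply(values, classes, mean)
  # significant pairs (rownames are "B-A")
  pairs <- do.call(rbind, strsplit(rownames(tuk), "-", fixed = TRUE))
  sig <- !is.nan(tuk[, "p adj"]) & tuk[, "p adj"] < alpha
  letters_out <- .compact_letters(levels(classes)[order(means, decreasing = TRUE)],
                                  pairs[sig, , drop = FALSE])
  structure(list(f = an[1, "F value"], p = an[1, "Pr(>F)"],
                 means = means, letters = letters_out[levels(classes)],
                 tukey = data.frame(comparison = rownames(tuk), tuk,
                                    row.names = NULL, check.names = FALSE),
                 n = table(classes)),
            class = "ev_anova")
}

# Insert-and-absorb compact letter display. `groups` is ordered (letters are
# assigned in that order); `sig_pairs` is a 2-column character matrix of
# significantly different pairs.
.compact_letters <- function(groups, sig_pairs) {
  cols <- list(groups) # each column = set of groups allowed to share a letter
  if (nrow(sig_pairs)) {
    for (k in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs[k, 1]; b <- sig_pairs[k, 2]
      newcols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          newcols <- c(newcols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else newcols <- c(newcols, list(col))
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(newcols))
      for (i in seq_along(newcols)) for (j in seq_along(newcols)) {
        if (i != j && keep[i] && keep[j] &&
            all(newcols[[i]] %in% newcols[[j]]) &&
            !(all(newcols[[j]] %in% newcols[[i]]) && i < j))
          keep[i] <- FALSE
      }
      cols <- newcols[keep]
    }
  }
  # order columns by the position of their first group, then assign letters
  first <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols))
    for (g in cols[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}

#' @export
print.ev_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.3f, p = %.3g\n", x$f, x$p))
  print(data.frame(mean = round(x$means, 4), letters = x$letters))
  invisible(x)
}

#' Partial log-log regression controlling for a covariate
#'
#' Residualizes `ln(y)` and `ln(x)` on `ln(control)` by OLS, then regresses
#' the residuals on each other. The raw R-squared of the residual fit
#' equals the squared partial correlation of ln(y) and ln(x) given
#' ln(control); the reported `adj_r2` applies the simple-regression
#' adjustment `1 - (1 - R2) (n - 1) / (n - 2)` to the residual fit.
#'
#' @param y,x,control Positive numeric vectors of equal length, n >= 4.
#' @return An `ev_regression` for the residual-residual fit.
#' @export
partial_regression <- function(y, x, control) {
  check_numeric(control, "control", positive = TRUE)
  check_numeric(x, "x", positive = TRUE)
  check_numeric(y, "y", positive = TRUE)
  if (length(unique(c(length(x), length(y), length(control)))) != 1L)
    ev_domain_error("y, x and control lengths differ")
  if (length(x) < 4L) ev_domain_error("need at least 4 observations")
  lc <- log(control)
  if (stats::var(lc) == 0) ev_domain_error("zero variance in control after log transform")
  ry <- stats::resid(stats::lm(log(y) ~ lc))
  rx <- stats::resid(stats::lm(log(x) ~ lc))
  if (stats::var(rx) == 0) ev_domain_error("x is collinear with control")
  .ols_result(stats::lm(ry ~ rx))
}

#' Three-block variance partitioning
#'
#' Partitions the variation in a single response across three predictor
#' blocks by inclusion-exclusion over the adjusted R-squared of the seven
#' OLS models on all non-empty block unions (the convention of classical
#' partial-RDA variance partitioning, applied to a univariate response).
#' Individual fractions may be negative; they are reported raw.
#'
#' @param response Numeric response vector.
#' @param block_a,block_b,block_c Data.frames of predictors with disjoint
#'   column names.
#' @param block_names Length-3 character labels for the blocks.
#' @return List of class `ev_vpa` with `fractions` (named numeric:
#'   `pure_a`, `pure_b`, `pure_c`, `shared_ab`, `shared_ac`, `shared_bc`,
#'   `shared_abc`, `residual`, summing to 1), `adj_r2` and `r2` of the
#'   seven union models, and `block_names`.
#' @export
variance_partition <- function(response, block_a, block_b, block_c,
                               block_names = c("a", "b", "c")) {
  check_numeric(response, "response")
  blocks <- list(a = as.data.frame(block_a), b = as.data.frame(block_b),
                 c = as.data.frame(block_c))
  nm <- unlist(lapply(blocks, names))
  if (anyDuplicated(nm))
    ev_domain_error("block predictor names must be disjoint")
  p_tot <- length(nm)
  n <- length(response)
  if (any(vapply(blocks, nrow, 0L) != n))
    ev_domain_error("blocks must have one row per response observation")
  if (n <= p_tot + 1) ev_domain_error("need n > total number of predictors + 1")
  fit_r2 <- function(cols, label, check_rank = FALSE) {
    X <- do.call(cbind, blocks[cols])
    names(X) <- unlist(lapply(blocks[cols], names))
    fit <- stats::lm(response ~ ., data = X)
    if (check_rank && fit$rank < ncol(X) + 1L)
      ev_domain_error(sprintf("singular fit for block '%s'",
                              block_names[match(label, c("a", "b", "c"))]))
    s <- summary(fit)
    c(r2 = s$r.squared, adj = s$adj.r.squared)
  }
  A   <- fit_r2("a", "a", check_rank = TRUE)
  B   <- fit_r2("b", "b", check_rank = TRUE)
  C   <- fit_r2("c", "c", check_rank = TRUE)
  AB  <- fit_r2(c("a", "b")); AC <- fit_r2(c("a", "c")); BC <- fit_r2(c("b", "c"))
  ABC <- fit_r2(c("a", "b", "c"))
  adj <- c(a = A[["adj"]], b = B[["adj"]], c = C[["adj"]],
           ab = AB[["adj"]], ac = AC[["adj"]], bc = BC[["adj"]],
           abc = ABC[["adj"]])
  pure_a <- adj[["abc"]] - adj[["bc"]]
  pure_b <- adj[["abc"]] - adj[["ac"]]
  pure_c <- adj[["abc"]] - adj[["ab"]]
  shared_ab <- adj[["abc"]] - adj[["c"]] - pure_a - pure_b
  shared_bc <- adj[["abc"]] - adj[["a"]] - pure_b - pure_c
  shared_ac <- adj[["abc"]] - adj[["b"]] - pure_a - pure_c
  shared_abc <- adj[["abc"]] -
    (pure_a + pure_b + pure_c + shared_ab + shared_ac + shared_bc)
  fr <- c(pure_a = pure_a, pure_b = pure_b, pure_c = pure_c,
          shared_ab = shared_ab, shared_ac = shared_ac,
          shared_bc = shared_bc, shared_abc = shared_abc,
          residual = 1 - adj[["abc"]])
  structure(list(fractions = fr, adj_r2 = adj,
                 r2 = c(a = A[["r2"]], b = B[["r2"]], c = C[["r2"]],
                        ab = AB[["r2"]], ac = AC[["r2"]], bc = BC[["r2"]],
                        abc = ABC[["r2"]]),
                 block_names = block_names, n = n),
            class = "ev_vpa")
}

#' @export
print.ev_vpa <- function(x, ...) {
  cat(sprintf("variance partitioning (n = %d; blocks: %s)\n", x$n,
              paste(x$block_names, collapse = ", ")))
  disp <- x$fractions
  disp[names(disp) != "residual"] <- pmax(disp[names(disp) != "residual"], 0)
  print(round(disp, 4))
  invisible(x)
}

#' Multiple regression on distance matrices (MRM)
#'
#' Unfolds the upper triangles of the response and predictor distance
#' matrices, fits OLS, and obtains permutation p-values by jointly
#' permuting the rows and columns of the response matrix and refitting.
#' P-values use the add-one rule `p = (1 + #{|b*| >= |b|}) / (n_perm + 1)`.
#'
#' @param response_dist Square symmetric zero-diagonal matrix or `dist`.
#' @param predictor_dists Named list of matrices/`dist` of the same size.
#' @param n_perm Number of permutations, >= 99 (default 999).
#' @param seed Integer seed; results are reproducible given (seed, n_perm).
#' @return List of class `ev_mrm`: `coefficients` (data.frame with
#'   estimates and permutation p-values), `r2`, `p_r2`, `n_perm`, `seed`,
#'   `n` (matrix dimension).
#' @export
mrm <- function(response_dist, predictor_dists, n_perm = 999, seed = 1) {
  if (n_perm < 99) ev_config_error("n_perm must be >= 99")
  Y <- .as_dist_matrix(response_dist, "response")
  n <- nrow(Y)
  if (is.data.frame(predictor_dists) || is.matrix(predictor_dists) ||
      inherits(predictor_dists, "dist"))
    predictor_dists <- list(X1 = predictor_dists)
  Xs <- lapply(predictor_dists, .as_dist_matrix, what = "predictor")
  if (any(vapply(Xs, nrow, 0L) != n))
    ev_data_error("all matrices must have the same dimension")
  if (is.null(names(Xs)) || any(names(Xs) == ""))
    names(Xs) <- paste0("X", seq_along(Xs))
  ut <- upper.tri(Y)
  y <- Y[ut]
  X <- cbind(1, vapply(Xs, function(m) m[ut], numeric(sum(ut))))
  colnames(X) <- c("(Intercept)", names(Xs))
  if (length(Xs) > 1) {
    cc <- stats::cor(X[, -1, drop = FALSE])
    if (any(abs(cc[upper.tri(cc)]) > 0.9999))
      warning("collinear predictor distance matrices", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    warning("rank-deficient predictor set in MRM", call. = FALSE)
  coef_obs <- qr.coef(qrX, y)
  fitted <- qr.fitted(qrX, y)
  sst <- sum((y - mean(y))^2)
  r2_obs <- if (sst > 0) 1 - sum((y - fitted)^2) / sst else NA_real_
  set.seed(seed)
  k <- ncol(X)
  exceed <- numeric(k); exceed_r2 <- 0
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    yp <- Y[pm, pm][ut]
    cb <- qr.coef(qrX, yp)
    exceed <- exceed + (abs(cb) >= abs(coef_obs) - 1e-12)
    fp <- qr.fitted(qrX, yp)
    sstp <- sum((yp - mean(yp))^2)
    r2p <- if (sstp > 0) 1 - sum((yp - fp)^2) / sstp else 0
    exceed_r2 <- exceed_r2 + (r2p >= r2_obs - 1e-12)
  }
  pvals <- (1 + exceed) / (n_perm + 1)
  structure(list(coefficients = data.frame(term = colnames(X),
                                           estimate = unname(coef_obs),
                                           p_value = unname(pvals),
                                           row.names = NULL),
                 r2 = r2_obs, p_r2 = (1 + exceed_r2) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, n = n),
            class = "ev_mrm")
}

.as_dist_matrix <- function(m, what) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (!is.matrix(m) || nrow(m) != ncol(m))
    ev_data_error(sprintf("%s must be a square matrix or dist", what))
  if (anyNA(m) || any(!is.finite(m)))
    ev_data_error(sprintf("%s matrix contains NA/non-finite values", what))
  if (max(abs(m - t(m))) > 1e-8)
    ev_data_error(sprintf("%s matrix is not symmetric", what))
  if (any(abs(diag(m)) > 1e-8))
    ev_data_error(sprintf("%s matrix must have a zero diagonal", what))
  m
}

#' @export
print.ev_mrm <- function(x, ...) {
  cat(sprintf("MRM (n = %d, %d permutations, seed %d): R2 = %.4f (p = %.3g)\n",
              x$n, x$n_perm, x$seed, x$r2, x$p_r2))
  print(x$coefficients)
  invisible(x)
}

#' Variance inflation factors
#'
#' @param predictors Data.frame of numeric predictors.
#' @return Named numeric VIFs (`Inf` for perfectly collinear predictors).
#' @export
vif <- function(predictors) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2) ev_domain_error("need at least 2 predictors")
  vapply(names(X), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[setdiff(names(X), j)])
    # perfect collinearity is a supported input (-> Inf), so silence the
    # "essentially perfect fit" warning from summary.lm
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative VIF-based collinearity filter
#'
#' Repeatedly drops the predictor with the highest VIF while any VIF
#' exceeds `threshold`. Ties (including several infinite VIFs from perfect
#' collinearity) are broken by dropping the alphabetically later name
#' first.
#'
#' @param predictors Data.frame of numeric predictors (>= 2 columns,
#'   n > number of predictors).
#' @param threshold VIF threshold (default 10).
#' @return List with `retained` (data.frame), `dropped` (named numeric: VIF
#'   at time of dropping), and `vif` (final VIFs of the retained set).
#' @export
vif_filter <- function(predictors, threshold = 10) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2) ev_domain_error("need at least 2 predictors")
  if (nrow(X) <= ncol(X)) ev_domain_error("need n > number of predictors")
  dropped <- numeric(0)
  repeat {
    if (ncol(X) < 2) break
    v <- vif(X)
    if (all(v <= threshold)) break
    worst <- names(v)[v == max(v)]
    worst <- sort(worst, decreasing = TRUE)[1] # later-alphabetical first
    dropped[worst] <- unname(v[worst])
    X <- X[setdiff(names(X), worst)]
  }
  final_v <- if (ncol(X) >= 2) vif(X) else stats::setNames(1, names(X))
  list(retained = X, dropped = dropped, vif = final_v)
}

#' Z-score standardization
#'
#' Centres to mean 0 and scales to sample standard deviation 1.
#'
#' @param values Numeric vector, n >= 2, with positive variance.
#' @return Standardized numeric vector.
#' @export
zscore <- function(values) {
  check_numeric(values, "values")
  if (length(values) < 2) ev_domain_error("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) ev_domain_error("zero variance: z-scores undefined")
  (values - mean(values)) / s
}
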