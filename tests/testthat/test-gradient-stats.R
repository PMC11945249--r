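test_that("salinity classification uses left-closed bands and is ordered", {
  s <- c(0.13, 0.49, 0.5, 2.99, 3, 19.99, 20, 31.06)
  cls <- classify_salinity(s)
  expect_equal(as.character(cls),
               c("FRESHWATER", "FRESHWATER", "SUBSALINE", "SUBSALINE",
                 "HYPOSALINE", "HYPOSALINE", "MESOSALINE", "MESOSALINE"))
  expect_true(is.ordered(cls))
  expect_false(is.unsorted(cls))
  expect_ev_error(classify_salinity(0), "ev_domain_error")
})

test_that("loglinear_fit recovers exact power laws and rejects bad input", {
  x <- c(0.2, 1, 3, 7, 20)
  fit <- loglinear_fit(x, x)
  expect_equal(fit$slope, 1)
  expect_equal(fit$adj_r2, 1)
  # y = c x^b noise-free recovers b to 1e-9
  fit2 <- loglinear_fit(x, 2.5 * x^-1.7)
  expect_equal(fit2$slope, -1.7, tolerance = 1e-9)
  expect_equal(fit2$intercept, log(2.5), tolerance = 1e-9)

  flat <- loglinear_fit(x, rep(2, 5) * c(1, 1 + 1e-15, 1, 1, 1))
  expect_lt(abs(flat$slope), 1e-10)
  expect_lte(flat$adj_r2, 0)

  expect_ev_error(loglinear_fit(c(-1, 1, 2), c(1, 2, 3)), "ev_domain_error")
  expect_ev_error(loglinear_fit(rep(2, 4), 1:4), "ev_domain_error")
  expect_ev_error(loglinear_fit(1:2, 1:2), "ev_domain_error")
  # adjusted R2 uses the (n - 1)/(n - 2) simple-regression convention
  set.seed(5)
  x2 <- exp(rnorm(20)); y2 <- exp(0.3 * log(x2) + rnorm(20))
  f <- loglinear_fit(x2, y2)
  expect_equal(f$adj_r2, 1 - (1 - f$r2) * 19 / 18)
})

test_that("class_anova separates groups and letters agree with a simulation oracle", {
  # identical values in two classes: F = 0, shared letter
  same <- class_anova(rep(1, 10) + rep(c(0, 1e-9, 0, 1e-9, 0), 2),
                      rep(c("a", "b"), each = 5))
  expect_lt(same$f, 1e-6)
  expect_identical(unname(same$letters), c("a", "a"))

  # clearly separated groups get distinct letters
  set.seed(21)
  sep <- class_anova(c(rnorm(5, 0, 0.01), rnorm(5, 10, 0.01)),
                     rep(c("lo", "hi"), each = 5))
  expect_false(same$p < 0.05)
  expect_lt(sep$p, 1e-6)
  expect_true(sep$letters[["lo"]] != sep$letters[["hi"]])

  # three-group oracle: N(0,1), N(0,1), N(5,1) -> third lettered separately
  set.seed(22)
  v <- c(rnorm(30), rnorm(30), rnorm(30, 5))
  g <- rep(c("g1", "g2", "g3"), each = 30)
  a3 <- class_anova(v, g)
  expect_identical(a3$letters[["g1"]], a3$letters[["g2"]])
  expect_false(a3$letters[["g3"]] == a3$letters[["g1"]])

  expect_warning(class_anova(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "dropping")
  expect_ev_error(
    suppressWarnings(class_anova(c(1, 2, 9), c("a", "a", "c"))),
    "ev_domain_error")
})

test_that("partial_regression equals the squared partial correlation (closed form)", {
  set.seed(31)
  for (i in 1:5) {
    n <- 60
    c0 <- rnorm(n)
    x <- exp(0.5 * c0 + rnorm(n))
    y <- exp(0.4 * c0 - 0.3 * log(x) + rnorm(n))
    ctrl <- exp(c0)
    pr <- partial_regression(y, x, ctrl)
    cm <- cor(cbind(ly = log(y), lx = log(x), lc = log(ctrl)))
    r_part <- (cm["ly", "lx"] - cm["ly", "lc"] * cm["lx", "lc"]) /
      sqrt((1 - cm["ly", "lc"]^2) * (1 - cm["lx", "lc"]^2))
    expect_equal(pr$r2, r_part^2, tolerance = 1e-6)
  }
})

test_that("partial_regression limits: independence and full confounding", {
  set.seed(32)
  n <- 400
  ctrl <- exp(rnorm(n))
  x <- exp(rnorm(n))
  y <- exp(0.6 * log(x) + rnorm(n, 0, 0.5))
  marg <- loglinear_fit(x, y)$adj_r2
  part <- partial_regression(y, x, ctrl)$adj_r2
  expect_equal(part, marg, tolerance = 0.05)
  # y an exact function of the control -> partial ~ 0
  y2 <- exp(2 * log(ctrl))
  expect_lt(partial_regression(y2, x, ctrl)$adj_r2, 0.02)
  expect_ev_error(partial_regression(y[1:3], x[1:3], ctrl[1:3]),
                  "ev_domain_error")
})

test_that("variance_partition matches vegan::varpart and sums to one", {
  skip_if_not_installed("vegan")
  set.seed(41)
  n <- 120
  X1 <- data.frame(p1 = rnorm(n), p2 = rnorm(n))
  X2 <- data.frame(q1 = rnorm(n))
  X3 <- data.frame(r1 = rnorm(n), r2 = rnorm(n))
  y <- X1$p1 + 0.5 * X2$q1 - 0.8 * X3$r1 + X1$p1 * 0 + rnorm(n)
  vp <- variance_partition(y, X1, X2, X3)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-9)
  vg <- vegan::varpart(y, X1, X2, X3)$part
  ind <- vg$indfract$Adj.R.square
  # vegan order: [a], [b], [c], [d]=ab, [e]=bc, [f]=ac, [g]=abc, residual
  expect_equal(unname(vp$fractions[c("pure_a", "pure_b", "pure_c")]),
               ind[1:3], tolerance = 1e-9)
  expect_equal(unname(vp$fractions[c("shared_ab", "shared_bc", "shared_ac",
                                     "shared_abc")]),
               ind[4:7], tolerance = 1e-9)
  expect_equal(unname(vp$fractions[["residual"]]), ind[8], tolerance = 1e-9)
  # raw R2 is monotone under nesting
  expect_gte(vp$r2[["abc"]], max(vp$r2[c("ab", "ac", "bc")]) - 1e-12)
  expect_gte(vp$r2[["ab"]], max(vp$r2[c("a", "b")]) - 1e-12)
})

test_that("variance_partition limit cases behave", {
  set.seed(42)
  n <- 200
  # exactly orthogonal, centred predictors: raw R2 is additive, so pure
  # fractions match marginal adjusted R2 and shared fractions collapse
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 3), n), scale = FALSE)))
  a <- data.frame(a1 = Q[, 1]); b <- data.frame(b1 = Q[, 2])
  cc <- data.frame(c1 = Q[, 3])
  y <- 20 * a$a1 + 10 * b$b1 + 5 * cc$c1 + rnorm(n)
  vp <- variance_partition(y, a, b, cc)
  marg <- vapply(list(a$a1, b$b1, cc$c1),
                 function(p) summary(lm(y ~ p))$adj.r.squared, numeric(1))
  expect_lt(max(abs(unname(vp$fractions[c("pure_a", "pure_b", "pure_c")]) - marg)),
            0.02)
  expect_lt(max(abs(vp$fractions[c("shared_ab", "shared_ac", "shared_bc",
                                   "shared_abc")])), 0.02)

  # duplicated block: pure fractions vanish, shared_ab carries the signal
  dup <- data.frame(b1dup = a$a1)
  vp2 <- variance_partition(y, a, dup, cc)
  expect_lt(abs(vp2$fractions[["pure_a"]]), 1e-9)
  expect_lt(abs(vp2$fractions[["pure_b"]]), 1e-9)
  expect_gt(vp2$fractions[["shared_ab"]], 0.5)

  # pure noise: residual ~ 1
  y0 <- rnorm(n)
  vp3 <- variance_partition(y0, a, b, cc)
  expect_gt(vp3$fractions[["residual"]], 0.9)
  expect_equal(sum(vp3$fractions), 1, tolerance = 1e-9)

  expect_ev_error(variance_partition(y, data.frame(z = rep(1, n)), b, cc),
                  "ev_domain_error")
  expect_ev_error(variance_partition(y, a, a, cc), "ev_domain_error")
})

test_that("mrm handles identity, reproducibility and collinearity", {
  set.seed(51)
  pts <- matrix(rnorm(30), ncol = 2)
  d <- as.matrix(dist(pts))
  res <- mrm(d, list(self = d), n_perm = 199, seed = 7)
  expect_equal(res$coefficients$estimate[2], 1, tolerance = 1e-9)
  expect_equal(res$r2, 1, tolerance = 1e-9)
  expect_equal(res$coefficients$p_value[2], 1 / 200)

  # bit-for-bit reproducible given (seed, n_perm)
  d2 <- as.matrix(dist(rnorm(15)))
  r1 <- mrm(d, list(x = d2), n_perm = 199, seed = 3)
  r2 <- mrm(d, list(x = d2), n_perm = 199, seed = 3)
  expect_identical(r1$coefficients, r2$coefficients)

  w <- testthat::capture_warnings(mrm(d, list(x = d2, xdup = d2),
                                      n_perm = 99, seed = 1))
  expect_true(any(grepl("collinear", w)))
  asym <- d; asym[1, 2] <- asym[1, 2] + 1
  expect_ev_error(mrm(asym, list(x = d2), n_perm = 99), "ev_data_error")
  expect_ev_error(mrm(d, list(x = d2[-1, -1]), n_perm = 99), "ev_data_error")
  expect_ev_error(mrm(d, list(x = d2), n_perm = 9), "ev_config_error")
})

test_that("vif and vif_filter detect collinearity deterministically", {
  set.seed(61)
  n <- 100
  orth <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  vf <- vif_filter(orth)
  expect_equal(names(vf$retained), c("a", "b", "c"))
  expect_equal(length(vf$dropped), 0)

  # exact collinearity: x2 = 2 x1 -> later-alphabetical dropped first
  coll <- data.frame(x1 = rnorm(n))
  coll$x2 <- 2 * coll$x1
  coll$z <- rnorm(n)
  vf2 <- vif_filter(coll)
  expect_equal(names(vf2$dropped), "x2")
  expect_true(is.infinite(vf2$dropped[["x2"]]))

  # three predictors with pairwise r ~ 0.99: direct VIF oracle says > 10
  base <- rnorm(n)
  trio <- data.frame(a = base + rnorm(n, 0, 0.1), b = base + rnorm(n, 0, 0.1),
                     c = base + rnorm(n, 0, 0.1))
  expect_gt(max(vif(trio)), 10)
  vf3 <- vif_filter(trio)
  expect_lt(ncol(vf3$retained), 3)
  expect_ev_error(vif_filter(data.frame(a = 1:5)), "ev_domain_error")
})

test_that("zscore standardizes, is idempotent, and rejects constants", {
  expect_equal(zscore(1:3), c(-1, 0, 1))
  z <- zscore(rnorm(50))
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_ev_error(zscore(rep(3, 10)), "ev_domain_error")
  expect_ev_error(zscore(1), "ev_domain_error")
})
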