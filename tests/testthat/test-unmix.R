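test_that("noiseless generative targets are recovered exactly", {
  lib <- standard_library("dNTP", axis = fp_axis)
  target <- raman_spectrum(fp_axis, 0.3 * lib$members$adenine$intensity +
                             0.7 * lib$members$guanine$intensity)
  fit <- unmix(target, lib)
  expect_equal(unname(coef(fit)[c("adenine", "guanine")]), c(0.3, 0.7),
               tolerance = 1e-9)
  expect_lt(sum(coef(fit)[setdiff(names(coef(fit)),
                                  c("adenine", "guanine"))]), 1e-9)
  expect_lt(fit$chi_squared, 1e-12)
  expect_equal(fit$dof, length(fp_axis) - 8L)
})

test_that("the unconstrained fit equals the normal-equations closed form", {
  lib <- standard_library("dNTP", axis = fp_axis)
  g <- generate_target(clean_config(21), lib)
  target <- single_target(g)
  fit <- unmix(target, lib, nonneg = FALSE)
  X <- vapply(lib$members, function(s) s$intensity, numeric(length(fp_axis)))
  beta <- drop(solve(crossprod(X), crossprod(X, target$intensity)))
  expect_equal(unname(coef(fit)), unname(beta), tolerance = 1e-8)
  # and against lm() as a second route
  lmfit <- lm(target$intensity ~ X - 1)
  expect_equal(unname(coef(fit)), unname(coef(lmfit)), tolerance = 1e-8)
})

test_that("the non-negative solver matches an independent NNLS implementation", {
  skip_if_not_installed("pracma")
  lib <- standard_library("nucleobase", axis = fp_axis)
  X <- vapply(lib$members, function(s) s$intensity, numeric(length(fp_axis)))
  set.seed(5)
  for (k in 1:5) {
    # weights with some zeros so constraints activate
    w <- pmax(rnorm(8, 0.1, 0.3), 0)
    y <- drop(X %*% w) + rnorm(length(fp_axis), 0, 0.02)
    target <- raman_spectrum(fp_axis, y)
    fit <- unmix(target, lib)
    oracle <- pracma::lsqnonneg(X, y)$x
    expect_equal(unname(coef(fit)), oracle, tolerance = 1e-7)
  }
})

test_that("a target orthogonal to all components yields the null fit", {
  lib <- standard_library("dNTP", axis = fp_axis)
  target <- peak_spectrum(900, height = 1)   # far from any dNTP standard?
  # 900 cm^-1 is far from every dNTP dominant mode (1214 is closest)
  fit <- unmix(target, lib)
  expect_lt(sum(coef(fit)), 0.02)
  expect_equal(fit$chi_squared, sum(target$intensity^2), tolerance = 0.02)
})

test_that("reconstruction identity holds channelwise", {
  lib <- standard_library("ssDNA_10mer", axis = fp_axis)
  g <- generate_target(clean_config(31, tier = "ssDNA_10mer"), lib)
  target <- single_target(g)
  fit <- unmix(target, lib)
  recon <- fit$fitted$intensity + fit$residual$intensity
  expect_equal(recon, target$intensity, tolerance = 1e-10)
})

test_that("chi-squared never increases when a component is added", {
  lib <- standard_library("dNTP", axis = fp_axis)
  g <- generate_target(clean_config(41), lib)
  target <- single_target(g)
  smaller <- lib
  smaller$members <- lib$members[1:7]
  f_small <- unmix(target, smaller, nonneg = FALSE)
  f_full <- unmix(target, lib, nonneg = FALSE)
  expect_lte(f_full$chi_squared, f_small$chi_squared + 1e-12)
})

test_that("true weights fall within 3 reported SEs", {
  hits <- 0; n <- 0
  for (s in 1:20) {
    cfg <- clean_config(600 + s)
    lib <- standard_library(cfg$tier, axis = cfg$axis)
    g <- generate_target(cfg, lib)
    fit <- unmix(single_target(g), lib)
    ok <- abs(coef(fit) - cfg$true_weights[names(coef(fit))]) <= 3 * fit$se
    hits <- hits + sum(ok); n <- n + length(ok)
  }
  expect_gte(hits / n, 0.95)
})

test_that("replicate spectral uncertainty propagates into the combined SE", {
  cfg <- synthetic_config(seed = 77, background_fraction = 0,
                          cosmic_ray_rate = 0, include_atmospheric = FALSE,
                          axis_offset_cm1 = 0, axis = fp_axis)
  lib <- standard_library(cfg$tier, axis = fp_axis)
  g <- generate_target(cfg, lib)
  avg <- average_replicates(g$set)
  fit <- unmix(avg, lib)
  expect_true(all(fit$se_spectrum[fit$coefficients > 0] > 0))
  expect_true(all(fit$se >= fit$se_fit))
  expect_equal(fit$se, sqrt(fit$se_fit^2 + fit$se_spectrum^2))
})

test_that("model ranking identifies the generating tier with tie-breaks", {
  libs <- lapply(c("nucleobase", "dNTP", "ssDNA_10mer"),
                 function(tr) standard_library(tr, axis = fp_axis))
  names(libs) <- c("nucleobase", "dNTP", "ssDNA_10mer")
  wins <- 0
  for (s in 1:10) {
    g <- generate_target(clean_config(700 + s, noise_sigma = 0.01), libs$dNTP)
    cmp <- compare_standard_sets(single_target(g), libs)
    wins <- wins + (cmp$ranking$tier[1] == "dNTP")
  }
  expect_gte(wins, 9)

  # singleton ranking
  g <- generate_target(clean_config(711), libs$dNTP)
  one <- compare_standard_sets(single_target(g), libs["dNTP"])
  expect_equal(nrow(one$ranking), 1L)

  # identical libraries tie and are broken by tier order
  two <- compare_standard_sets(single_target(g), list(libs$dNTP, libs$dNTP))
  expect_lt(abs(diff(two$ranking$chi_squared)), 1e-10)
  expect_equal(two$ranking$rank, c(1L, 2L))
})

test_that("collinear amino-acid coefficients are pooled into one group", {
  # three near-identical standards sharing a ~1600 cm^-1 dominant mode
  lib <- standard_library("dNTP", axis = fp_axis)
  centers <- c(phenylalanine = 1598, tryptophan = 1600, tyrosine = 1602)
  for (nm in names(centers))
    lib$members[[nm]] <- peak_spectrum(centers[[nm]], height = 1)
  g_w <- c(adenine = 0.3, guanine = 0.3, phenylalanine = 0.1,
           tryptophan = 0.1, tyrosine = 0.1)
  y <- Reduce(`+`, Map(function(nm, w) w * lib$members[[nm]]$intensity,
                       names(g_w), g_w))
  set.seed(8)
  target <- raman_spectrum(fp_axis, y + rnorm(length(fp_axis), 0, 0.005))
  fit <- suppressWarnings(unmix(target, lib, nonneg = FALSE))
  groups <- coefficient_correlations(fit, threshold = 0.9)
  expect_length(groups, 1L)
  expect_setequal(groups[[1]]$components,
                  c("phenylalanine", "tryptophan", "tyrosine"))
  expect_equal(groups[[1]]$coefficient, 0.3, tolerance = 0.05)

  # well-separated standards produce no groups; threshold > 1 never groups
  lib0 <- standard_library("dNTP", axis = fp_axis)
  sep_centers <- seq(850, 1750, length.out = 8)
  for (k in seq_along(lib0$members))
    lib0$members[[k]] <- peak_spectrum(sep_centers[k], height = 1)
  set.seed(9)
  y0 <- Reduce(`+`, lapply(lib0$members, function(s) 0.2 * s$intensity))
  fit0 <- unmix(raman_spectrum(fp_axis,
                               y0 + rnorm(length(fp_axis), 0, 0.005)),
                lib0, nonneg = FALSE)
  expect_length(coefficient_correlations(fit0, 0.9), 0L)
  expect_length(coefficient_correlations(fit, 1.01), 0L)
})

test_that("residual fraction is 0 for perfect fits and 1 for pure background", {
  lib <- standard_library("dNTP", axis = fp_axis)
  perfect <- raman_spectrum(fp_axis, 0.5 * lib$members$guanine$intensity +
                              0.5 * lib$members$adenine$intensity)
  expect_lt(residual_fraction(unmix(perfect, lib)), 1e-6)
  bgonly <- peak_spectrum(900, height = 1)
  fit <- unmix(bgonly, lib)
  expect_gt(residual_fraction(fit), 0.97)
})

test_that("fit reports carry all components and round-trip through JSON", {
  lib <- standard_library("dNTP", axis = fp_axis)
  g <- generate_target(clean_config(61), lib)
  fit <- unmix(single_target(g), lib)
  tab <- report_fit(fit)
  expect_equal(nrow(tab), 8L)
  expect_equal(attr(tab, "chi_squared"), fit$chi_squared)
  js <- report_fit(fit, format = "json")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$table$coefficient, unname(coef(fit)))
  expect_equal(parsed$chi_squared, fit$chi_squared)
})
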