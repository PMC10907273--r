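mm_grid <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64) # mM, sub- to supra-Km

test_that("generated rates follow the competitive Michaelis-Menten law", {
  # half-saturation identity, exact with no noise or inhibitor
  d <- generate_assay(vmax = 1, km = 2.2, substrate = 2.2)
  expect_identical(d$rate, 0.5)

  # inhibition only rescales the apparent Km
  d0 <- generate_assay(vmax = 1, km = 2.2, substrate = mm_grid)
  di <- generate_assay(vmax = 1, km = 2.2, substrate = mm_grid,
                       inhibitor = 10, ki = 2.366)
  km_app <- 2.2 * (1 + 10 / 2.366)
  expect_equal(di$rate, 1 * mm_grid / (km_app + mm_grid))
  expect_true(all(di$rate < d0$rate))

  expect_error(generate_assay(1, 2.2, substrate = c(1, -2)), "positive")
  expect_error(generate_assay(-1, 2.2, substrate = 1))
})

test_that("the same seed reproduces a dataset without touching the RNG", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  d1 <- generate_assay(1, 2.2, mm_grid, noise_sd = 0.05, seed = 77)
  d2 <- generate_assay(1, 2.2, mm_grid, noise_sd = 0.05, seed = 77)
  expect_identical(d1$rate, d2$rate)
  expect_false(identical(d1$rate,
                         generate_assay(1, 2.2, mm_grid, noise_sd = 0.05,
                                        seed = 78)$rate))
  # caller's RNG stream is unaffected by the seeded draw
  expect_identical(stats::runif(1), before)
})

test_that("noise-free fits recover the generating constants", {
  d <- generate_assay(vmax = 8.5e-7, km = 2.2, substrate = mm_grid)
  fit <- fit_mm(d)
  co <- coef(fit)
  expect_lt(rel_err(co[["vmax"]], 8.5e-7), 1e-3)
  expect_lt(rel_err(co[["km"]], 2.2), 1e-3)
  expect_true(generics::glance(fit)$converged)

  # fitting inhibited data with the plain MM form yields the apparent Km
  di <- generate_assay(vmax = 8.5e-7, km = 2.2, substrate = mm_grid,
                       inhibitor = 10, ki = 2.366)
  expect_lt(rel_err(coef(fit_mm(di))[["km"]], 11.5), 1e-3)

  expect_error(fit_mm(d[1:3, ]), "at least 4")
  expect_error(fit_mm(data.frame(x = 1)), "columns")
})

test_that("tidy and glance expose broom-style summaries", {
  d <- generate_assay(1, 2.2, mm_grid, noise_sd = 0.02, seed = 5)
  fit <- fit_mm(d)
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("vmax", "km"))
  expect_true(all(td$std.error >= 0))
  gl <- generics::glance(fit)
  expect_equal(gl$nobs, length(mm_grid))
  expect_gte(gl$rss, 0)
})

test_that("estimates are unbiased and their errors calibrated", {
  n <- 60
  fits <- purrr::map_dfr(seq_len(n), function(i) {
    d <- generate_assay(vmax = 1, km = 2.2, substrate = mm_grid,
                        noise_sd = 0.05, seed = 1000 + i)
    generics::tidy(fit_mm(d))
  })
  km <- fits[fits$term == "km", ]
  expect_lt(rel_err(mean(km$estimate), 2.2), 0.1)
  # asymptotic SEs agree with the Monte-Carlo spread within a factor of 2
  ratio <- mean(km$std.error) / stats::sd(km$estimate)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)

  # competitive signature: Km moves, Vmax barely does
  pair <- purrr::map_dfr(1:20, function(i) {
    d0 <- generate_assay(1, 2.2, mm_grid, noise_sd = 0.03, seed = 300 + i)
    di <- generate_assay(1, 2.2, mm_grid, inhibitor = 10, ki = 2.366,
                         noise_sd = 0.03, seed = 600 + i)
    tibble::tibble(km0 = coef(fit_mm(d0))[["km"]],
                   kmi = coef(fit_mm(di))[["km"]],
                   v0 = coef(fit_mm(d0))[["vmax"]],
                   vi = coef(fit_mm(di))[["vmax"]])
  })
  expect_gt(mean(pair$kmi / pair$km0), 3)
  expect_lt(abs(mean(pair$vi / pair$v0) - 1), 0.2)
  expect_lt(abs(mean(pair$vi / pair$v0) - 1),
            abs(mean(pair$kmi / pair$km0) - 1))
})
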