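test_that("number density converts to molar correctly", {
  # one molecule per (1000 A)^3 is 1e-9 A^-3, i.e. 1.66 uM
  p <- wlc_params()
  # pick d0 so that the WLC density equals 1e-9 A^-3, then check the molar value
  lc <- contour_length(30, p)
  a <- p$lp * lc
  d0 <- sqrt(-log(1e-9 / (3 / (4 * pi * a))^1.5) * 4 * a / 3)
  res <- ceff_delta(d0, 30, p)
  expect_equal(res$value_M, 1e-9 * 1e27 / 6.02214076e23, tolerance = 1e-9)
  expect_equal(res$value_M, 1.6606e-6, tolerance = 1e-4)
})

test_that("delta back-end is the WLC density at a point and is monotone", {
  p <- wlc_params()
  expect_equal(ceff_delta(1e-9, 50, p)$value_M,
               (3 / (4 * pi * p$lp * contour_length(50, p)))^1.5 *
                 1e27 / 6.02214076e23,
               tolerance = 1e-9)
  d0s <- c(10, 20, 40, 60, 80)
  vals <- vapply(d0s, function(d) ceff_delta(d, 50, p)$value_mM, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(ceff_delta(-5, 50, p), "d0")
})

test_that("hybrid back-end agrees with the delta back-end on degenerate traces", {
  p <- wlc_params()
  expect_warning(one <- ceff_hybrid(40, 50, p), "noisy")
  expect_equal(one$value_M, ceff_delta(40, 50, p)$value_M, tolerance = 1e-15)
  many <- ceff_hybrid(rep(37.5, 250), 24, p)
  expect_equal(many$value_M, ceff_delta(37.5, 24, p)$value_M,
               tolerance = 1e-15)
  expect_equal(many$n_samples, 250L)
})

test_that("hybrid back-end matches the analytic Gaussian overlap", {
  mu <- c(35, 10, -5); sigma <- 6; n_link <- 45
  tr <- gen_distance_trace(2e5, mean_offset = mu, per_axis_sd = sigma,
                           seed = 101)
  got <- ceff_hybrid(tr$distance_A, n_link)
  want <- gaussian_overlap_ceff(mu, sigma, n_link)
  # Monte-Carlo tolerance: 4 standard errors of the sampled density mean
  p <- wlc_params()
  dens <- wlc_vector_density(tr$distance_A, n_link, p)
  se <- sd(dens) / sqrt(length(dens)) * 1e27 / 6.02214076e23
  expect_lt(abs(got$value_M - want), 4 * se)
  expect_equal(got$value_M, want, tolerance = 0.02)
})

test_that("hybrid accepts histogram distributions consistently", {
  tr <- gen_distance_trace(5e4, 40, 4, seed = 9)
  h <- radial_density_from_samples(tr$distance_A, n_bins = 100)
  from_hist <- ceff_hybrid(h, 30)
  from_samples <- ceff_hybrid(tr$distance_A, 30)
  expect_equal(from_hist$value_M, from_samples$value_M, tolerance = 1e-3)
})

test_that("Monte-Carlo spread shrinks with trace length", {
  spread <- function(n) {
    vals <- vapply(1:12, function(s) {
      tr <- gen_distance_trace(n, 40, 5, seed = 1000 + s)
      ceff_hybrid(tr$distance_A, 40)$value_mM
    }, numeric(1))
    sd(vals)
  }
  expect_lt(spread(16000), spread(1000) / 2)
})

test_that("scaffold-like geometries land in the millimolar range", {
  # linker length and bound-site separation co-vary on a real scaffold:
  # longer tethers reach across larger separations
  p <- wlc_params()
  geom <- list(c(18, 30), c(30, 35), c(45, 40), c(60, 50))
  for (g in geom) {
    v <- ceff_delta(g[2], g[1], p)$value_mM
    expect_gt(v, 0.1); expect_lt(v, 10)
  }
})

test_that("the pair table covers ordered pairs with the right geometry", {
  gs <- gen_sequence(c("PPPVPPRRR", "PPLLPPREP", "TRRHLPSPP"),
                     linker_lengths = c(20, 35), seed = 5)
  tab <- ceff_table(gs$layout, distance_delta(40))
  expect_equal(dim(tab), c(3L, 3L))
  expect_true(all(is.na(diag(tab))))
  expect_equal(sum(!is.na(tab)), 6L)
  # shared separation + identical linker both ways => symmetric table
  expect_equal(unname(tab), unname(t(tab)))
  # five motifs give the 20 populated cells
  gs5 <- gen_sequence(unname(sos1_peptides),
                      linker_lengths = c(20, 25, 30, 35), seed = 6)
  tab5 <- ceff_table(gs5$layout, distance_delta(38))
  expect_equal(sum(!is.na(tab5)), 20L)

  # per-pair separations: missing key is a keyed error
  ids <- gs$layout$sites$motif_id
  seps <- list()
  for (i in ids) for (j in ids) if (i != j) {
    seps[[paste0(i, "->", j)]] <- distance_delta(40)
  }
  expect_equal(ceff_table(gs$layout, seps), tab)
  seps[[paste0(ids[1], "->", ids[2])]] <- NULL
  expect_error(ceff_table(gs$layout, seps), "missing separation")
})

test_that("longer tethers dilute the effective concentration at contact", {
  p <- wlc_params()
  v <- vapply(c(10, 20, 40, 80), function(n) ceff_delta(1, n, p)$value_mM,
              numeric(1))
  expect_true(all(diff(v) < 0))
})
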