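test_that("contour length is residues times per-residue length", {
  p <- wlc_params(lp = 3.0, b = 3.8)
  expect_equal(contour_length(20, p), 76.0)
  expect_equal(contour_length(1, p), 3.8)
  expect_equal(contour_length(203, p), 771.4)
  expect_error(contour_length(0, p), "n_linker")
  expect_error(wlc_params(lp = -1), "lp")
})

test_that("end-to-end vector density has the Gaussian-limit closed form", {
  p <- wlc_params()
  lc <- contour_length(40, p)
  expect_equal(wlc_vector_density(0, 40, p),
               (3 / (4 * pi * p$lp * lc))^1.5)
  # strictly decreasing in r
  r <- seq(0, 120, by = 2)
  expect_true(all(diff(wlc_vector_density(r, 40, p)) < 0))
  expect_error(wlc_vector_density(-1, 40, p), ">= 0")
})

test_that("vector density normalises and has <r^2> = 2 lp Lc by quadrature", {
  cases <- expand.grid(lp = c(3.0, 4.5), b = c(3.8, 3.6), n = c(18, 60))
  for (k in seq_len(nrow(cases))) {
    p <- wlc_params(lp = cases$lp[k], b = cases$b[k])
    a <- 2 * p$lp * contour_length(cases$n[k], p)
    norm <- integrate(function(r) 4 * pi * r^2 *
                        wlc_vector_density(r, cases$n[k], p),
                      0, Inf, rel.tol = 1e-10)$value
    m2 <- integrate(function(r) 4 * pi * r^4 *
                      wlc_vector_density(r, cases$n[k], p),
                    0, Inf, rel.tol = 1e-10)$value
    expect_equal(norm, 1, tolerance = 1e-6)
    expect_equal(m2, a, tolerance = 1e-6)
  }
})

test_that("doubling the contour length doubles the mean-square separation", {
  p <- wlc_params()
  msd <- function(n) {
    integrate(function(r) 4 * pi * r^4 * wlc_vector_density(r, n, p),
              0, Inf, rel.tol = 1e-10)$value
  }
  expect_equal(msd(60) / msd(30), 2, tolerance = 1e-6)
})

test_that("sample histograms integrate to one and recover known densities", {
  set.seed(7)
  # uniform on [10, 20]: density 0.1 per Angstrom in every bin
  x <- runif(1e5, 10, 20)
  h <- radial_density_from_samples(x, n_bins = 10)
  widths <- diff(h$breaks)
  expect_equal(sum(h$density * widths), 1, tolerance = 1e-12)
  p_bin <- widths / 10
  se <- sqrt(p_bin * (1 - p_bin) / 1e5) / widths
  expect_true(all(abs(h$density - 0.1) <= 3 * se))

  # degenerate trace: unit mass on a single bin
  h1 <- radial_density_from_samples(rep(15, 50), n_bins = 1)
  expect_equal(h1$density, 1 / diff(h1$breaks))

  # normalisation holds for arbitrary inputs
  for (seed in 1:3) {
    set.seed(seed)
    hh <- radial_density_from_samples(rlnorm(500, 3, 0.4), n_bins = 100)
    expect_equal(sum(hh$density * diff(hh$breaks)), 1, tolerance = 1e-12)
  }
  expect_error(radial_density_from_samples(numeric(0)), "at least 2")
  expect_error(radial_density_from_samples(c(1, -2)), "> 0")
})

test_that("histogram density sharpens around the sampling density at large n", {
  # sup-norm distance to the true density shrinks as samples accumulate
  dens_err <- function(n, seed) {
    set.seed(seed)
    x <- runif(n, 10, 20)
    h <- radial_density_from_samples(x, n_bins = 10)
    max(abs(h$density - 0.1))
  }
  expect_lt(dens_err(1e5, 11), dens_err(1e3, 11))
})

test_that("distance distribution constructors validate their invariants", {
  expect_error(distance_delta(0), "d0")
  expect_error(distance_samples(c(5, 0)), "> 0")
  expect_error(distance_histogram(c(0, 1, 2), c(0.3, 0.3)),
               "integrate to 1")
  ok <- distance_histogram(c(0, 1, 2), c(0.25, 0.75))
  expect_s3_class(ok, "distance_distribution")
})

test_that("distance traces round-trip through CSV with validation", {
  tr <- gen_distance_trace(200, mean_offset = 40, per_axis_sd = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_trace(tr, path)
  back <- read_distance_trace(path)
  expect_equal(back$samples, tr$distance_A, tolerance = 1e-12)

  bad <- tr; bad$distance_A[5] <- -1
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_distance_trace(bad, path2)
  expect_error(read_distance_trace(path2), "> 0")
})
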