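# Worm-like-chain end-to-end statistics for disordered linkers, and
# empirical radial densities from inter-site distance samples.

#' Worm-like-chain parameters for a disordered linker
#'
#' @param lp Persistence length in Angstrom. Default 3.0 A, the standard
#'   value for unfolded polypeptides.
#' @param b Contour length per residue in Angstrom. Default 3.8 A, the
#'   Calpha-Calpha virtual bond length.
#' @return An object of class `wlc_params`.
#' @export
wlc_params <- function(lp = 3.0, b = 3.8) {
  assert_scalar_number(lp, "lp", positive = TRUE)
  assert_scalar_number(b, "b", positive = TRUE)
  structure(list(lp = lp, b = b), class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("WLC parameters: lp = %g A, b = %g A/residue\n", x$lp, x$b))
  invisible(x)
}

#' Contour length of a linker
#'
#' @param n_linker Number of residues in the linker (>= 1).
#' @param params A [wlc_params()] object.
#' @return Contour length `n_linker * b` in Angstrom.
#' @export
contour_length <- function(n_linker, params = wlc_params()) {
  n_linker <- assert_count(n_linker, "n_linker", min = 1L)
  stopifnot(inherits(params, "wlc_params"))
  n_linker * params$b
}

#' Gaussian-limit WLC density of the end-to-end vector
#'
#' Probability density (per cubic Angstrom) of the end-to-end *vector* of a
#' worm-like chain in the long-chain (Gaussian) limit,
#' \deqn{p(r) = \left(\frac{3}{4\pi l_p L_c}\right)^{3/2}
#'   \exp\!\left(-\frac{3 r^2}{4 l_p L_c}\right),}
#' an isotropic density with mean-square end-to-end distance
#' \eqn{\langle r^2\rangle = 2 l_p L_c}. The radial (per-Angstrom) density
#' of the scalar distance is `4 pi r^2` times this; see
#' [wlc_radial_density()].
#'
#' @param r Scalar separation(s) in Angstrom (vectorised), non-negative.
#' @param n_linker Number of residues in the linker.
#' @param params A [wlc_params()] object.
#' @return Density values in 1/A^3.
#' @export
wlc_vector_density <- function(r, n_linker, params = wlc_params()) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0)) {
    stopf("'r' must be finite and >= 0")
  }
  lc <- contour_length(n_linker, params)
  a <- params$lp * lc
  (3 / (4 * pi * a))^1.5 * exp(-3 * r^2 / (4 * a))
}

#' Radial density of the scalar end-to-end distance
#'
#' `4 pi r^2` times [wlc_vector_density()]; integrates to 1 over the
#' half-line of separations.
#'
#' @inheritParams wlc_vector_density
#' @return Density values in 1/A.
#' @export
wlc_radial_density <- function(r, n_linker, params = wlc_params()) {
  4 * pi * r^2 * wlc_vector_density(r, n_linker, params)
}

#' Distance distributions for the bound inter-site separation
#'
#' Three interchangeable representations of the distance between the two
#' motif anchor points when one motif is bound: raw samples (e.g. from a
#' molecular-dynamics distance trace), a normalised histogram, or a single
#' delta point.
#'
#' @param samples Numeric vector of positive distances in Angstrom.
#' @return An object of class `distance_distribution`.
#' @export
distance_samples <- function(samples) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stopf("'samples' must be a non-empty numeric vector")
  }
  if (any(!is.finite(samples)) || any(samples <= 0)) {
    stopf("all distance samples must be finite and > 0")
  }
  structure(list(kind = "samples", samples = as.numeric(samples)),
            class = "distance_distribution")
}

#' @rdname distance_samples
#' @param breaks Histogram bin edges in Angstrom (increasing, positive).
#' @param density Probability density per Angstrom, one value per bin; must
#'   integrate to 1 over the bins (tolerance 1e-9).
#' @export
distance_histogram <- function(breaks, density) {
  if (!is.numeric(breaks) || length(breaks) < 2L || any(diff(breaks) <= 0) ||
      any(breaks < 0)) {
    stopf("'breaks' must be a non-negative increasing numeric vector")
  }
  if (length(density) != length(breaks) - 1L || any(density < 0)) {
    stopf("'density' must be non-negative with one value per bin")
  }
  mass <- sum(density * diff(breaks))
  if (abs(mass - 1) > 1e-9) {
    stopf("histogram density must integrate to 1 (got %.12g)", mass)
  }
  structure(list(kind = "histogram", breaks = as.numeric(breaks),
                 density = as.numeric(density)),
            class = "distance_distribution")
}

#' @rdname distance_samples
#' @param d0 Single separation in Angstrom (> 0) for the delta-point model.
#' @export
distance_delta <- function(d0) {
  assert_scalar_number(d0, "d0", positive = TRUE)
  structure(list(kind = "delta", d0 = d0), class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  switch(x$kind,
    samples = cat(sprintf(
      "Distance distribution (samples): n = %d, mean = %.2f A\n",
      length(x$samples), mean(x$samples))),
    histogram = cat(sprintf(
      "Distance distribution (histogram): %d bins on [%.2f, %.2f] A\n",
      length(x$density), min(x$breaks), max(x$breaks))),
    delta = cat(sprintf("Distance distribution (delta): d0 = %.2f A\n", x$d0)))
  invisible(x)
}

#' Empirical radial density from distance samples
#'
#' Bins scalar distance samples into `n_bins` equal-width intervals and
#' converts counts to a probability density per Angstrom,
#' `H(r) / (N * dr)`, which integrates to 1 over the binned support.
#'
#' @param samples Numeric vector of positive distances (>= 2 values), or a
#'   `distance_distribution` of kind `"samples"`.
#' @param n_bins Number of equal-width bins (default 100).
#' @return A `distance_distribution` of kind `"histogram"`.
#' @export
radial_density_from_samples <- function(samples, n_bins = 100L) {
  if (inherits(samples, "distance_distribution")) {
    if (samples$kind != "samples") stopf("'samples' distribution required")
    samples <- samples$samples
  }
  if (!is.numeric(samples) || length(samples) < 2L) {
    stopf("need at least 2 distance samples")
  }
  if (any(!is.finite(samples)) || any(samples <= 0)) {
    stopf("all distance samples must be finite and > 0")
  }
  n_bins <- assert_count(n_bins, "n_bins", min = 1L)
  rng <- range(samples)
  if (diff(rng) == 0) {
    # degenerate trace: one point; give it unit mass on a 1 A support
    rng <- rng + c(-0.5, 0.5)
    rng[1] <- max(rng[1], 0)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(findInterval(samples, breaks, rightmost.closed = TRUE), n_bins),
    nbins = n_bins)
  dr <- diff(breaks)
  distance_histogram(breaks, counts / (length(samples) * dr))
}

#' Read a distance trace from CSV
#'
#' Expects a two-column CSV with header `frame,distance_A`; distances must
#' be positive and finite.
#'
#' @param path Path to the CSV file.
#' @return A `distance_distribution` of kind `"samples"`.
#' @export
read_distance_trace <- function(path) {
  if (!file.exists(path)) stopf("distance trace not found: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("frame", "distance_A") %in% names(df))) {
    stopf("trace CSV must have columns 'frame' and 'distance_A'")
  }
  distance_samples(df$distance_A)
}
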