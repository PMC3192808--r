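# Effective local concentration of a tethered motif at the free SH3 site.
#
# C_eff is the overlap integral of two probability densities: the WLC
# end-to-end vector density of the linker (per A^3) and the density of the
# vector between the two bound anchor points on the adaptor. With only
# scalar inter-site distances available, the anchor distribution is treated
# as isotropic, so the overlap reduces to averaging the WLC vector density
# at the sampled radii. Densities in molecules/A^3 convert to molar via
# 1 molecule/A^3 = 1e27 / N_A mol/L.

AVOGADRO <- 6.02214076e23

# molecules per A^3 -> mol/L
.density_to_molar <- function(d) d * 1e27 / AVOGADRO

new_ceff_result <- function(value_M, back_end, n_samples = NA_integer_) {
  structure(list(value_M = value_M, value_mM = value_M * 1e3,
                 back_end = back_end, n_samples = n_samples),
            class = "ceff_result")
}

#' @export
print.ceff_result <- function(x, ...) {
  cat(sprintf("C_eff = %.4g mM  [back-end: %s%s]\n", x$value_mM, x$back_end,
              if (!is.na(x$n_samples)) sprintf(", n = %d", x$n_samples) else ""))
  invisible(x)
}

#' Effective concentration from an empirical distance trace (hybrid back-end)
#'
#' Averages the WLC end-to-end vector density over the sampled bound-state
#' inter-site distances and converts molecules/A^3 to mol/L. This realises
#' the overlap integral of the linker density with an empirically sampled
#' anchor-separation density.
#'
#' @param separation Numeric vector of positive distances in Angstrom, a
#'   `distance_distribution` (any kind), or a path readable by
#'   [read_distance_trace()].
#' @param linker_n Number of residues in the tether between the two motifs.
#' @param wlc A [wlc_params()] object.
#' @return A `ceff_result` with the value in molar (`value_M`) and
#'   millimolar (`value_mM`).
#' @export
ceff_hybrid <- function(separation, linker_n, wlc = wlc_params()) {
  if (is.character(separation) && length(separation) == 1L) {
    separation <- read_distance_trace(separation)
  }
  if (is.numeric(separation)) separation <- distance_samples(separation)
  stopifnot(inherits(separation, "distance_distribution"))
  if (separation$kind == "delta") {
    res <- ceff_delta(separation$d0, linker_n, wlc)
    return(res)
  }
  if (separation$kind == "histogram") {
    mids <- (separation$breaks[-1] + separation$breaks[-length(separation$breaks)]) / 2
    dens <- sum(separation$density * diff(separation$breaks) *
                  wlc_vector_density(mids, linker_n, wlc))
    return(new_ceff_result(.density_to_molar(dens), "hybrid"))
  }
  samples <- separation$samples
  if (length(samples) < 100L) {
    warning(sprintf("only %d distance samples; C_eff estimate may be noisy",
                    length(samples)), call. = FALSE)
  }
  dens <- mean(wlc_vector_density(samples, linker_n, wlc))
  new_ceff_result(.density_to_molar(dens), "hybrid", length(samples))
}

#' Effective concentration from a delta-point separation
#'
#' Evaluates the WLC vector density at a single anchor separation `d0`
#' (the delta-function approximation of the anchor-separation density).
#'
#' @param d0 Anchor separation in Angstrom (> 0).
#' @inheritParams ceff_hybrid
#' @return A `ceff_result`.
#' @export
ceff_delta <- function(d0, linker_n, wlc = wlc_params()) {
  assert_scalar_number(d0, "d0", positive = TRUE)
  dens <- wlc_vector_density(d0, linker_n, wlc)
  new_ceff_result(.density_to_molar(dens), "delta")
}

#' Effective-concentration table over ordered motif pairs
#'
#' For every ordered pair (N-bound motif, C-bound motif) of a layout,
#' computes C_eff of the free motif at the unoccupied SH3 site from the
#' linker separating the two motifs and a bound-state separation
#' distribution. The tether length is the number of residues strictly
#' between the two motif spans (any intervening motifs count as linker);
#' with `include_motif_flanks = TRUE` the spans of the two motifs
#' themselves are added to the contour.
#'
#' @param layout A [build_layout()] object with >= 2 sites.
#' @param separations Either a single `distance_distribution` shared by all
#'   pairs, or a named list keyed `"<n_motif>-><c_motif>"` with one
#'   distribution per ordered pair.
#' @param wlc A [wlc_params()] object.
#' @param include_motif_flanks Count the motif residues in the contour
#'   length (default `FALSE`).
#' @return A numeric matrix of C_eff in mM with rows indexed by the C-bound
#'   motif and columns by the N-bound motif; the diagonal is `NA` (one
#'   motif cannot occupy both domains).
#' @export
ceff_table <- function(layout, separations, wlc = wlc_params(),
                       include_motif_flanks = FALSE) {
  stopifnot(inherits(layout, "motif_layout"))
  sites <- layout$sites
  m <- nrow(sites)
  if (m < 2L) stopf("need at least two motif sites for a C_eff table")
  ids <- sites$motif_id
  shared <- inherits(separations, "distance_distribution")
  if (!shared && (!is.list(separations) || is.null(names(separations)))) {
    stopf("'separations' must be a distance_distribution or a named list")
  }
  out <- matrix(NA_real_, m, m, dimnames = list(c_motif = ids, n_motif = ids))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    n_id <- ids[i]; c_id <- ids[j]
    lo <- min(i, j); hi <- max(i, j)
    n_link <- sites$start[hi] - sites$end[lo] - 1L
    if (include_motif_flanks) {
      n_link <- n_link + (sites$end[lo] - sites$start[lo] + 1L) +
        (sites$end[hi] - sites$start[hi] + 1L)
    }
    if (n_link < 1L) stopf("adjacent motifs '%s' and '%s' have no linker",
                           n_id, c_id)
    sep <- if (shared) separations else {
      key <- paste0(n_id, "->", c_id)
      if (is.null(separations[[key]])) {
        stopf("missing separation distribution for pair '%s'", key)
      }
      separations[[key]]
    }
    out[c_id, n_id] <- ceff_hybrid(sep, n_link, wlc)$value_mM
  }
  out
}
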