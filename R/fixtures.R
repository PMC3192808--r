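# Packaged reference data for the Grb2-Sos1 system: single-site binding of
# the five Sos1 polyproline peptides (P1-P4 measured, RP predicted) to the
# two Grb2 SH3 domains, and effective local concentrations for every
# ordered motif pair. Compiled from published peptide-binding measurements
# and hybrid MD-polymer effective-concentration estimates.

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "avidity")
  if (p == "") stopf("packaged fixture '%s' not found", file)
  p
}

#' Single-site binding table for the Sos1 motifs
#'
#' Peptide sequences, computed and experimental binding free energies
#' (kcal/mol) and dissociation constants (uM) of the five Sos1 polyproline
#' motifs for one Grb2 SH3 domain. The predicted RP motif has no measured
#' values (`NA`); analyses substitute the affinities of P3.
#'
#' @param domain `"N"` for the N-terminal SH3 domain, `"C"` for the
#'   C-terminal one.
#' @return Data frame with columns `motif`, `sequence`, `dg_comp_kcal`,
#'   `kd_comp_uM`, `dg_expt_kcal`, `kd_expt_uM`.
#' @export
sos1_motif_table <- function(domain = c("N", "C")) {
  domain <- match.arg(domain)
  file <- if (domain == "N") "grb2_sos1_nsh3.csv" else "grb2_sos1_csh3.csv"
  utils::read.csv(.fixture_path(file), stringsAsFactors = FALSE)
}

#' Effective-concentration table for ordered Sos1 motif pairs
#'
#' Effective local concentration (mM) of the motif bound at the C-SH3 site
#' as experienced near the N-SH3 site and vice versa, for all 20 ordered
#' pairs of the five motifs, with the corresponding effective bivalent
#' dissociation constants (uM) as published.
#'
#' @return Data frame with columns `n_motif`, `c_motif`, `ceff_mM`,
#'   `kd_eff_uM`.
#' @export
sos1_ceff_table <- function() {
  utils::read.csv(.fixture_path("grb2_sos1_ceff.csv"),
                  stringsAsFactors = FALSE)
}

#' Reference affinity model for the Grb2-Sos1 system
#'
#' Assembles an [affinity_model()] from the packaged experimental
#' single-site dissociation constants and effective-concentration table,
#' substituting P3's affinities for the unmeasured RP motif.
#'
#' @param use_printed_kd_eff Use the published (rounded) effective
#'   bivalent Kd values instead of re-deriving them from the single-site
#'   constants and C_eff (default `FALSE`).
#' @return An `affinity_model` over motifs P1, P2, P3, RP, P4.
#' @export
sos1_affinity_model <- function(use_printed_kd_eff = FALSE) {
  nt <- sos1_motif_table("N")
  ct <- sos1_motif_table("C")
  ce <- sos1_ceff_table()
  kd_n <- stats::setNames(nt$kd_expt_uM, nt$motif)
  kd_c <- stats::setNames(ct$kd_expt_uM, ct$motif)
  ids <- nt$motif
  empty <- matrix(NA_real_, length(ids), length(ids),
                  dimnames = list(c_motif = ids, n_motif = ids))
  ceff <- empty
  kd_eff <- if (use_printed_kd_eff) empty else NULL
  for (k in seq_len(nrow(ce))) {
    ceff[ce$c_motif[k], ce$n_motif[k]] <- ce$ceff_mM[k]
    if (use_printed_kd_eff) {
      kd_eff[ce$c_motif[k], ce$n_motif[k]] <- ce$kd_eff_uM[k]
    }
  }
  affinity_model(kd_n, kd_c, ceff, substitutions = c(RP = "P3"),
                 kd_eff = kd_eff)
}
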