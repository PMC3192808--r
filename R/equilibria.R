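# Equilibrium-constant algebra for a bivalent adaptor on a multivalent
# scaffold: free-energy/Kd conversion, effective bivalent constants,
# enumeration of 1:1 and 2:1 binding configurations, and the composite
# association constants K_GS (adaptor + scaffold -> 1:1 complex) and
# K_GSG (adaptor + 1:1 complex -> 2:1 complex).

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal / (mol K)

#' Convert a binding free energy to a dissociation constant
#'
#' `Kd = exp(dG / RT)` with the standard-state convention in which
#' `dG = -7.1` kcal/mol at 298 K gives `Kd = 6.2e-6` M (6.2 uM).
#'
#' @param dg Binding free energy in kcal/mol (negative for favourable
#'   binding). Vectorised.
#' @param temperature Temperature in K (default 298).
#' @param gas_constant Gas constant in kcal/(mol K).
#' @return Dissociation constant(s) in molar.
#' @export
kd_from_dg <- function(dg, temperature = 298,
                       gas_constant = GAS_CONSTANT_KCAL) {
  assert_scalar_number(temperature, "temperature", positive = TRUE)
  exp(dg / (gas_constant * temperature))
}

#' @rdname kd_from_dg
#' @param kd Dissociation constant(s) in molar.
#' @return `dg_from_kd` returns the free energy in kcal/mol; the two
#'   functions are exact inverses.
#' @export
dg_from_kd <- function(kd, temperature = 298,
                       gas_constant = GAS_CONSTANT_KCAL) {
  if (any(kd <= 0)) stopf("'kd' must be > 0")
  gas_constant * temperature * log(kd)
}

#' Effective bivalent dissociation constant
#'
#' For motif `i` bound at the N-SH3 site and motif `j` at the C-SH3 site of
#' the same adaptor, the doubly bound state has
#' `Kd_eff = Kd_N(i) * Kd_C(j) / C_eff(i, j)`; equivalently the effective
#' association constant is the product of the two single-site association
#' constants times the effective local concentration. By detailed balance
#' the result does not depend on which domain binds first.
#'
#' @param kd_n Single-site dissociation constant of the N-SH3:motif
#'   interaction, in uM.
#' @param kd_c Single-site dissociation constant of the C-SH3:motif
#'   interaction, in uM.
#' @param ceff_mM Effective local concentration of the second motif at the
#'   free site, in mM.
#' @return Effective dissociation constant in uM. Vectorised.
#' @export
kd_eff_bivalent <- function(kd_n, kd_c, ceff_mM) {
  if (any(kd_n <= 0) || any(kd_c <= 0) || any(ceff_mM <= 0)) {
    stopf("all of 'kd_n', 'kd_c', 'ceff_mM' must be > 0")
  }
  kd_n * kd_c / (ceff_mM * 1000)  # uM * uM / uM -> uM
}

#' Assemble an affinity model for one adaptor-scaffold system
#'
#' Collects the single-site dissociation constants of every motif for the
#' two SH3 domains, the effective-concentration table over ordered motif
#' pairs, and a substitution map supplying proxies for motifs whose
#' affinities have not been measured (by default the predicted RP motif
#' inherits the affinities of P3, the weakest measured binder).
#'
#' @param kd_n Named numeric vector, uM: motif -> Kd at the N-SH3 domain.
#'   `NA` or missing entries are filled through `substitutions`.
#' @param kd_c Named numeric vector, uM: motif -> Kd at the C-SH3 domain.
#' @param ceff Effective concentrations in mM: either a square matrix with
#'   rows = C-bound motif and columns = N-bound motif (`NA` diagonal), or a
#'   long data frame with columns `n_motif`, `c_motif`, `ceff_mM`.
#' @param substitutions Named character vector mapping a motif to the motif
#'   whose measured affinities it borrows, e.g. `c(RP = "P3")`.
#' @param kd_eff Optional pre-computed effective bivalent Kd matrix (uM,
#'   same orientation as `ceff`); when `NULL` (default) it is derived from
#'   the single-site constants and `ceff` via [kd_eff_bivalent()].
#' @param temperature Temperature in K used for any free-energy
#'   conversions (default 298).
#' @return An object of class `affinity_model` with elements `motifs`,
#'   `kd_n`, `kd_c` (uM, substitutions applied), `ceff` (mM matrix),
#'   `kd_eff` (uM matrix), `substituted` (log of applied substitutions).
#' @export
affinity_model <- function(kd_n, kd_c, ceff, substitutions = c(RP = "P3"),
                           kd_eff = NULL, temperature = 298) {
  if (is.data.frame(ceff)) {
    req <- c("n_motif", "c_motif", "ceff_mM")
    if (!all(req %in% names(ceff))) {
      stopf("long-format 'ceff' needs columns %s", paste(req, collapse = ", "))
    }
    ids <- unique(c(ceff$n_motif, ceff$c_motif))
    mat <- matrix(NA_real_, length(ids), length(ids),
                  dimnames = list(c_motif = ids, n_motif = ids))
    for (k in seq_len(nrow(ceff))) {
      mat[ceff$c_motif[k], ceff$n_motif[k]] <- ceff$ceff_mM[k]
    }
    ceff <- mat
  }
  if (!is.matrix(ceff) || nrow(ceff) != ncol(ceff) ||
      !identical(rownames(ceff), colnames(ceff))) {
    stopf("'ceff' must be a square matrix with matching motif names")
  }
  motifs <- rownames(ceff)
  fill <- function(kd, domain) {
    out <- kd[motifs]
    names(out) <- motifs
    applied <- character(0)
    for (m in motifs[is.na(out)]) {
      proxy <- if (m %in% names(substitutions)) substitutions[[m]] else NULL
      if (is.null(proxy) || !proxy %in% names(kd) || is.na(kd[[proxy]])) {
        stopf("no measured %s-domain affinity for motif '%s' and no usable substitution",
              domain, m)
      }
      out[m] <- kd[[proxy]]
      applied <- c(applied, sprintf("%s:=%s (%s)", m, proxy, domain))
    }
    if (any(out <= 0)) stopf("all Kd values must be > 0")
    list(kd = out, applied = applied)
  }
  fn <- fill(kd_n, "N"); fc <- fill(kd_c, "C")
  off <- !diag(length(motifs))
  if (any(is.na(ceff[off])) || any(ceff[off] <= 0, na.rm = TRUE)) {
    stopf("'ceff' must be positive for every ordered motif pair")
  }
  if (is.null(kd_eff)) {
    kd_eff <- ceff
    for (cm in motifs) for (nm in motifs) {
      if (nm != cm) kd_eff[cm, nm] <- kd_eff_bivalent(fn$kd[[nm]], fc$kd[[cm]],
                                                      ceff[cm, nm])
    }
  } else {
    if (!is.matrix(kd_eff) || !identical(dimnames(kd_eff), dimnames(ceff))) {
      stopf("'kd_eff' must have the same dimnames as 'ceff'")
    }
  }
  structure(list(motifs = motifs, kd_n = fn$kd, kd_c = fc$kd, ceff = ceff,
                 kd_eff = kd_eff, substituted = c(fn$applied, fc$applied),
                 temperature = temperature),
            class = "affinity_model")
}

#' @export
print.affinity_model <- function(x, ...) {
  cat(sprintf("Affinity model: %d motifs (%s)\n", length(x$motifs),
              paste(x$motifs, collapse = ", ")))
  cat("Single-site Kd (uM):\n")
  print(rbind(N = x$kd_n, C = x$kd_c))
  if (length(x$substituted)) {
    cat("Substituted affinities:", paste(x$substituted, collapse = "; "), "\n")
  }
  cat("Effective bivalent Kd (uM), rows C-bound / cols N-bound:\n")
  print(round(x$kd_eff, 1))
  invisible(x)
}

#' Enumerate all 1:1 adaptor-scaffold binding configurations
#'
#' A 1:1 complex has the adaptor attached either through a single SH3
#' domain (2 domains x m motifs singly bound modes) or through both
#' domains to two distinct motifs (m * (m - 1) ordered doubly bound
#' modes); five motifs give the 30 distinct configurations.
#'
#' @param motifs Character vector of distinct motif labels.
#' @return Data frame with columns `mode`, `kind` (`"singly"`/`"doubly"`),
#'   `domain` (`"N"`, `"C"`, or `NA` for doubly), `n_motif`, `c_motif`.
#' @export
enumerate_1to1 <- function(motifs) {
  if (!is.character(motifs) || length(motifs) < 1L) {
    stopf("'motifs' must be a non-empty character vector")
  }
  if (anyDuplicated(motifs)) stopf("duplicate motif labels")
  singly <- rbind(
    data.frame(kind = "singly", domain = "N", n_motif = motifs,
               c_motif = NA_character_, stringsAsFactors = FALSE),
    data.frame(kind = "singly", domain = "C", n_motif = NA_character_,
               c_motif = motifs, stringsAsFactors = FALSE))
  pairs <- expand.grid(n_motif = motifs, c_motif = motifs,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$n_motif != pairs$c_motif, , drop = FALSE]
  doubly <- data.frame(kind = rep("doubly", nrow(pairs)),
                       domain = rep(NA_character_, nrow(pairs)),
                       n_motif = pairs$n_motif, c_motif = pairs$c_motif,
                       stringsAsFactors = FALSE)
  out <- rbind(singly, doubly)
  out$mode <- ifelse(out$kind == "singly",
                     paste0(out$domain, ":", ifelse(is.na(out$n_motif),
                                                    out$c_motif, out$n_motif)),
                     paste0("N:", out$n_motif, "+C:", out$c_motif))
  rownames(out) <- NULL
  out[, c("mode", "kind", "domain", "n_motif", "c_motif")]
}

# modes with association constants (1/Kd, uM^-1) from an affinity model
.mode_associations <- function(model, motifs) {
  modes <- enumerate_1to1(motifs)
  missing <- setdiff(motifs, model$motifs)
  if (length(missing)) {
    stopf("model has no affinities for motif(s): %s",
          paste(missing, collapse = ", "))
  }
  assoc <- numeric(nrow(modes))
  for (k in seq_len(nrow(modes))) {
    assoc[k] <- if (modes$kind[k] == "singly") {
      if (modes$domain[k] == "N") 1 / model$kd_n[[modes$n_motif[k]]]
      else 1 / model$kd_c[[modes$c_motif[k]]]
    } else {
      1 / model$kd_eff[modes$c_motif[k], modes$n_motif[k]]
    }
  }
  modes$association_per_uM <- assoc
  modes
}

#' Effective association constant for the 1:1 complex (K_GS)
#'
#' Sums the association constants of every 1:1 binding configuration:
#' `K_GS = sum over singly modes of 1/Kd + sum over doubly modes of
#' 1/Kd_eff`. The singly bound share of the total is the predicted
#' fraction of 1:1 complexes attached through a single SH3 domain.
#'
#' @param model An [affinity_model()].
#' @param motifs Motifs to include (default: all motifs in the model);
#'   subsets correspond to truncated scaffold fragments.
#' @return An object of class `kgs_summary`: list with `K_GS` (uM^-1),
#'   `Kd_GS` (uM), `fraction_singly`, `fraction_doubly`, and the per-mode
#'   table `modes`.
#' @export
k_gs <- function(model, motifs = model$motifs) {
  stopifnot(inherits(model, "affinity_model"))
  modes <- .mode_associations(model, motifs)
  singly <- sum(modes$association_per_uM[modes$kind == "singly"])
  doubly <- sum(modes$association_per_uM[modes$kind == "doubly"])
  K <- singly + doubly
  structure(list(K_GS = K, Kd_GS = 1 / K,
                 fraction_singly = singly / K,
                 fraction_doubly = doubly / K,
                 n_modes = nrow(modes), modes = modes),
            class = "kgs_summary")
}

#' @export
print.kgs_summary <- function(x, ...) {
  cat(sprintf("K_GS = %.4g uM^-1 (Kd_GS = %.3g uM) over %d modes\n",
              x$K_GS, x$Kd_GS, x$n_modes))
  cat(sprintf("  singly bound: %.1f%%   doubly bound: %.1f%%\n",
              100 * x$fraction_singly, 100 * x$fraction_doubly))
  invisible(x)
}

#' Effective association constant for the 2:1 complex (K_GSG)
#'
#' Enumerates every unordered pair of 1:1 binding modes whose motif sets
#' are disjoint (two adaptors cannot share a motif), weights each pair by
#' the product of the two mode association constants, and reports
#' `K_GSG = total weight / K_GS`, the association constant for a second
#' adaptor binding an existing 1:1 complex. The weight shares over
#' {both doubly, one doubly + one singly, both singly} give the predicted
#' composition of 2:1 complexes.
#'
#' Because the two adaptor molecules are indistinguishable, ordered pairs
#' are double-counted and a symmetry correction applies. Two conventions
#' are provided: `"paper"` (default) additionally halves the
#' doubly-singly cross terms, reproducing the published 68/27/5 percent
#' composition for the five-motif system; `"strict"` weights every
#' unordered pair of distinct modes by the plain product `K1 * K2`, which
#' on the same inputs gives roughly 52/44/4. The numerical consequences of
#' the choice are documented in the package vignette.
#'
#' @inheritParams k_gs
#' @param convention `"paper"` or `"strict"` (see Details).
#' @return An object of class `kgsg_summary`: list with `K_GS`, `K_GSG`
#'   (uM^-1), `Kd_GSG` (uM), `gsg_fractions` (named: `both_doubly`,
#'   `mixed`, `both_singly`), `n_pairs`, `convention`, and the pair table
#'   `pairs`.
#' @export
k_gsg <- function(model, motifs = model$motifs,
                  convention = c("paper", "strict")) {
  stopifnot(inherits(model, "affinity_model"))
  convention <- match.arg(convention)
  if (length(motifs) < 2L) stopf("need at least 2 motifs for a 2:1 complex")
  gs <- k_gs(model, motifs)
  modes <- gs$modes
  motif_sets <- lapply(seq_len(nrow(modes)), function(k) {
    stats::na.omit(c(modes$n_motif[k], modes$c_motif[k]))
  })
  n <- nrow(modes)
  rows <- vector("list", n * (n - 1L) / 2L)
  nr <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (length(intersect(motif_sets[[i]], motif_sets[[j]]))) next
    k1 <- modes$kind[i]; k2 <- modes$kind[j]
    category <- if (k1 == "doubly" && k2 == "doubly") "both_doubly"
      else if (k1 == "singly" && k2 == "singly") "both_singly"
      else "mixed"
    w <- modes$association_per_uM[i] * modes$association_per_uM[j]
    if (convention == "paper" && category == "mixed") w <- w / 2
    nr <- nr + 1L
    rows[[nr]] <- data.frame(mode_1 = modes$mode[i], mode_2 = modes$mode[j],
                             category = category, weight = w,
                             stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows[seq_len(nr)])
  total <- sum(pairs$weight)
  shares <- vapply(c("both_doubly", "mixed", "both_singly"), function(cat) {
    sum(pairs$weight[pairs$category == cat]) / total
  }, numeric(1))
  K_GSG <- total / gs$K_GS
  structure(list(K_GS = gs$K_GS, K_GSG = K_GSG, Kd_GSG = 1 / K_GSG,
                 gsg_fractions = shares, n_pairs = nr,
                 convention = convention, pairs = pairs),
            class = "kgsg_summary")
}

#' @export
print.kgsg_summary <- function(x, ...) {
  cat(sprintf("K_GSG = %.4g uM^-1 (Kd_GSG = %.3g uM), convention '%s', %d pairs\n",
              x$K_GSG, x$Kd_GSG, x$convention, x$n_pairs))
  cat(sprintf("  2:1 composition: both doubly %.1f%%, mixed %.1f%%, both singly %.1f%%\n",
              100 * x$gsg_fractions[["both_doubly"]],
              100 * x$gsg_fractions[["mixed"]],
              100 * x$gsg_fractions[["both_singly"]]))
  invisible(x)
}
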