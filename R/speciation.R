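# Mass-action speciation of adaptor (G) and scaffold (S) among free
# molecules, the 1:1 complex GS and the 2:1 complex GSG:
#   [GS]  = K_GS  [G][S]
#   [GSG] = K_GSG [G][GS]
# with conservation  G_t = [G] + [GS] + 2[GSG],  S_t = [S] + [GS] + [GSG].
# Eliminating [S] leaves one monotone equation in [G], solved by bracketed
# root-finding on [0, G_t] and polished by Newton steps.

#' Solve the three-species binding equilibrium
#'
#' @param total_G Total adaptor concentration (molar, >= 0).
#' @param total_S Total scaffold concentration (molar, >= 0).
#' @param K_GS Association constant for G + S -> GS (1/molar, >= 0).
#' @param K_GSG Association constant for G + GS -> GSG (1/molar, >= 0).
#' @param tol Relative tolerance of the root solve (default 1e-12).
#' @return An object of class `speciation_result`: list with `free_G`,
#'   `free_S`, `conc_GS`, `conc_GSG` (molar), `f_GSG` (fraction of
#'   complexes that are 2:1), `effective_stoichiometry` (bound G per bound
#'   S), `bound_fraction_G`, `bound_fraction_S`.
#' @examples
#' solve_equilibrium(1e-6, 1e-7, K_GS = 7.9e5, K_GSG = 6.3e4)
#' @export
solve_equilibrium <- function(total_G, total_S, K_GS, K_GSG, tol = 1e-12) {
  for (v in c("total_G", "total_S", "K_GS", "K_GSG")) {
    assert_scalar_number(get(v), v, nonneg = TRUE)
  }
  free_S_of <- function(g) total_S / (1 + K_GS * g + K_GS * K_GSG * g^2)
  g_balance <- function(g) {
    g + (K_GS * g + 2 * K_GS * K_GSG * g^2) * free_S_of(g) - total_G
  }
  if (total_G == 0 || total_S == 0 || K_GS == 0) {
    g <- total_G
  } else {
    root <- stats::uniroot(g_balance, c(0, total_G),
                           tol = max(tol * total_G, .Machine$double.xmin))
    g <- root$root
    # Newton polish: the uniroot interval tolerance alone can leave the
    # conservation residual above the 1e-9 relative target.
    for (it in 1:5) {
      f <- g_balance(g)
      if (abs(f) <= 1e-14 * total_G) break
      h <- max(1e-8 * g, 1e-30)
      df <- (g_balance(g + h) - g_balance(g - h)) / (2 * h)
      step <- f / df
      g_new <- min(max(g - step, 0), total_G)
      if (!is.finite(g_new)) break
      g <- g_new
    }
  }
  s <- free_S_of(g)
  gs <- K_GS * g * s
  gsg <- K_GSG * g * gs
  complexes <- gs + gsg
  bound_G <- gs + 2 * gsg
  bound_S <- gs + gsg
  structure(list(
    free_G = g, free_S = s, conc_GS = gs, conc_GSG = gsg,
    f_GSG = if (complexes > 0) gsg / complexes else 0,
    effective_stoichiometry = if (bound_S > 0) bound_G / bound_S else NA_real_,
    bound_fraction_G = if (total_G > 0) bound_G / total_G else 0,
    bound_fraction_S = if (total_S > 0) bound_S / total_S else 0,
    total_G = total_G, total_S = total_S, K_GS = K_GS, K_GSG = K_GSG),
    class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf(
    "Speciation (G_t = %.3g M, S_t = %.3g M):\n  [G] = %.3g  [S] = %.3g  [GS] = %.3g  [GSG] = %.3g M\n",
    x$total_G, x$total_S, x$free_G, x$free_S, x$conc_GS, x$conc_GSG))
  cat(sprintf("  f_GSG = %.3f   effective stoichiometry = %.3f\n",
              x$f_GSG, x$effective_stoichiometry))
  invisible(x)
}

#' Sweep the speciation over a range of concentration ratios
#'
#' Re-solves the equilibrium while one total concentration is varied as a
#' multiple of the other held fixed, mirroring titration experiments where
#' the adaptor is titrated against constant scaffold (or vice versa).
#'
#' @param total_G,total_S Baseline totals in molar; the varied one is
#'   replaced by `ratio * fixed` at each step.
#' @param K_GS,K_GSG Association constants (1/molar).
#' @param vary `"G"` to vary the adaptor at fixed scaffold, `"S"` for the
#'   converse.
#' @param ratios Positive numeric vector of varied/fixed concentration
#'   ratios.
#' @return Data frame with one row per ratio: totals, free and complex
#'   concentrations, `f_GSG`, `effective_stoichiometry` and bound
#'   fractions.
#' @export
stoichiometry_sweep <- function(total_G, total_S, K_GS, K_GSG,
                                vary = c("G", "S"), ratios) {
  vary <- match.arg(vary)
  if (!is.numeric(ratios) || length(ratios) < 1L || any(ratios <= 0)) {
    stopf("'ratios' must be a non-empty vector of positive numbers")
  }
  rows <- lapply(ratios, function(rho) {
    if (vary == "G") {
      res <- solve_equilibrium(rho * total_S, total_S, K_GS, K_GSG)
    } else {
      res <- solve_equilibrium(total_G, rho * total_G, K_GS, K_GSG)
    }
    data.frame(ratio = rho, total_G = res$total_G, total_S = res$total_S,
               free_G = res$free_G, free_S = res$free_S,
               conc_GS = res$conc_GS, conc_GSG = res$conc_GSG,
               f_GSG = res$f_GSG,
               effective_stoichiometry = res$effective_stoichiometry,
               bound_fraction_G = res$bound_fraction_G,
               bound_fraction_S = res$bound_fraction_S)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
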