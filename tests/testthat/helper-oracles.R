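# Shared fixtures and independent oracles used across test files.

# The five scaffold motif peptides (shorter N-SH3 constructs) and their
# expected consensus classes.
sos1_peptides <- c(P1 = "PPPVPPRRR", P2 = "PPAIPPRQP", P3 = "PPLLPPREP",
                   P4 = "GPPVPPRQS", RP = "TRRHLPSPP")
sos1_classes <- c(P1 = "II", P2 = "II", P3 = "II", P4 = "II", RP = "I")

# Closed-form overlap of an isotropic Gaussian displacement (mean vector
# mu, per-axis sd sigma) with the Gaussian-limit WLC vector density:
# independent oracle for ceff_hybrid on synthetic traces. Returns molar.
gaussian_overlap_ceff <- function(mu, sigma, linker_n, lp = 3.0, b = 3.8) {
  a <- 2 * lp * (linker_n * b)        # <r^2> of the WLC
  mu2 <- sum(mu^2)
  dens <- (3 / (2 * pi * (a + 3 * sigma^2)))^1.5 *
    exp(-3 * mu2 / (2 * (a + 3 * sigma^2)))
  dens * 1e27 / 6.02214076e23
}

# Independent 2:1 pair enumeration over ORDERED mode pairs with an
# explicit double-count correction, kept deliberately different from the
# package's unordered enumeration.
oracle_gsg_weights <- function(modes, convention) {
  sets <- lapply(seq_len(nrow(modes)), function(k) {
    na.omit(c(modes$n_motif[k], modes$c_motif[k]))
  })
  w <- c(both_doubly = 0, mixed = 0, both_singly = 0)
  n <- nrow(modes)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (length(intersect(sets[[i]], sets[[j]]))) next
    cat_ <- if (modes$kind[i] == "doubly" && modes$kind[j] == "doubly") {
      "both_doubly"
    } else if (modes$kind[i] == "singly" && modes$kind[j] == "singly") {
      "both_singly"
    } else "mixed"
    wt <- modes$association_per_uM[i] * modes$association_per_uM[j]
    if (convention == "paper" && cat_ == "mixed") wt <- wt / 2
    w[cat_] <- w[cat_] + wt / 2   # ordered pairs double-count each pair
  }
  w
}

# Closed-form bimolecular binding (no 2:1 complex): quadratic solution for
# G + S <-> GS with association K.
bimolecular_gs <- function(total_G, total_S, K) {
  kd <- 1 / K
  b <- total_G + total_S + kd
  (b - sqrt(b^2 - 4 * total_G * total_S)) / 2
}

# Random affinity model over a few motifs for property tests.
random_model <- function(m, seed) {
  set.seed(seed)
  ids <- paste0("M", seq_len(m))
  kd_n <- setNames(runif(m, 20, 2000), ids)
  kd_c <- setNames(runif(m, 20, 2000), ids)
  ceff <- matrix(runif(m * m, 0.5, 3), m, m,
                 dimnames = list(c_motif = ids, n_motif = ids))
  diag(ceff) <- NA
  affinity_model(kd_n, kd_c, ceff, substitutions = character(0))
}
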