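test_that("free energy and dissociation constant convert both ways", {
  # published pairs (kcal/mol -> uM, 298 K)
  expect_equal(kd_from_dg(-7.1) * 1e6, 6.2, tolerance = 0.01)
  expect_equal(kd_from_dg(-7.5) * 1e6, 3.2, tolerance = 0.02)
  expect_equal(kd_from_dg(-5.1) * 1e6, 182, tolerance = 0.01)
  expect_equal(kd_from_dg(-4.3) * 1e6, 702, tolerance = 0.01)
  expect_equal(kd_from_dg(0), 1)
  # exact round trip
  dg <- c(-7.5, -5.1, -0.3, 2)
  expect_equal(dg_from_kd(kd_from_dg(dg)), dg, tolerance = 1e-12)
  expect_error(dg_from_kd(-1), "> 0")
})

test_that("bivalent effective Kd follows Kd_N * Kd_C / C_eff", {
  expect_equal(kd_eff_bivalent(117, 125, 1.6), 9.140625)
  expect_equal(kd_eff_bivalent(56, 125, 2.1), 3.3333, tolerance = 1e-4)
  expect_equal(kd_eff_bivalent(117, 1396, 2.1), 77.777, tolerance = 1e-4)
  # no avidity without proximity: Kd_eff diverges as C_eff -> 0
  expect_gt(kd_eff_bivalent(100, 100, 1e-9), 1e9)
  expect_error(kd_eff_bivalent(-1, 100, 1), "> 0")
})

test_that("1:1 mode enumeration matches the exhaustive oracle", {
  expect_equal(nrow(enumerate_1to1(c("P1", "P2", "P3", "RP", "P4"))), 30L)
  expect_equal(nrow(enumerate_1to1("P1")), 2L)
  for (m in 1:6) {
    motifs <- paste0("x", seq_len(m))
    # oracle: assignments (n, c) over motifs + 'empty', minus the all-empty
    # and same-motif cases
    oracle <- 0L
    for (n_pick in c(motifs, NA)) for (c_pick in c(motifs, NA)) {
      if (is.na(n_pick) && is.na(c_pick)) next
      if (!is.na(n_pick) && !is.na(c_pick) && n_pick == c_pick) next
      oracle <- oracle + 1L
    }
    modes <- enumerate_1to1(motifs)
    expect_equal(nrow(modes), oracle)
    expect_equal(anyDuplicated(modes$mode), 0L)
  }
  expect_error(enumerate_1to1(c("a", "a")), "duplicate")
})

test_that("affinity model applies substitutions and validates coverage", {
  model <- sos1_affinity_model()
  expect_equal(unname(model$kd_n[["RP"]]), 117)
  expect_equal(unname(model$kd_c[["RP"]]), 1718)
  expect_length(model$substituted, 2L)
  expect_equal(model$kd_eff["P1", "P3"], 9.140625,
               ignore_attr = TRUE)
  # removing the substitution makes RP unsatisfiable
  nt <- sos1_motif_table("N"); ct <- sos1_motif_table("C")
  expect_error(
    affinity_model(setNames(nt$kd_expt_uM, nt$motif),
                   setNames(ct$kd_expt_uM, ct$motif),
                   sos1_ceff_table()[, c("n_motif", "c_motif", "ceff_mM")],
                   substitutions = character(0)),
    "no measured")
})

test_that("1:1 effective constant decomposes into singly and doubly shares", {
  model <- sos1_affinity_model()
  gs <- k_gs(model)
  # frozen from the hand-summed association oracle on the packaged tables
  expect_equal(gs$K_GS, 0.799489, tolerance = 1e-5)
  expect_equal(gs$Kd_GS, 1.2508, tolerance = 1e-4)
  expect_equal(gs$fraction_singly, 0.10435, tolerance = 1e-4)
  expect_equal(gs$fraction_singly + gs$fraction_doubly, 1, tolerance = 1e-12)
  expect_equal(gs$n_modes, 30L)

  # published rounded effective Kds give the same picture
  gsp <- k_gs(sos1_affinity_model(use_printed_kd_eff = TRUE))
  expect_equal(gsp$K_GS, 0.792415, tolerance = 1e-5)
  expect_equal(gsp$fraction_singly, 0.10528, tolerance = 1e-4)

  # N-terminal fragment (P1-P3) binds about 1.8 uM
  nt <- k_gs(model, c("P1", "P2", "P3"))
  expect_equal(nt$Kd_GS, 1.807, tolerance = 0.01)
})

test_that("2:1 composition matches the ordered-pair oracle for both conventions", {
  for (seed in c(2, 11)) {
    for (m in 3:5) {
      model <- random_model(m, seed)
      for (conv in c("paper", "strict")) {
        res <- k_gsg(model, convention = conv)
        want <- oracle_gsg_weights(k_gs(model)$modes, conv)
        expect_equal(res$K_GSG, sum(want) / res$K_GS, tolerance = 1e-12)
        expect_equal(unname(res$gsg_fractions), unname(want / sum(want)),
                     tolerance = 1e-12)
        expect_equal(sum(res$gsg_fractions), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("the reference system predicts the published 2:1 composition", {
  model <- sos1_affinity_model()
  paper <- k_gsg(model, convention = "paper")
  expect_equal(unname(paper$gsg_fractions),
               c(0.67554, 0.27371, 0.05075), tolerance = 1e-3)
  strict <- k_gsg(model, convention = "strict")
  expect_equal(unname(strict$gsg_fractions),
               c(0.53030, 0.42989, 0.03981), tolerance = 1e-3)
  # the convention flag is numerically consequential
  expect_gt(paper$gsg_fractions[["both_doubly"]] -
              strict$gsg_fractions[["both_doubly"]], 0.1)
})

test_that("with two motifs a 2:1 complex can only hold singly bound adaptors", {
  model <- random_model(2, seed = 4)
  res <- k_gsg(model)
  expect_equal(res$gsg_fractions[["both_singly"]], 1)
  expect_equal(res$gsg_fractions[["both_doubly"]], 0)
  expect_error(k_gsg(model, motifs = "M1"), "at least 2")
})

test_that("composite constants respond monotonically to the inputs", {
  model <- random_model(4, seed = 8)
  base_gs <- k_gs(model)$K_GS
  base_gsg_w <- sum(k_gsg(model)$pairs$weight)
  # improving one single-site affinity raises both total associations
  better <- model
  better$kd_n["M1"] <- better$kd_n["M1"] / 4
  better$kd_eff <- better$ceff
  for (cm in better$motifs) for (nm in better$motifs) {
    if (nm != cm) better$kd_eff[cm, nm] <-
        kd_eff_bivalent(better$kd_n[[nm]], better$kd_c[[cm]],
                        better$ceff[cm, nm])
  }
  expect_gt(k_gs(better)$K_GS, base_gs)
  expect_gt(sum(k_gsg(better)$pairs$weight), base_gsg_w)
  # removing a motif never increases K_GS
  expect_lt(k_gs(model, c("M1", "M2", "M3"))$K_GS, base_gs)
})

test_that("symmetric inputs make the 2:1 composition depend only on motif count", {
  make_uniform <- function(m, kd, ce) {
    ids <- paste0("u", seq_len(m))
    mat <- matrix(ce, m, m, dimnames = list(c_motif = ids, n_motif = ids))
    diag(mat) <- NA
    affinity_model(setNames(rep(kd, m), ids), setNames(rep(kd, m), ids),
                   mat, substitutions = character(0))
  }
  # the composition is set by the doubly/singly association ratio
  # C_eff/Kd, so co-scaling Kd and C_eff leaves it unchanged
  a <- k_gsg(make_uniform(4, kd = 200, ce = 1.5))$gsg_fractions
  b <- k_gsg(make_uniform(4, kd = 600, ce = 4.5))$gsg_fractions
  expect_equal(a, b, tolerance = 1e-12)
  # permuting motif labels of an asymmetric model leaves fractions unchanged
  model <- random_model(4, seed = 13)
  perm <- c("M3", "M1", "M4", "M2")
  shuffled <- affinity_model(model$kd_n[perm], model$kd_c[perm],
                             model$ceff[perm, perm],
                             substitutions = character(0))
  expect_equal(k_gsg(shuffled)$gsg_fractions,
               k_gsg(model)$gsg_fractions, tolerance = 1e-12)
})
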