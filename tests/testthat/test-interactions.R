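test_that("salt bridges require charge, identity and distance", {
  fx <- make_motif("salt_bridge_pair", 3.0)
  both_charged <- assign_states(fx$pkas, 7.0)
  sb <- detect_salt_bridges(fx$model, both_charged)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$kind, "salt_bridge")
  expect_equal(sb$distance, 3.0, tolerance = 1e-3)
  expect_equal(sort(c(sb$resid_a, sb$resid_b)), c("ARG", "GLU"))

  # protonated Glu (low pH) removes the charge precondition
  low <- assign_states(fx$pkas, 2.0)
  expect_equal(nrow(detect_salt_bridges(fx$model, low)), 0)

  # beyond the 4.0 A cutoff
  far <- make_motif("salt_bridge_pair", 4.5)
  expect_equal(nrow(detect_salt_bridges(far$model,
                                        assign_states(far$pkas, 7.0))), 0)
  # but detected again with a wider threshold
  wide <- interaction_params(salt_bridge_dist = 5.0)
  expect_equal(nrow(detect_salt_bridges(far$model,
                                        assign_states(far$pkas, 7.0),
                                        wide)), 1)
})

test_that("protonating the acid never creates a salt bridge involving it", {
  for (d in c(2.8, 3.5, 3.9)) {
    fx <- make_motif("salt_bridge_pair", d)
    hi <- detect_salt_bridges(fx$model, assign_states(fx$pkas, 7.0))
    lo <- detect_salt_bridges(fx$model, assign_states(fx$pkas, 2.0))
    glu_in <- function(r) any(r$resid_a == "GLU" | r$resid_b == "GLU")
    expect_true(!glu_in(lo))
    expect_true(nrow(hi) >= nrow(lo))
  }
})

test_that("hydrogen bonds follow distance and state-dependent capabilities", {
  fx <- make_motif("hbond_pair", 2.9)  # His NE2 ... Ser OG
  neutral <- assign_states(fx$pkas, 7.5)
  hb <- detect_hydrogen_bonds(fx$model, neutral)
  expect_equal(nrow(hb), 1)
  expect_true("OG" %in% c(hb$label_a, hb$label_b))
  expect_true("NE2" %in% c(hb$label_a, hb$label_b))
  expect_true(hb$state_dependent)

  # beyond the cutoff
  far <- make_motif("hbond_pair", 3.8)
  expect_equal(nrow(detect_hydrogen_bonds(far$model,
                                          assign_states(far$pkas, 7.5))), 0)

  # capability tables differ between the two states: a protonated His ring
  # nitrogen cannot accept
  prot <- assign_states(fx$pkas, 5.5)
  his_n <- neutral[neutral$resid == "HIS" & neutral$group == "side_chain", ]
  his_p <- prot[prot$resid == "HIS" & prot$group == "side_chain", ]
  expect_true(his_n$acceptor_capable)
  expect_false(his_p$acceptor_capable)
  expect_true(his_p$donor_capable)
})

test_that("a protonated carboxylate turns a former salt-bridge contact into a donor bond", {
  fx <- make_motif("salt_bridge_pair", 3.0)
  hi <- detect_all(fx$model, assign_states(fx$pkas, 7.0))
  lo <- detect_all(fx$model, assign_states(fx$pkas, 2.0))
  expect_equal(hi$kind, "salt_bridge")       # H-bond for same pair suppressed
  expect_equal(lo$kind, "hydrogen_bond")     # COOH...N contact at low pH
})

test_that("aromatic detection recategorizes protonated His rings as cations", {
  fx <- make_motif("ring_stack", 4.5)
  neutral <- assign_states(fx$pkas, 7.5)
  ar <- detect_aromatic(fx$model, neutral)
  expect_equal(ar$kind, "pi_pi")
  expect_equal(ar$distance, 4.5, tolerance = 1e-3)

  # one His protonated (pKa override): pi-pi disappears, cation-pi appears
  pk <- fx$pkas
  pk$pka[pk$key == "A:2" & pk$group == "side_chain"] <- 8.0
  mixed <- assign_states(pk, 7.5)
  ar2 <- detect_aromatic(fx$model, mixed)
  expect_equal(ar2$kind, "cation_pi")
  expect_equal(ar2$key_a, "A:2")             # the cation partner comes first

  # both protonated: no rings left, nothing reported
  low <- assign_states(fx$pkas, 5.5)
  expect_equal(nrow(detect_aromatic(fx$model, low)), 0)

  # Arg guanidinium to neutral His ring
  cp <- make_motif("cation_pi_pair", 5.0)
  ar3 <- detect_aromatic(cp$model, assign_states(cp$pkas, 7.0))
  expect_equal(ar3$kind, "cation_pi")
  expect_equal(ar3$distance, 5.0, tolerance = 1e-3)
  # beyond the 6.0 A cation-pi cutoff
  cp2 <- make_motif("cation_pi_pair", 6.5)
  expect_equal(nrow(detect_aromatic(cp2$model,
                                    assign_states(cp2$pkas, 7.0))), 0)
})

test_that("detect_all composes the three detectors deterministically", {
  gly <- parse_structure(tri_gly_pdb_text())
  st <- assign_states(assign_model_pkas(gly), 7)
  expect_equal(nrow(detect_all(gly, st)), 0)

  fx <- make_motif("salt_bridge_pair", 3.0)
  states <- assign_states(fx$pkas, 7.0)
  all1 <- detect_all(fx$model, states)
  expect_equal(as.data.frame(all1)[all1$kind == "salt_bridge", ],
               as.data.frame(detect_salt_bridges(fx$model, states)),
               ignore_attr = TRUE)
  all2 <- detect_all(fx$model, states)
  expect_identical(as.data.frame(all1), as.data.frame(all2))
  expect_equal(attr(all1, "pH"), 7.0)
})

test_that("detection matches the brute-force all-pairs oracle on random fixtures", {
  n_checked <- 0
  for (seed in 1:30) {
    rnd <- make_random_structure(10, seed = 1000 + seed, box = 18)
    for (ph in c(5.5, 7.5)) {
      st <- assign_states(rnd$pkas, ph)
      recs <- detect_all(rnd$model, st)
      expect_equal(records_sb_ids(recs),
                   oracle_salt_bridges(rnd$model, st),
                   info = sprintf("salt bridges, seed %d pH %.1f", seed, ph))
      expect_equal(records_hb_ids(recs),
                   oracle_hydrogen_bonds(rnd$model, st),
                   info = sprintf("hydrogen bonds, seed %d pH %.1f", seed, ph))
      ora <- oracle_aromatics(rnd$model, st)
      expect_equal(records_pipi_ids(recs), ora$pi_pi,
                   info = sprintf("pi-pi, seed %d pH %.1f", seed, ph))
      expect_equal(records_catpi_ids(recs), ora$cation_pi,
                   info = sprintf("cation-pi, seed %d pH %.1f", seed, ph))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 60)
})

test_that("records are canonical: partner_a precedes partner_b", {
  for (seed in 1:5) {
    rnd <- make_random_structure(10, seed = 2000 + seed, box = 16)
    recs <- detect_all(rnd$model, assign_states(rnd$pkas, 6.5))
    sym <- recs[recs$kind != "cation_pi", ]
    if (nrow(sym) > 0)
      expect_true(all(sym$resno_a < sym$resno_b |
                        sym$chain_a != sym$chain_b))
    # no duplicates under canonical identity
    expect_false(any(duplicated(paste(recs$kind, recs$key_a, recs$label_a,
                                      recs$key_b, recs$label_b))))
    # bonded neighbors are never reported
    expect_true(all(abs(recs$resno_a - recs$resno_b) > 1 |
                      recs$chain_a != recs$chain_b))
  }
})
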