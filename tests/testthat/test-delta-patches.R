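# three His rings in a row: centroid spacing `gap` between neighbors, so
# residues 1-3 form a path (not a triangle) in the proximity graph
his_path_model <- function(gap = 6.5, n = 3) {
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    phdelta:::fixture_atom_rows(phdelta:::TPL_HIS_RING, "HIS", "A", i * 8,
                                offset = c((i - 1) * gap, 0, 0))))
  model <- parse_structure(paste(phdelta:::fixture_pdb_text(rows),
                                 collapse = "\n"))
  list(model = model, pkas = assign_model_pkas(model))
}

test_that("interaction deltas are set differences with antisymmetry", {
  fx <- make_motif("salt_bridge_pair", 3.0)
  hi <- detect_all(fx$model, assign_states(fx$pkas, 7.0))
  lo <- detect_all(fx$model, assign_states(fx$pkas, 2.0))

  same <- interaction_delta(hi, hi)
  expect_equal(nrow(same$created), 0)
  expect_equal(nrow(same$destroyed), 0)

  d <- interaction_delta(hi, lo)   # reference high pH, interest low pH
  expect_equal(d$destroyed$kind, "salt_bridge")
  expect_equal(d$created$kind, "hydrogen_bond")

  rev <- interaction_delta(lo, hi)
  expect_equal(rev$created, d$destroyed)
  expect_equal(rev$destroyed, d$created)

  # per-residue summary counts both partners
  expect_setequal(d$per_residue$key[d$per_residue$direction == "destroyed"],
                  c("A:2", "A:10"))

  # mismatched geometry parameters are refused
  other <- detect_all(fx$model, assign_states(fx$pkas, 2.0),
                      interaction_params(hbond_dist = 3.2))
  expect_error(interaction_delta(hi, other), "different geometry")
})

test_that("His ring recategorization yields one destroyed and one created record", {
  fx <- make_motif("ring_stack", 4.5)
  pk <- fx$pkas
  pk$pka[pk$key == "A:2" & pk$group == "side_chain"] <- 8.0
  hi <- detect_all(fx$model, assign_states(pk, 7.5))   # one His protonated
  lo <- detect_all(fx$model, assign_states(pk, 9.0))   # both neutral
  d <- interaction_delta(lo, hi)
  expect_equal(d$destroyed$kind, "pi_pi")
  expect_equal(d$created$kind, "cation_pi")
})

test_that("every created or destroyed bond involves a shifting residue", {
  for (seed in 1:10) {
    rnd <- make_random_structure(10, seed = 3000 + seed, box = 16)
    hi <- detect_all(rnd$model, assign_states(rnd$pkas, 7.5))
    lo <- detect_all(rnd$model, assign_states(rnd$pkas, 5.5))
    d <- interaction_delta(hi, lo)
    sh <- shifting_residues(rnd$pkas, 5.5, 7.5)
    chg <- rbind(d$created, d$destroyed)
    if (nrow(chg) > 0)
      expect_true(all(chg$state_dependent |
                        chg$key_a %in% sh$key | chg$key_b %in% sh$key))
  }
})

test_that("patch graph edges follow the distance rule in every mode", {
  fx <- his_path_model(gap = 5, n = 2)
  sh <- shifting_residues(fx$pkas, 5.5, 7.5)
  g8 <- build_patch_graph(fx$model, sh, radius = 8)
  expect_equal(igraph::ecount(g8), 1)
  g3 <- build_patch_graph(fx$model, sh, radius = 3)
  expect_equal(igraph::ecount(g3), 0)
  # edge appears exactly at the minimum side-chain distance
  dmin <- oracle_min_sidechain_dist(fx$model, "A:8", "A:16")
  expect_equal(igraph::ecount(build_patch_graph(fx$model, sh,
                                                radius = dmin + 1e-6)), 1)
  expect_equal(igraph::ecount(build_patch_graph(fx$model, sh,
                                                radius = dmin - 1e-6)), 0)
  for (mode in c("any_atom", "centroid"))
    expect_s3_class(build_patch_graph(fx$model, sh, radius = 8,
                                      distance_mode = mode), "igraph")
})

test_that("patch graph adjacency matches brute-force distance thresholding", {
  for (seed in 1:15) {
    rnd <- make_random_structure(12, seed = 4000 + seed, box = 25)
    pk <- rnd$pkas
    set.seed(seed); pk$pka <- round(runif(nrow(pk), 5, 8), 2)
    sh <- shifting_residues(pk, 5.5, 7.5)
    radius <- runif(1, 5, 10)
    g <- build_patch_graph(rnd$model, sh, radius = radius)
    keys <- igraph::vertex_attr(g, "name")
    if (length(keys) < 2) next
    adj <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
    for (i in 1:(length(keys) - 1)) for (j in (i + 1):length(keys)) {
      expect_equal(unname(adj[i, j]),
                   oracle_min_sidechain_dist(rnd$model, keys[i],
                                             keys[j]) <= radius,
                   info = sprintf("seed %d pair %s-%s radius %.2f",
                                  seed, keys[i], keys[j], radius))
    }
    # components equal BFS on the brute-force adjacency
    p <- find_patches(g, min_size = 2)
    comp <- oracle_components(adj)
    brute <- unname(Filter(function(m) length(m) >= 2, split(keys, comp)))
    expect_setequal(lapply(p$patches, sort), lapply(brute, sort))
  }
})

test_that("patches are connected components of at least min_size members", {
  # path a-b-c: one patch of 3 under transitive closure, no clique needed
  fx <- his_path_model(gap = 6.5, n = 3)
  sh <- shifting_residues(fx$pkas, 5.5, 7.5)
  g <- build_patch_graph(fx$model, sh, radius = 8)
  p <- find_patches(g, min_size = 3)
  expect_equal(length(p$patches), 1)
  expect_setequal(p$patches[[1]], c("A:8", "A:16", "A:24"))
  expect_equal(length(p$near_patch), 0)

  # two disjoint edges: zero patches at min_size 3, both reported near-patch
  fx4 <- his_path_model(gap = 30, n = 2)
  rows <- rbind(
    phdelta:::fixture_atom_rows(phdelta:::TPL_HIS_RING, "HIS", "A", 8),
    phdelta:::fixture_atom_rows(phdelta:::TPL_HIS_RING, "HIS", "A", 16,
                                offset = c(6, 0, 0)),
    phdelta:::fixture_atom_rows(phdelta:::TPL_HIS_RING, "HIS", "A", 24,
                                offset = c(40, 0, 0)),
    phdelta:::fixture_atom_rows(phdelta:::TPL_HIS_RING, "HIS", "A", 32,
                                offset = c(46, 0, 0)))
  model <- parse_structure(paste(phdelta:::fixture_pdb_text(rows),
                                 collapse = "\n"))
  sh2 <- shifting_residues(assign_model_pkas(model), 5.5, 7.5)
  g2 <- build_patch_graph(model, sh2, radius = 8)
  p2 <- find_patches(g2, min_size = 3)
  expect_equal(length(p2$patches), 0)
  expect_equal(length(p2$near_patch), 4)
  # with min_size 2 the same graph yields two patches
  p3 <- find_patches(g2, min_size = 2)
  expect_equal(lengths(p3$patches), c(2L, 2L))
  expect_error(find_patches(g2, min_size = 1), "at least 2")

  # every patch member is a shifting residue
  expect_true(all(unlist(p3$patches) %in% sh2$key))
})

test_that("enlarging the radius only merges components", {
  for (seed in 1:8) {
    rnd <- make_random_structure(10, seed = 5000 + seed, box = 28)
    pk <- rnd$pkas
    set.seed(seed); pk$pka <- round(runif(nrow(pk), 5, 8), 2)
    sh <- shifting_residues(pk, 5.5, 7.5)
    if (nrow(sh[!sh$is_terminal, ]) < 2) next
    g_small <- build_patch_graph(rnd$model, sh, radius = 6)
    g_big <- build_patch_graph(rnd$model, sh, radius = 10)
    p_small <- find_patches(g_small, min_size = 2)
    p_big <- find_patches(g_big, min_size = 2)
    # each small patch is contained in exactly one big patch
    for (m in p_small$patches) {
      containing <- Filter(function(b) all(m %in% b), p_big$patches)
      expect_equal(length(containing), 1)
    }
  }
})

test_that("terminal-group shifts are excluded from patches by default", {
  fx <- his_path_model(gap = 5, n = 3)
  sh <- shifting_residues(fx$pkas, 7.5, 8.5)  # only the N-terminus shifts
  g <- build_patch_graph(fx$model, sh, radius = 8)
  expect_equal(igraph::vcount(g), 0)
  g_incl <- build_patch_graph(fx$model, sh, radius = 8,
                              include_termini = TRUE)
  expect_equal(igraph::vcount(g_incl), 1)
})

test_that("the PyMOL script colors shifting, delta and patch layers", {
  fx <- make_motif("shifting_cluster")
  res <- run_structure_mode(fx$model, 7.5, 5.5)
  path <- tempfile(fileext = ".pml")
  lines <- write_pml(path, res$shifting, res$delta, res$patches)
  expect_true(file.exists(path))
  expect_true(any(grepl("color yellow, shifting", lines)))
  expect_true(any(grepl("color orange, delta_bonds", lines)))
  expect_true(any(grepl("color green, patch_members", lines)))
})
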