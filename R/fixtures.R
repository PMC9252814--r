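# Idealized residue templates for toy-structure construction.  Each template
# is a matrix of heavy-atom coordinates (rows named by PDB atom name) in an
# "anchored" frame: the motif's interaction anchor (an atom, or a ring or
# guanidinium centroid) sits exactly at the origin and every other atom has
# x <= 0.  Placing a second residue mirrored through the y-z plane at
# (d, 0, 0) then makes the anchor-anchor distance the exact minimum distance
# between the two residues, which is what the geometry contract of
# make_motif() relies on.

tpl <- function(...) {
  v <- list(...)
  m <- do.call(rbind, v)
  rownames(m) <- names(v)
  m
}

TPL_ARG_NH1 <- tpl(
  NH1 = c(0, 0, 0), CZ = c(-1.33, 0, 0),
  NH2 = c(-1.99, 1.15, 0), NE = c(-1.99, -1.15, 0),
  CD = c(-3.45, -1.25, 0.1), CG = c(-4.15, -2.55, 0.2),
  CB = c(-5.65, -2.55, 0.3), CA = c(-6.35, -1.25, 0.8),
  N = c(-7.75, -1.30, 0.8), C = c(-6.05, -0.05, 1.6), O = c(-6.25, 1.05, 1.1))

TPL_GLU_OE1 <- tpl(
  OE1 = c(0, 0, 0), CD = c(-1.25, 0, 0), OE2 = c(-1.85, 1.05, 0),
  CG = c(-1.95, -1.30, 0), CB = c(-3.45, -1.30, 0.1),
  CA = c(-4.15, -0.05, 0.6), N = c(-5.55, -0.10, 0.6),
  C = c(-3.95, 1.20, 1.3), O = c(-4.35, 2.30, 0.9))

TPL_ASP_OD1 <- tpl(
  OD1 = c(0, 0, 0), CG = c(-1.25, 0, 0), OD2 = c(-1.85, 1.05, 0),
  CB = c(-1.95, -1.30, 0), CA = c(-3.45, -1.30, 0.1),
  N = c(-4.15, -2.55, 0.4), C = c(-4.15, -0.05, 0.6), O = c(-5.35, 0.0, 0.7))

TPL_LYS_NZ <- tpl(
  NZ = c(0, 0, 0), CE = c(-1.50, 0, 0), CD = c(-2.20, -1.30, 0),
  CG = c(-3.70, -1.30, 0), CB = c(-4.40, -2.60, 0.1),
  CA = c(-5.90, -2.60, 0.2), N = c(-6.60, -3.85, 0.5),
  C = c(-6.60, -1.35, 0.7), O = c(-7.80, -1.30, 0.8))

TPL_SER_OG <- tpl(
  OG = c(0, 0, 0), CB = c(-1.40, 0, 0), CA = c(-2.10, -1.30, 0),
  N = c(-3.50, -1.30, 0.3), C = c(-1.50, -2.60, 0.3), O = c(-2.10, -3.65, 0.6))

# histidine with the imidazole ring in the y-z plane, ring centroid at origin
TPL_HIS_RING <- local({
  r <- 1.17
  ang <- c(CE1 = 90, ND1 = 162, CG = 234, CD2 = 306, NE2 = 18) * pi / 180
  ring <- t(vapply(ang, function(a) c(0, r * cos(a), r * sin(a)), numeric(3)))
  cg <- ring["CG", ]
  rest <- rbind(CB = cg + c(-1.25, -0.45, -0.65),
                CA = cg + c(-2.55, -0.40, -1.35),
                N = cg + c(-2.65, 0.80, -2.15),
                C = cg + c(-3.75, -0.90, -0.65),
                O = cg + c(-4.85, -0.40, -0.85))
  rbind(ring, rest)
})

# histidine anchored at NE2 (hydrogen-bond acceptor/donor atom)
TPL_HIS_NE2 <- sweep(TPL_HIS_RING, 2, TPL_HIS_RING["NE2", ])

# arginine with the guanidinium plane in the y-z plane, centroid at origin
TPL_ARG_GUAN <- local({
  plane <- tpl(CZ = c(0, 0, 0.33), NH1 = c(0, 1.15, 0.99),
               NH2 = c(0, -1.15, 0.99), NE = c(0, 0, -1.00))
  plane <- sweep(plane, 2, colMeans(plane))
  ne <- plane["NE", ]
  rest <- rbind(CD = ne + c(-1.30, 0.05, -0.75),
                CG = ne + c(-2.75, 0.05, -0.80),
                CB = ne + c(-3.45, -1.25, -0.85),
                CA = ne + c(-4.95, -1.25, -0.90),
                N = ne + c(-5.65, -2.45, -0.60),
                C = ne + c(-5.55, -0.05, -0.40),
                O = ne + c(-6.75, 0.05, -0.40))
  rbind(plane, rest)
})

TPL_GLY <- tpl(N = c(-1.20, 0.80, 0), CA = c(0, 0, 0),
               C = c(-1.30, -0.80, 0.6), O = c(-2.40, -0.30, 0.8))

FIXTURE_TEMPLATES <- list(
  ARG = TPL_ARG_NH1, GLU = TPL_GLU_OE1, ASP = TPL_ASP_OD1,
  LYS = TPL_LYS_NZ, SER = TPL_SER_OG, HIS = TPL_HIS_RING, GLY = TPL_GLY)

# mirror through the y-z plane (x -> -x, y -> -y keeps chirality sane enough
# for a toy fixture and maps "all x <= 0" to "all x >= 0")
mirror_tpl <- function(m) {
  m[, 1] <- -m[, 1]; m[, 2] <- -m[, 2]
  m
}

fixture_atom_rows <- function(tplm, resid, chain, resno, offset = c(0, 0, 0)) {
  data.frame(elety = rownames(tplm), resid = resid, chain = chain,
             resno = resno,
             x = tplm[, 1] + offset[1], y = tplm[, 2] + offset[2],
             z = tplm[, 3] + offset[3],
             element = substr(rownames(tplm), 1, 1),
             stringsAsFactors = FALSE)
}

fixture_pdb_text <- function(atom_rows) {
  format_pdb_atom(seq_len(nrow(atom_rows)), atom_rows$elety, atom_rows$resid,
                  atom_rows$chain, atom_rows$resno, "",
                  atom_rows$x, atom_rows$y, atom_rows$z, 1.0, 0.0,
                  atom_rows$element)
}

#' Build a toy structure containing a controlled interaction motif
#'
#' Emits genuine PDB text containing one of the named two- or three-residue
#' motifs with the requested inter-group distance exact to better than
#' 0.01 A, parses it through the public [parse_structure] path, and returns
#' the model together with a model-table pKa set (optionally overridden per
#' residue).  Residues are spaced in sequence so that the bonded-neighbor
#' exclusion of the detectors never applies.
#'
#' @param motif one of `"salt_bridge_pair"` (Arg NH1 ... Glu OE1),
#'   `"hbond_pair"` (His NE2 ... Ser OG), `"ring_stack"` (two His ring
#'   centroids), `"cation_pi_pair"` (Arg guanidinium centroid ... His ring
#'   centroid), `"shifting_cluster"` (three His, pairwise ring-centroid
#'   distance `distance`).
#' @param distance the controlled inter-anchor distance in Angstrom.
#' @param pka_overrides optional named numeric vector: names are residue
#'   keys (e.g. `"A:2"`), values replace the side-chain pKa.
#' @return list with `model` (a `structure_model`), `pkas` (a `pka_set`),
#'   and `pdb` (the PDB text lines).
#' @export
make_motif <- function(motif = c("salt_bridge_pair", "hbond_pair",
                                 "ring_stack", "cation_pi_pair",
                                 "shifting_cluster"),
                       distance = NULL, pka_overrides = NULL) {
  motif <- match.arg(motif)
  if (is.null(distance))
    distance <- switch(motif, salt_bridge_pair = 3.0, hbond_pair = 2.9,
                       ring_stack = 4.5, cation_pi_pair = 5.0,
                       shifting_cluster = 6.0)
  if (distance <= 0) stop("distance must be positive")
  min_sep <- switch(motif, salt_bridge_pair = 1.5, hbond_pair = 1.5, 2.0)
  if (distance < min_sep)
    stop("distance ", distance, " A is not achievable without atom clashes")
  d <- distance
  rows <- switch(motif,
    salt_bridge_pair = rbind(
      fixture_atom_rows(TPL_ARG_NH1, "ARG", "A", 2),
      fixture_atom_rows(mirror_tpl(TPL_GLU_OE1), "GLU", "A", 10, c(d, 0, 0))),
    hbond_pair = rbind(
      fixture_atom_rows(TPL_HIS_NE2, "HIS", "A", 2),
      fixture_atom_rows(mirror_tpl(TPL_SER_OG), "SER", "A", 10, c(d, 0, 0))),
    ring_stack = rbind(
      fixture_atom_rows(TPL_HIS_RING, "HIS", "A", 2),
      fixture_atom_rows(mirror_tpl(TPL_HIS_RING), "HIS", "A", 10, c(d, 0, 0))),
    cation_pi_pair = rbind(
      fixture_atom_rows(TPL_ARG_GUAN, "ARG", "A", 2),
      fixture_atom_rows(mirror_tpl(TPL_HIS_RING), "HIS", "A", 10, c(d, 0, 0))),
    shifting_cluster = rbind(
      fixture_atom_rows(TPL_HIS_RING, "HIS", "A", 2),
      fixture_atom_rows(mirror_tpl(TPL_HIS_RING), "HIS", "A", 10, c(d, 0, 0)),
      fixture_atom_rows(TPL_HIS_RING, "HIS", "A", 18,
                        c(d / 2, d * sqrt(3) / 2, 0))))
  pdb <- fixture_pdb_text(rows)
  model <- parse_structure(paste(pdb, collapse = "\n"),
                           structure_id = motif)
  pkas <- assign_model_pkas(model)
  if (!is.null(pka_overrides)) {
    for (k in names(pka_overrides)) {
      i <- which(pkas$key == k & pkas$group == "side_chain")
      if (length(i) == 0) stop("pka override refers to unknown residue ", k)
      pkas$pka[i] <- pka_overrides[[k]]
    }
  }
  list(model = model, pkas = pkas, pdb = pdb)
}

#' Random toy structure for oracle testing
#'
#' Scatters randomly chosen residues (from the idealized template set) at
#' random positions and orientations inside a cubic box, emits PDB text and
#' parses it back.  All randomness is governed by `seed`.
#'
#' @param n_residues number of residues.
#' @param seed integer seed fixing all randomness.
#' @param box box edge length in Angstrom (default 20).
#' @param residues pool of residue names to sample from.
#' @return list with `model`, `pkas`, `pdb` as in [make_motif].
#' @export
make_random_structure <- function(n_residues, seed, box = 20,
                                  residues = names(FIXTURE_TEMPLATES)) {
  stopifnot(n_residues >= 1)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_residues)) {
    resid <- sample(residues, 1)
    m <- FIXTURE_TEMPLATES[[resid]]
    # random rotation from a normalized quaternion
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
      2 * (q[2] * q[4] + q[3] * q[1]),
      2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[2] * q[1]),
      2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
    mm <- m %*% t(R)
    rownames(mm) <- rownames(m)
    rows[[i]] <- fixture_atom_rows(mm, resid, "A", i,
                                   offset = stats::runif(3, 0, box))
  }
  rows <- do.call(rbind, rows)
  pdb <- fixture_pdb_text(rows)
  model <- parse_structure(paste(pdb, collapse = "\n"),
                           structure_id = paste0("random", seed))
  list(model = model, pkas = assign_model_pkas(model), pdb = pdb)
}

#' Reproducible random peptide sequences
#'
#' @param n sequence length.
#' @param seed integer seed.
#' @param composition `"any"` (all 20 residues), `"ionizable_rich"` (only
#'   D, E, C, Y, H, K, R) or `"ionizable_free"` (none of them).
#' @return a single amino-acid string.
#' @export
make_random_peptide <- function(n, seed = 1,
                                composition = c("any", "ionizable_rich",
                                                "ionizable_free")) {
  stopifnot(n >= 1)
  composition <- match.arg(composition)
  pool <- switch(composition,
                 any = STANDARD_AA,
                 ionizable_rich = IONIZABLE_AA1,
                 ionizable_free = setdiff(STANDARD_AA, IONIZABLE_AA1))
  set.seed(seed)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}
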