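# Independent brute-force oracles used to cross-check the detectors.
# Everything here is written as plain nested loops over the atom table,
# without the canonicalization/aggregation machinery of the package.

odist <- function(p, q) sqrt(sum((p - q)^2))

oracle_atoms <- function(model) {
  at <- model$atoms
  at$key <- phdelta:::res_key(at$chain, at$resno, at$insert)
  at
}

oracle_state <- function(states, key, group = "side_chain") {
  i <- which(states$key == key & states$group == group)
  if (length(i) == 0) NULL else states[i[1], ]
}

oracle_adjacent <- function(at, key1, key2, max_sep = 1) {
  r1 <- at[at$key == key1, ][1, ]; r2 <- at[at$key == key2, ][1, ]
  r1$chain == r2$chain && abs(r1$resno - r2$resno) <= max_sep
}

# all (pos atom, neg atom) contacts at or under the cutoff, as atom pairs
oracle_sb_atom_pairs <- function(model, states, cutoff = 4.0) {
  at <- oracle_atoms(model)
  pos <- list(); neg <- list()
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    if (s$group == "side_chain" && s$formal_charge == 1) {
      nm <- switch(s$resid, ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                   HIS = c("ND1", "NE2"), character(0))
      for (a in nm) pos[[length(pos) + 1]] <- c(s$key, "side_chain", a)
    }
    if (s$group == "side_chain" && s$formal_charge == -1) {
      nm <- switch(s$resid, ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                   character(0))
      for (a in nm) neg[[length(neg) + 1]] <- c(s$key, "side_chain", a)
    }
    if (s$group == "n_term" && s$formal_charge == 1)
      pos[[length(pos) + 1]] <- c(s$key, "n_term", "N")
    if (s$group == "c_term" && s$formal_charge == -1)
      for (a in c("O", "OXT")) neg[[length(neg) + 1]] <- c(s$key, "c_term", a)
  }
  out <- character(0)
  for (p in pos) for (q in neg) {
    if (p[1] == q[1]) next
    if (oracle_adjacent(at, p[1], q[1])) next
    pa <- at[at$key == p[1] & at$elety == p[3], ]
    qa <- at[at$key == q[1] & at$elety == q[3], ]
    if (nrow(pa) == 0 || nrow(qa) == 0) next
    d <- odist(c(pa$x, pa$y, pa$z), c(qa$x, qa$y, qa$z))
    if (d <= cutoff)
      out <- c(out, paste(p[1], p[2], p[3], q[1], q[2], q[3], sep = "|"))
  }
  sort(unique(out))
}

# salt-bridge records at the group-pair level: key_a|group_a|key_b|group_b
# with the pair ordered positive-first (matching the detector's convention
# before canonicalization is undone by sorting keys here)
oracle_salt_bridges <- function(model, states, cutoff = 4.0) {
  pairs <- oracle_sb_atom_pairs(model, states, cutoff)
  if (length(pairs) == 0) return(character(0))
  parts <- strsplit(pairs, "|", fixed = TRUE)
  grp <- vapply(parts, function(p)
    paste(sort(c(paste(p[1], p[2]), paste(p[4], p[5]))), collapse = "|"),
    character(1))
  sort(unique(grp))
}

oracle_hb_capabilities <- function(at, states, key) {
  res <- at[at$key == key, ]
  resid <- res$resid[1]
  ss <- oracle_state(states, key)
  don <- character(0); acc <- character(0)
  has <- function(a) a %in% res$elety
  if (resid != "PRO" && has("N")) don <- c(don, "N")
  if (has("O")) acc <- c(acc, "O")
  if (has("OXT")) acc <- c(acc, "OXT")
  if (resid == "SER" && has("OG")) { don <- c(don, "OG"); acc <- c(acc, "OG") }
  if (resid == "THR" && has("OG1")) { don <- c(don, "OG1"); acc <- c(acc, "OG1") }
  if (resid == "ASN") { if (has("ND2")) don <- c(don, "ND2")
                        if (has("OD1")) acc <- c(acc, "OD1") }
  if (resid == "GLN") { if (has("NE2")) don <- c(don, "NE2")
                        if (has("OE1")) acc <- c(acc, "OE1") }
  if (resid == "TRP" && has("NE1")) don <- c(don, "NE1")
  if (resid == "MET" && has("SD")) acc <- c(acc, "SD")
  if (resid == "TYR" && has("OH")) {
    if (is.null(ss) || ss$protonated) don <- c(don, "OH")
    acc <- c(acc, "OH")
  }
  if (resid == "CYS" && has("SG") && !is.null(ss)) {
    if (ss$protonated) don <- c(don, "SG")
    acc <- c(acc, "SG")
  }
  if (resid == "LYS" && has("NZ")) {
    don <- c(don, "NZ")
    if (!is.null(ss) && !ss$protonated) acc <- c(acc, "NZ")
  }
  if (resid == "ARG") for (a in c("NE", "NH1", "NH2"))
    if (has(a)) don <- c(don, a)
  if (resid == "HIS") for (a in c("ND1", "NE2")) {
    if (has(a)) {
      don <- c(don, a)
      if (is.null(ss) || !ss$protonated) acc <- c(acc, a)
    }
  }
  if (resid %in% c("ASP", "GLU")) {
    nm <- if (resid == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
    for (a in nm) if (has(a)) {
      if (!is.null(ss) && ss$protonated) don <- c(don, a)
      acc <- c(acc, a)
    }
  }
  list(don = unique(don), acc = unique(acc))
}

# hydrogen bonds as unordered atom-pair ids (no-hydrogen structures: the
# angle criterion never applies)
oracle_hydrogen_bonds <- function(model, states, cutoff = 3.5,
                                  sb_cutoff = 4.0) {
  at <- oracle_atoms(model)
  keys <- unique(at$key)
  caps <- lapply(keys, function(k) oracle_hb_capabilities(at, states, k))
  names(caps) <- keys
  sb <- oracle_sb_atom_pairs(model, states, sb_cutoff)
  sb_ap <- vapply(strsplit(sb, "|", fixed = TRUE), function(p)
    paste(sort(c(paste(p[1], p[3]), paste(p[4], p[6]))), collapse = "|"),
    character(1))
  out <- character(0)
  for (kd in keys) for (ka in keys) {
    if (kd == ka) next
    if (oracle_adjacent(at, kd, ka)) next
    for (ad in caps[[kd]]$don) for (aa in caps[[ka]]$acc) {
      pa <- at[at$key == kd & at$elety == ad, ][1, ]
      qa <- at[at$key == ka & at$elety == aa, ][1, ]
      d <- odist(c(pa$x, pa$y, pa$z), c(qa$x, qa$y, qa$z))
      if (d > cutoff) next
      id <- paste(sort(c(paste(kd, ad), paste(ka, aa))), collapse = "|")
      if (id %in% sb_ap) next
      out <- c(out, id)
    }
  }
  sort(unique(out))
}

oracle_ring_centroid <- function(at, key, names) {
  sel <- at$key == key & at$elety %in% names
  if (sum(sel) < length(names)) return(NULL)
  colMeans(as.matrix(at[sel, c("x", "y", "z")]))
}

oracle_aromatics <- function(model, states, pipi = 7.0, catpi = 6.0) {
  at <- oracle_atoms(model)
  keys <- unique(at$key)
  rings <- list(); cations <- list()
  for (k in keys) {
    resid <- at$resid[at$key == k][1]
    ss <- oracle_state(states, k)
    if (resid %in% c("PHE", "TYR")) {
      c6 <- oracle_ring_centroid(at, k, c("CG","CD1","CD2","CE1","CE2","CZ"))
      if (!is.null(c6)) rings[[paste(k, "ring")]] <- c6
    }
    if (resid == "TRP") {
      c5 <- oracle_ring_centroid(at, k, c("CG","CD1","CD2","NE1","CE2"))
      c6 <- oracle_ring_centroid(at, k, c("CD2","CE2","CE3","CZ2","CZ3","CH2"))
      if (!is.null(c5)) rings[[paste(k, "ring5")]] <- c5
      if (!is.null(c6)) rings[[paste(k, "ring6")]] <- c6
    }
    if (resid == "HIS") {
      c5 <- oracle_ring_centroid(at, k, c("CG","ND1","CD2","CE1","NE2"))
      if (!is.null(c5)) {
        if (!is.null(ss) && ss$protonated) cations[[paste(k, "ring")]] <- c5
        else rings[[paste(k, "ring")]] <- c5
      }
    }
    if (resid == "LYS" && !is.null(ss) && ss$protonated) {
      nz <- at[at$key == k & at$elety == "NZ", ]
      if (nrow(nz) == 1) cations[[paste(k, "NZ")]] <- c(nz$x, nz$y, nz$z)
    }
    if (resid == "ARG" && !is.null(ss) && ss$protonated) {
      g <- oracle_ring_centroid(at, k, c("CZ", "NE", "NH1", "NH2"))
      if (!is.null(g)) cations[[paste(k, "guan")]] <- g
    }
  }
  pp <- character(0); cp <- character(0)
  rk <- names(rings)
  if (length(rk) > 1) for (i in 1:(length(rk) - 1)) for (j in (i+1):length(rk)) {
    k1 <- strsplit(rk[i], " ")[[1]][1]; k2 <- strsplit(rk[j], " ")[[1]][1]
    if (k1 == k2 || oracle_adjacent(at, k1, k2)) next
    if (odist(rings[[i]], rings[[j]]) <= pipi)
      pp <- c(pp, paste(sort(c(rk[i], rk[j])), collapse = "|"))
  }
  for (ci in names(cations)) for (ri in names(rings)) {
    k1 <- strsplit(ci, " ")[[1]][1]; k2 <- strsplit(ri, " ")[[1]][1]
    if (k1 == k2 || oracle_adjacent(at, k1, k2)) next
    if (odist(cations[[ci]], rings[[ri]]) <= catpi)
      cp <- c(cp, paste(ci, ri, sep = "|"))
  }
  list(pi_pi = sort(unique(pp)), cation_pi = sort(unique(cp)))
}

# canonical ids from package records, matching the oracle formats above
records_sb_ids <- function(recs) {
  r <- recs[recs$kind == "salt_bridge", ]
  if (nrow(r) == 0) return(character(0))
  sort(vapply(seq_len(nrow(r)), function(i)
    paste(sort(c(paste(r$key_a[i], r$group_a[i]),
                 paste(r$key_b[i], r$group_b[i]))), collapse = "|"),
    character(1)))
}

records_hb_ids <- function(recs) {
  r <- recs[recs$kind == "hydrogen_bond", ]
  if (nrow(r) == 0) return(character(0))
  sort(vapply(seq_len(nrow(r)), function(i)
    paste(sort(c(paste(r$key_a[i], r$label_a[i]),
                 paste(r$key_b[i], r$label_b[i]))), collapse = "|"),
    character(1)))
}

records_pipi_ids <- function(recs) {
  r <- recs[recs$kind == "pi_pi", ]
  if (nrow(r) == 0) return(character(0))
  sort(vapply(seq_len(nrow(r)), function(i)
    paste(sort(c(paste(r$key_a[i], r$label_a[i]),
                 paste(r$key_b[i], r$label_b[i]))), collapse = "|"),
    character(1)))
}

records_catpi_ids <- function(recs) {
  r <- recs[recs$kind == "cation_pi", ]
  if (nrow(r) == 0) return(character(0))
  sort(paste(paste(r$key_a, r$label_a), paste(r$key_b, r$label_b), sep = "|"))
}

# minimum side-chain heavy-atom distance between two residues
oracle_min_sidechain_dist <- function(model, key1, key2) {
  at <- oracle_atoms(model)
  bb <- c("N", "CA", "C", "O", "OXT")
  sel1 <- at$key == key1 & !(at$elety %in% bb)
  if (!any(sel1)) sel1 <- at$key == key1 & at$elety == "CA"
  sel2 <- at$key == key2 & !(at$elety %in% bb)
  if (!any(sel2)) sel2 <- at$key == key2 & at$elety == "CA"
  m1 <- as.matrix(at[sel1, c("x", "y", "z")])
  m2 <- as.matrix(at[sel2, c("x", "y", "z")])
  min(apply(m1, 1, function(p) apply(m2, 1, function(q) odist(p, q))))
}

# connected components by breadth-first search over an adjacency matrix
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}
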