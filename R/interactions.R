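#' Geometry thresholds for noncovalent bond detection
#'
#' All detection cutoffs in one overridable object.  Defaults follow widely
#' used residue-interaction-network conventions: salt bridge N-O distance
#' 4.0 A; hydrogen bond donor-acceptor distance 3.5 A with a D-H...A angle
#' of at least 120 degrees when explicit hydrogens are present; pi-pi ring
#' centroid distance 7.0 A; cation-pi distance 6.0 A.  Residue pairs
#' adjacent in sequence (|delta resno| <= `exclude_adjacent`, same chain)
#' are never reported.
#'
#' @param salt_bridge_dist,hbond_dist,pipi_dist,catpi_dist distance cutoffs
#'   in Angstrom.
#' @param hbond_angle minimum donor-hydrogen-acceptor angle in degrees,
#'   applied only when an explicit hydrogen bonded to the donor exists.
#' @param exclude_adjacent sequence-separation exclusion (bonded neighbors).
#' @return list of class `interaction_params`.
#' @export
interaction_params <- function(salt_bridge_dist = 4.0, hbond_dist = 3.5,
                               hbond_angle = 120, pipi_dist = 7.0,
                               catpi_dist = 6.0, exclude_adjacent = 1) {
  p <- list(salt_bridge_dist = salt_bridge_dist, hbond_dist = hbond_dist,
            hbond_angle = hbond_angle, pipi_dist = pipi_dist,
            catpi_dist = catpi_dist, exclude_adjacent = exclude_adjacent)
  if (any(unlist(p) <= 0)) stop("all thresholds must be positive")
  class(p) <- "interaction_params"
  p
}

RING_ATOMS <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(ring5 = c("CG", "CD1", "CD2", "NE1", "CE2"),
             ring6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

RECORD_COLS <- c("kind",
                 "key_a", "resid_a", "label_a", "group_a",
                 "chain_a", "resno_a", "insert_a",
                 "key_b", "resid_b", "label_b", "group_b",
                 "chain_b", "resno_b", "insert_b",
                 "distance", "angle", "state_dependent")

empty_records <- function() {
  chr <- function() character(0)
  data.frame(kind = chr(),
             key_a = chr(), resid_a = chr(), label_a = chr(), group_a = chr(),
             chain_a = chr(), resno_a = integer(0), insert_a = chr(),
             key_b = chr(), resid_b = chr(), label_b = chr(), group_b = chr(),
             chain_b = chr(), resno_b = integer(0), insert_b = chr(),
             distance = numeric(0), angle = numeric(0),
             state_dependent = logical(0), stringsAsFactors = FALSE)
}

# residue ordering value for canonicalization and adjacency tests
res_rank <- function(chain, resno, insert) {
  paste(chain, sprintf("%08d", resno + 10000L), insert)
}

# state lookup helpers -------------------------------------------------------

state_of <- function(states, key, group) {
  i <- which(states$key == key & states$group == group)
  if (length(i) == 0) NULL else states[i[1], , drop = FALSE]
}

# per-residue coordinate access
atom_xyz <- function(at, sel) as.matrix(at[sel, c("x", "y", "z"), drop = FALSE])

cross_dist <- function(A, B) {
  # euclidean distances between rows of A (n x 3) and rows of B (m x 3)
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

adjacent_pair <- function(chain_a, resno_a, chain_b, resno_b, max_sep) {
  chain_a == chain_b & abs(resno_a - resno_b) <= max_sep
}

# build the table of charged-group member atoms at the given states
charged_sites <- function(model, states) {
  at <- model$atoms
  at$key <- res_key(at$chain, at$resno, at$insert)
  rows <- list()
  add <- function(st, names, group_label) {
    sel <- at$key == st$key & at$elety %in% names
    if (!any(sel)) return(NULL)
    cbind(at[sel, c("key", "chain", "resno", "insert", "resid", "elety",
                    "x", "y", "z"), drop = FALSE],
          group = group_label, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    if (st$group == "side_chain") {
      if (st$polarity == "basic" && st$formal_charge == 1L) {
        names <- switch(st$resid, ARG = c("NE", "NH1", "NH2"),
                        LYS = "NZ", HIS = c("ND1", "NE2"), NULL)
        if (!is.null(names)) rows[[length(rows) + 1L]] <- add(st, names, "side_chain")
      } else if (st$polarity == "acidic" && st$formal_charge == -1L) {
        names <- switch(st$resid, ASP = c("OD1", "OD2"),
                        GLU = c("OE1", "OE2"), NULL)
        if (!is.null(names)) rows[[length(rows) + 1L]] <- add(st, names, "side_chain")
      }
    } else if (st$group == "n_term" && st$formal_charge == 1L) {
      rows[[length(rows) + 1L]] <- add(st, "N", "n_term")
    } else if (st$group == "c_term" && st$formal_charge == -1L) {
      rows[[length(rows) + 1L]] <- add(st, c("OXT", "O"), "c_term")
    }
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  chg <- states$formal_charge[match(paste(out$key, out$group),
                                    paste(states$key, states$group))]
  out$charge <- chg
  rownames(out) <- NULL
  out
}

#' Detect salt bridges under a protonation assignment
#'
#' A salt bridge is recorded for every pair of a positively charged
#' nitrogen-bearing group (Arg NE/NH1/NH2, Lys NZ, protonated His ND1/NE2,
#' protonated N-terminal amine) and a negatively charged oxygen-bearing
#' group (deprotonated Asp OD1/OD2, Glu OE1/OE2, deprotonated C-terminal
#' carboxylate) whose minimum N-O distance does not exceed the cutoff.
#' Charge preconditions are read from `states`, so the inventory is
#' pH-dependent.
#'
#' @param model a `structure_model`.
#' @param states a `protonation` assignment from [assign_states] for this
#'   model's pKa set.
#' @param params an [interaction_params] object.
#' @return data frame of interaction records (one per charged-group pair,
#'   atom labels of the closest N-O contact).
#' @export
detect_salt_bridges <- function(model, states, params = interaction_params()) {
  sites <- charged_sites(model, states)
  if (is.null(sites)) return(empty_records())
  pos <- sites[sites$charge > 0, , drop = FALSE]
  neg <- sites[sites$charge < 0, , drop = FALSE]
  if (nrow(pos) == 0 || nrow(neg) == 0) return(empty_records())
  D <- cross_dist(atom_xyz(pos, TRUE), atom_xyz(neg, TRUE))
  hits <- which(D <= params$salt_bridge_dist, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_records())
  recs <- data.frame(
    kind = "salt_bridge",
    key_a = pos$key[hits[, 1]], resid_a = pos$resid[hits[, 1]],
    label_a = pos$elety[hits[, 1]], group_a = pos$group[hits[, 1]],
    chain_a = pos$chain[hits[, 1]], resno_a = pos$resno[hits[, 1]],
    insert_a = pos$insert[hits[, 1]],
    key_b = neg$key[hits[, 2]], resid_b = neg$resid[hits[, 2]],
    label_b = neg$elety[hits[, 2]], group_b = neg$group[hits[, 2]],
    chain_b = neg$chain[hits[, 2]], resno_b = neg$resno[hits[, 2]],
    insert_b = neg$insert[hits[, 2]],
    distance = D[hits], stringsAsFactors = FALSE)
  recs <- recs[recs$key_a != recs$key_b, , drop = FALSE]
  recs <- recs[!adjacent_pair(recs$chain_a, recs$resno_a, recs$chain_b,
                              recs$resno_b, params$exclude_adjacent), ,
               drop = FALSE]
  if (nrow(recs) == 0) return(empty_records())
  # one record per group pair: keep the closest atom contact
  pid <- paste(recs$key_a, recs$group_a, recs$key_b, recs$group_b)
  recs <- recs[order(pid, recs$distance), , drop = FALSE]
  recs <- recs[!duplicated(paste(recs$key_a, recs$group_a, recs$key_b,
                                 recs$group_b)), , drop = FALSE]
  recs$angle <- NA_real_
  recs$state_dependent <- TRUE
  canonicalize_records(recs)
}

# donor/acceptor heavy-atom capability tables under a protonation assignment
hbond_sites <- function(model, states) {
  at <- model$atoms
  at$key <- res_key(at$chain, at$resno, at$insert)
  rt <- residue_table(model)
  skey <- paste(states$key, states$group)

  side_state <- function(key) {
    i <- match(paste(key, "side_chain"), skey)
    if (is.na(i)) NULL else states[i, ]
  }
  don <- list(); acc <- list()
  grab <- function(key, names) {
    sel <- at$key == key & at$elety %in% names
    if (!any(sel)) return(NULL)
    at[sel, c("key", "chain", "resno", "insert", "resid", "elety",
              "x", "y", "z"), drop = FALSE]
  }
  push <- function(lst, x, state_dep) {
    if (is.null(x)) return(lst)
    x$state_dep <- state_dep
    lst[[length(lst) + 1L]] <- x
    lst
  }
  nterm_keys <- states$key[states$group == "n_term"]
  cterm_keys <- states$key[states$group == "c_term"]
  for (i in seq_len(nrow(rt))) {
    key <- rt$key[i]; resid <- rt$resid[i]
    # backbone: amide N donates (except proline), carbonyl O accepts
    if (resid != "PRO")
      don <- push(don, grab(key, "N"), key %in% nterm_keys)
    acc <- push(acc, grab(key, "O"), key %in% cterm_keys)
    acc <- push(acc, grab(key, "OXT"), key %in% cterm_keys)
    ss <- side_state(key)
    switch(resid,
      SER = { don <- push(don, grab(key, "OG"), FALSE)
              acc <- push(acc, grab(key, "OG"), FALSE) },
      THR = { don <- push(don, grab(key, "OG1"), FALSE)
              acc <- push(acc, grab(key, "OG1"), FALSE) },
      ASN = { don <- push(don, grab(key, "ND2"), FALSE)
              acc <- push(acc, grab(key, "OD1"), FALSE) },
      GLN = { don <- push(don, grab(key, "NE2"), FALSE)
              acc <- push(acc, grab(key, "OE1"), FALSE) },
      TRP = { don <- push(don, grab(key, "NE1"), FALSE) },
      MET = { acc <- push(acc, grab(key, "SD"), FALSE) },
      TYR = { if (is.null(ss) || ss$protonated)
                don <- push(don, grab(key, "OH"), TRUE)
              acc <- push(acc, grab(key, "OH"), TRUE) },
      CYS = { if (!is.null(ss)) {
                if (ss$protonated) don <- push(don, grab(key, "SG"), TRUE)
                acc <- push(acc, grab(key, "SG"), TRUE)
              } },
      LYS = { don <- push(don, grab(key, "NZ"), TRUE)
              if (!is.null(ss) && !ss$protonated)
                acc <- push(acc, grab(key, "NZ"), TRUE) },
      ARG = { don <- push(don, grab(key, c("NE", "NH1", "NH2")), TRUE) },
      HIS = { nn <- c("ND1", "NE2")
              don <- push(don, grab(key, nn), TRUE)   # both tautomer-agnostic
              if (is.null(ss) || !ss$protonated)
                acc <- push(acc, grab(key, nn), TRUE) },
      ASP = { if (!is.null(ss) && ss$protonated)
                don <- push(don, grab(key, c("OD1", "OD2")), TRUE)
              acc <- push(acc, grab(key, c("OD1", "OD2")), TRUE) },
      GLU = { if (!is.null(ss) && ss$protonated)
                don <- push(don, grab(key, c("OE1", "OE2")), TRUE)
              acc <- push(acc, grab(key, c("OE1", "OE2")), TRUE) }
    )
  }
  bind <- function(lst) {
    if (length(lst) == 0) return(NULL)
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  }
  list(donors = bind(don), acceptors = bind(acc))
}

#' Detect hydrogen bonds under a protonation assignment
#'
#' Records every donor-heavy-atom/acceptor pair within the distance cutoff.
#' Donor/acceptor eligibility is taken from per-residue chemistry combined
#' with the protonation states (e.g. a neutral His ring nitrogen can donate
#' or accept, a protonated His only donates; a protonated carboxylate gains
#' an OH donor).  Backbone amide/carbonyl groups are included.  When the
#' structure contains an explicit hydrogen bonded to the donor, the
#' D-H...A angle must also pass; otherwise the heavy-atom distance criterion
#' alone is used.  Atom pairs already qualifying as salt bridges are
#' suppressed.
#'
#' @inheritParams detect_salt_bridges
#' @return data frame of hydrogen-bond records.
#' @export
detect_hydrogen_bonds <- function(model, states,
                                  params = interaction_params()) {
  sites <- hbond_sites(model, states)
  if (is.null(sites$donors) || is.null(sites$acceptors))
    return(empty_records())
  don <- sites$donors; acc <- sites$acceptors
  D <- cross_dist(atom_xyz(don, TRUE), atom_xyz(acc, TRUE))
  hits <- which(D <= params$hbond_dist, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_records())

  recs <- data.frame(
    kind = "hydrogen_bond",
    key_a = don$key[hits[, 1]], resid_a = don$resid[hits[, 1]],
    label_a = don$elety[hits[, 1]], group_a = "atom",
    chain_a = don$chain[hits[, 1]], resno_a = don$resno[hits[, 1]],
    insert_a = don$insert[hits[, 1]],
    key_b = acc$key[hits[, 2]], resid_b = acc$resid[hits[, 2]],
    label_b = acc$elety[hits[, 2]], group_b = "atom",
    chain_b = acc$chain[hits[, 2]], resno_b = acc$resno[hits[, 2]],
    insert_b = acc$insert[hits[, 2]],
    distance = D[hits],
    state_dependent = don$state_dep[hits[, 1]] | acc$state_dep[hits[, 2]],
    stringsAsFactors = FALSE)
  recs <- recs[recs$key_a != recs$key_b, , drop = FALSE]
  recs <- recs[!adjacent_pair(recs$chain_a, recs$resno_a, recs$chain_b,
                              recs$resno_b, params$exclude_adjacent), ,
               drop = FALSE]
  if (nrow(recs) == 0) return(empty_records())

  # angle criterion when explicit hydrogens are present on the donor
  at <- model$atoms
  at$key <- res_key(at$chain, at$resno, at$insert)
  hyd <- at[at$element == "H" | grepl("^[0-9]*H", at$elety), , drop = FALSE]
  if (nrow(hyd) > 0) {
    keep <- rep(TRUE, nrow(recs))
    angle <- rep(NA_real_, nrow(recs))
    for (r in seq_len(nrow(recs))) {
      dsel <- at$key == recs$key_a[r] & at$elety == recs$label_a[r]
      dxyz <- as.numeric(at[which(dsel)[1], c("x", "y", "z")])
      hres <- hyd[hyd$key == recs$key_a[r], , drop = FALSE]
      if (nrow(hres) == 0) next
      hd <- cross_dist(atom_xyz(hres, TRUE), matrix(dxyz, 1))
      bonded <- hres[hd[, 1] <= 1.25, , drop = FALSE]
      if (nrow(bonded) == 0) next
      asel <- at$key == recs$key_b[r] & at$elety == recs$label_b[r]
      axyz <- as.numeric(at[which(asel)[1], c("x", "y", "z")])
      best <- -Inf
      for (hh in seq_len(nrow(bonded))) {
        hxyz <- as.numeric(bonded[hh, c("x", "y", "z")])
        v1 <- dxyz - hxyz; v2 <- axyz - hxyz
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        best <- max(best, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
      }
      angle[r] <- best
      keep[r] <- best >= params$hbond_angle
    }
    recs$angle <- angle
    recs <- recs[keep, , drop = FALSE]
  } else {
    recs$angle <- NA_real_
  }
  if (nrow(recs) == 0) return(empty_records())

  # suppress atom pairs that already form a salt bridge
  sb_sites <- charged_sites(model, states)
  if (!is.null(sb_sites)) {
    pos <- sb_sites[sb_sites$charge > 0, , drop = FALSE]
    neg <- sb_sites[sb_sites$charge < 0, , drop = FALSE]
    if (nrow(pos) > 0 && nrow(neg) > 0) {
      Dsb <- cross_dist(atom_xyz(pos, TRUE), atom_xyz(neg, TRUE))
      sb <- which(Dsb <= params$salt_bridge_dist, arr.ind = TRUE)
      if (nrow(sb) > 0) {
        sbid <- c(paste(pos$key[sb[, 1]], pos$elety[sb[, 1]],
                        neg$key[sb[, 2]], neg$elety[sb[, 2]]),
                  paste(neg$key[sb[, 2]], neg$elety[sb[, 2]],
                        pos$key[sb[, 1]], pos$elety[sb[, 1]]))
        rid <- paste(recs$key_a, recs$label_a, recs$key_b, recs$label_b)
        recs <- recs[!(rid %in% sbid), , drop = FALSE]
      }
    }
  }
  if (nrow(recs) == 0) return(empty_records())
  recs <- canonicalize_records(recs)
  # a pair of mutually capable hydroxyls yields the same contact twice
  recs[!duplicated(paste(recs$kind, recs$key_a, recs$label_a,
                         recs$key_b, recs$label_b)), , drop = FALSE]
}

# ring centroids and cation sites --------------------------------------------

aromatic_sites <- function(model, states) {
  at <- model$atoms
  at$key <- res_key(at$chain, at$resno, at$insert)
  rt <- residue_table(model)
  skey <- paste(states$key, states$group)
  rings <- list(); cations <- list()
  for (i in seq_len(nrow(rt))) {
    key <- rt$key[i]; resid <- rt$resid[i]
    base <- rt[i, c("chain", "resno", "insert")]
    his_prot <- FALSE
    if (resid == "HIS") {
      j <- match(paste(key, "side_chain"), skey)
      his_prot <- !is.na(j) && states$protonated[j]
    }
    if (resid %in% names(RING_ATOMS)) {
      for (ring_name in names(RING_ATOMS[[resid]])) {
        names <- RING_ATOMS[[resid]][[ring_name]]
        sel <- at$key == key & at$elety %in% names
        if (sum(sel) < length(names)) {
          warning("residue ", key, " (", resid, "): incomplete ", ring_name,
                  "; skipped in aromatic detection")
          next
        }
        cen <- colMeans(atom_xyz(at, sel))
        row <- data.frame(key = key, chain = base$chain, resno = base$resno,
                          insert = base$insert, resid = resid,
                          label = ring_name, x = cen[1], y = cen[2],
                          z = cen[3], stringsAsFactors = FALSE)
        if (resid == "HIS" && his_prot) {
          cations[[length(cations) + 1L]] <- row  # charged ring: cation only
        } else {
          rings[[length(rings) + 1L]] <- row
        }
      }
    }
    if (resid == "LYS") {
      j <- match(paste(key, "side_chain"), skey)
      if (!is.na(j) && states$protonated[j]) {
        sel <- at$key == key & at$elety == "NZ"
        if (any(sel)) {
          cen <- colMeans(atom_xyz(at, sel))
          cations[[length(cations) + 1L]] <-
            data.frame(key = key, chain = base$chain, resno = base$resno,
                       insert = base$insert, resid = resid, label = "NZ",
                       x = cen[1], y = cen[2], z = cen[3],
                       stringsAsFactors = FALSE)
        }
      }
    }
    if (resid == "ARG") {
      j <- match(paste(key, "side_chain"), skey)
      if (!is.na(j) && states$protonated[j]) {
        names <- c("CZ", "NE", "NH1", "NH2")
        sel <- at$key == key & at$elety %in% names
        if (sum(sel) == length(names)) {
          cen <- colMeans(atom_xyz(at, sel))
          cations[[length(cations) + 1L]] <-
            data.frame(key = key, chain = base$chain, resno = base$resno,
                       insert = base$insert, resid = resid, label = "guan",
                       x = cen[1], y = cen[2], z = cen[3],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  bind <- function(lst) if (length(lst) == 0) NULL else
    { out <- do.call(rbind, lst); rownames(out) <- NULL; out }
  list(rings = bind(rings), cations = bind(cations))
}

#' Detect pi-pi and cation-pi interactions under a protonation assignment
#'
#' Pi-pi contacts are ring-centroid pairs (Phe, Tyr, both Trp rings, and
#' neutral His rings) within the pi-pi cutoff.  Cation-pi contacts pair a
#' cation site (protonated Lys NZ, Arg guanidinium centroid, protonated His
#' ring centroid) with a ring centroid within the cation-pi cutoff.  A
#' protonated His ring acts exclusively as a cation: it is removed from the
#' pi-pi ring set, so protonation recategorizes His-His stacking into a
#' cation-pi contact (or none, by distance).
#'
#' @inheritParams detect_salt_bridges
#' @return data frame combining `pi_pi` and `cation_pi` records.
#' @export
detect_aromatic <- function(model, states, params = interaction_params()) {
  sites <- aromatic_sites(model, states)
  out <- list()
  if (!is.null(sites$rings) && nrow(sites$rings) > 1) {
    rg <- sites$rings
    D <- cross_dist(atom_xyz(rg, TRUE), atom_xyz(rg, TRUE))
    hits <- which(D <= params$pipi_dist & upper.tri(D), arr.ind = TRUE)
    if (nrow(hits) > 0) {
      recs <- data.frame(
        kind = "pi_pi",
        key_a = rg$key[hits[, 1]], resid_a = rg$resid[hits[, 1]],
        label_a = rg$label[hits[, 1]], group_a = "ring",
        chain_a = rg$chain[hits[, 1]], resno_a = rg$resno[hits[, 1]],
        insert_a = rg$insert[hits[, 1]],
        key_b = rg$key[hits[, 2]], resid_b = rg$resid[hits[, 2]],
        label_b = rg$label[hits[, 2]], group_b = "ring",
        chain_b = rg$chain[hits[, 2]], resno_b = rg$resno[hits[, 2]],
        insert_b = rg$insert[hits[, 2]],
        distance = D[hits], angle = NA_real_,
        state_dependent = rg$resid[hits[, 1]] == "HIS" |
          rg$resid[hits[, 2]] == "HIS",
        stringsAsFactors = FALSE)
      out$pipi <- recs
    }
  }
  if (!is.null(sites$cations) && !is.null(sites$rings)) {
    ct <- sites$cations; rg <- sites$rings
    D <- cross_dist(atom_xyz(ct, TRUE), atom_xyz(rg, TRUE))
    hits <- which(D <= params$catpi_dist, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      recs <- data.frame(
        kind = "cation_pi",
        key_a = ct$key[hits[, 1]], resid_a = ct$resid[hits[, 1]],
        label_a = ct$label[hits[, 1]], group_a = "cation",
        chain_a = ct$chain[hits[, 1]], resno_a = ct$resno[hits[, 1]],
        insert_a = ct$insert[hits[, 1]],
        key_b = rg$key[hits[, 2]], resid_b = rg$resid[hits[, 2]],
        label_b = rg$label[hits[, 2]], group_b = "ring",
        chain_b = rg$chain[hits[, 2]], resno_b = rg$resno[hits[, 2]],
        insert_b = rg$insert[hits[, 2]],
        distance = D[hits], angle = NA_real_, state_dependent = TRUE,
        stringsAsFactors = FALSE)
      out$catpi <- recs
    }
  }
  if (length(out) == 0) return(empty_records())
  recs <- do.call(rbind, out)
  recs <- recs[recs$key_a != recs$key_b, , drop = FALSE]
  recs <- recs[!adjacent_pair(recs$chain_a, recs$resno_a, recs$chain_b,
                              recs$resno_b, params$exclude_adjacent), ,
               drop = FALSE]
  if (nrow(recs) == 0) return(empty_records())
  canonicalize_records(recs)
}

# order partners so that partner_a precedes partner_b in (chain, resno) order
# (cation-pi records keep the cation first: partner roles differ)
canonicalize_records <- function(recs) {
  if (nrow(recs) == 0) return(empty_records())
  symmetric <- recs$kind %in% c("pi_pi", "hydrogen_bond", "salt_bridge")
  flip <- symmetric &
    res_rank(recs$chain_a, recs$resno_a, recs$insert_a) >
    res_rank(recs$chain_b, recs$resno_b, recs$insert_b)
  if (any(flip)) {
    a_cols <- c("key_a", "resid_a", "label_a", "group_a",
                "chain_a", "resno_a", "insert_a")
    b_cols <- sub("_a$", "_b", a_cols)
    tmp <- recs[flip, a_cols]
    recs[flip, a_cols] <- recs[flip, b_cols]
    recs[flip, b_cols] <- tmp
  }
  recs <- recs[order(recs$kind,
                     res_rank(recs$chain_a, recs$resno_a, recs$insert_a),
                     res_rank(recs$chain_b, recs$resno_b, recs$insert_b),
                     recs$label_a, recs$label_b), , drop = FALSE]
  rownames(recs) <- NULL
  recs[, RECORD_COLS, drop = FALSE]
}

#' Detect all noncovalent bonds at one protonation state
#'
#' Union of [detect_salt_bridges], [detect_hydrogen_bonds] and
#' [detect_aromatic], canonicalized and deduplicated (salt bridges take
#' precedence over hydrogen bonds for the same atom pair).
#'
#' @inheritParams detect_salt_bridges
#' @return An `interaction_set`: the combined record data frame with
#'   attributes `pH` (from `states`) and `params`.
#' @export
detect_all <- function(model, states, params = interaction_params()) {
  recs <- rbind(detect_salt_bridges(model, states, params),
                detect_hydrogen_bonds(model, states, params),
                detect_aromatic(model, states, params))
  recs <- recs[!duplicated(paste(recs$kind, recs$key_a, recs$label_a,
                                 recs$key_b, recs$label_b)), , drop = FALSE]
  rownames(recs) <- NULL
  attr(recs, "pH") <- attr(states, "pH")
  attr(recs, "params") <- params
  class(recs) <- c("interaction_set", "data.frame")
  recs
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("Interaction set at pH %.2f: %d record(s)\n",
              attr(x, "pH"), nrow(x)))
  if (nrow(x) > 0) print(table(x$kind))
  invisible(x)
}
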