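# identity of an interaction record for set comparison: geometry excluded,
# since distances can differ slightly between states via hydrogen placement
record_identity <- function(recs) {
  paste(recs$kind, recs$key_a, recs$label_a, recs$key_b, recs$label_b,
        sep = "|")
}

#' Created and destroyed noncovalent bonds between two pH states
#'
#' Set difference of two interaction inventories computed on the same
#' structure with identical geometry parameters.  `created` records are
#' present only in `set_b`, `destroyed` only in `set_a`; by the reporting
#' convention of [run_structure_mode], `set_a` is the reference pH and
#' `set_b` the pH of interest.  Record identity is (kind, partner keys, atom
#' or centroid labels); a His contact that is pi-pi at one pH and cation-pi
#' at the other therefore appears as one destroyed plus one created record.
#'
#' @param set_a,set_b two `interaction_set` objects from [detect_all].
#' @return A list of class `interaction_delta` with `created`, `destroyed`
#'   (record data frames), `per_residue` (created/destroyed counts per
#'   residue key and kind), and `ph_a`, `ph_b`.
#' @export
interaction_delta <- function(set_a, set_b) {
  if (!identical(unclass(attr(set_a, "params")),
                 unclass(attr(set_b, "params"))))
    stop("interaction sets were computed with different geometry parameters")
  id_a <- record_identity(set_a); id_b <- record_identity(set_b)
  created <- set_b[!(id_b %in% id_a), , drop = FALSE]
  destroyed <- set_a[!(id_a %in% id_b), , drop = FALSE]
  rownames(created) <- rownames(destroyed) <- NULL
  per_res <- function(recs, direction) {
    if (nrow(recs) == 0) return(NULL)
    long <- rbind(data.frame(key = recs$key_a, kind = recs$kind),
                  data.frame(key = recs$key_b, kind = recs$kind))
    agg <- stats::aggregate(list(n = rep(1L, nrow(long))),
                            by = list(key = long$key, kind = long$kind), sum)
    agg$direction <- direction
    agg
  }
  summary <- rbind(per_res(created, "created"), per_res(destroyed, "destroyed"))
  out <- list(created = as.data.frame(created),
              destroyed = as.data.frame(destroyed),
              per_residue = summary,
              ph_a = attr(set_a, "pH"), ph_b = attr(set_b, "pH"))
  class(out) <- "interaction_delta"
  out
}

#' @export
print.interaction_delta <- function(x, ...) {
  cat(sprintf("Interaction delta, pH %.2f -> %.2f: %d created, %d destroyed\n",
              x$ph_a, x$ph_b, nrow(x$created), nrow(x$destroyed)))
  invisible(x)
}

# side-chain heavy atoms of a residue (CA fallback for glycine)
side_chain_atoms <- function(at, key) {
  sel <- at$res_key == key & !(at$elety %in% BACKBONE_ATOMS) &
    at$element != "H"
  if (!any(sel)) sel <- at$res_key == key & at$elety == "CA"
  sel
}

#' Proximity graph over protonation-shifting residues
#'
#' Builds the adjacency graph whose vertices are the shifting residues and
#' whose edges connect residues within `radius` of each other.  The default
#' distance is the minimum distance between the two residues' side-chain
#' heavy atoms; alternatives are any-atom minimum distance or side-chain
#' centroid distance.  Terminal-group-only shifts are excluded by default.
#'
#' @param model a `structure_model`.
#' @param shifting a `shift_report` from [shifting_residues].
#' @param radius adjacency cutoff in Angstrom (default 8).
#' @param distance_mode `"side_chain"`, `"any_atom"` or `"centroid"`.
#' @param include_termini also treat terminal-group shifts as vertices.
#' @return an \pkg{igraph} undirected graph; vertex attributes `resid` and
#'   `x`, `y`, `z` (side-chain centroid).
#' @export
build_patch_graph <- function(model, shifting, radius = 8,
                              distance_mode = c("side_chain", "any_atom",
                                                "centroid"),
                              include_termini = FALSE) {
  distance_mode <- match.arg(distance_mode)
  if (radius <= 0) stop("radius must be positive")
  sh <- shifting
  if (!include_termini) sh <- sh[!sh$is_terminal, , drop = FALSE]
  keys <- unique(sh$key)
  g <- igraph::make_empty_graph(n = length(keys), directed = FALSE)
  if (length(keys) == 0) return(g)
  at <- model$atoms
  at$res_key <- res_key(at$chain, at$resno, at$insert)
  coords <- lapply(keys, function(k) {
    sel <- switch(distance_mode,
                  side_chain = side_chain_atoms(at, k),
                  any_atom = at$res_key == k & at$element != "H",
                  centroid = side_chain_atoms(at, k))
    xyz <- atom_xyz(at, sel)
    if (distance_mode == "centroid") xyz <- matrix(colMeans(xyz), 1)
    xyz
  })
  centroids <- t(vapply(seq_along(keys), function(i)
    colMeans(coords[[i]]), numeric(3)))
  g <- igraph::set_vertex_attr(g, "name", value = keys)
  g <- igraph::set_vertex_attr(g, "resid",
                               value = sh$resid[match(keys, sh$key)])
  g <- igraph::set_vertex_attr(g, "x", value = centroids[, 1])
  g <- igraph::set_vertex_attr(g, "y", value = centroids[, 2])
  g <- igraph::set_vertex_attr(g, "z", value = centroids[, 3])
  if (length(keys) > 1) {
    edges <- integer(0)
    for (i in seq_len(length(keys) - 1L)) {
      for (j in seq(i + 1L, length(keys))) {
        if (min(cross_dist(coords[[i]], coords[[j]])) <= radius)
          edges <- c(edges, i, j)
      }
    }
    if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  }
  attr(g, "radius") <- radius
  attr(g, "distance_mode") <- distance_mode
  g
}

#' pH-sensitive patches: connected clusters of shifting residues
#'
#' Patches are the connected components of the proximity graph with at least
#' `min_size` members, i.e. groups of residues that all change protonation
#' state between the two pH values and lie in close spatial proximity.
#' Smaller components are returned separately as near-patch residues.
#'
#' @param graph graph from [build_patch_graph].
#' @param min_size minimum component size to qualify as a patch (default 3:
#'   each member near at least two other shifting residues through the
#'   component).
#' @return A list of class `patch_set`: `patches` (list of member-key
#'   vectors, sorted by decreasing size then first member), `centroids`
#'   (matrix of patch centroids), `near_patch` (keys in components smaller
#'   than `min_size`), `radius`, `min_size`.
#' @export
find_patches <- function(graph, min_size = 3) {
  if (min_size < 2) stop("min_size must be at least 2")
  n <- igraph::vcount(graph)
  if (n == 0)
    return(structure(list(patches = list(),
                          centroids = matrix(numeric(0), 0, 3),
                          near_patch = character(0),
                          radius = attr(graph, "radius"),
                          min_size = min_size), class = "patch_set"))
  comp <- igraph::components(graph)
  keys <- igraph::vertex_attr(graph, "name")
  xyz <- cbind(igraph::vertex_attr(graph, "x"),
               igraph::vertex_attr(graph, "y"),
               igraph::vertex_attr(graph, "z"))
  members <- split(keys, comp$membership)
  coords <- split(seq_len(n), comp$membership)
  big <- vapply(members, length, integer(1)) >= min_size
  patches <- members[big]
  ord <- order(-vapply(patches, length, integer(1)),
               vapply(patches, function(m) sort(m)[1], character(1)))
  patches <- patches[ord]
  centroids <- t(vapply(coords[big][ord], function(i)
    colMeans(xyz[i, , drop = FALSE]), numeric(3)))
  out <- list(patches = unname(lapply(patches, sort)),
              centroids = centroids,
              near_patch = sort(unlist(members[!big], use.names = FALSE)),
              radius = attr(graph, "radius"),
              min_size = min_size)
  class(out) <- "patch_set"
  out
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("pH-sensitive patches (radius %.1f A, min size %d): %d patch(es)\n",
              x$radius, x$min_size, length(x$patches)))
  for (i in seq_along(x$patches))
    cat(sprintf("  patch %d (%d residues): %s\n", i, length(x$patches[[i]]),
                paste(x$patches[[i]], collapse = ", ")))
  if (length(x$near_patch) > 0)
    cat("  near-patch residues:", paste(x$near_patch, collapse = ", "), "\n")
  invisible(x)
}

# "A:38" -> PyMOL selection "(chain A and resi 38)"
key_to_pml_sel <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  vapply(parts, function(p)
    sprintf("(chain %s and resi %s)",
            if (p[1] == "_") '""' else p[1], p[2]), character(1))
}

#' Write a PyMOL coloring script for a pH-shift analysis
#'
#' Paints protonation-shifting residues yellow, residues involved in created
#' or destroyed bonds orange (drawing dashed distance objects for each delta
#' bond), and patch members green, mirroring the standard delta/patch views.
#'
#' @param path output file for the `.pml` script.
#' @param shifting a `shift_report`.
#' @param delta an `interaction_delta` (optional).
#' @param patches a `patch_set` (optional).
#' @param object PyMOL object name the selections refer to.
#' @return the script lines, invisibly.
#' @export
write_pml <- function(path, shifting, delta = NULL, patches = NULL,
                      object = "structure") {
  lines <- c("# phdelta pH-shift coloring script",
             "bg_color white", "hide everything",
             sprintf("show cartoon, %s", object),
             "color grey80")
  if (nrow(shifting) > 0) {
    sel <- paste(key_to_pml_sel(unique(shifting$key)), collapse = " or ")
    lines <- c(lines,
               sprintf("select shifting, %s", sel),
               "color yellow, shifting", "show sticks, shifting")
  }
  if (!is.null(delta)) {
    bonds <- rbind(delta$created, delta$destroyed)
    if (nrow(bonds) > 0) {
      keys <- unique(c(bonds$key_a, bonds$key_b))
      sel <- paste(key_to_pml_sel(keys), collapse = " or ")
      lines <- c(lines, sprintf("select delta_bonds, %s", sel),
                 "color orange, delta_bonds", "show sticks, delta_bonds")
      for (i in seq_len(nrow(bonds))) {
        lines <- c(lines, sprintf(
          "distance delta_%02d, %s, %s", i,
          key_to_pml_sel(bonds$key_a[i]), key_to_pml_sel(bonds$key_b[i])))
      }
      lines <- c(lines, "color orange, delta_*")
    }
  }
  if (!is.null(patches) && length(patches$patches) > 0) {
    keys <- unlist(patches$patches, use.names = FALSE)
    sel <- paste(key_to_pml_sel(keys), collapse = " or ")
    lines <- c(lines, sprintf("select patch_members, %s", sel),
               "color green, patch_members",
               "show spheres, patch_members and name CA")
  }
  writeLines(lines, path)
  invisible(lines)
}
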