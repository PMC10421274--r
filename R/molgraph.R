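# Molecular-graph featurization: SMILES -> node features, adjacency matrix,
# 3D distance matrix, and intramolecular hydrogen-bond descriptors.

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Atoms are returned in the toolkit's canonical-rank order, so two SMILES
#' forms of the same molecule (e.g. `"CCO"` and `"OCC"`) yield identical
#' graphs and descriptor matrices.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `AtomGraph`: a list with `atoms` (data frame of
#'   element, formal charge, heavy-atom degree, aromatic flag, ring flag and
#'   attached-hydrogen count), `bonds` (two-column matrix of 1-based
#'   heavy-atom index pairs), `natoms`, and the canonical `smiles`.
#' @details Errors of class `math_parse_error` are raised for syntactically
#'   invalid SMILES and `math_sanitize_error` for chemically invalid valence.
#' @examples
#' \dontrun{
#' g <- parse_smiles("CCO")
#' g$natoms  # 3
#' }
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  rec <- .mol_query("parse", smiles)[[1]]
  .check_record(rec, smiles)
  .graph_from_record(rec)
}

.graph_from_record <- function(rec) {
  atoms <- data.frame(
    element  = vapply(rec$atoms$element, identity, character(1)),
    charge   = vapply(rec$atoms$charge, as.integer, integer(1)),
    degree   = vapply(rec$atoms$degree, as.integer, integer(1)),
    aromatic = vapply(rec$atoms$aromatic, isTRUE, logical(1)),
    in_ring  = vapply(rec$atoms$in_ring, isTRUE, logical(1)),
    num_hs   = vapply(rec$atoms$num_hs, as.integer, integer(1)),
    stringsAsFactors = FALSE)
  bonds <- if (length(rec$bonds)) {
    b <- t(vapply(rec$bonds, as.integer, integer(2)))
    # canonical edge list: (min, max) pairs in lexicographic order, so the
    # graph is identical whichever SMILES form produced it
    b <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    b[order(b[, 1], b[, 2]), , drop = FALSE]
  } else {
    matrix(integer(0), ncol = 2)
  }
  structure(list(atoms = atoms, bonds = bonds, natoms = nrow(atoms),
                 smiles = rec$canonical_smiles,
                 coords3d = NULL, elements_full = NULL, bonds_full = NULL,
                 heavy_index_map = NULL, embedded = FALSE, fallback = FALSE),
            class = "AtomGraph")
}

#' @export
print.AtomGraph <- function(x, ...) {
  cat("<AtomGraph> ", x$smiles, "\n  ", x$natoms, " heavy atoms, ",
      nrow(x$bonds), " bonds",
      if (x$embedded) ", 3D conformer embedded" else "",
      if (x$fallback) " (topological-distance fallback)" else "", "\n",
      sep = "")
  invisible(x)
}

#' Embed a single 3D conformer for a molecular graph
#'
#' Adds explicit hydrogens and generates one conformer by seeded
#' distance-geometry embedding (ETKDG) followed by MMFF force-field
#' relaxation. The result is deterministic given `(graph, seed)`. If
#' embedding fails, the seed is incremented up to `max_attempts` times; on
#' total failure the graph is returned with a topological fallback flag
#' (inter-atomic distances then come from bond-graph shortest paths scaled
#' by 1.5 Angstrom per bond and hydrogen-bond detection is disabled) and a
#' warning is emitted.
#'
#' @param graph An `AtomGraph` from [parse_smiles()], or a SMILES string.
#' @param seed Integer random seed for the distance-geometry embedding.
#' @param max_attempts Embedding retries (seed incremented each retry).
#' @return The `AtomGraph` with `coords3d` (all-atom coordinates including
#'   explicit hydrogens, Angstrom), `elements_full`, `bonds_full`, and
#'   `heavy_index_map` (positions of the heavy atoms within `coords3d`).
#' @export
embed_conformer <- function(graph, seed = 42L, max_attempts = 5L) {
  if (is.character(graph)) graph <- parse_smiles(graph)
  stopifnot(inherits(graph, "AtomGraph"))
  rec <- .mol_query("embed", graph$smiles, seed = seed,
                    max_attempts = max_attempts)[[1]]
  .check_record(rec, graph$smiles)  # parse/sanitize errors only
  g <- .graph_from_record(rec)
  if (isTRUE(rec$embedded)) {
    g$coords3d <- t(vapply(rec$coords, as.numeric, numeric(3)))
    colnames(g$coords3d) <- c("x", "y", "z")
    g$elements_full <- vapply(rec$elements_full, identity, character(1))
    g$bonds_full <- t(vapply(rec$bonds_full, as.integer, integer(2)))
    g$heavy_index_map <- vapply(rec$heavy_map, as.integer, integer(1))
    g$embedded <- TRUE
    g$seed <- rec$seed_used
  } else {
    warning("conformer embedding failed for ", graph$smiles,
            " after ", max_attempts, " attempts; ",
            "falling back to topological distances (H-bond detection off)",
            call. = FALSE)
    g$fallback <- TRUE
  }
  g
}

#' Build the heavy-atom adjacency matrix
#'
#' @param graph An `AtomGraph`.
#' @return A symmetric `{0,1}` matrix with zero diagonal; entry `(i, j)` is 1
#'   iff a covalent bond joins heavy atoms `i` and `j`.
#' @export
build_adjacency <- function(graph) {
  stopifnot(inherits(graph, "AtomGraph"), graph$natoms >= 1L)
  A <- matrix(0, graph$natoms, graph$natoms)
  if (nrow(graph$bonds)) {
    A[graph$bonds] <- 1
    A[graph$bonds[, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' Build the pairwise heavy-atom distance matrix from a 3D conformer
#'
#' @param graph An embedded `AtomGraph` (see [embed_conformer()]). Graphs
#'   carrying the topological fallback return shortest-path distances scaled
#'   by 1.5 Angstrom per bond.
#' @return A symmetric non-negative matrix of Euclidean distances (Angstrom)
#'   with zero diagonal.
#' @export
build_distance_matrix <- function(graph) {
  stopifnot(inherits(graph, "AtomGraph"))
  if (isTRUE(graph$fallback)) return(.topological_distance(graph))
  if (!isTRUE(graph$embedded) || is.null(graph$coords3d)) {
    .raise("math_missing_conformer_error",
           "no 3D conformer present; call embed_conformer() first")
  }
  xyz <- graph$coords3d[graph$heavy_index_map, , drop = FALSE]
  as.matrix(stats::dist(xyz))
}

# Bond-graph shortest paths scaled to a typical bond length; used only when
# distance-geometry embedding fails outright.
.topological_distance <- function(graph, bond_length = 1.5) {
  g <- igraph::graph_from_edgelist(graph$bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, graph$natoms - igraph::vcount(g)))
  D <- igraph::distances(g)
  dimnames(D) <- NULL
  D * bond_length
}

#' Detect intramolecular hydrogen bonds from an embedded conformer
#'
#' A hydrogen bond is recorded when a hydrogen covalently bound to a donor
#' heavy atom of element N, O or S lies within `dthreshold` Angstrom of an
#' acceptor heavy atom of element N, O or S. Triples are projected onto
#' heavy-atom indices: the donor index is the heavy atom carrying the
#' hydrogen. Pairs where the acceptor is covalently bonded to the donor
#' (1,2-contacts) are always excluded; 1,3-contacts (donor and acceptor
#' sharing a bonded neighbour) are excluded by default.
#'
#' @param graph An embedded `AtomGraph`.
#' @param dthreshold Maximum distance in Angstrom (must be positive).
#' @param strict_literal If `TRUE`, any hydrogen (including C-H) is treated
#'   as a potential donor; default restricts donors to N/O/S.
#' @param exclude_13 Exclude 1,3-contacts (default `TRUE`).
#' @param distance_mode `"h_acceptor"` (default) measures the
#'   hydrogen-to-acceptor distance; `"donor_acceptor"` measures the
#'   donor-heavy-atom-to-acceptor distance.
#' @return A data frame with columns `donor`, `acceptor` (1-based heavy-atom
#'   indices) and `distance` (Angstrom), sorted by (donor, acceptor,
#'   distance). Zero rows when no bond is found.
#' @export
detect_hbonds <- function(graph, dthreshold = 3.0, strict_literal = FALSE,
                          exclude_13 = TRUE,
                          distance_mode = c("h_acceptor", "donor_acceptor")) {
  stopifnot(inherits(graph, "AtomGraph"))
  distance_mode <- match.arg(distance_mode)
  if (!is.numeric(dthreshold) || dthreshold <= 0) {
    stop("dthreshold must be a positive length in Angstrom", call. = FALSE)
  }
  if (isTRUE(graph$fallback)) return(.empty_triples())
  if (!isTRUE(graph$embedded) || is.null(graph$coords3d)) {
    .raise("math_missing_conformer_error",
           "no 3D conformer present; call embed_conformer() first")
  }
  acceptor_elements <- c("N", "O", "S")
  els <- graph$elements_full
  coords <- graph$coords3d
  nb <- .neighbour_list(graph$bonds_full, length(els))
  heavy_of <- integer(length(els))            # full index -> heavy index
  heavy_of[graph$heavy_index_map] <- seq_along(graph$heavy_index_map)
  A <- build_adjacency(graph)
  acceptors_full <- which(els %in% acceptor_elements & heavy_of > 0)

  out <- .empty_triples()
  for (h in which(els == "H")) {
    partners <- nb[[h]]
    if (length(partners) != 1L) next
    donor_full <- partners
    if (!strict_literal && !(els[donor_full] %in% acceptor_elements)) next
    donor <- heavy_of[donor_full]
    if (donor == 0L) next
    for (a_full in acceptors_full) {
      acc <- heavy_of[a_full]
      if (acc == donor) next
      if (A[donor, acc] == 1) next                       # 1,2-contact
      if (a_full %in% nb[[h]]) next                      # bonded to the H
      if (exclude_13 && any(A[donor, ] * A[acc, ] > 0)) next
      from <- if (distance_mode == "h_acceptor") h else donor_full
      d <- sqrt(sum((coords[from, ] - coords[a_full, ])^2))
      if (d <= dthreshold) {
        out <- rbind(out, data.frame(donor = donor, acceptor = acc,
                                     distance = d))
      }
    }
  }
  out[order(out$donor, out$acceptor, out$distance), , drop = FALSE]
}

.empty_triples <- function() {
  data.frame(donor = integer(0), acceptor = integer(0),
             distance = numeric(0))
}

.neighbour_list <- function(bonds, n) {
  nb <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Convert hydrogen-bond triples to a Boolean matrix
#'
#' @param triples A data frame with `donor` and `acceptor` columns (1-based
#'   heavy-atom indices), as returned by [detect_hbonds()].
#' @param natoms Heavy-atom count (matrix dimension).
#' @return A symmetric `{0,1}` matrix with zero diagonal; `(donor, acceptor)`
#'   and `(acceptor, donor)` are 1 for every triple. Duplicate triples are
#'   idempotent.
#' @export
hbond_matrix <- function(triples, natoms) {
  stopifnot(is.data.frame(triples), natoms >= 1L)
  H <- matrix(0, natoms, natoms)
  if (nrow(triples)) {
    idx <- cbind(triples$donor, triples$acceptor)
    if (any(idx < 1L) || any(idx > natoms)) {
      stop("hydrogen-bond triple index out of range", call. = FALSE)
    }
    H[idx] <- 1
    H[idx[, 2:1, drop = FALSE]] <- 1
  }
  diag(H) <- 0
  H
}

#' Featurizer configuration
#'
#' @param dthreshold Hydrogen-bond distance threshold in Angstrom (used in
#'   `"distance"` mode).
#' @param mode `"distance"` filters hydrogen bonds at `dthreshold`;
#'   `"boolean"` records presence at the default 3.0 Angstrom threshold.
#'   Both produce a `{0,1}` matrix; they differ only in the detection
#'   threshold applied upstream.
#' @param seed Conformer-embedding seed.
#' @param strict_literal,exclude_13,distance_mode Passed to [detect_hbonds()].
#' @param max_attempts Embedding retries.
#' @return A list of class `featurizer_config`.
#' @export
featurizer_config <- function(dthreshold = 3.0,
                              mode = c("distance", "boolean"),
                              seed = 42L, strict_literal = FALSE,
                              exclude_13 = TRUE,
                              distance_mode = c("h_acceptor",
                                                "donor_acceptor"),
                              max_attempts = 5L) {
  mode <- match.arg(mode)
  structure(list(dthreshold = if (mode == "boolean") 3.0 else dthreshold,
                 mode = mode, seed = as.integer(seed),
                 strict_literal = strict_literal, exclude_13 = exclude_13,
                 distance_mode = match.arg(distance_mode),
                 max_attempts = as.integer(max_attempts)),
            class = "featurizer_config")
}

# One-hot atom feature encoding (MAT convention): element over
# {B,N,C,O,F,P,S,Cl,Br,I,other}, heavy degree 0-5, attached-H count 0-4,
# formal charge {-1,0,+1}, ring flag, aromatic flag -> 27 columns.
.FEATURE_ELEMENTS <- c("B", "N", "C", "O", "F", "P", "S", "Cl", "Br", "I")

node_feature_dim <- function() {
  length(.FEATURE_ELEMENTS) + 1L + 6L + 5L + 3L + 2L
}

.node_features <- function(atoms) {
  n <- nrow(atoms)
  el <- match(atoms$element, .FEATURE_ELEMENTS,
              nomatch = length(.FEATURE_ELEMENTS) + 1L)
  deg <- pmin(atoms$degree, 5L)
  nh <- pmin(atoms$num_hs, 4L)
  chg <- pmax(pmin(atoms$charge, 1L), -1L) + 2L
  X <- matrix(0, n, node_feature_dim())
  off <- 0L
  X[cbind(seq_len(n), el)] <- 1
  off <- off + length(.FEATURE_ELEMENTS) + 1L
  X[cbind(seq_len(n), off + deg + 1L)] <- 1
  off <- off + 6L
  X[cbind(seq_len(n), off + nh + 1L)] <- 1
  off <- off + 5L
  X[cbind(seq_len(n), off + chg)] <- 1
  off <- off + 3L
  X[, off + 1L] <- as.numeric(atoms$in_ring)
  X[, off + 2L] <- as.numeric(atoms$aromatic)
  X
}

#' Featurize a SMILES string into the full molecular-graph descriptor set
#'
#' Produces the five descriptors consumed by the hydrogen-bond-augmented
#' attention model: per-atom feature vectors, the adjacency matrix, the 3D
#' inter-atomic distance matrix, the hydrogen-bond Boolean matrix, and the
#' underlying (donor, acceptor, distance) triples.
#'
#' @param smiles A single SMILES string.
#' @param config A [featurizer_config()].
#' @return An object of class `DescriptorSet`: list with `node_features`
#'   (`natoms x 27`), `adjacency`, `distance`, `hbond_bool` (all
#'   `natoms x natoms`), `hbond_triples` (data frame), `natoms`, canonical
#'   `smiles`, the `config` used, and a `fallback` flag.
#' @export
featurize <- function(smiles, config = featurizer_config()) {
  stopifnot(inherits(config, "featurizer_config"))
  g <- embed_conformer(parse_smiles(smiles), seed = config$seed,
                       max_attempts = config$max_attempts)
  triples <- if (g$fallback) .empty_triples() else {
    detect_hbonds(g, dthreshold = config$dthreshold,
                  strict_literal = config$strict_literal,
                  exclude_13 = config$exclude_13,
                  distance_mode = config$distance_mode)
  }
  structure(list(node_features = .node_features(g$atoms),
                 adjacency = build_adjacency(g),
                 distance = build_distance_matrix(g),
                 hbond_bool = hbond_matrix(triples, g$natoms),
                 hbond_triples = triples,
                 natoms = g$natoms, smiles = g$smiles,
                 config = config, fallback = g$fallback),
            class = "DescriptorSet")
}

#' @export
print.DescriptorSet <- function(x, ...) {
  cat("<DescriptorSet> ", x$smiles, "\n  ", x$natoms, " heavy atoms; ",
      nrow(x$hbond_triples), " H-bond triple(s) at ",
      x$config$dthreshold, " Angstrom (", x$config$mode, " mode)",
      if (x$fallback) "; topological-distance fallback" else "", "\n",
      sep = "")
  invisible(x)
}
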