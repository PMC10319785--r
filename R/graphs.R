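# Molecular graph construction: node attribute matrix X, edge attribute
# matrix E (one-hot over the four bond types, one row per directed edge),
# and binary adjacency A.

#' Node featurizer configuration
#'
#' Controls which attribute blocks enter the node attribute matrix and in
#' which fixed order: element one-hot | degree | radius | mass | in_ring |
#' x,y,z. With every block enabled and the default 13-element vocabulary
#' the node feature width is 13 + 1 + 1 + 1 + 1 + 3 = 20.
#'
#' @param element_vocabulary Ordered element symbols for the one-hot block.
#' @param include Named logical vector over blocks
#'   \code{symbol, degree, radius, mass, in_ring, coords}.
#' @param coord_centering Centre coordinates at the molecule centroid.
#' @return A \code{featurizer_config} object.
#' @export
featurizer_config <- function(element_vocabulary = default_elements(),
                              include = c(symbol = TRUE, degree = TRUE,
                                          radius = TRUE, mass = TRUE,
                                          in_ring = TRUE, coords = TRUE),
                              coord_centering = TRUE) {
  blocks <- c("symbol", "degree", "radius", "mass", "in_ring", "coords")
  inc <- rep(TRUE, 6); names(inc) <- blocks
  inc[names(include)] <- include
  structure(list(element_vocabulary = element_vocabulary,
                 include = inc, coord_centering = coord_centering),
            class = "featurizer_config")
}

.block_widths <- function(cfg) {
  c(symbol = length(cfg$element_vocabulary), degree = 1, radius = 1,
    mass = 1, in_ring = 1, coords = 3)[cfg$include]
}

#' Column ranges of the feature blocks
#'
#' @param cfg A \code{featurizer_config}.
#' @return Named list mapping each enabled block to its column indices in X.
#' @export
feature_blocks <- function(cfg = featurizer_config()) {
  w <- .block_widths(cfg)
  ends <- cumsum(w)
  starts <- ends - w + 1
  stats::setNames(lapply(seq_along(w), function(k) starts[k]:ends[k]),
                  names(w))
}

#' Build the molecular graph of a molecule
#'
#' Assembles the network input: node attribute matrix \code{X} (blocks in
#' the order symbol one-hot, degree, radius, mass, in_ring, centred x/y/z),
#' directed edge attribute matrix \code{E} (one-hot over single, double,
#' triple, aromatic; both directions of every bond), \code{edge_index}
#' aligned with the rows of \code{E}, and symmetric binary adjacency
#' \code{A}.
#'
#' @param mol A \code{ccs_molecule}.
#' @param conf Conformer coordinates (defaults to \code{mol$conformer}).
#' @param cfg A \code{\link{featurizer_config}}.
#' @return A \code{molecular_graph}: list(X, E, edge_index, A, blocks, cfg).
#' @export
build_graph <- function(mol, conf = mol$conformer, cfg = featurizer_config()) {
  stopifnot(inherits(mol, "ccs_molecule"))
  n <- nrow(mol$atoms)
  if (cfg$include["coords"]) {
    if (is.null(conf)) {
      stop(errorCondition("molecule has no conformer",
                          class = c("graphccs_inconsistent_input",
                                    "graphccs_error")))
    }
    if (nrow(conf) != n) {
      stop(errorCondition("conformer and molecule atom counts disagree",
                          class = c("graphccs_inconsistent_input",
                                    "graphccs_error")))
    }
  }
  blocks <- feature_blocks(cfg)
  X <- matrix(0, n, sum(.block_widths(cfg)))
  if (cfg$include["symbol"]) {
    idx <- match(mol$atoms$element, cfg$element_vocabulary)
    hit <- !is.na(idx)
    X[cbind(which(hit), blocks$symbol[idx[hit]])] <- 1
  }
  if (cfg$include["degree"]) X[, blocks$degree] <- mol$atoms$degree
  if (cfg$include["radius"]) X[, blocks$radius] <- mol$atoms$radius
  if (cfg$include["mass"])   X[, blocks$mass] <- mol$atoms$mass
  if (cfg$include["in_ring"]) X[, blocks$in_ring] <- as.numeric(mol$atoms$in_ring)
  if (cfg$include["coords"]) {
    co <- unclass(conf)[, 1:3, drop = FALSE]
    if (cfg$coord_centering && n > 0) {
      co <- sweep(co, 2, colMeans(co))
    }
    X[, blocks$coords] <- co
  }
  m <- nrow(mol$bonds)
  edge_index <- matrix(0L, 2 * m, 2)
  E <- matrix(0, 2 * m, 4)
  A <- matrix(0, n, n)
  if (m > 0) {
    i <- mol$bonds$i; j <- mol$bonds$j
    edge_index[, 1] <- c(i, j)
    edge_index[, 2] <- c(j, i)
    typ <- match(mol$bonds$order, .BOND_ORDERS)
    E[cbind(seq_len(2 * m), c(typ, typ))] <- 1
    A[cbind(c(i, j), c(j, i))] <- 1
  }
  structure(list(X = X, E = E, edge_index = edge_index, A = A,
                 blocks = blocks, cfg = cfg),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %d nodes x %d features, %d directed edges\n",
              nrow(x$X), ncol(x$X), nrow(x$E)))
  invisible(x)
}

#' Zero out one attribute block of a molecular graph
#'
#' Returns a copy of the graph with the named block's columns of X replaced
#' by zeros; everything else untouched. Masking is idempotent. This is the
#' inference-time masking used by the feature-importance analysis.
#'
#' @param graph A \code{molecular_graph}.
#' @param attribute One of \code{symbol, degree, radius, mass, in_ring,
#'   coords}.
#' @return Masked copy of the graph.
#' @export
mask_attribute <- function(graph, attribute) {
  if (!attribute %in% names(graph$blocks)) {
    stop(errorCondition(
      sprintf("unknown attribute block '%s' (have: %s)", attribute,
              paste(names(graph$blocks), collapse = ", ")),
      class = c("graphccs_unknown_attribute", "graphccs_error")))
  }
  graph$X[, graph$blocks[[attribute]]] <- 0
  graph
}

#' Rotate a conformer about its centroid
#'
#' @param conf N x 3 coordinate matrix.
#' @param rotation 3 x 3 proper rotation matrix (orthonormal, det +1,
#'   checked to 1e-8).
#' @return Rotated coordinates; all pairwise distances are preserved.
#' @export
rotate_conformer <- function(conf, rotation) {
  R <- rotation
  if (!is.matrix(R) || any(dim(R) != 3) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8 ||
      abs(det(R) - 1) > 1e-8) {
    stop(errorCondition("not a proper rotation matrix",
                        class = c("graphccs_not_a_rotation", "graphccs_error")))
  }
  att <- attr(conf, "energy_minimized")
  co <- unclass(conf)
  centroid <- colMeans(co)
  out <- sweep(sweep(co, 2, centroid) %*% t(R), 2, centroid, `+`)
  attr(out, "energy_minimized") <- att
  out
}

#' Uniformly random rotation matrices
#'
#' Samples rotations uniformly over SO(3) via Shoemake's quaternion method.
#'
#' @param n Number of rotations.
#' @param seed Optional integer seed (local to this call).
#' @return List of 3 x 3 rotation matrices.
#' @export
random_rotations <- function(n, seed = NULL) {
  u <- if (!is.null(seed)) {
    with_local_seed(seed, matrix(stats::runif(3 * n), n, 3))
  } else {
    matrix(stats::runif(3 * n), n, 3)
  }
  lapply(seq_len(n), function(k) .quat_to_rot(.shoemake_quat(u[k, ])))
}

.shoemake_quat <- function(u) {
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

.quat_to_rot <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

# Run expr with a temporary RNG state, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
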