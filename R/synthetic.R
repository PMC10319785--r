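# Download-free synthetic data: random small organic molecules with 3D
# conformers, labelled by a deterministic physics-shaped CCS oracle (an
# orientation-averaged projected area in the projection-approximation
# family) plus per-adduct offsets and Gaussian noise. The emitted records
# use the same schema chem_io reads, so every downstream module consumes
# synthetic data unchanged.

.VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1)

#' Synthetic dataset specification
#'
#' @param n_molecules Number of molecules to generate.
#' @param elements Heavy-atom palette (hydrogens are implicit in the
#'   generated SMILES and added back at parse time).
#' @param heavy_atom_range Inclusive range of heavy-atom counts.
#' @param adduct_offsets Named offsets (Angstrom^2) added to the oracle
#'   area per adduct; the defaults (+H: 0, +Na: +4, -H: -2) are arbitrary
#'   but fixed, giving the model a learnable adduct effect.
#' @param noise_sd Gaussian noise on the CCS labels (Angstrom^2).
#' @param p_ring Probability a molecule gets one ring-closure bond.
#' @param p_double Per-tree-bond probability of promotion to a double bond
#'   (valence permitting).
#' @param max_retries Total resampling budget for molecules that fail
#'   parsing or embedding.
#' @param seed Seed driving the whole generation.
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_molecules = 500,
                           elements = c("C", "C", "C", "N", "O", "S"),
                           heavy_atom_range = c(3, 10),
                           adduct_offsets = c(`[M+H]+` = 0, `[M+Na]+` = 4,
                                              `[M-H]-` = -2),
                           noise_sd = 1.5,
                           p_ring = 0.4, p_double = 0.15,
                           max_retries = 10L * n_molecules,
                           seed = 1L) {
  stopifnot(n_molecules > 0, noise_sd >= 0,
            all(elements %in% names(.VALENCE)))
  structure(list(n_molecules = as.integer(n_molecules), elements = elements,
                 heavy_atom_range = as.integer(heavy_atom_range),
                 adduct_offsets = adduct_offsets, noise_sd = noise_sd,
                 p_ring = p_ring, p_double = p_double,
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Draw one random molecular skeleton (tree + optional ring closure +
# optional double bonds) and serialise it as SMILES. Uses the current RNG
# stream.
.random_smiles <- function(spec) {
  n <- sample(spec$heavy_atom_range[1]:spec$heavy_atom_range[2], 1)
  el <- sample(spec$elements, n, replace = TRUE)
  free <- .VALENCE[el]
  parent <- integer(n)
  bonds <- NULL                      # columns: i, j, order(1/2), ring flag
  for (k in seq_len(n)[-1]) {
    avail <- which(free[seq_len(k - 1)] > 0)
    if (!length(avail)) return(NULL)
    p <- if (length(avail) == 1) avail else sample(avail, 1)
    parent[k] <- p
    bonds <- rbind(bonds, c(p, k, 1, 0))
    free[p] <- free[p] - 1
    free[k] <- free[k] - 1
  }
  if (!is.null(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      if (stats::runif(1) < spec$p_double) {
        i <- bonds[r, 1]; j <- bonds[r, 2]
        if (free[i] > 0 && free[j] > 0) {
          bonds[r, 3] <- 2
          free[i] <- free[i] - 1
          free[j] <- free[j] - 1
        }
      }
    }
  }
  if (n >= 3 && stats::runif(1) < spec$p_ring) {
    # tree distance for ring-size control
    depth <- integer(n)
    for (k in seq_len(n)[-1]) depth[k] <- depth[parent[k]] + 1
    anc <- function(a) { out <- a; while (a != 1) { a <- parent[a]
      out <- c(out, a) }; out }
    cand <- which(free > 0)
    if (length(cand) >= 2) {
      pairs <- t(utils::combn(cand, 2))
      dist2 <- apply(pairs, 1, function(pr) {
        pa <- anc(pr[1]); pb <- anc(pr[2])
        common <- intersect(pa, pb)[1]
        depth[pr[1]] + depth[pr[2]] - 2 * depth[common]
      })
      ok <- which(dist2 >= 2 & dist2 <= 6)
      if (length(ok)) {
        pick <- pairs[if (length(ok) == 1) ok else sample(ok, 1), ]
        bonds <- rbind(bonds, c(pick[1], pick[2], 1, 1))
      }
    }
  }
  .write_smiles(el, bonds, n)
}

# Minimal SMILES writer for single/double bonds with ring closures over the
# organic subset (no charges, implicit hydrogens).
.write_smiles <- function(el, bonds, n) {
  if (n == 1) return(el[1])
  tree_nb <- vector("list", n)
  ring_at <- vector("list", n)
  bond_ord <- new.env()
  bkey <- function(i, j) paste(min(i, j), max(i, j))
  ring_id <- 0
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    assign(bkey(i, j), bonds[r, 3], envir = bond_ord)
    if (bonds[r, 4] == 1) {
      ring_id <- ring_id + 1
      ring_at[[i]] <- c(ring_at[[i]], ring_id)
      ring_at[[j]] <- c(ring_at[[j]], ring_id)
    } else {
      tree_nb[[i]] <- c(tree_nb[[i]], j)
      tree_nb[[j]] <- c(tree_nb[[j]], i)
    }
  }
  sym <- function(o) if (o == 2) "=" else ""
  visit <- function(u, par) {
    s <- el[u]
    for (d in ring_at[[u]]) s <- paste0(s, d)
    kids <- setdiff(tree_nb[[u]], par)
    if (length(kids)) {
      for (k in seq_along(kids)) {
        child <- kids[k]
        part <- paste0(sym(get(bkey(u, child), envir = bond_ord)),
                       visit(child, u))
        s <- if (k < length(kids)) paste0(s, "(", part, ")")
             else paste0(s, part)
      }
    }
    s
  }
  visit(1, 0)
}

#' Generate random molecules with conformers
#'
#' Draws random valid SMILES from the palette grammar (random trees plus
#' optional ring closures and double bonds), parses and embeds them, and
#' resamples any that fail. Deterministic per seed.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return Named list of \code{ccs_molecule} (length \code{n_molecules}),
#'   each with a conformer.
#' @export
generate_molecules <- function(spec = synthetic_spec()) {
  with_local_seed(spec$seed, {
    mols <- list()
    tries <- 0L
    while (length(mols) < spec$n_molecules) {
      want <- spec$n_molecules - length(mols)
      cand <- list()
      while (length(cand) < want && tries < spec$max_retries) {
        tries <- tries + 1L
        smi <- .random_smiles(spec)
        if (is.null(smi)) next
        mol <- tryCatch(parse_molecule(smi),
                        graphccs_error = function(e) NULL)
        if (is.null(mol) || mol$smiles %in% names(mols)) next
        cand[[mol$smiles]] <- mol
      }
      if (!length(cand)) break
      cand <- embed_molecules(cand, on_failure = "keep")
      good <- vapply(cand, function(m) !is.null(m$conformer), logical(1))
      mols <- c(mols, cand[good])
      if (tries >= spec$max_retries) break
    }
    if (length(mols) < spec$n_molecules) {
      stop(errorCondition(
        sprintf("molecule generation exhausted after %d tries (%d/%d built)",
                tries, length(mols), spec$n_molecules),
        class = c("graphccs_generation_exhausted", "graphccs_error")))
    }
    mols[seq_len(spec$n_molecules)]
  })
}

#' Oracle configuration for the projected-area CCS reference
#'
#' @param probe Radius addition (Angstrom) applied to every atomic sphere
#'   (an effective buffer-gas contact distance).
#' @param n_rotations Orientations for the rotation average.
#' @param grid Stratified-grid resolution per side (grid^2 sample points
#'   per orientation).
#' @param seed Seed for the jitter and the orientation-sequence shift.
#' @return An \code{oracle_config} list.
#' @export
oracle_config <- function(probe = 1.0, n_rotations = 256, grid = 48,
                          seed = 1L) {
  stopifnot(n_rotations >= 1, grid >= 4)
  structure(list(probe = probe, n_rotations = as.integer(n_rotations),
                 grid = as.integer(grid), seed = as.integer(seed)),
            class = "oracle_config")
}

# Halton low-discrepancy sequence (bases 2, 3, 5), optionally shifted.
.halton <- function(n, shift = c(0, 0, 0)) {
  radical <- function(i, base) {
    f <- 1; r <- 0
    while (any(i > 0)) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  u <- cbind(radical(seq_len(n), 2), radical(seq_len(n), 3),
             radical(seq_len(n), 5))
  (u + matrix(shift, n, 3, byrow = TRUE)) %% 1
}

#' Orientation-averaged projected area (CCS oracle)
#'
#' Estimates the average, over a low-discrepancy set of orientations, of
#' the area of the union of the projected atomic disks (radius = atomic
#' radius + probe). A stratified jittered grid over the bounding square
#' estimates each projection's area. Deterministic per seed; optionally
#' adds a fixed per-adduct offset.
#'
#' @param conf N x 3 coordinate matrix.
#' @param radii Per-atom radii (Angstrom), e.g. van der Waals.
#' @param cfg An \code{\link{oracle_config}}.
#' @param adduct Optional adduct label; adds \code{adduct_offsets[adduct]}.
#' @param adduct_offsets Named offsets (defaults as in
#'   \code{\link{synthetic_spec}}).
#' @return CCS value in Angstrom^2.
#' @export
oracle_ccs <- function(conf, radii, cfg = oracle_config(), adduct = NULL,
                       adduct_offsets = c(`[M+H]+` = 0, `[M+Na]+` = 4,
                                          `[M-H]-` = -2)) {
  co <- unclass(conf)[, 1:3, drop = FALSE]
  stopifnot(length(radii) == nrow(co))
  co <- sweep(co, 2, colMeans(co))
  K <- cfg$grid
  with_local_seed(cfg$seed, {
    shift <- stats::runif(3)
    u <- .halton(cfg$n_rotations, shift)
    gx <- rep(seq_len(K) - 1, each = K)
    gy <- rep(seq_len(K) - 1, times = K)
    areas <- numeric(cfg$n_rotations)
    r2 <- radii^2  # placeholder, recomputed with probe below
    R <- radii + cfg$probe
    R2 <- R^2
    for (o in seq_len(cfg$n_rotations)) {
      rot <- .quat_to_rot(.shoemake_quat(u[o, ]))
      xy <- co %*% t(rot)
      xy <- xy[, 1:2, drop = FALSE]
      xmin <- min(xy[, 1] - R); xmax <- max(xy[, 1] + R)
      ymin <- min(xy[, 2] - R); ymax <- max(xy[, 2] + R)
      wx <- (xmax - xmin) / K; wy <- (ymax - ymin) / K
      px <- xmin + (gx + stats::runif(K * K)) * wx
      py <- ymin + (gy + stats::runif(K * K)) * wy
      inside <- rep(FALSE, K * K)
      for (a in seq_len(nrow(xy))) {
        inside <- inside |
          ((px - xy[a, 1])^2 + (py - xy[a, 2])^2 <= R2[a])
      }
      areas[o] <- mean(inside) * (xmax - xmin) * (ymax - ymin)
    }
    off <- if (is.null(adduct)) 0 else
      unname(adduct_offsets[normalize_adduct(adduct)])
    mean(areas) + off
  })
}

#' Build a synthetic CCS dataset
#'
#' Generates molecules, labels every (molecule, adduct) pair over the three
#' supported adducts with the projected-area oracle plus the adduct offset
#' and Gaussian noise, and computes m/z from the molecular mass and the
#' adduct mass shift.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param oracle_cfg An \code{\link{oracle_config}}.
#' @return A \code{ccs_dataset} (3 records per molecule) whose molecules
#'   carry conformers; the true noise-free oracle value is kept in column
#'   \code{ccs_true}.
#' @export
make_dataset <- function(spec = synthetic_spec(),
                         oracle_cfg = oracle_config(seed = spec$seed)) {
  mols <- generate_molecules(spec)
  vdw <- stats::setNames(element_table()$vdw_radius, element_table()$element)
  base <- vapply(mols, function(m)
    oracle_ccs(m$conformer, unname(vdw[m$atoms$element]), oracle_cfg),
    numeric(1))
  mass <- vapply(mols, .neutral_mass, numeric(1))
  adducts <- supported_adducts()
  nm <- length(mols)
  records <- data.frame(
    identifier = paste0(rep(sprintf("syn_%04d", seq_len(nm)), each = 3),
                        "_", rep(seq_len(3), nm)),
    smiles = rep(vapply(mols, `[[`, "", "smiles"), each = 3),
    adduct = rep(adducts, nm),
    ccs = NA_real_,
    mz = rep(mass, each = 3) + adduct_mass_shift(rep(adducts, nm)),
    rt = NA_real_,
    instrument = "synthetic",
    stringsAsFactors = FALSE)
  truth <- rep(base, each = 3) +
    unname(spec$adduct_offsets[records$adduct])
  noise <- with_local_seed(spec$seed + 7L,
                           stats::rnorm(nrow(records), 0, spec$noise_sd))
  records$ccs <- truth + noise
  records$ccs_true <- truth
  ccs_dataset(records, mols, embed = FALSE)
}
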