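# Shared fixtures, built in code and memoised for the test run.

.fx_env <- new.env(parent = emptyenv())

.fx_memo <- function(key, builder) {
  if (!exists(key, envir = .fx_env)) assign(key, builder(), envir = .fx_env)
  get(key, envir = .fx_env)
}

# Small synthetic dataset: 40 molecules x 3 adducts, fixed seed.
fx_dataset <- function() {
  .fx_memo("dataset", function()
    make_dataset(synthetic_spec(n_molecules = 40, seed = 101),
                 oracle_config(n_rotations = 128, grid = 32, seed = 101)))
}

# A tiny trained model on the fixture dataset (fast, loose fit).
fx_model <- function() {
  .fx_memo("model", function() {
    parts <- split_records(fx_dataset(), c(train = 0.8, test = 0.2),
                           seed = 101, level = "molecule")
    fit(parts$train,
        config = scaled_model_config(epochs = 200, patience = 200,
                                     lr_decay_every = 0, n_restarts = 1,
                                     seed = 101))
  })
}

fx_split <- function() {
  .fx_memo("split", function()
    split_records(fx_dataset(), c(train = 0.8, test = 0.2),
                  seed = 101, level = "molecule"))
}

# Random small molecular graph (tree plus optional extra edges) with
# one-hot bond types; for network math tests.
fx_random_graph <- function(n_nodes, n_feat) {
  ei <- NULL
  types <- integer(0)
  if (n_nodes > 1) {
    for (k in 2:n_nodes) {
      p <- if (k == 2) 1 else sample(k - 1, 1)
      ei <- rbind(ei, c(k, p), c(p, k))
      t <- sample(4, 1)
      types <- c(types, t, t)
    }
  }
  E <- matrix(0, length(types), 4)
  if (length(types)) E[cbind(seq_along(types), types)] <- 1
  list(X = matrix(rnorm(n_nodes * n_feat), n_nodes, n_feat),
       E = E, edge_index = if (is.null(ei)) matrix(0L, 0, 2) else ei)
}

# Independent brute-force ECC reference: explicit double loop, per-edge
# MLP evaluated scalar-wise.
brute_force_ecc <- function(X, E, edge_index, params) {
  n <- nrow(X)
  fin <- nrow(params$W); fout <- ncol(params$W)
  out <- matrix(0, n, fout)
  for (i in seq_len(n)) {
    out[i, ] <- as.numeric(X[i, , drop = FALSE] %*% params$W) + params$b
  }
  for (e in seq_len(nrow(edge_index))) {
    i <- edge_index[e, 1]; j <- edge_index[e, 2]
    h <- pmax(as.numeric(E[e, ] %*% params$mlp$W1) + params$mlp$b1, 0)
    th <- matrix(as.numeric(h %*% params$mlp$W2) + params$mlp$b2, fin, fout)
    out[i, ] <- out[i, ] + as.numeric(X[j, , drop = FALSE] %*% th)
  }
  out
}

# Apply a node permutation to a molecule (atoms, bonds, conformer).
permute_molecule <- function(mol, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  mol$atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol$bonds$i <- inv[mol$bonds$i]
  mol$bonds$j <- inv[mol$bonds$j]
  if (!is.null(mol$conformer)) {
    em <- attr(mol$conformer, "energy_minimized")
    mol$conformer <- unclass(mol$conformer)[perm, , drop = FALSE]
    attr(mol$conformer, "energy_minimized") <- em
  }
  mol
}

# Write a records data.frame to a temp CSV.
fx_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
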