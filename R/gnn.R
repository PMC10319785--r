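# Network core: edge-conditioned graph convolution, global sum pooling,
# adduct fusion, the fully connected head, and checkpoint I/O.
#
# One ECC layer maps node features X (N x Fin) to (N x Fout):
#   out_i = x_i W + sum_{j in N(i)} x_j MLP(e_ij) + b
# where MLP turns the 4-dim one-hot bond attribute e_ij into an
# Fin x Fout filter matrix. The root term x_i W excludes self-loops from
# the neighbour sum. Each layer is followed by ReLU.

.relu <- function(x) pmax(x, 0)

#' Model configuration
#'
#' Architecture and training hyperparameters. The reference architecture is
#' 3 ECC layers of width 16 (so the pooled representation p has length 16),
#' global sum pooling, concatenation with the 3-dim adduct one-hot, then 8
#' fully connected ReLU layers (geometric taper) and a ReLU output unit.
#' L2 regularisation applies to ECC and FC weights, not the output layer.
#'
#' @param ecc_widths Output widths of the ECC layers; the last one is the
#'   pooled dimension.
#' @param fc_widths Widths of the hidden fully connected layers (the output
#'   layer of width 1 is implicit).
#' @param edge_mlp_hidden Hidden width of the per-edge filter MLP.
#' @param l2 L2 coefficient on ECC and FC weights.
#' @param learning_rate,batch_size,epochs,patience Adam training controls;
#'   \code{patience} is the early-stopping window in epochs (validation MSE).
#' @param lr_decay,lr_decay_every Step learning-rate schedule: the rate is
#'   multiplied by \code{lr_decay} every \code{lr_decay_every} epochs
#'   (0 disables the schedule).
#' @param n_restarts Independent training restarts (seeds seed, seed+1,
#'   ...); the restart with the lowest validation MSE is kept. Averages
#'   out initialisation luck on small networks.
#' @param standardize Standardise continuous node features (radius, mass,
#'   coordinates) with training-set statistics stored in the checkpoint.
#' @param domain_ceiling CCS (Angstrom^2) above which predictions trigger a
#'   training-domain warning.
#' @param seed Seed for parameter initialisation, shuffling and batching.
#' @return A \code{model_config} object.
#' @export
model_config <- function(ecc_widths = c(16, 16, 16),
                         fc_widths = c(384, 192, 96, 48, 24, 12, 6, 3),
                         edge_mlp_hidden = 32,
                         l2 = 1e-6,
                         learning_rate = 1e-3,
                         batch_size = 32,
                         epochs = 300,
                         patience = 40,
                         lr_decay = 0.5,
                         lr_decay_every = 0,
                         n_restarts = 1,
                         standardize = TRUE,
                         domain_ceiling = 380,
                         adduct_dim = 3,
                         seed = 1L) {
  structure(list(ecc_widths = ecc_widths, fc_widths = fc_widths,
                 n_ecc_layers = length(ecc_widths),
                 n_fc_layers = length(fc_widths),
                 edge_mlp_hidden = edge_mlp_hidden, l2 = l2,
                 learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, patience = patience,
                 lr_decay = lr_decay, lr_decay_every = lr_decay_every,
                 n_restarts = as.integer(n_restarts),
                 standardize = standardize, domain_ceiling = domain_ceiling,
                 adduct_dim = adduct_dim, seed = as.integer(seed)),
            class = "model_config")
}

#' Scaled-down model configuration
#'
#' A small configuration (2 ECC layers of width 8, 3 FC layers) that trains
#' in minutes on one CPU; used for synthetic-data experiments and tests.
#' @param ... Overrides passed on to \code{\link{model_config}}.
#' @export
scaled_model_config <- function(...) {
  args <- list(...)
  defaults <- list(ecc_widths = c(8, 8), fc_widths = c(32, 16, 8),
                   edge_mlp_hidden = 32, l2 = 1e-6, learning_rate = 1e-2,
                   batch_size = 32, epochs = 800, patience = 120,
                   lr_decay = 0.3, lr_decay_every = 400, n_restarts = 3)
  do.call(model_config, utils::modifyList(defaults, args))
}

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialise ECC layer parameters
#'
#' @param fin,fout Input/output widths.
#' @param hidden Hidden width of the edge-filter MLP.
#' @return list(W, b, mlp = list(W1, b1, W2, b2)). The MLP maps a 4-dim
#'   edge attribute vector to an fin x fout filter matrix (column-major
#'   reshape of its output).
#' @export
ecc_layer_params <- function(fin, fout, hidden = 32) {
  list(W = .glorot(fin, fout), b = numeric(fout),
       mlp = list(W1 = .glorot(4, hidden), b1 = numeric(hidden),
                  W2 = .glorot(hidden, fin * fout) /
                    sqrt(max(1, fin / 4)),  # temper message scale
                  b2 = numeric(fin * fout)))
}

#' Initialise all model parameters
#'
#' @param config A \code{\link{model_config}}.
#' @param input_dim Node feature width Fn.
#' @param seed Integer seed (defaults to the config seed).
#' @return A \code{model_params} list: \code{ecc} (per-layer), \code{fc}
#'   (per-layer), \code{out} (output layer), \code{feat_stats}
#'   (standardisation statistics, NULL until fitted).
#' @export
init_params <- function(config, input_dim, seed = config$seed) {
  with_local_seed(seed, {
    widths <- c(input_dim, config$ecc_widths)
    ecc <- lapply(seq_len(config$n_ecc_layers), function(l)
      ecc_layer_params(widths[l], widths[l + 1], config$edge_mlp_hidden))
    fused <- config$ecc_widths[config$n_ecc_layers] + config$adduct_dim
    fw <- c(fused, config$fc_widths)
    fc <- lapply(seq_len(config$n_fc_layers), function(k)
      list(W = .glorot(fw[k], fw[k + 1]), b = numeric(fw[k + 1])))
    out <- list(W = .glorot(fw[length(fw)], 1), b = 0)
    structure(list(ecc = ecc, fc = fc, out = out,
                   feat_stats = NULL, input_dim = input_dim),
              class = "model_params")
  })
}

# Per-bond-type filter matrices Theta_t (t = single, double, triple,
# aromatic). Because edge attributes are one-hot, MLP(e_t) takes only four
# values; precomputing them makes both the dense-edge and the sparse
# batched paths share one code path.
.edge_filters <- function(mlp, fin, fout) {
  H <- .relu(sweep(mlp$W1, 2, mlp$b1, `+`))       # 4 x hidden (rows = types)
  TH <- sweep(H %*% mlp$W2, 2, mlp$b2, `+`)       # 4 x (fin*fout)
  lapply(1:4, function(t) matrix(TH[t, ], fin, fout))
}

#' Edge-conditioned convolution forward pass
#'
#' Computes \code{out_i = x_i W + sum_j x_j MLP(e_ij) + b} for every node,
#' optionally followed by ReLU. Handles arbitrary (not necessarily one-hot)
#' edge attribute matrices by evaluating the filter MLP on each edge row.
#'
#' @param X N x Fin node feature matrix.
#' @param E M x 4 edge attribute matrix (row e describes the directed edge
#'   \code{edge_index[e, ]}).
#' @param edge_index M x 2 integer matrix of (target i, source j) pairs;
#'   both directions of every bond must be present.
#' @param params \code{\link{ecc_layer_params}}-shaped list.
#' @param activation Apply ReLU (default TRUE); FALSE returns the
#'   pre-activation output.
#' @return N x Fout matrix.
#' @export
ecc_forward <- function(X, E, edge_index, params, activation = TRUE) {
  fin <- nrow(params$W); fout <- ncol(params$W)
  if (ncol(X) != fin) {
    stop(errorCondition(
      sprintf("node feature width %d does not match layer input %d",
              ncol(X), fin),
      class = c("graphccs_shape_error", "graphccs_error")))
  }
  out <- X %*% params$W
  if (nrow(E) > 0) {
    if (nrow(E) != nrow(edge_index)) {
      stop(errorCondition("E and edge_index row counts disagree",
                          class = c("graphccs_shape_error", "graphccs_error")))
    }
    H <- .relu(sweep(E %*% params$mlp$W1, 2, params$mlp$b1, `+`))
    TH <- sweep(H %*% params$mlp$W2, 2, params$mlp$b2, `+`)  # M x (fin*fout)
    for (e in seq_len(nrow(E))) {
      i <- edge_index[e, 1]; j <- edge_index[e, 2]
      out[i, ] <- out[i, ] + X[j, ] %*% matrix(TH[e, ], fin, fout)
    }
  }
  out <- sweep(out, 2, params$b, `+`)
  if (activation) out <- .relu(out)
  out
}

#' Global sum pooling
#'
#' Pools a graph by summing node features across the node dimension:
#' \code{p_j = sum_i X[i, j]}.
#'
#' @param X_last Nonempty node feature matrix (output of the last ECC layer).
#' @return Numeric vector p of length \code{ncol(X_last)}.
#' @export
global_sum_pool <- function(X_last) {
  if (is.null(dim(X_last)) || nrow(X_last) == 0) {
    stop(errorCondition("cannot pool an empty graph",
                        class = c("graphccs_empty_graph", "graphccs_error")))
  }
  colSums(X_last)
}

#' Fuse the pooled representation with the adduct one-hot
#'
#' @param p Pooled representation vector.
#' @param adduct Adduct label.
#' @return Feature vector \code{m = c(p, a)} of length \code{length(p) + 3}.
#' @export
fuse_adduct <- function(p, adduct) {
  c(p, adduct_code(adduct))
}

# Standardise node features in place using stored stats; optionally zero a
# masked block afterwards (mask value 0 on the standardised scale).
.prep_X <- function(X, params, blocks, mask = NULL) {
  fs <- params$feat_stats
  if (!is.null(fs)) {
    X[, fs$cols] <- sweep(sweep(X[, fs$cols, drop = FALSE], 2, fs$mean),
                          2, fs$sd, `/`)
  }
  if (!is.null(mask)) {
    for (b in mask) {
      if (!b %in% names(blocks)) {
        stop(errorCondition(sprintf("unknown attribute block '%s'", b),
                            class = c("graphccs_unknown_attribute",
                                      "graphccs_error")))
      }
      X[, blocks[[b]]] <- 0
    }
  }
  X
}

.fc_forward <- function(m, params) {
  h <- m
  for (layer in params$fc) {
    h <- .relu(sweep(h %*% layer$W, 2, layer$b, `+`))
  }
  .relu(sweep(h %*% params$out$W, 2, params$out$b, `+`))
}

# Full forward pass for one graph; returns list(pred, p).
.forward_graph <- function(graph, adduct, params, config, mask = NULL) {
  X <- .prep_X(graph$X, params, graph$blocks, mask)
  for (l in seq_len(config$n_ecc_layers)) {
    X <- ecc_forward(X, graph$E, graph$edge_index, params$ecc[[l]],
                     activation = TRUE)
  }
  p <- global_sum_pool(X)
  m <- matrix(fuse_adduct(p, adduct), 1)
  list(pred = as.numeric(.fc_forward(m, params)), p = p)
}

#' Predict the CCS value of a molecule
#'
#' Deterministic forward pass: ECC layers, global sum pooling, adduct
#' fusion, fully connected head, ReLU output. Warns when the prediction
#' reaches the training-domain ceiling (the model is not trained on very
#' large ions).
#'
#' @param graph A \code{\link{build_graph}} result.
#' @param adduct Adduct label.
#' @param params Trained \code{\link{init_params}}-shaped parameters.
#' @param config The matching \code{\link{model_config}}.
#' @param mask Optional character vector of attribute blocks to zero out at
#'   inference (on the standardised scale).
#' @return Nonnegative CCS prediction in Angstrom^2.
#' @export
predict_ccs <- function(graph, adduct, params, config, mask = NULL) {
  pred <- .forward_graph(graph, adduct, params, config, mask)$pred
  if (pred >= config$domain_ceiling) {
    warning(sprintf(
      "prediction %.1f A^2 is at/above the training-domain ceiling (%g A^2)",
      pred, config$domain_ceiling))
  }
  pred
}

# ---- Checkpoint I/O --------------------------------------------------------

.CHECKPOINT_SCHEMA <- 1L

.pack <- function(x) {
  if (is.list(x)) return(lapply(x, .pack))
  if (is.matrix(x)) return(list(.dim = dim(x), .data = as.numeric(x)))
  x
}

.unpack <- function(x) {
  if (is.list(x)) {
    if (!is.null(x$.dim)) {
      return(matrix(as.numeric(unlist(x$.data)),
                    x$.dim[[1]], x$.dim[[2]]))
    }
    return(lapply(x, .unpack))
  }
  x
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding \code{config.json},
#' \code{weights.json} (all weight arrays plus feature-standardisation
#' statistics, full precision) and \code{MANIFEST.json} with an md5
#' checksum of the weight file and a schema version. Loading verifies the
#' checksum and the schema; predictions after a round trip agree with the
#' original to well within 1e-7.
#'
#' @param params,config Model parameters and configuration (or a fitted
#'   \code{ccs_model} as the first argument, in which case \code{config}
#'   is taken from it).
#' @param path Checkpoint directory.
#' @param feat_cfg Featurizer configuration stored alongside the weights.
#' @return \code{save_model}: the path, invisibly. \code{load_model}:
#'   list(params, config, feat_cfg, model) where \code{model} is a ready
#'   \code{ccs_model}.
#' @export
save_model <- function(params, config = NULL, path,
                       feat_cfg = featurizer_config()) {
  if (inherits(params, "ccs_model")) {
    config <- params$config
    feat_cfg <- params$feat_cfg
    params <- params$params
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wfile <- file.path(path, "weights.json")
  cfile <- file.path(path, "config.json")
  jsonlite::write_json(.pack(unclass(params)), wfile,
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(model = unclass(config),
                            featurizer = unclass(feat_cfg)),
                       cfile, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(schema_version = .CHECKPOINT_SCHEMA,
         weights_md5 = unname(tools::md5sum(wfile))),
    file.path(path, "MANIFEST.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mfile <- file.path(path, "MANIFEST.json")
  wfile <- file.path(path, "weights.json")
  cfile <- file.path(path, "config.json")
  if (!file.exists(mfile) || !file.exists(wfile) || !file.exists(cfile)) {
    stop(errorCondition(
      sprintf("checkpoint at '%s' is missing files", path),
      class = c("graphccs_checksum_error", "graphccs_error")))
  }
  manifest <- jsonlite::read_json(mfile)
  if (is.null(manifest$schema_version) ||
      manifest$schema_version != .CHECKPOINT_SCHEMA) {
    stop(errorCondition(
      sprintf("checkpoint schema %s does not match supported schema %d",
              manifest$schema_version, .CHECKPOINT_SCHEMA),
      class = c("graphccs_version_error", "graphccs_error")))
  }
  if (unname(tools::md5sum(wfile)) != manifest$weights_md5) {
    stop(errorCondition("checkpoint weight file is corrupted (md5 mismatch)",
                        class = c("graphccs_checksum_error", "graphccs_error")))
  }
  raw <- jsonlite::read_json(wfile, simplifyVector = TRUE,
                             simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  params <- .unpack(raw)
  for (nm in c("ecc", "fc")) params[[nm]] <- lapply(params[[nm]], identity)
  if (!is.null(params$feat_stats)) {
    params$feat_stats$cols <- as.integer(unlist(params$feat_stats$cols))
    params$feat_stats$mean <- as.numeric(unlist(params$feat_stats$mean))
    params$feat_stats$sd <- as.numeric(unlist(params$feat_stats$sd))
  }
  for (l in seq_along(params$ecc)) {
    params$ecc[[l]]$b <- as.numeric(unlist(params$ecc[[l]]$b))
    params$ecc[[l]]$mlp$b1 <- as.numeric(unlist(params$ecc[[l]]$mlp$b1))
    params$ecc[[l]]$mlp$b2 <- as.numeric(unlist(params$ecc[[l]]$mlp$b2))
  }
  for (k in seq_along(params$fc)) {
    params$fc[[k]]$b <- as.numeric(unlist(params$fc[[k]]$b))
  }
  params$out$b <- as.numeric(unlist(params$out$b))
  params$input_dim <- as.integer(params$input_dim)
  class(params) <- "model_params"
  both <- jsonlite::read_json(cfile, simplifyVector = TRUE)
  cfg <- both$model
  cfg$ecc_widths <- as.numeric(cfg$ecc_widths)
  cfg$fc_widths <- as.numeric(cfg$fc_widths)
  class(cfg) <- "model_config"
  fc <- both$featurizer
  feat_cfg <- if (is.null(fc)) featurizer_config() else
    featurizer_config(element_vocabulary = as.character(fc$element_vocabulary),
                      include = unlist(fc$include),
                      coord_centering = isTRUE(fc$coord_centering))
  list(params = params, config = cfg, feat_cfg = feat_cfg,
       model = as_ccs_model(params, cfg, feat_cfg))
}

#' Assemble a usable model from parameters and configurations
#'
#' @param params,config,feat_cfg Components as produced by
#'   \code{\link{fit}} or \code{\link{load_model}}.
#' @return A \code{ccs_model}.
#' @export
as_ccs_model <- function(params, config, feat_cfg = featurizer_config()) {
  structure(list(params = params, config = config, feat_cfg = feat_cfg,
                 log = NULL, best_epoch = NA_integer_),
            class = "ccs_model")
}
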