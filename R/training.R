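# Dataset curation, splitting, model fitting (manual backpropagation +
# Adam on sparse disjoint-union batches) and evaluation metrics.

# ---- Dataset container -----------------------------------------------------

#' Bundle CCS records with their parsed molecules
#'
#' @param records data.frame of records (see \code{\link{read_records}}).
#' @param molecules Named list of \code{ccs_molecule} keyed by canonical
#'   SMILES; parsed (and embedded, if absent) on demand.
#' @param embed Embed missing conformers now (batch call).
#' @param seed Seed forwarded to conformer generation.
#' @return A \code{ccs_dataset}: list(records, molecules).
#' @export
ccs_dataset <- function(records, molecules = NULL, embed = TRUE, seed = 1L) {
  if (inherits(records, "ccs_dataset")) return(records)
  smis <- unique(records$smiles)
  if (is.null(molecules)) molecules <- list()
  missing <- setdiff(smis, names(molecules))
  if (length(missing)) {
    parsed <- lapply(missing, function(s)
      tryCatch(parse_molecule(s), graphccs_error = function(e) NULL))
    names(parsed) <- missing
    ok <- !vapply(parsed, is.null, logical(1))
    if (!all(ok)) {
      stop(errorCondition(
        sprintf("unparsable SMILES in dataset (run curate() first): %s",
                paste(utils::head(missing[!ok], 3), collapse = ", ")),
        class = c("graphccs_invalid_smiles", "graphccs_error")))
    }
    molecules <- c(molecules, parsed)
  }
  # re-key records by canonical SMILES so molecule lookup is stable
  canon <- vapply(molecules, `[[`, "", "smiles")
  records$smiles <- unname(canon[match(records$smiles, names(molecules))])
  names(molecules) <- canon
  molecules <- molecules[!duplicated(names(molecules))]
  if (embed) {
    need <- vapply(molecules, function(m) is.null(m$conformer), logical(1))
    if (any(need)) {
      molecules[need] <- embed_molecules(molecules[need], seed = seed)
      still <- vapply(molecules, function(m) is.null(m$conformer), logical(1))
      if (any(still)) {
        stop(errorCondition(
          sprintf("conformer generation failed for: %s",
                  paste(utils::head(names(molecules)[still], 3),
                        collapse = ", ")),
          class = c("graphccs_embedding_failed", "graphccs_error")))
      }
    }
  }
  structure(list(records = records, molecules = molecules),
            class = "ccs_dataset")
}

#' @export
print.ccs_dataset <- function(x, ...) {
  cat(sprintf("<ccs_dataset> %d records, %d molecules (%d with CCS labels)\n",
              nrow(x$records), length(x$molecules), sum(!is.na(x$records$ccs))))
  invisible(x)
}

.neutral_mass <- function(mol) sum(mol$atoms$mass)

# Ensure the full record column set exists (missing optional columns are
# filled with NA) so downstream code can index them unconditionally.
.normalize_records <- function(records) {
  n <- nrow(records)
  if (!"identifier" %in% names(records)) {
    records$identifier <- sprintf("rec_%05d", seq_len(n))
  }
  for (col in c("ccs", "mz", "rt")) {
    if (!col %in% names(records)) records[[col]] <- rep(NA_real_, n)
  }
  if (!"instrument" %in% names(records)) {
    records$instrument <- rep("unknown", n)
  }
  records
}

.fill_mz <- function(records, molecules) {
  need <- is.na(records$mz)
  if (any(need)) {
    mass <- vapply(molecules[records$smiles[need]], .neutral_mass, numeric(1))
    records$mz[need] <- mass + adduct_mass_shift(records$adduct[need])
  }
  records
}

# ---- Curation --------------------------------------------------------------

#' Five-step dataset curation
#'
#' Cleans a raw record table in five ordered steps: (1) SMILES verification
#' (unparsable strings and unsupported elements dropped); (2) adduct type
#' selection (only \code{[M+H]+}, \code{[M+Na]+}, \code{[M-H]-} kept);
#' (3) duplicate (molecule, adduct) entries collapsed to their median CCS;
#' (4) molecules whose 3D conformer generation or force-field minimisation
#' fails dropped; (5) outlier removal — records whose CCS deviates from a
#' robust per-adduct linear CCS~m/z trend (MASS::rlm) by more than
#' \code{k_mad} times the MAD of the residuals are dropped. Every removal
#' is reason-coded in the report; nothing errors.
#'
#' @param records Raw record data.frame.
#' @param seed Seed for conformer generation.
#' @param k_mad Outlier threshold in residual MADs (default 5).
#' @param min_group Minimum per-adduct group size for the outlier fit.
#' @return A \code{ccs_dataset} with a \code{report} element
#'   (\code{curation_report}: per-step survivor counts and the reason-coded
#'   drop list).
#' @export
curate <- function(records, seed = 1L, k_mad = 5, min_group = 8) {
  if (inherits(records, "ccs_dataset")) records <- records$records
  records <- .normalize_records(records)
  steps <- c(initial = nrow(records))
  dropped <- list()
  note_drop <- function(rec, reason, step) {
    if (nrow(rec) == 0) return()
    dropped[[length(dropped) + 1]] <<- data.frame(
      identifier = rec$identifier, smiles = rec$smiles,
      adduct = rec$adduct, reason = reason, step = step,
      stringsAsFactors = FALSE)
  }

  # step 1: SMILES verification
  molecules <- list()
  if (nrow(records)) {
    usmi <- unique(records$smiles)
    parsed <- lapply(usmi, function(s)
      tryCatch(parse_molecule(s), graphccs_error = function(e) NULL))
    names(parsed) <- usmi
    bad <- names(parsed)[vapply(parsed, is.null, logical(1))]
    note_drop(records[records$smiles %in% bad, , drop = FALSE],
              "invalid_smiles", 1L)
    records <- records[!records$smiles %in% bad, , drop = FALSE]
    molecules <- parsed[!vapply(parsed, is.null, logical(1))]
  }
  steps["smiles_verified"] <- nrow(records)

  # step 2: adduct type selection
  if (nrow(records)) {
    norm <- vapply(records$adduct, function(a) {
      out <- try(normalize_adduct(a), silent = TRUE)
      if (inherits(out, "try-error")) NA_character_ else out
    }, character(1), USE.NAMES = FALSE)
    note_drop(records[is.na(norm), , drop = FALSE], "unsupported_adduct", 2L)
    records <- records[!is.na(norm), , drop = FALSE]
    records$adduct <- norm[!is.na(norm)]
  }
  steps["adduct_selected"] <- nrow(records)

  # step 3: duplicate (molecule, adduct) groups -> median CCS
  if (nrow(records)) {
    canon <- vapply(molecules, `[[`, "", "smiles")
    records$smiles <- unname(canon[match(records$smiles, names(molecules))])
    names(molecules) <- canon
    molecules <- molecules[!duplicated(names(molecules))]
    key <- paste(records$smiles, records$adduct, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      agg <- function(x) if (all(is.na(x))) NA_real_ else
        stats::median(x[!is.na(x)])
      first <- records[!dup, , drop = FALSE]
      first$ccs <- unname(tapply(records$ccs, key, agg)[key[!dup]])
      first$mz <- unname(tapply(records$mz, key, agg)[key[!dup]])
      first$rt <- unname(tapply(records$rt, key, agg)[key[!dup]])
      note_drop(records[dup, , drop = FALSE], "duplicate_collapsed", 3L)
      records <- first
    }
  }
  steps["median_collapsed"] <- nrow(records)

  # step 4: conformer generation
  if (nrow(records)) {
    molecules <- molecules[intersect(names(molecules), records$smiles)]
    molecules <- embed_molecules(molecules, seed = seed, on_failure = "keep")
    failed <- names(molecules)[vapply(molecules, function(m)
      is.null(m$conformer), logical(1))]
    note_drop(records[records$smiles %in% failed, , drop = FALSE],
              "conformer_failed", 4L)
    records <- records[!records$smiles %in% failed, , drop = FALSE]
    molecules <- molecules[setdiff(names(molecules), failed)]
  }
  steps["conformer_ok"] <- nrow(records)

  # step 5: outlier removal on a robust CCS ~ m/z trend per adduct
  if (nrow(records)) {
    records <- .fill_mz(records, molecules)
    keep <- rep(TRUE, nrow(records))
    labelled <- !is.na(records$ccs)
    for (a in unique(records$adduct)) {
      idx <- which(records$adduct == a & labelled)
      if (length(idx) < min_group) next
      fit <- try(suppressWarnings(
        MASS::rlm(ccs ~ mz, data = records[idx, ], maxit = 50)),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      res <- stats::residuals(fit)
      s <- stats::mad(res)
      if (!is.finite(s) || s <= 0) next
      keep[idx[abs(res) > k_mad * s]] <- FALSE
    }
    note_drop(records[!keep, , drop = FALSE], "outlier", 5L)
    records <- records[keep, , drop = FALSE]
    molecules <- molecules[intersect(names(molecules), records$smiles)]
  }
  steps["outlier_removed"] <- nrow(records)

  report <- structure(
    list(steps = steps,
         dropped = if (length(dropped)) do.call(rbind, dropped) else
           data.frame(identifier = character(0), smiles = character(0),
                      adduct = character(0), reason = character(0),
                      step = integer(0))),
    class = "curation_report")
  out <- ccs_dataset(records, molecules, embed = FALSE)
  out$report <- report
  out
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n")
  for (nm in names(x$steps)) cat(sprintf("  %-18s %d\n", nm, x$steps[[nm]]))
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    cat("  dropped:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- Splitting -------------------------------------------------------------

#' Random dataset split
#'
#' Splits records into named partitions by the given fractions, either at
#' the entry level (default) or at the molecule level, where no canonical
#' SMILES spans two partitions. Deterministic for a fixed seed.
#'
#' @param data A \code{ccs_dataset} or a record data.frame.
#' @param fractions Named numeric vector summing to 1, e.g.
#'   \code{c(train = 0.9, test = 0.1)}.
#' @param seed Integer seed.
#' @param level \code{"entry"} or \code{"molecule"}.
#' @return Named list of partitions, same type as the input.
#' @export
split_records <- function(data, fractions = c(train = 0.9, test = 0.1),
                          seed = 1L, level = c("entry", "molecule")) {
  level <- match.arg(level)
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    stop(errorCondition("fractions must be nonnegative and sum to 1",
                        class = c("graphccs_value_error", "graphccs_error")))
  }
  is_ds <- inherits(data, "ccs_dataset")
  records <- if (is_ds) data$records else data
  assign_groups <- function(n) {
    sizes <- floor(fractions * n)
    rem <- n - sum(sizes)
    if (rem > 0) {
      extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1
    }
    rep(seq_along(fractions), sizes)
  }
  if (level == "entry") {
    ord <- with_local_seed(seed, sample.int(nrow(records)))
    grp <- integer(nrow(records))
    grp[ord] <- assign_groups(nrow(records))
  } else {
    mols <- unique(records$smiles)
    ordm <- with_local_seed(seed, sample.int(length(mols)))
    mgrp <- integer(length(mols))
    mgrp[ordm] <- assign_groups(length(mols))
    grp <- mgrp[match(records$smiles, mols)]
  }
  out <- lapply(seq_along(fractions), function(k) {
    rec <- records[grp == k, , drop = FALSE]
    if (is_ds) {
      ccs_dataset(rec,
                  data$molecules[intersect(names(data$molecules),
                                           rec$smiles)],
                  embed = FALSE)
    } else rec
  })
  stats::setNames(out, names(fractions))
}

# ---- Metrics ---------------------------------------------------------------

#' Regression metrics for CCS prediction
#'
#' R^2 = 1 - SS_res/SS_tot; Median RE = median of |pred - obs|/obs x 100;
#' RMSE in the units of the observations (Angstrom^2).
#'
#' @param obs,pred Observed and predicted CCS vectors.
#' @return list(r2, median_re, rmse).
#' @export
ccs_metrics <- function(obs, pred) {
  if (length(obs) == 0 || length(obs) != length(pred)) {
    stop(errorCondition("need matching, nonempty obs/pred vectors",
                        class = c("graphccs_empty_evaluation",
                                  "graphccs_error")))
  }
  ss_res <- sum((pred - obs)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  list(r2 = 1 - ss_res / ss_tot,
       median_re = stats::median(abs(pred - obs) / obs) * 100,
       rmse = sqrt(mean((pred - obs)^2)))
}

# ---- Batched forward / backward --------------------------------------------

# Disjoint-union batch of molecular graphs: all node features stacked, one
# sparse adjacency per bond type, sparse pooling (molecule x node) and
# record-expansion (record x molecule) operators.
.build_batch <- function(records, graphs) {
  smis <- names(graphs)
  mol_of_rec <- match(records$smiles, smis)
  used <- sort(unique(mol_of_rec))
  graphs <- graphs[used]
  mol_of_rec <- match(mol_of_rec, used)
  nmol <- length(graphs)
  nn <- vapply(graphs, function(g) nrow(g$X), integer(1))
  offset <- cumsum(c(0L, nn[-nmol]))
  X <- do.call(rbind, lapply(graphs, `[[`, "X"))
  ntot <- nrow(X)
  S <- vector("list", 4)
  for (t in 1:4) {
    ii <- integer(0); jj <- integer(0)
    for (g in seq_len(nmol)) {
      sel <- graphs[[g]]$E[, t] == 1
      if (any(sel)) {
        ii <- c(ii, graphs[[g]]$edge_index[sel, 1] + offset[g])
        jj <- c(jj, graphs[[g]]$edge_index[sel, 2] + offset[g])
      }
    }
    S[[t]] <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                                   dims = c(ntot, ntot))
  }
  P <- Matrix::sparseMatrix(i = rep(seq_len(nmol), nn),
                            j = seq_len(ntot), x = 1,
                            dims = c(nmol, ntot))
  R <- Matrix::sparseMatrix(i = seq_along(mol_of_rec), j = mol_of_rec, x = 1,
                            dims = c(length(mol_of_rec), nmol))
  Arec <- t(vapply(records$adduct, adduct_code, numeric(3)))
  list(X = X, S = S, P = P, R = R, Arec = Arec,
       y = records$ccs, blocks = graphs[[1]]$blocks,
       n_rec = nrow(records))
}

.batch_forward <- function(batch, params, config, mask = NULL,
                           keep_cache = FALSE) {
  X <- .prep_X(batch$X, params, batch$blocks, mask)
  L <- config$n_ecc_layers
  cache <- if (keep_cache) list(Xin = vector("list", L),
                                Z = vector("list", L),
                                TH = vector("list", L)) else NULL
  for (l in seq_len(L)) {
    pl <- params$ecc[[l]]
    TH <- .edge_filters(pl$mlp, nrow(pl$W), ncol(pl$W))
    Z <- X %*% pl$W
    for (t in 1:4) {
      if (length(batch$S[[t]]@x)) {
        Z <- Z + as.matrix(batch$S[[t]] %*% (X %*% TH[[t]]))
      }
    }
    Z <- sweep(Z, 2, pl$b, `+`)
    if (keep_cache) {
      cache$Xin[[l]] <- X; cache$Z[[l]] <- Z; cache$TH[[l]] <- TH
    }
    X <- .relu(Z)
  }
  pmat <- as.matrix(batch$P %*% X)
  M <- cbind(as.matrix(batch$R %*% pmat), batch$Arec)
  K <- config$n_fc_layers
  H <- M
  Zfc <- if (keep_cache) vector("list", K + 1) else NULL
  Hs <- if (keep_cache) vector("list", K + 1) else NULL
  for (k in seq_len(K)) {
    if (keep_cache) Hs[[k]] <- H
    Zk <- sweep(H %*% params$fc[[k]]$W, 2, params$fc[[k]]$b, `+`)
    if (keep_cache) Zfc[[k]] <- Zk
    H <- .relu(Zk)
  }
  if (keep_cache) Hs[[K + 1]] <- H
  Zo <- sweep(H %*% params$out$W, 2, params$out$b, `+`)
  pred <- as.numeric(.relu(Zo))
  if (keep_cache) {
    cache$XL <- X; cache$Zfc <- Zfc; cache$Hs <- Hs; cache$Zo <- Zo
  }
  list(pred = pred, p = pmat, cache = cache)
}

.batch_backward <- function(batch, params, config, fwd) {
  cache <- fwd$cache
  n <- batch$n_rec
  y <- batch$y
  dZo <- matrix((2 / n) * (fwd$pred - y) * (cache$Zo > 0), ncol = 1)
  K <- config$n_fc_layers
  l2 <- config$l2
  g <- list(ecc = vector("list", config$n_ecc_layers),
            fc = vector("list", K),
            out = list(W = crossprod(cache$Hs[[K + 1]], dZo),
                       b = sum(dZo)))
  dH <- dZo %*% t(params$out$W)
  for (k in rev(seq_len(K))) {
    dZ <- dH * (cache$Zfc[[k]] > 0)
    g$fc[[k]] <- list(W = crossprod(cache$Hs[[k]], dZ) +
                        2 * l2 * params$fc[[k]]$W,
                      b = colSums(dZ))
    dH <- dZ %*% t(params$fc[[k]]$W)
  }
  Fdim <- ncol(fwd$p)
  dprec <- dH[, seq_len(Fdim), drop = FALSE]
  dp <- as.matrix(Matrix::crossprod(batch$R, dprec))
  dX <- as.matrix(Matrix::crossprod(batch$P, dp))
  for (l in rev(seq_len(config$n_ecc_layers))) {
    pl <- params$ecc[[l]]
    dZ <- dX * (cache$Z[[l]] > 0)
    Xin <- cache$Xin[[l]]
    gW <- crossprod(Xin, dZ) + 2 * l2 * pl$W
    gb <- colSums(dZ)
    fin <- nrow(pl$W); fout <- ncol(pl$W)
    hidden <- length(pl$mlp$b1)
    gW1 <- 2 * l2 * pl$mlp$W1
    gb1 <- numeric(hidden)
    gW2 <- 2 * l2 * pl$mlp$W2
    gb2 <- numeric(fin * fout)
    dXnew <- dZ %*% t(pl$W)
    for (t in 1:4) {
      if (!length(batch$S[[t]]@x)) next
      SdZ <- as.matrix(batch$S[[t]] %*% dZ)        # S symmetric
      Gt <- crossprod(Xin, SdZ)                    # fin x fout
      dXnew <- dXnew + SdZ %*% t(cache$TH[[l]][[t]])
      gt <- as.numeric(Gt)
      u <- pl$mlp$W1[t, ] + pl$mlp$b1
      h <- .relu(u)
      gW2 <- gW2 + outer(h, gt)
      gb2 <- gb2 + gt
      dh <- as.numeric(pl$mlp$W2 %*% gt)
      du <- dh * (u > 0)
      gW1[t, ] <- gW1[t, ] + du
      gb1 <- gb1 + du
    }
    g$ecc[[l]] <- list(W = gW, b = gb,
                       mlp = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
    dX <- dXnew
  }
  g
}

# Recursive Adam over nested parameter lists (numeric leaves).
.adam_init <- function(p) {
  if (is.list(p)) return(lapply(p, .adam_init))
  array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
}

.adam_step <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  if (is.list(p)) {
    out <- list(p = p, m = m, v = v)
    for (nm in names(p)) {
      r <- .adam_step(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, beta1,
                      beta2, eps)
      out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
    }
    return(out)
  }
  m <- beta1 * m + (1 - beta1) * as.numeric(g)
  v <- beta2 * v + (1 - beta2) * as.numeric(g)^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  upd <- p - lr * array(mhat / (sqrt(vhat) + eps),
                        dim = if (is.null(dim(p))) length(p) else dim(p))
  list(p = upd, m = m, v = v)
}

# ---- Fitting ---------------------------------------------------------------

.build_graphs <- function(data, feat_cfg) {
  graphs <- lapply(data$molecules, build_graph, cfg = feat_cfg)
  names(graphs) <- names(data$molecules)
  graphs
}

.feat_stats_from <- function(X, feat_cfg) {
  blocks <- feature_blocks(feat_cfg)
  cols <- unlist(blocks[intersect(c("radius", "mass", "coords"),
                                  names(blocks))], use.names = FALSE)
  mu <- colMeans(X[, cols, drop = FALSE])
  sd <- apply(X[, cols, drop = FALSE], 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(cols = as.integer(cols), mean = unname(mu), sd = unname(sd))
}

#' Fit the CCS model
#'
#' Minimises the mean squared error with Adam on minibatches of
#' disjoint-union graph batches, with L2 regularisation on ECC and FC
#' weights. Training tracks the validation MSE every epoch, keeps the
#' best-validation parameters and stops early after \code{config$patience}
#' epochs without improvement. All randomness (initialisation, shuffling)
#' derives from \code{config$seed}.
#'
#' @param train,validation \code{ccs_dataset}s with CCS labels
#'   (\code{validation} may be NULL: the last 10\% of a seeded shuffle of
#'   the training records is then held out).
#' @param config A \code{\link{model_config}}.
#' @param feat_cfg A \code{\link{featurizer_config}}.
#' @param verbose Print a progress line every 25 epochs.
#' @return A \code{ccs_model}: list(params, config, feat_cfg, log,
#'   best_epoch); \code{log} holds per-epoch train/validation MSE.
#' @export
fit <- function(train, validation = NULL, config = model_config(),
                feat_cfg = featurizer_config(), verbose = FALSE) {
  train <- ccs_dataset(train)
  if (is.null(validation)) {
    parts <- split_records(train, c(tr = 0.9, val = 0.1),
                           seed = config$seed)
    train <- parts$tr; validation <- parts$val
  }
  validation <- ccs_dataset(validation)
  n_restarts <- max(1L, config$n_restarts %||% 1L)
  best <- NULL
  for (k in seq_len(n_restarts)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + (k - 1L)
    m <- .fit_once(train, validation, cfg_k, feat_cfg, verbose)
    if (is.null(best) ||
        min(m$log$val_loss) < min(best$log$val_loss)) {
      best <- m
    }
    if (verbose && n_restarts > 1) {
      message(sprintf("restart %d/%d: best val MSE %.4f", k, n_restarts,
                      min(m$log$val_loss)))
    }
  }
  best$config <- config
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fit_once <- function(train, validation, config, feat_cfg, verbose) {
  tr_rec <- train$records[!is.na(train$records$ccs), , drop = FALSE]
  va_rec <- validation$records[!is.na(validation$records$ccs), , drop = FALSE]
  if (nrow(tr_rec) == 0) {
    stop(errorCondition("no labelled training records",
                        class = c("graphccs_empty_evaluation",
                                  "graphccs_error")))
  }
  graphs_tr <- .build_graphs(train, feat_cfg)
  graphs_va <- .build_graphs(validation, feat_cfg)
  input_dim <- ncol(graphs_tr[[1]]$X)
  params <- init_params(config, input_dim, seed = config$seed)
  if (config$standardize) {
    Xall <- do.call(rbind, lapply(graphs_tr, `[[`, "X"))
    params$feat_stats <- .feat_stats_from(Xall, feat_cfg)
  }
  # start the output unit at the mean target so the ReLU output is active
  params$out$b <- mean(tr_rec$ccs)

  batches <- with_local_seed(config$seed + 1L, {
    ord <- sample.int(nrow(tr_rec))
    nb <- max(1L, ceiling(nrow(tr_rec) / config$batch_size))
    idx <- split(ord, rep(seq_len(nb), length.out = nrow(tr_rec),
                          each = config$batch_size)[seq_len(nrow(tr_rec))])
    lapply(idx, function(ii) .build_batch(tr_rec[ii, , drop = FALSE],
                                          graphs_tr))
  })
  val_batch <- .build_batch(va_rec, graphs_va)

  trainable <- params[c("ecc", "fc", "out")]
  m_state <- .adam_init(trainable)
  v_state <- .adam_init(trainable)
  best <- list(val = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  t_adam <- 0L
  for (epoch in seq_len(config$epochs)) {
    tr_loss <- 0
    for (b in batches) {
      fwd <- .batch_forward(b, params, config, keep_cache = TRUE)
      mse <- mean((fwd$pred - b$y)^2)
      if (!is.finite(mse)) {
        stop(errorCondition(
          sprintf("training diverged at epoch %d (non-finite loss)", epoch),
          class = c("graphccs_divergence", "graphccs_error")))
      }
      tr_loss <- tr_loss + mse * b$n_rec
      grads <- .batch_backward(b, params, config, fwd)
      t_adam <- t_adam + 1L
      lr <- config$learning_rate
      if (!is.null(config$lr_decay_every) && config$lr_decay_every > 0) {
        lr <- lr * config$lr_decay^((epoch - 1) %/% config$lr_decay_every)
      }
      upd <- .adam_step(params[c("ecc", "fc", "out")], grads, m_state,
                        v_state, lr, t_adam)
      params$ecc <- upd$p$ecc; params$fc <- upd$p$fc; params$out <- upd$p$out
      m_state <- upd$m; v_state <- upd$v
    }
    tr_loss <- tr_loss / nrow(tr_rec)
    val_pred <- .batch_forward(val_batch, params, config)$pred
    val_loss <- mean((val_pred - val_batch$y)^2)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                 val_loss = val_loss))
    if (val_loss < best$val - 1e-12) {
      best <- list(val = val_loss, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
    if (verbose && epoch %% 25 == 0) {
      message(sprintf("epoch %4d  train MSE %.3f  val MSE %.3f",
                      epoch, tr_loss, val_loss))
    }
  }
  structure(list(params = best$params, config = config,
                 feat_cfg = feat_cfg, log = log, best_epoch = best$epoch),
            class = "ccs_model")
}

#' @export
print.ccs_model <- function(x, ...) {
  cat(sprintf(
    "<ccs_model> %d ECC layers (widths %s), %d FC layers; best epoch %d (val MSE %.3f)\n",
    x$config$n_ecc_layers, paste(x$config$ecc_widths, collapse = "/"),
    x$config$n_fc_layers, x$best_epoch,
    x$log$val_loss[x$log$epoch == x$best_epoch]))
  invisible(x)
}

#' Predict CCS for every record of a dataset
#'
#' @param model A \code{ccs_model} (from \code{\link{fit}} or rebuilt from
#'   a checkpoint).
#' @param data A \code{ccs_dataset} or record data.frame.
#' @param mask Optional attribute blocks to zero at inference.
#' @return The record data.frame with a \code{ccs_pred} column and an
#'   \code{above_ceiling} flag.
#' @export
predict_records <- function(model, data, mask = NULL) {
  data <- ccs_dataset(data)
  if (nrow(data$records) == 0) {
    out <- data$records
    out$ccs_pred <- numeric(0)
    out$above_ceiling <- logical(0)
    return(out)
  }
  graphs <- .build_graphs(data, model$feat_cfg)
  batch <- .build_batch(data$records, graphs)
  pred <- .batch_forward(batch, model$params, model$config, mask = mask)$pred
  out <- data$records
  out$ccs_pred <- pred
  out$above_ceiling <- pred >= model$config$domain_ceiling
  out
}

#' Evaluate a model on labelled records
#'
#' @inheritParams predict_records
#' @return list(metrics = \code{\link{ccs_metrics}} result,
#'   predictions = record data.frame with \code{ccs_pred}).
#' @export
evaluate <- function(model, data, mask = NULL) {
  data <- ccs_dataset(data)
  rec <- data$records[!is.na(data$records$ccs), , drop = FALSE]
  if (nrow(rec) == 0) {
    stop(errorCondition("no labelled records to evaluate",
                        class = c("graphccs_empty_evaluation",
                                  "graphccs_error")))
  }
  preds <- predict_records(model,
                           ccs_dataset(rec, data$molecules, embed = FALSE),
                           mask = mask)
  list(metrics = ccs_metrics(preds$ccs, preds$ccs_pred), predictions = preds)
}
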