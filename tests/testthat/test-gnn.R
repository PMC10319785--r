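# Network math: ECC layer, pooling, adduct fusion, forward pass,
# checkpoints, and gradient correctness.

test_that("ECC with zero filters and identity root is the identity", {
  X <- matrix(rnorm(12), 4, 3)
  g <- fx_random_graph(4, 3)
  params <- list(W = diag(3), b = numeric(3),
                 mlp = list(W1 = matrix(0, 4, 2), b1 = numeric(2),
                            W2 = matrix(0, 2, 9), b2 = numeric(9)))
  out <- ecc_forward(X, g$E, g$edge_index, params, activation = FALSE)
  expect_equal(out, X)
})

test_that("ECC on a path graph reproduces hand-computed message passing", {
  # path 1-2-3, scalar features (1,2,3), W=0, b=0, MLP == 1:
  # pre-activation output is the neighbour sum (2, 4, 2)
  X <- matrix(c(1, 2, 3), 3, 1)
  edge_index <- rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L))
  E <- matrix(0, 4, 4); E[, 1] <- 1
  params <- list(W = matrix(0, 1, 1), b = 0,
                 mlp = list(W1 = matrix(0, 4, 1), b1 = 1,
                            W2 = matrix(1, 1, 1), b2 = 0))
  out <- ecc_forward(X, E, edge_index, params, activation = FALSE)
  expect_equal(as.numeric(out), c(2, 4, 2))
})

test_that("ECC matches the brute-force double-loop reference", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    fin <- sample(2:5, 1); fout <- sample(2:5, 1)
    g <- fx_random_graph(n, fin)
    params <- ecc_layer_params(fin, fout, hidden = 6)
    fast <- ecc_forward(g$X, g$E, g$edge_index, params, activation = FALSE)
    slow <- brute_force_ecc(g$X, g$E, g$edge_index, params)
    expect_equal(fast, slow, tolerance = 1e-10)
  }
})

test_that("global sum pooling sums across the node dimension", {
  expect_equal(global_sum_pool(matrix(c(1, 3, 2, 4), 2, 2)), c(4, 6))
  expect_equal(global_sum_pool(matrix(c(5, 7), 1, 2)), c(5, 7))
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(global_sum_pool(X), global_sum_pool(X[sample(10), ]))
  expect_error(global_sum_pool(matrix(0, 0, 3)),
               class = "graphccs_empty_graph")
})

test_that("adduct fusion appends the exact one-hot codes", {
  expect_equal(adduct_code("[M+H]+"), c(1, 0, 0))
  expect_equal(adduct_code("[M+Na]+"), c(0, 1, 0))
  expect_equal(adduct_code("[M-H]-"), c(0, 0, 1))
  p <- seq_len(16)
  m <- fuse_adduct(p, "[M+H]+")
  expect_length(m, 19)
  expect_equal(tail(m, 3), c(1, 0, 0))
  expect_equal(tail(fuse_adduct(p, "[M-H]-"), 3), c(0, 0, 1))
  expect_error(fuse_adduct(p, "[M+K]+"), class = "graphccs_unknown_adduct")
})

test_that("prediction is deterministic, nonnegative, zero for zero weights", {
  m <- embed_molecule(parse_molecule("CCO"))
  g <- build_graph(m)
  cfg <- scaled_model_config()
  params <- init_params(cfg, ncol(g$X), seed = 3)
  p1 <- predict_ccs(g, "[M+H]+", params, cfg)
  p2 <- predict_ccs(g, "[M+H]+", params, cfg)
  expect_identical(p1, p2)
  expect_gte(p1, 0)

  zero <- rapply(params, function(x) x * 0, how = "replace",
                 classes = c("matrix", "numeric", "integer"))
  class(zero) <- "model_params"
  expect_equal(predict_ccs(g, "[M+H]+", zero, cfg), 0)

  big <- params; big$out$b <- 500
  expect_warning(predict_ccs(g, "[M+H]+", big, cfg), "ceiling")
})

test_that("full forward matches an independent straight-line reimplementation", {
  m <- embed_molecule(parse_molecule("CC(C)O"))
  g <- build_graph(m)
  cfg <- scaled_model_config()
  params <- init_params(cfg, ncol(g$X), seed = 11)
  got <- predict_ccs(g, "[M+Na]+", params, cfg)

  X <- g$X
  for (l in seq_along(params$ecc)) {
    X <- pmax(brute_force_ecc(X, g$E, g$edge_index, params$ecc[[l]]), 0)
  }
  h <- c(colSums(X), 0, 1, 0)
  for (k in seq_along(params$fc)) {
    h <- pmax(as.numeric(h %*% params$fc[[k]]$W) + params$fc[[k]]$b, 0)
  }
  want <- max(as.numeric(h %*% params$out$W) + params$out$b, 0)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("pooled representation is invariant to node relabelling,
           node outputs permute consistently", {
  cfg <- scaled_model_config()
  mols <- fx_dataset()$molecules[1:10]
  g0 <- build_graph(mols[[1]])
  params <- init_params(cfg, ncol(g0$X), seed = 21)
  for (m in mols) {
    g <- build_graph(m)
    perm <- sample(nrow(m$atoms))
    gp <- build_graph(permute_molecule(m, perm))
    out <- ecc_forward(g$X, g$E, g$edge_index, params$ecc[[1]])
    outp <- ecc_forward(gp$X, gp$E, gp$edge_index, params$ecc[[1]])
    expect_equal(outp, out[perm, , drop = FALSE], tolerance = 1e-10)
    p1 <- predict_ccs(g, "[M+H]+", params, cfg)
    p2 <- predict_ccs(gp, "[M+H]+", params, cfg)
    expect_equal(p1, p2, tolerance = 1e-9)
  }
})

test_that("prediction is continuous in the coordinates", {
  m <- embed_molecule(parse_molecule("CCCCO"))
  cfg <- scaled_model_config()
  g <- build_graph(m)
  params <- init_params(cfg, ncol(g$X), seed = 4)
  base <- predict_ccs(g, "[M+H]+", params, cfg)
  conf2 <- unclass(m$conformer) + 1e-6
  g2 <- build_graph(m, conf = conf2)
  expect_lt(abs(predict_ccs(g2, "[M+H]+", params, cfg) - base), 1e-3)
})

test_that("batched forward equals per-graph forward", {
  ds <- fx_dataset()
  sub <- ds$records[1:12, ]
  mols <- ds$molecules[unique(sub$smiles)]
  cfg <- scaled_model_config()
  graphs <- lapply(mols, build_graph)
  params <- init_params(cfg, ncol(graphs[[1]]$X), seed = 8)
  batch <- graphccs:::.build_batch(sub, graphs)
  bp <- graphccs:::.batch_forward(batch, params, cfg)$pred
  single <- vapply(seq_len(nrow(sub)), function(i) {
    g <- graphs[[sub$smiles[i]]]
    predict_ccs(g, sub$adduct[i], params, cfg)
  }, numeric(1))
  expect_equal(bp, single, tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  ds <- fx_dataset()
  sub <- ds$records[1:9, ]
  sub$ccs <- sub$ccs / 40  # small targets for well-conditioned differences
  mols <- ds$molecules[unique(sub$smiles)]
  cfg <- scaled_model_config(l2 = 1e-3)
  graphs <- lapply(mols, build_graph)
  params <- init_params(cfg, ncol(graphs[[1]]$X), seed = 5)
  params$feat_stats <- graphccs:::.feat_stats_from(
    do.call(rbind, lapply(graphs, `[[`, "X")), featurizer_config())
  params$out$b <- mean(sub$ccs)
  batch <- graphccs:::.build_batch(sub, graphs)
  lossfn <- function(p) {
    fwd <- graphccs:::.batch_forward(batch, p, cfg)
    reg <- 0
    for (l in p$ecc) reg <- reg + sum(l$W^2) + sum(l$mlp$W1^2) +
      sum(l$mlp$W2^2)
    for (l in p$fc) reg <- reg + sum(l$W^2)
    mean((fwd$pred - batch$y)^2) + cfg$l2 * reg
  }
  fwd <- graphccs:::.batch_forward(batch, params, cfg, keep_cache = TRUE)
  g <- graphccs:::.batch_backward(batch, params, cfg, fwd)
  eps <- 1e-5
  set.seed(31)
  getp <- function(x, path) Reduce(`[[`, path, x)
  setp <- function(x, path, val) {
    if (length(path) == 1) { x[[path[[1]]]] <- val; return(x) }
    x[[path[[1]]]] <- setp(x[[path[[1]]]], path[-1], val)
    x
  }
  paths <- list(list("ecc", 1L, "W"), list("ecc", 2L, "W"),
                list("ecc", 1L, "b"), list("ecc", 1L, "mlp", "W1"),
                list("ecc", 2L, "mlp", "W2"), list("ecc", 2L, "mlp", "b1"),
                list("fc", 1L, "W"), list("fc", 2L, "b"), list("out", "W"))
  for (pa in paths) {
    arr <- getp(params, pa); ana <- getp(g, pa)
    for (i in sample(length(arr), min(4, length(arr)))) {
      a1 <- arr; a1[i] <- a1[i] + eps
      a2 <- arr; a2[i] <- a2[i] - eps
      num <- (lossfn(setp(params, pa, a1)) -
              lossfn(setp(params, pa, a2))) / (2 * eps)
      expect_equal(unname(ana[i]), num, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip exactly and detect corruption", {
  mod <- fx_model()
  m <- fx_dataset()$molecules[[3]]
  g <- build_graph(m)
  before <- predict_ccs(g, "[M+Na]+", mod$params, mod$config)
  dir <- tempfile("ckpt")
  save_model(mod$params, mod$config, dir)
  back <- load_model(dir)
  after <- predict_ccs(g, "[M+Na]+", back$params, back$config)
  expect_equal(after, before, tolerance = 1e-7)
  expect_equal(back$config$ecc_widths, mod$config$ecc_widths)
  expect_equal(back$config$learning_rate, mod$config$learning_rate)
  expect_equal(back$config$epochs, mod$config$epochs)

  # corruption and schema failures
  writeLines(c(readLines(file.path(dir, "weights.json")), " "),
             file.path(dir, "weights.json"))
  expect_error(load_model(dir), class = "graphccs_checksum_error")
  save_model(mod$params, mod$config, dir)
  mani <- jsonlite::read_json(file.path(dir, "MANIFEST.json"))
  mani$schema_version <- 99
  jsonlite::write_json(mani, file.path(dir, "MANIFEST.json"),
                       auto_unbox = TRUE)
  expect_error(load_model(dir), class = "graphccs_version_error")
  file.remove(file.path(dir, "weights.json"))
  expect_error(load_model(dir), class = "graphccs_checksum_error")
})
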