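# Curation, splitting, metrics and fitting behaviour.

curation_fixture <- function() {
  data.frame(
    identifier = sprintf("r%02d", 1:10),
    smiles = c("xxBADxx",                         # 1 unparsable
               "CCO", "CCO",                      # 2 unsupported adducts
               "CCC", "CCC", "CCC",               # 3 duplicates of one key
               "CCN", "CC(C)O", "c1ccccc1", "CS"),
    adduct = c("[M+H]+",
               "[M+K]+", "[M+NH4]+",
               "[M+H]+", "[M+H]+", "[M+H]+",
               "[M+H]+", "[M-H]-", "[M+Na]+", "[M+H]+"),
    ccs = c(90, 100, 101, 100, 110, 150, 95, 105, 130, 80),
    stringsAsFactors = FALSE)
}

test_that("curation walks the hand-derived per-step survivor counts", {
  out <- curate(curation_fixture())
  expect_equal(unname(out$report$steps),
               c(10, 9, 7, 5, 5, 5))
  expect_equal(names(out$report$steps),
               c("initial", "smiles_verified", "adduct_selected",
                 "median_collapsed", "conformer_ok", "outlier_removed"))
  # duplicate group {100, 110, 150} collapsed to its median
  ccc <- out$records$ccs[out$records$smiles ==
                           parse_molecule("CCC")$smiles]
  expect_equal(ccc, 110)
  reasons <- table(out$report$dropped$reason)
  expect_equal(as.integer(reasons[c("invalid_smiles", "unsupported_adduct",
                                    "duplicate_collapsed")]),
               c(1L, 2L, 2L))
})

test_that("curation of empty input yields empty output with zero counts", {
  out <- curate(curation_fixture()[0, ])
  expect_equal(nrow(out$records), 0)
  expect_true(all(out$report$steps == 0))
})

test_that("curation is idempotent on the fixture", {
  once <- curate(curation_fixture())
  twice <- curate(once$records)
  expect_equal(twice$records$ccs, once$records$ccs)
  expect_equal(nrow(twice$report$dropped), 0)
})

test_that("entry-level split is seeded, disjoint and exhaustive", {
  rec <- fx_dataset()$records
  s1 <- split_records(rec, c(train = 0.9, test = 0.1), seed = 7)
  s2 <- split_records(rec, c(train = 0.9, test = 0.1), seed = 7)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$train), 108)
  expect_equal(nrow(s1$test), 12)
  expect_length(intersect(s1$train$identifier, s1$test$identifier), 0)
  s3 <- split_records(rec, c(train = 0.9, test = 0.1), seed = 8)
  expect_false(identical(s1$train$identifier, s3$train$identifier))
  expect_error(split_records(rec, c(a = 0.5, b = 0.6)),
               class = "graphccs_value_error")
})

test_that("molecule-level split keeps every SMILES in one partition", {
  s <- split_records(fx_dataset(), c(train = 0.8, test = 0.2),
                     seed = 3, level = "molecule")
  expect_length(intersect(unique(s$train$records$smiles),
                          unique(s$test$records$smiles)), 0)
})

test_that("metrics match a naive reimplementation and the hand cases", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    obs <- runif(n, 50, 300)
    pred <- obs + rnorm(n, 0, 10)
    m <- ccs_metrics(obs, pred)
    expect_equal(m$r2, 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2),
                 tolerance = 1e-12)
    expect_equal(m$median_re,
                 median(abs(pred - obs) / obs) * 100, tolerance = 1e-12)
    expect_equal(m$rmse, sqrt(mean((pred - obs)^2)), tolerance = 1e-12)
  }
  perfect <- ccs_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$median_re, 0)
  expect_equal(perfect$rmse, 0)
  m2 <- ccs_metrics(c(100, 200), c(110, 200))
  expect_equal(m2$median_re, 5)          # REs are 10% and 0%
  expect_equal(m2$rmse, sqrt(50))
  obs <- c(80, 120, 100)
  expect_equal(ccs_metrics(obs, rep(mean(obs), 3))$r2, 0)
  expect_error(ccs_metrics(numeric(0), numeric(0)),
               class = "graphccs_empty_evaluation")
})

test_that("a constant-target toy set is fit essentially exactly", {
  ds <- fx_dataset()
  toy <- ds$records[ds$records$adduct == "[M+H]+", ][1:20, ]
  toy$ccs <- 100
  toyds <- ccs_dataset(toy, ds$molecules, embed = FALSE)
  mod <- fit(toyds, toyds,
             config = scaled_model_config(epochs = 150, patience = 150,
                                          lr_decay_every = 0,
                                          n_restarts = 1, seed = 2))
  final <- tail(mod$log$train_loss, 1)
  expect_lt(final, 1e-2)
  expect_true(all(is.finite(mod$log$train_loss)))
  expect_lte(min(mod$log$val_loss), mod$log$val_loss[1])
})

test_that("training is deterministic for a fixed seed", {
  ds <- fx_dataset()
  sub <- ccs_dataset(ds$records[1:30, ], ds$molecules, embed = FALSE)
  cfg <- scaled_model_config(epochs = 15, patience = 15,
                             lr_decay_every = 0, n_restarts = 1, seed = 9)
  m1 <- fit(sub, sub, config = cfg)
  m2 <- fit(sub, sub, config = cfg)
  expect_equal(tail(m1$log$train_loss, 1), tail(m2$log$train_loss, 1),
               tolerance = 1e-6)
  expect_identical(m1$params$out$W, m2$params$out$W)
})

test_that("evaluate and predict_records agree and flag the ceiling", {
  mod <- fx_model()
  te <- fx_split()$test
  ev <- evaluate(mod, te)
  preds <- predict_records(mod, te)
  expect_equal(ev$predictions$ccs_pred, preds$ccs_pred)
  expect_equal(ev$metrics$rmse,
               sqrt(mean((preds$ccs_pred - preds$ccs)^2)))
  expect_type(preds$above_ceiling, "logical")
})
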