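# Multidimensional m/z -> RT -> CCS candidate filtering and recall@k.

fixture_library <- function() {
  data.frame(
    identifier = c("truth", "iso_far_rt", "iso_far_ccs", "far_mz", "way_off"),
    smiles = "C",  # structures irrelevant for the filter math
    adduct = "[M-H]-",
    mz = c(500.0000, 500.0020, 499.9990, 500.4000, 650.0),
    rt = c(5.00, 7.50, 5.10, 5.00, 1.00),
    ccs = c(210.0, 209.0, 222.0, 210.0, 300.0),
    stringsAsFactors = FALSE)
}

fixture_query <- function() {
  list(mz = 500.0005, rt = 5.05, ccs = 210.5, true_identifier = "truth")
}

test_that("staged filtering shrinks monotonically to the true hit", {
  th <- filter_thresholds(mz_ppm = 10, rt_tol = 0.5, ccs_pct = 3)
  res <- filter_candidates(fixture_query(), fixture_library(), th)
  expect_equal(unname(res$counts), c(3, 2, 1))
  expect_true(res$counts["mlist"] >= res$counts["rlist"])
  expect_true(res$counts["rlist"] >= res$counts["clist"])
  expect_equal(res$candidates$identifier[1], "truth")
  expect_equal(res$candidates$rank, seq_len(nrow(res$candidates)))
  # fused score decreases down the ranking
  expect_true(all(diff(res$candidates$score) <= 1e-12))
})

test_that("degenerate thresholds behave as no-op or exact filters", {
  lib <- fixture_library()
  open <- filter_thresholds(mz_ppm = Inf, rt_tol = Inf, ccs_pct = Inf)
  res <- filter_candidates(fixture_query(), lib, open)
  expect_equal(unname(res$counts["clist"]), nrow(lib))
  closed <- filter_thresholds(mz_ppm = 0, rt_tol = Inf, ccs_pct = Inf)
  res0 <- filter_candidates(fixture_query(), lib, closed)
  expect_equal(unname(res0$counts["mlist"]), 0)
  expect_error(filter_candidates(fixture_query(), lib[0, ]),
               class = "graphccs_empty_library")
})

test_that("recall@k scores the fixtures and is monotone in k", {
  lib <- fixture_library()
  th <- filter_thresholds(mz_ppm = 10, rt_tol = 0.5, ccs_pct = 3)
  q1 <- as.data.frame(fixture_query())
  expect_equal(recall_at_k(q1, lib, th, k = 1), 100)

  # truth outside every window -> recall 0
  q_miss <- q1; q_miss$mz <- 600
  expect_equal(recall_at_k(q_miss, lib, th, k = 5), 0)
  expect_error(recall_at_k(q1[, setdiff(names(q1), "true_identifier")],
                           lib, th, 1),
               class = "graphccs_missing_truth")

  # 10-query fixture with 4 top-1 hits
  set.seed(20)
  lib10 <- data.frame(identifier = sprintf("e%02d", 1:10), smiles = "C",
                      adduct = "[M-H]-", mz = 400 + (1:10) * 10,
                      rt = rep(5, 10), ccs = 200 + (1:10) * 2,
                      stringsAsFactors = FALSE)
  qs <- data.frame(mz = lib10$mz[1:10] + 1e-4, rt = 5, ccs = lib10$ccs,
                   true_identifier = lib10$identifier)
  # sabotage 6 queries so a decoy inside the window outranks the truth
  decoys <- lib10[1:6, ]
  decoys$identifier <- paste0("decoy", 1:6)
  decoys$mz <- decoys$mz + 2e-5
  qs$mz[1:6] <- decoys$mz + 1e-6  # decoy closer in m/z than the truth
  lib16 <- rbind(lib10, decoys)
  r1 <- recall_at_k(qs, lib16, th, k = 1)
  r2 <- recall_at_k(qs, lib16, th, k = 2)
  expect_equal(r1, 40)
  expect_equal(r2, 100)
  expect_true(r2 >= r1)
})

test_that("the CCS stage improves recall on a synthetic identification
           benchmark", {
  ds <- fx_dataset()
  rec <- ds$records[ds$records$adduct == "[M-H]-", ]
  rec$rt <- 2 + 0.05 * (rec$mz - min(rec$mz)) / 2  # synthetic RT model
  n <- nrow(rec)
  lib <- data.frame(identifier = rec$identifier, smiles = rec$smiles,
                    adduct = rec$adduct, mz = rec$mz, rt = rec$rt,
                    ccs = rec$ccs_true, stringsAsFactors = FALSE)
  # decoys: same m/z neighbourhood, similar RT, wrong CCS
  set.seed(8)
  mkdecoys <- function(k) {
    idx <- rep(seq_len(n), k)
    data.frame(identifier = sprintf("decoy_%03d", seq_along(idx)),
               smiles = lib$smiles[idx], adduct = lib$adduct[idx],
               mz = lib$mz[idx] * (1 + runif(length(idx), -4e-6, 4e-6)),
               rt = lib$rt[idx] + rnorm(length(idx), 0, 0.05),
               ccs = lib$ccs[idx] * (1 + sample(c(-1, 1), length(idx),
                                                TRUE) *
                                       runif(length(idx), 0.05, 0.15)),
               stringsAsFactors = FALSE)
  }
  # measured queries: small instrument-like noise on all three dimensions
  queries <- data.frame(mz = rec$mz * (1 + rnorm(n, 0, 3e-6)),
                        rt = rec$rt + rnorm(n, 0, 0.05),
                        ccs = rec$ccs_true * (1 + rnorm(n, 0, 0.005)),
                        true_identifier = rec$identifier)
  for (dens in c(2, 4)) {
    full <- rbind(lib, mkdecoys(dens))
    th_no_ccs <- filter_thresholds(mz_ppm = 10, rt_tol = 0.3,
                                   ccs_pct = Inf)
    th_ccs <- filter_thresholds(mz_ppm = 10, rt_tol = 0.3, ccs_pct = 3)
    r_no <- recall_at_k(queries, full, th_no_ccs, k = 1)
    r_yes <- recall_at_k(queries, full, th_ccs, k = 1)
    expect_gt(r_yes, r_no)
  }
})
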