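# Multidimensional candidate filtering for compound identification:
# m/z window -> retention-time window -> CCS window, then ranking of the
# surviving candidates by a fused score.

#' Filtering thresholds
#'
#' @param mz_ppm m/z window in parts per million.
#' @param rt_tol Absolute retention-time tolerance (same unit as the data,
#'   typically minutes).
#' @param ccs_pct CCS window in percent of the observed value.
#' @param weights Named weights of the fused score over \code{mz},
#'   \code{rt}, \code{ccs} (equal by default).
#' @return A \code{filter_thresholds} list.
#' @export
filter_thresholds <- function(mz_ppm = 10, rt_tol = 0.5, ccs_pct = 3,
                              weights = c(mz = 1, rt = 1, ccs = 1)) {
  structure(list(mz_ppm = mz_ppm, rt_tol = rt_tol, ccs_pct = ccs_pct,
                 weights = weights),
            class = "filter_thresholds")
}

#' Filter and rank library candidates for one query
#'
#' Applies three nested windows: MList (|dm/z| within \code{mz_ppm}),
#' RList (MList members also within \code{rt_tol} of the observed RT), and
#' CList (RList members also within \code{ccs_pct} of the observed CCS).
#' CList candidates are ranked by the fused score
#' \code{1 - sum_d w_d |err_d| / (tol_d * sum w)} over the dimensions
#' available for the query, which is monotone non-increasing in every error
#' dimension. Ties break on smaller m/z error, then identifier. A query or
#' library entry lacking RT (or CCS) passes that stage unfiltered with a
#' zero contribution to the score.
#'
#' @param query list or one-row data.frame with \code{mz} (required) and
#'   optional \code{rt}, \code{ccs}, \code{true_identifier}.
#' @param library data.frame with identifier, mz and optional rt, ccs
#'   columns (e.g. predictions from \code{\link{predict_records}}).
#' @param thresholds A \code{\link{filter_thresholds}}.
#' @return list(candidates = ranked data.frame with per-dimension errors
#'   and \code{score}, counts = c(mlist, rlist, clist)).
#' @export
filter_candidates <- function(query, library,
                              thresholds = filter_thresholds()) {
  if (is.null(library) || nrow(library) == 0) {
    stop(errorCondition("candidate library is empty",
                        class = c("graphccs_empty_library", "graphccs_error")))
  }
  q <- as.list(query)
  stopifnot(!is.null(q$mz), is.finite(q$mz))
  lib <- library
  if (!"rt" %in% names(lib)) lib$rt <- NA_real_
  if (!"ccs" %in% names(lib)) lib$ccs <- NA_real_

  mz_err_ppm <- abs(lib$mz - q$mz) / q$mz * 1e6
  m_sel <- mz_err_ppm <= thresholds$mz_ppm
  mlist <- which(m_sel)

  has_rt <- !is.null(q$rt) && !is.na(q$rt)
  rt_err <- if (has_rt) abs(lib$rt - q$rt) else rep(NA_real_, nrow(lib))
  r_pass <- if (has_rt) (is.na(lib$rt) | rt_err <= thresholds$rt_tol)
            else rep(TRUE, nrow(lib))
  rlist <- which(m_sel & r_pass)

  has_ccs <- !is.null(q$ccs) && !is.na(q$ccs)
  ccs_err_pct <- if (has_ccs) abs(lib$ccs - q$ccs) / q$ccs * 100
                 else rep(NA_real_, nrow(lib))
  c_pass <- if (has_ccs) (is.na(lib$ccs) | ccs_err_pct <= thresholds$ccs_pct)
            else rep(TRUE, nrow(lib))
  clist <- which(m_sel & r_pass & c_pass)

  cand <- lib[clist, , drop = FALSE]
  cand$mz_error_ppm <- mz_err_ppm[clist]
  cand$rt_error <- rt_err[clist]
  cand$ccs_error_pct <- ccs_err_pct[clist]
  w <- thresholds$weights
  norm_err <- cbind(
    mz = cand$mz_error_ppm / thresholds$mz_ppm,
    rt = if (has_rt) cand$rt_error / thresholds$rt_tol else NA_real_,
    ccs = if (has_ccs) cand$ccs_error_pct / thresholds$ccs_pct else NA_real_)
  if (nrow(cand)) {
    contrib <- sweep(norm_err, 2, w[colnames(norm_err)], `*`)
    contrib[is.na(contrib)] <- 0
    cand$score <- 1 - rowSums(contrib) / sum(w)
    ord <- order(-cand$score, cand$mz_error_ppm, cand$identifier)
    cand <- cand[ord, , drop = FALSE]
    cand$rank <- seq_len(nrow(cand))
  } else {
    cand$score <- numeric(0)
    cand$rank <- integer(0)
  }
  rownames(cand) <- NULL
  list(candidates = cand,
       counts = c(mlist = length(mlist), rlist = length(rlist),
                  clist = length(clist)))
}

#' Recall at k over a set of queries
#'
#' Fraction (in percent) of queries whose true identifier ranks within the
#' top k of the filtered, fused-score-ranked candidate list.
#'
#' @param queries data.frame with mz (and optional rt, ccs) plus
#'   \code{true_identifier}.
#' @param library Candidate library (see \code{\link{filter_candidates}}).
#' @param thresholds A \code{\link{filter_thresholds}}.
#' @param k Rank cutoff.
#' @return Percentage in [0, 100].
#' @export
recall_at_k <- function(queries, library, thresholds = filter_thresholds(),
                        k = 1) {
  if (!"true_identifier" %in% names(queries) ||
      any(is.na(queries$true_identifier))) {
    stop(errorCondition("queries must carry true_identifier for recall",
                        class = c("graphccs_missing_truth", "graphccs_error")))
  }
  hits <- vapply(seq_len(nrow(queries)), function(i) {
    res <- filter_candidates(queries[i, , drop = FALSE], library, thresholds)
    cand <- res$candidates
    any(cand$identifier[cand$rank <= k] == queries$true_identifier[i])
  }, logical(1))
  mean(hits) * 100
}
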