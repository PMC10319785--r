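# Model interpretation: masking-based feature importance, rotation
# robustness of predictions, and export of the learned (pooled)
# representations.

#' Masking-based feature importance
#'
#' For each node attribute block, evaluates the trained model with that
#' block masked (zeroed on the standardised scale) at inference time and
#' compares the error against the unmasked baseline. Raw drops
#' (masked error - baseline error) are clipped at zero and normalised to
#' percentages summing to 100.
#'
#' @param model A \code{ccs_model}.
#' @param data Labelled \code{ccs_dataset} to evaluate on.
#' @param metric Error metric for the drop: \code{"median_re"} (default) or
#'   \code{"rmse"}.
#' @return A \code{feature_importance} object: data.frame with columns
#'   \code{attribute}, \code{raw_drop}, \code{importance} (percent), plus
#'   attributes \code{baseline} and \code{metric}.
#' @export
feature_importance <- function(model, data, metric = c("median_re", "rmse")) {
  metric <- match.arg(metric)
  data <- ccs_dataset(data)
  blocks <- names(feature_blocks(model$feat_cfg))
  baseline <- evaluate(model, data)$metrics[[metric]]
  drops <- vapply(blocks, function(b) {
    evaluate(model, data, mask = b)$metrics[[metric]] - baseline
  }, numeric(1))
  clipped <- pmax(drops, 0)
  total <- sum(clipped)
  importance <- if (total > 0) clipped / total * 100 else
    rep(0, length(clipped))
  structure(data.frame(attribute = blocks, raw_drop = unname(drops),
                       importance = unname(importance),
                       stringsAsFactors = FALSE),
            baseline = baseline, metric = metric,
            class = c("feature_importance", "data.frame"))
}

#' @export
print.feature_importance <- function(x, ...) {
  cat(sprintf("<feature_importance> baseline %s = %.4f\n",
              attr(x, "metric"), attr(x, "baseline")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rotation robustness of a prediction
#'
#' Predicts the CCS of one molecule under n uniformly random rotations of
#' its conformer (uniform over SO(3) via quaternion sampling) and
#' summarises the spread. A physically faithful model should show a small
#' coefficient of variation even though raw coordinates enter the network.
#'
#' @param model A \code{ccs_model}.
#' @param mol Molecule with a conformer.
#' @param adduct Adduct label.
#' @param n_rotations Number of random rotations.
#' @param seed Seed for the rotation sample.
#' @param mask Optional attribute blocks to zero at inference.
#' @return list(mean, sd, cv, values).
#' @export
rotation_robustness <- function(model, mol, adduct = "[M+H]+",
                                n_rotations = 100, seed = 1L, mask = NULL) {
  stopifnot(inherits(mol, "ccs_molecule"), !is.null(mol$conformer))
  rots <- random_rotations(n_rotations, seed = seed)
  values <- vapply(rots, function(R) {
    g <- build_graph(mol, conf = rotate_conformer(mol$conformer, R),
                     cfg = model$feat_cfg)
    .forward_graph(g, adduct, model$params, model$config, mask = mask)$pred
  }, numeric(1))
  mu <- mean(values)
  s <- if (n_rotations > 1) stats::sd(values) else 0
  list(mean = mu, sd = s, cv = if (mu > 0) s / mu else 0, values = values)
}

#' Ring count of a molecule
#'
#' Cyclomatic number (bonds - atoms + components) of the molecular graph.
#' @param mol A \code{ccs_molecule}.
#' @return Integer ring count.
#' @export
ring_count <- function(mol) {
  n <- nrow(mol$atoms); m <- nrow(mol$bonds)
  if (m == 0) return(0L)
  g <- igraph::graph_from_edgelist(cbind(mol$bonds$i, mol$bonds$j),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  as.integer(m - n + igraph::count_components(g))
}

#' Export learned molecular representations
#'
#' One row per record: the pooled representation p (length 16 with the
#' reference architecture), the molecule's ring count, and the record
#' metadata. The table is suitable input for any external 2-D embedding
#' tool (e.g. UMAP).
#'
#' @param model A \code{ccs_model}.
#' @param data A \code{ccs_dataset} or record data.frame.
#' @return data.frame with columns identifier, smiles, adduct, ring_count
#'   and p1..pF.
#' @export
export_representations <- function(model, data) {
  data <- ccs_dataset(data)
  graphs <- .build_graphs(data, model$feat_cfg)
  batch <- .build_batch(data$records, graphs)
  fwd <- .batch_forward(batch, model$params, model$config)
  pm <- as.matrix(batch$R %*% fwd$p)
  colnames(pm) <- paste0("p", seq_len(ncol(pm)))
  rc <- vapply(data$molecules, ring_count, integer(1))
  out <- data.frame(identifier = data$records$identifier,
                    smiles = data$records$smiles,
                    adduct = data$records$adduct,
                    ring_count = unname(rc[data$records$smiles]),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pm))
}
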