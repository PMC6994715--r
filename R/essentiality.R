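# Human cell-line essentiality from CRISPR proliferation scores.
#
# Per-gene essentiality is summarised as the arithmetic mean of the
# proliferation (dependency) scores across cell lines; lower means more
# essential.  The essential/non-essential cut-off is either supplied
# directly (default -0.45) or selected by maximising the F1 score of the
# thresholded means against a reference labelling.

#' Per-gene mean proliferation scores
#'
#' @param scores numeric matrix, genes in rows (rownames = gene ids),
#'   cell lines in columns.  Missing cells (`NA`) are ignored; genes with
#'   no non-missing score are dropped with a warning.
#' @return tibble with columns `gene_id`, `n_lines`, `mean_score`.
#' @export
gene_mean_scores <- function(scores) {
  if (!is.matrix(scores) || nrow(scores) == 0 || ncol(scores) == 0) {
    fusil_stop("`scores` must be a non-empty gene x cell-line matrix",
               class = "fusil_data_error")
  }
  if (is.null(rownames(scores))) {
    fusil_stop("`scores` must have gene ids as rownames",
               class = "fusil_data_error")
  }
  n_obs <- rowSums(!is.na(scores))
  if (any(n_obs == 0)) {
    rlang::warn(sprintf(
      "dropping %d gene(s) with no non-missing proliferation score",
      sum(n_obs == 0)))
  }
  keep <- n_obs > 0
  tibble::tibble(
    gene_id = rownames(scores)[keep],
    n_lines = as.integer(n_obs[keep]),
    mean_score = unname(rowMeans(scores[keep, , drop = FALSE],
                                 na.rm = TRUE))
  )
}

#' F1 score from confusion counts
#'
#' `2 * tp / (2 * tp + fp + fn)`.  Returns `NA` with a warning when all
#' three counts are zero.
#'
#' @param tp,fp,fn non-negative counts (vectorised).
#' @return numeric F1 in `[0, 1]` (or `NA`).
#' @export
f1_from_confusion <- function(tp, fp, fn) {
  check_count(tp, "tp"); check_count(fp, "fp"); check_count(fn, "fn")
  denom <- 2 * tp + fp + fn
  if (any(denom == 0)) {
    rlang::warn("F1 undefined when tp, fp and fn are all zero; returning NA")
  }
  ifelse(denom == 0, NA_real_, 2 * tp / denom)
}

#' Select the essentiality threshold by F1 maximisation
#'
#' For every candidate threshold `t` in `grid`, genes with
#' `mean_score <= t` are predicted essential and the F1 score is computed
#' against `reference` (reference essentials are the positive class).  The
#' threshold maximising F1 is selected; when several grid values tie, the
#' value closest to the midpoint of the tied run is returned (lower index
#' on an exact midpoint tie), which is deterministic and sits centrally in
#' a plateau of equivalent cut-offs.
#'
#' @param means tibble from [gene_mean_scores()] (columns `gene_id`,
#'   `mean_score`), or a named numeric vector of means.
#' @param reference named character vector (or tibble with `gene_id`,
#'   `label`) giving `"essential"` / `"non_essential"` per gene.
#' @param grid sorted numeric vector of candidate thresholds.
#' @return list with elements `grid`, `f1_values`, `selected`.
#' @export
select_threshold_f1 <- function(means, reference,
                                grid = seq(-1.5, 0, by = 0.01)) {
  if (is.data.frame(means)) {
    check_columns(means, c("gene_id", "mean_score"), "mean scores")
    means <- setNames(means$mean_score, means$gene_id)
  }
  if (is.data.frame(reference)) {
    check_columns(reference, c("gene_id", "label"), "reference labels")
    reference <- setNames(reference$label, reference$gene_id)
  }
  if (length(grid) == 0 || is.unsorted(grid)) {
    fusil_stop("`grid` must be a non-empty sorted numeric vector",
               class = "fusil_config_error")
  }
  common <- intersect(names(means), names(reference))
  if (length(common) < 2) {
    fusil_stop("means and reference share fewer than 2 genes",
               class = "fusil_data_error")
  }
  m <- means[common]
  pos <- reference[common] == "essential"
  if (!any(pos) || all(pos)) {
    fusil_stop("reference labelling must contain both classes",
               class = "fusil_data_error")
  }
  # cumulative confusion counts over the sorted grid
  tp <- vapply(grid, function(t) sum(m <= t & pos), numeric(1))
  fp <- vapply(grid, function(t) sum(m <= t & !pos), numeric(1))
  fn <- sum(pos) - tp
  f1 <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  best <- which(f1 == max(f1))
  mid <- mean(range(best))
  sel <- best[which.min(abs(best - mid))]
  list(grid = grid, f1_values = f1, selected = grid[sel])
}

#' Classify genes as cell-essential
#'
#' Essential iff `mean_score <= threshold`; the boundary belongs to the
#' essential side.
#'
#' @param mean_score numeric vector of per-gene mean proliferation scores.
#' @param threshold essentiality cut-off (default -0.45).
#' @return character vector, `"essential"` or `"non_essential"`.
#' @examples
#' classify_essential(c(-0.46, -0.45, 0))
#' @export
classify_essential <- function(mean_score, threshold = -0.45) {
  if (!all(is.finite(mean_score))) {
    fusil_stop("mean scores must be finite", class = "fusil_data_error")
  }
  ifelse(mean_score <= threshold, "essential", "non_essential")
}
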