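# Per-gene features and per-bin comparisons: recombination rates,
# expression tissue decorrelation, network statistics, paralogues, age of
# onset, affected physiological systems, and pairwise bin tests.

#' Average recombination rate per gene
#'
#' Assigns each recombination-map interval to its closest gene on the same
#' chromosome (distance 0 when overlapping; ties broken to the gene with
#' the lower start coordinate) and averages the assigned interval rates
#' per gene.  Coordinates are 0-based half-open.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`,
#'   `rate` (cM/Mb).
#' @param genes data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`.
#' @return tibble with columns `gene_id`, `recomb_rate`, `n_intervals`.
#' @export
average_recombination_per_gene <- function(intervals, genes) {
  check_columns(intervals, c("chrom", "start", "end", "rate"),
                "recombination intervals")
  check_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  if (any(intervals$start >= intervals$end) ||
      any(genes$start >= genes$end)) {
    fusil_stop("intervals must satisfy start < end",
               class = "fusil_data_error")
  }
  orphan <- !(intervals$chrom %in% genes$chrom)
  if (any(orphan)) {
    rlang::warn(sprintf(
      "dropping %d interval(s) on chromosomes with no genes", sum(orphan)))
    intervals <- intervals[!orphan, , drop = FALSE]
  }
  # 0-based half-open -> 1-based closed for IRanges
  iv <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end))
  gn <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  near <- GenomicRanges::distanceToNearest(iv, gn)
  d <- S4Vectors::mcols(near)$distance
  # recover all equidistant genes: a gene at gap <= d overlaps the
  # interval widened by d + 1 on both sides
  widened <- GenomicRanges::resize(iv, GenomicRanges::width(iv) +
                                     2 * (d + 1), fix = "center")
  hits <- GenomicRanges::findOverlaps(widened, gn)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  exact <- GenomicRanges::distance(iv[q], gn[s])
  keep <- !is.na(exact) & exact == d[q]
  hd <- tibble::tibble(interval = q[keep], gene = s[keep],
                       gene_start = genes$start[s[keep]])
  # among equidistant genes keep the upstream (lower-coordinate) one
  assigned <- hd |>
    dplyr::group_by(.data$interval) |>
    dplyr::slice_min(.data$gene_start, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  assigned$rate <- intervals$rate[assigned$interval]
  assigned |>
    dplyr::group_by(gene_id = genes$gene_id[assigned$gene]) |>
    dplyr::summarise(recomb_rate = mean(.data$rate),
                     n_intervals = dplyr::n(), .groups = "drop")
}

#' Drop mutually correlated tissue columns
#'
#' Greedy decorrelation: columns are visited in input order and a column
#' is retained only when its absolute Spearman correlation with every
#' already-retained column is at most `rho_max`.  Constant columns (rho
#' undefined) are retained with a warning.
#'
#' @param mat numeric matrix, genes x tissues (column names = tissues).
#' @param rho_max maximum tolerated absolute Spearman rho (default 0.8).
#' @return character vector of retained column names.
#' @export
drop_correlated_columns <- function(mat, rho_max = 0.8) {
  if (!is.matrix(mat) || ncol(mat) < 2) {
    fusil_stop("`mat` must be a matrix with at least two columns",
               class = "fusil_data_error")
  }
  if (is.null(colnames(mat))) colnames(mat) <- paste0("col", seq_len(ncol(mat)))
  retained <- character(0)
  for (j in colnames(mat)) {
    if (length(retained) == 0) {
      retained <- j
      next
    }
    if (length(unique(mat[, j])) == 1) {
      rlang::warn(sprintf(
        "column '%s' is constant; correlation undefined, retaining it", j))
      retained <- c(retained, j)
      next
    }
    rho <- suppressWarnings(
      cor(mat[, j], mat[, retained, drop = FALSE], method = "spearman"))
    rho[is.na(rho)] <- 0  # against constant retained columns
    if (all(abs(rho) <= rho_max)) retained <- c(retained, j)
  }
  retained
}

#' Node degree and topological coefficient of an interaction network
#'
#' Filters the edge list to high-confidence interactions
#' (`score > min_score`), drops self-loops with a warning, and computes
#' per node the degree and the topological coefficient: for a node n with
#' k_n >= 2 neighbours, T_n is the average over all nodes m sharing at
#' least one neighbour with n of J(n, m) / k_n, where J(n, m) is the
#' number of shared neighbours plus one if n and m interact directly.
#' Nodes with fewer than two neighbours get T_n = 0.
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `score`.
#' @param min_score combined-score cut-off; only edges with
#'   `score > min_score` are kept (default 0.7).
#' @return tibble with columns `gene_id`, `degree`, `topo_coeff`.
#' @export
network_node_stats <- function(edges, min_score = 0.7) {
  check_columns(edges, c("gene_a", "gene_b", "score"), "edge list")
  edges <- edges[edges$score > min_score, , drop = FALSE]
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    rlang::warn(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0) {
    return(tibble::tibble(gene_id = character(0), degree = integer(0),
                          topo_coeff = numeric(0)))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE)
  g <- igraph::simplify(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  deg <- Matrix::rowSums(A)
  S <- A %*% A                 # shared-neighbour counts
  Matrix::diag(S) <- 0
  J <- S + A                   # +1 where directly linked
  share <- S > 0               # m in M(n): shares >= 1 neighbour with n
  num <- Matrix::rowSums(J * share)
  cnt <- Matrix::rowSums(share)
  tc <- ifelse(deg >= 2 & cnt > 0, num / (cnt * deg), 0)
  tibble::tibble(gene_id = rownames(A),
                 degree = as.integer(deg),
                 topo_coeff = as.numeric(tc))
}

#' Percentage of paralogue-free genes per bin
#'
#' A gene counts as paralogue-free when it has no paralogue partner with
#' amino-acid identity at or above `cutoff` percent.
#'
#' @param assignments tibble with columns `gene_id`, `bin`.
#' @param paralogues data frame with columns `gene_id`, `partner_id`,
#'   `identity` (percent, 0-100).  Genes absent from the table have no
#'   partners.
#' @param cutoff identity threshold in percent (default 30).
#' @return tibble with columns `bin`, `n_genes`, `pct_paralogue_free`.
#' @export
paralogue_free_rate <- function(assignments, paralogues, cutoff = 30) {
  check_columns(assignments, c("gene_id", "bin"), "assignments")
  check_columns(paralogues, c("gene_id", "partner_id", "identity"),
                "paralogue pairs")
  if (any(paralogues$identity < 0 | paralogues$identity > 100)) {
    fusil_stop("identity must be a percentage in [0, 100]",
               class = "fusil_data_error")
  }
  with_par <- unique(paralogues$gene_id[paralogues$identity >= cutoff])
  assignments |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      pct_paralogue_free =
        100 * mean(!(.data$gene_id %in% with_par)),
      .groups = "drop")
}

#' Earliest age of onset per gene
#'
#' @param onsets data frame with columns `gene_id`, `onset` (levels
#'   `r paste(ONSET_LEVELS, collapse = " < ")`).
#' @return tibble with columns `gene_id`, `onset_earliest` (ordered
#'   factor).
#' @export
earliest_onset <- function(onsets) {
  check_columns(onsets, c("gene_id", "onset"), "onset annotations")
  bad <- setdiff(unique(onsets$onset), ONSET_LEVELS)
  if (length(bad) > 0) {
    fusil_stop(sprintf("unknown onset categor%s: %s",
                       if (length(bad) > 1) "ies" else "y",
                       paste(bad, collapse = ", ")),
               class = "fusil_data_error")
  }
  onsets |>
    dplyr::mutate(onset = factor(.data$onset, levels = ONSET_LEVELS,
                                 ordered = TRUE)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(onset_earliest = min(.data$onset), .groups = "drop")
}

#' Number of affected physiological systems per gene
#'
#' Counts unique top-level phenotype terms per gene (terms are expected to
#' be pre-mapped to the ontology's top level).
#'
#' @param systems data frame with columns `gene_id`, `system`.
#' @return tibble with columns `gene_id`, `n_systems`.
#' @export
count_affected_systems <- function(systems) {
  check_columns(systems, c("gene_id", "system"), "system annotations")
  systems |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_systems = dplyr::n_distinct(.data$system),
                     .groups = "drop")
}

#' Pairwise bin comparisons of a gene feature
#'
#' Two-sided Wilcoxon rank-sum tests for every pair of bins, BH-adjusted
#' across the pairs.  Pairs involving a bin with fewer than `min_n` genes
#' are skipped with a warning.
#'
#' @param values named numeric vector of the feature (names = gene ids),
#'   or tibble with columns `gene_id`, `value`.
#' @param assignments tibble with columns `gene_id`, `bin`.
#' @param min_n minimum genes per bin (default 3).
#' @return symmetric matrix of BH-adjusted P values (diagonal `NA`).
#' @export
pairwise_bin_tests <- function(values, assignments, min_n = 3) {
  if (is.data.frame(values)) {
    check_columns(values, c("gene_id", "value"), "feature values")
    values <- setNames(values$value, values$gene_id)
  }
  check_columns(assignments, c("gene_id", "bin"), "assignments")
  groups <- split(values[assignments$gene_id], assignments$bin)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  bins <- names(groups)
  if (length(bins) < 2) {
    fusil_stop("need at least two bins", class = "fusil_data_error")
  }
  small <- names(groups)[vapply(groups, length, integer(1)) < min_n]
  if (length(small) > 0) {
    rlang::warn(sprintf("skipping pairs involving small bin(s): %s",
                        paste(small, collapse = ", ")))
  }
  pairs <- utils::combn(bins, 2, simplify = FALSE)
  praw <- vapply(pairs, function(pr) {
    if (pr[1] %in% small || pr[2] %in% small) return(NA_real_)
    suppressWarnings(
      wilcox.test(groups[[pr[1]]], groups[[pr[2]]],
                  alternative = "two.sided", exact = FALSE)$p.value)
  }, numeric(1))
  padj <- rep(NA_real_, length(praw))
  padj[!is.na(praw)] <- bh_adjust(praw[!is.na(praw)])
  out <- matrix(NA_real_, length(bins), length(bins),
                dimnames = list(bins, bins))
  for (i in seq_along(pairs)) {
    out[pairs[[i]][1], pairs[[i]][2]] <- padj[i]
    out[pairs[[i]][2], pairs[[i]][1]] <- padj[i]
  }
  out
}
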