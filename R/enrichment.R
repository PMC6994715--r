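# Disease-gene enrichment per FUSIL bin and generic term
# over-representation.
#
# Each bin is compared against the rest of the binned universe in a 2x2
# table of disease vs non-disease genes: the odds ratio is the
# unconditional maximum-likelihood (Wald) estimate with a log-scale
# normal-approximation confidence interval, the P value is a two-sided
# Fisher exact test, and Benjamini-Hochberg correction is applied across
# the bins of each disease resource.

#' Wald odds ratio with normal-approximation confidence interval
#'
#' For a 2x2 table (a, b, c, d), the estimate is `(a*d)/(b*c)` and the
#' interval `exp(log(or) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.  Tables
#' with a zero cell return 0 or `Inf` with `degenerate = TRUE` and an
#' undefined interval; optionally the Haldane-Anscombe correction
#' (add 0.5 to every cell) can be applied instead.
#'
#' @param a,b,c,d non-negative counts: `a` disease genes in the group,
#'   `b` non-disease genes in the group, `c`/`d` the same outside it.
#' @param level confidence level (default 0.95).
#' @param haldane apply the +0.5 continuity correction to zero-cell tables
#'   (default `FALSE`).
#' @return list with `or_hat`, `ci_low`, `ci_high`, `degenerate`.
#' @examples
#' odds_ratio_wald(20, 10, 10, 20)
#' @export
odds_ratio_wald <- function(a, b, c, d, level = 0.95, haldane = FALSE) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0)) {
    fusil_stop("contingency counts must be non-negative",
               class = "fusil_data_error")
  }
  if (sum(counts) < 1) {
    fusil_stop("contingency table is empty", class = "fusil_data_error")
  }
  z <- qnorm(1 - (1 - level) / 2)
  if (any(counts == 0)) {
    if (haldane) {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    } else {
      or <- if (a * d == 0) 0 else Inf
      return(list(or_hat = or, ci_low = NA_real_, ci_high = NA_real_,
                  degenerate = TRUE))
    }
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or_hat = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       degenerate = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates the hypergeometric distribution over all tables with the
#' observed margins and sums the probabilities of tables no more probable
#' than the observed one (probability-ordering convention, with the
#' standard relative tolerance for floating-point ties).
#'
#' @inheritParams odds_ratio_wald
#' @return two-sided P value.
#' @examples
#' fisher_two_sided(3, 1, 1, 3)
#' @export
fisher_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    fusil_stop("contingency counts must be non-negative integers",
               class = "fusil_data_error")
  }
  m <- a + b          # row 1 margin
  k <- a + c          # column 1 margin
  n_tot <- a + b + c + d
  if (m == 0 || k == 0 || m == n_tot || k == n_tot) return(1)
  support <- max(0, k - (n_tot - m)):min(k, m)
  probs <- dhyper(support, m, n_tot - m, k)
  p_obs <- dhyper(a, m, n_tot - m, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction, returned in input order.
#'
#' @param pvalues numeric vector of P values in `[0, 1]`.
#' @return adjusted P values.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    fusil_stop("P values must lie in [0, 1]", class = "fusil_data_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Disease-gene enrichment per FUSIL bin
#'
#' For each disease resource and each bin: `a` = resource genes in the
#' bin, `b` = genes annotated in no resource in the bin, `c`/`d` the same
#' outside the bin.  Genes annotated only in other resources are excluded
#' from that resource's table, so each comparison is resource vs clean
#' non-disease background.  BH correction is applied across bins within
#' each resource.  The universe is the five-bin assignment set.
#'
#' @param assignments tibble with columns `gene_id`, `bin`.
#' @param disease_sets named list of character vectors of disease gene ids
#'   (one element per resource).
#' @param bins bins to test (default the five FUSIL bins present).
#' @return tibble with one row per (resource, bin): counts `a`-`d`,
#'   `or_hat`, `ci_low`, `ci_high`, `degenerate`, `p_fisher`, `p_adjusted`.
#' @export
bin_disease_enrichment <- function(assignments, disease_sets,
                                   bins = NULL) {
  check_columns(assignments, c("gene_id", "bin"), "assignments")
  universe <- assignments |>
    dplyr::filter(.data$bin %in% FUSIL_BINS)
  if (is.null(bins)) bins <- intersect(FUSIL_BINS, unique(universe$bin))
  if (length(unique(universe$bin)) < 2) {
    fusil_stop("assignments must cover at least two bins",
               class = "fusil_data_error")
  }
  if (is.null(names(disease_sets)) || any(names(disease_sets) == "")) {
    fusil_stop("`disease_sets` must be a named list",
               class = "fusil_config_error")
  }
  any_disease <- unique(unlist(disease_sets, use.names = FALSE))
  res <- list()
  for (resource in names(disease_sets)) {
    dset <- intersect(disease_sets[[resource]], universe$gene_id)
    if (length(dset) == 0) {
      rlang::warn(sprintf(
        "resource '%s' has no genes in the binned universe; skipped",
        resource))
      next
    }
    is_d <- universe$gene_id %in% dset
    is_clean <- !(universe$gene_id %in% any_disease)
    rows <- lapply(bins, function(bb) {
      inb <- universe$bin == bb
      a <- sum(inb & is_d);  b <- sum(inb & is_clean)
      c_ <- sum(!inb & is_d); d <- sum(!inb & is_clean)
      orw <- odds_ratio_wald(a, b, c_, d)
      tibble::tibble(resource = resource, bin = bb,
                     a = a, b = b, c = c_, d = d,
                     or_hat = orw$or_hat, ci_low = orw$ci_low,
                     ci_high = orw$ci_high, degenerate = orw$degenerate,
                     p_fisher = fisher_two_sided(a, b, c_, d))
    })
    tab <- dplyr::bind_rows(rows)
    tab$p_adjusted <- bh_adjust(tab$p_fisher)
    res[[resource]] <- tab
  }
  dplyr::bind_rows(res)
}

#' Hypergeometric term over-representation
#'
#' One-sided upper-tail hypergeometric test of each annotation term's
#' overlap with a study set against a reference universe, BH-corrected
#' across terms.  Stands in for ontology (GO/pathway) over-representation
#' with the full binned gene set as the reference.
#'
#' @param study_set character vector of study gene ids (must be a subset
#'   of `universe`).
#' @param annotations named list of character vectors: term -> gene set.
#' @param universe character vector of reference gene ids.
#' @return tibble with one row per term: `term`, `n_term`, `n_overlap`,
#'   `expected`, `p_hyper`, `p_adjusted`.
#' @export
term_overrepresentation <- function(study_set, annotations, universe) {
  universe <- unique(universe)
  study_set <- unique(study_set)
  if (!all(study_set %in% universe)) {
    fusil_stop("study set must be a subset of the universe",
               class = "fusil_data_error")
  }
  if (is.null(names(annotations)) || any(names(annotations) == "")) {
    fusil_stop("`annotations` must be a named list",
               class = "fusil_config_error")
  }
  N <- length(universe)
  n_s <- length(study_set)
  rows <- lapply(names(annotations), function(term) {
    tg <- intersect(unique(annotations[[term]]), universe)
    if (length(tg) == 0) {
      rlang::warn(sprintf("term '%s' has no genes in the universe; skipped",
                          term))
      return(NULL)
    }
    K <- length(tg)
    x <- length(intersect(tg, study_set))
    tibble::tibble(term = term, n_term = K, n_overlap = x,
                   expected = n_s * K / N,
                   p_hyper = phyper(x - 1, K, N - K, n_s,
                                    lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$p_adjusted <- bh_adjust(out$p_hyper)
  out
}
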