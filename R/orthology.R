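# Orthologue support tiers and one-to-one pair selection.
#
# Orthology inferences are scored by the number of independent inference
# methods (0-12) that support each human-mouse pair.  The pipeline keeps
# pairs with moderate-or-better support (>= 5 methods) where at least one
# member is protein coding, and then accepts only pairs whose support is
# the strict unique maximum among the surviving pairs of BOTH genes
# (bidirectional best hit with duplicated maxima discarded).

#' Orthologue support confidence tier
#'
#' Maps the number of supporting inference methods (0-12) to a confidence
#' tier: 9-12 good, 5-8 moderate, 1-4 low, 0 none.
#'
#' @param n_methods integer vector in 0..12.
#' @return character vector of tiers.
#' @examples
#' support_tier(c(12, 5, 1, 0))
#' @export
support_tier <- function(n_methods) {
  check_count(n_methods, "n_methods")
  if (any(n_methods > 12)) {
    fusil_stop("n_methods must be <= 12 (twelve inference methods)",
               class = "fusil_data_error")
  }
  dplyr::case_when(
    n_methods >= 9 ~ "good",
    n_methods >= 5 ~ "moderate",
    n_methods >= 1 ~ "low",
    TRUE ~ "none"
  )
}

#' Select unambiguous one-to-one orthologue pairs
#'
#' Filters candidate pairs to those with `n_methods >= min_support` and at
#' least one protein-coding member, then accepts a pair only when its
#' support count is the strict unique maximum among surviving pairs of both
#' its human gene and its mouse gene.  Ties for the maximum on either side
#' reject all tied pairs, so the result is a matching: no gene of either
#' species appears twice.
#'
#' @param edges data frame with columns `human_id`, `mouse_id`,
#'   `n_methods`, `human_coding`, `mouse_coding`; rows unique on
#'   (`human_id`, `mouse_id`).
#' @param min_support minimum number of supporting methods (default 5,
#'   i.e. moderate confidence or better).
#' @return tibble of accepted pairs (same columns as `edges`).
#' @export
select_one_to_one <- function(edges, min_support = 5) {
  check_columns(edges, c("human_id", "mouse_id", "n_methods",
                         "human_coding", "mouse_coding"),
                "orthology edges")
  key <- paste(edges$human_id, edges$mouse_id, sep = "\r")
  if (anyDuplicated(key)) {
    fusil_stop("duplicated (human_id, mouse_id) pairs in orthology edges",
               class = "fusil_data_error")
  }
  surviving <- edges |>
    dplyr::filter(.data$n_methods >= min_support,
                  .data$human_coding | .data$mouse_coding)
  if (nrow(surviving) == 0) return(surviving)

  unique_max <- function(df, id_col) {
    df |>
      dplyr::group_by(.data[[id_col]]) |>
      dplyr::mutate(
        .is_max = .data$n_methods == max(.data$n_methods),
        .ok = .data$.is_max & sum(.data$.is_max) == 1L
      ) |>
      dplyr::ungroup()
  }
  surviving <- unique_max(surviving, "human_id")
  ok_h <- surviving$.ok
  surviving <- unique_max(dplyr::select(surviving, -".is_max", -".ok"),
                          "mouse_id")
  ok_m <- surviving$.ok
  surviving |>
    dplyr::filter(ok_h & ok_m) |>
    dplyr::select(-".is_max", -".ok")
}
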