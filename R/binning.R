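# FUSIL binning: combine mouse viability and cell essentiality calls.
#
# Five mutually exclusive bins cover the non-excluded genes:
#   CL  cellular lethal        lethal    + essential
#   DL  developmental lethal   lethal    + non-essential
#   SV  subviable              subviable + non-essential
#   VP  viable with phenotype  viable    + non-essential, >= 1 significant
#   VN  viable, no phenotype   viable    + non-essential, 0 significant
# Subviable/viable genes scoring as cell-essential are flagged outliers
# (their means sit at or just below the threshold), and viable genes with
# under half their phenotyping procedures completed are set aside as
# V.insuffProcedures rather than split into VP/VN.

#' Assign FUSIL categories
#'
#' Vectorised over genes.  Inputs must already be resolved gene-level
#' calls; excluded viability calls (hemizygous, conflicting, insufficient)
#' must be filtered out upstream and raise an error here.
#'
#' @param gene_id character vector of gene ids.
#' @param viability `"lethal"`, `"subviable"` or `"viable"` per gene.
#' @param essentiality `"essential"` or `"non_essential"` per gene.
#' @param n_significant_phenotypes count of significant phenotype hits.
#' @param procedures_done,procedures_total phenotyping procedure counts
#'   used for the 50% completeness rule.
#' @param completeness_threshold minimum fraction of completed procedures
#'   for a viable gene to be split into VP/VN (default 0.5).
#' @return tibble with columns `gene_id`, `bin`, `viability`,
#'   `essentiality`, `mouse_category`, `cell_category`.
#' @export
assign_fusil <- function(gene_id, viability, essentiality,
                         n_significant_phenotypes,
                         procedures_done, procedures_total,
                         completeness_threshold = 0.5) {
  if (!all(viability %in% c("lethal", "subviable", "viable"))) {
    fusil_stop(
      "excluded or unresolved viability calls reached the binning stage",
      class = "fusil_data_error")
  }
  if (!all(essentiality %in% c("essential", "non_essential"))) {
    fusil_stop("essentiality must be 'essential' or 'non_essential'",
               class = "fusil_data_error")
  }
  check_count(n_significant_phenotypes, "n_significant_phenotypes")
  completeness <- procedures_done / procedures_total
  ess <- essentiality == "essential"

  bin <- dplyr::case_when(
    viability == "lethal" & ess ~ "CL",
    viability == "lethal" ~ "DL",
    viability == "subviable" & ess ~ "SV.outlier",
    viability == "subviable" ~ "SV",
    ess ~ "V.outlier",
    completeness < completeness_threshold ~ "V.insuffProcedures",
    n_significant_phenotypes >= 1 ~ "VP",
    TRUE ~ "VN"
  )
  mouse_category <- dplyr::case_when(
    viability != "viable" ~ viability,
    completeness < completeness_threshold ~ "viable_insufficient_procedures",
    n_significant_phenotypes >= 1 ~ "viable_with_phenotype",
    TRUE ~ "viable_normal_phenotype"
  )
  tibble::tibble(
    gene_id = gene_id,
    bin = bin,
    viability = viability,
    essentiality = essentiality,
    mouse_category = mouse_category,
    cell_category = ifelse(ess, "essential", "non_essential")
  )
}

#' Cross-tabulate FUSIL assignments
#'
#' Summarises assignments as a mouse-category x cell-category table with
#' counts and row percentages (two decimals, exact halves to even, e.g.
#' 318/320 = 99.375 prints as 99.38 and 2/320 = 0.625 as 0.62), mirroring
#' the headline cross-tabulation of bins.  Genes set aside for
#' insufficient procedures are excluded from the table.
#'
#' @param assignments tibble from [assign_fusil()].
#' @return tibble with columns `mouse_category`, `cell_category`, `n`,
#'   `pct_overlap`, `bin`.
#' @export
summarize_bins <- function(assignments) {
  check_columns(assignments, c("bin", "mouse_category", "cell_category"),
                "assignments")
  if (nrow(assignments) == 0) {
    fusil_stop("no assignments to summarise", class = "fusil_data_error")
  }
  assignments |>
    dplyr::filter(.data$bin != "V.insuffProcedures") |>
    dplyr::count(.data$mouse_category, .data$cell_category, .data$bin,
                 name = "n") |>
    dplyr::group_by(.data$mouse_category) |>
    dplyr::mutate(pct_overlap = round(100 * .data$n / sum(.data$n), 2)) |>
    dplyr::ungroup() |>
    dplyr::select("mouse_category", "cell_category", "n", "pct_overlap",
                  "bin")
}
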