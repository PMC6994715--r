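# Staged prioritisation funnel for developmental-disorder candidate genes:
# developmental-lethal (DL) bin -> not yet disease-associated -> highly
# likely haploinsufficient -> supported by large sequencing programmes ->
# final candidate criteria.

#' Constraint-filtered DL candidates
#'
#' Keeps genes assigned to the DL bin, absent from every supplied disease
#' resource, and highly likely to be haploinsufficient:
#' `hi_percentile < hi_max` OR `loeuf < loeuf_max` OR `pli > pli_min`.
#' A missing score fails its own clause only; genes missing all three
#' scores cannot pass.
#'
#' @param assignments tibble with columns `gene_id`, `bin`.
#' @param disease_sets named list of character vectors of disease genes.
#' @param constraints data frame with columns `gene_id` and any of
#'   `hi_percentile`, `loeuf`, `pli` (missing values allowed).
#' @param hi_max,loeuf_max,pli_min constraint thresholds (defaults 10,
#'   0.35, 0.90).
#' @return character vector of prioritised gene ids.
#' @export
filter_dl_candidates <- function(assignments, disease_sets, constraints,
                                 hi_max = 10, loeuf_max = 0.35,
                                 pli_min = 0.90) {
  check_columns(assignments, c("gene_id", "bin"), "assignments")
  check_columns(constraints, "gene_id", "constraints")
  disease <- unique(unlist(disease_sets, use.names = FALSE))
  dl <- assignments$gene_id[assignments$bin == "DL"]
  dl <- setdiff(dl, disease)

  get_score <- function(col) {
    if (col %in% names(constraints)) {
      constraints[[col]][match(dl, constraints$gene_id)]
    } else {
      rep(NA_real_, length(dl))
    }
  }
  hi <- get_score("hi_percentile")
  loeuf <- get_score("loeuf")
  pli <- get_score("pli")
  pass <- (!is.na(hi) & hi < hi_max) |
    (!is.na(loeuf) & loeuf < loeuf_max) |
    (!is.na(pli) & pli > pli_min)
  dl[pass]
}

#' Consortium evidence overlap (Venn regions)
#'
#' Tabulates candidate genes by membership in the three sequencing
#' programmes and reports the seven Venn region counts plus the union.
#'
#' @param candidates character vector of candidate gene ids.
#' @param evidence data frame with columns `gene_id`, `in_100kgp`,
#'   `in_ddd`, `in_cmg` (logical).  Rows for genes outside `candidates`
#'   are ignored with a warning.
#' @return list with `matrix` (tibble of per-gene flags) and `regions`
#'   (named integer vector: `only_100kgp`, `only_ddd`, `only_cmg`,
#'   `kgp_ddd`, `kgp_cmg`, `ddd_cmg`, `all_three`, `any`).
#' @export
consortium_overlap <- function(candidates, evidence) {
  check_columns(evidence, c("gene_id", "in_100kgp", "in_ddd", "in_cmg"),
                "consortium evidence")
  extra <- setdiff(evidence$gene_id, candidates)
  if (length(extra) > 0) {
    rlang::warn(sprintf(
      "ignoring evidence for %d gene(s) outside the candidate set",
      length(extra)))
  }
  ev <- evidence[evidence$gene_id %in% candidates,
                 c("gene_id", "in_100kgp", "in_ddd", "in_cmg"),
                 drop = FALSE]
  missing <- setdiff(candidates, ev$gene_id)
  if (length(missing) > 0) {
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      gene_id = missing, in_100kgp = FALSE, in_ddd = FALSE,
      in_cmg = FALSE))
  }
  k <- ev$in_100kgp; d <- ev$in_ddd; m <- ev$in_cmg
  regions <- c(
    only_100kgp = sum(k & !d & !m),
    only_ddd = sum(!k & d & !m),
    only_cmg = sum(!k & !d & m),
    kgp_ddd = sum(k & d & !m),
    kgp_cmg = sum(k & !d & m),
    ddd_cmg = sum(!k & d & m),
    all_three = sum(k & d & m),
    any = sum(k | d | m)
  )
  list(matrix = tibble::as_tibble(ev), regions = regions)
}

#' Final candidate selection
#'
#' Keeps genes with evidence from the 100KGP and at least one of DDD or
#' CMG, whose associated variants are absent from the population reference
#' (gnomAD), and which are intolerant to missense variation
#' (`oe_missense < oe_missense_max`).
#'
#' @param evidence data frame with columns `gene_id`, `in_100kgp`,
#'   `in_ddd`, `in_cmg`, `variant_in_gnomad` (logical), `oe_missense`.
#' @param oe_missense_max missense observed/expected cut-off (default
#'   0.8).
#' @return character vector of final candidate gene ids.
#' @export
final_candidates <- function(evidence, oe_missense_max = 0.8) {
  check_columns(evidence, c("gene_id", "in_100kgp", "in_ddd", "in_cmg",
                            "variant_in_gnomad", "oe_missense"),
                "candidate evidence")
  keep <- evidence$in_100kgp & (evidence$in_ddd | evidence$in_cmg) &
    !evidence$variant_in_gnomad &
    !is.na(evidence$oe_missense) & evidence$oe_missense < oe_missense_max
  evidence$gene_id[keep]
}

#' Shared-annotation rates against a reference gene set
#'
#' For each gene in `gene_set`, flags whether it shares at least one
#' protein family, at least one (lowest-level) pathway, or a
#' high-confidence interaction with any gene of `reference_set`
#' (self-matches excluded), and reports the three percentages.
#'
#' @param gene_set character vector of genes to annotate (non-empty).
#' @param reference_set character vector of reference genes (e.g. known
#'   monoallelic developmental-disorder genes).
#' @param family_map data frame with columns `gene_id`, `family`.
#' @param pathway_map data frame with columns `gene_id`, `pathway`.
#' @param edges data frame with columns `gene_a`, `gene_b`, `score`.
#' @param min_score interaction score cut-off (default 0.7).
#' @return list with `per_gene` (tibble of per-gene logical flags) and
#'   `rates` (named numeric vector `pct_shared_family`,
#'   `pct_shared_pathway`, `pct_interacting`).
#' @export
shared_annotation_rates <- function(gene_set, reference_set, family_map,
                                    pathway_map, edges, min_score = 0.7) {
  if (length(gene_set) == 0) {
    fusil_stop("`gene_set` is empty", class = "fusil_data_error")
  }
  check_columns(family_map, c("gene_id", "family"), "family map")
  check_columns(pathway_map, c("gene_id", "pathway"), "pathway map")
  check_columns(edges, c("gene_a", "gene_b", "score"), "edge list")

  shares_annotation <- function(map, key) {
    vapply(gene_set, function(g) {
      ref <- setdiff(reference_set, g)
      mine <- map[[key]][map$gene_id == g]
      theirs <- map[[key]][map$gene_id %in% ref]
      length(intersect(mine, theirs)) > 0
    }, logical(1))
  }
  hi_edges <- edges[edges$score > min_score, , drop = FALSE]
  interacts <- vapply(gene_set, function(g) {
    ref <- setdiff(reference_set, g)
    any((hi_edges$gene_a == g & hi_edges$gene_b %in% ref) |
          (hi_edges$gene_b == g & hi_edges$gene_a %in% ref))
  }, logical(1))

  per_gene <- tibble::tibble(
    gene_id = gene_set,
    shares_family = shares_annotation(family_map, "family"),
    shares_pathway = shares_annotation(pathway_map, "pathway"),
    interacts = interacts
  )
  rates <- c(
    pct_shared_family = 100 * mean(per_gene$shares_family),
    pct_shared_pathway = 100 * mean(per_gene$shares_pathway),
    pct_interacting = 100 * mean(per_gene$interacts)
  )
  list(per_gene = per_gene, rates = rates)
}
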