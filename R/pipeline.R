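# End-to-end orchestration: simulate (or read) inputs, call viability,
# select orthologues, classify essentiality, assign FUSIL bins, run
# enrichment, features and prioritisation, and report.

#' Pipeline configuration
#'
#' All analysis constants are surfaced here with the published defaults:
#' 28-pup minimum, 0.05 binomial significance, -0.45 essentiality
#' threshold (or `"fit"` to select it by F1 against the bundled reference
#' labelling), 50% procedure completeness, constraint thresholds
#' (HI percentile 10, LOEUF 0.35, pLI 0.90, o/e missense 0.8), 30%
#' paralogue identity and 0.7 network combined score.
#'
#' @param simulate a [fusil_sim_config()]; mutually exclusive with
#'   `paths`.
#' @param paths named list of TSV paths as written by
#'   [write_dataset_bundle()]; mutually exclusive with `simulate`.
#' @param alpha binomial significance level for subviability.
#' @param min_pups minimum fully informative litter size.
#' @param essentiality_threshold numeric cut-off or `"fit"`.
#' @param completeness_threshold procedure completeness cut-off.
#' @param hi_max,loeuf_max,pli_min,oe_missense_max constraint thresholds.
#' @param paralogue_identity_cutoff paralogue identity cut-off (percent).
#' @param network_min_score interaction combined-score cut-off.
#' @param rho_max tissue decorrelation threshold (absolute Spearman rho).
#' @param out_dir optional output directory for per-stage TSVs.
#' @return validated configuration (class `fusil_pipeline_config`).
#' @export
fusil_pipeline_config <- function(simulate = fusil_sim_config(),
                                  paths = NULL,
                                  alpha = 0.05,
                                  min_pups = 28,
                                  essentiality_threshold = -0.45,
                                  completeness_threshold = 0.5,
                                  hi_max = 10, loeuf_max = 0.35,
                                  pli_min = 0.90, oe_missense_max = 0.8,
                                  paralogue_identity_cutoff = 30,
                                  network_min_score = 0.7,
                                  rho_max = 0.8,
                                  out_dir = NULL) {
  if (is.null(simulate) == is.null(paths)) {
    fusil_stop("exactly one of `simulate` and `paths` must be given",
               class = "fusil_config_error")
  }
  check_prob(alpha, "alpha")
  check_prob(completeness_threshold, "completeness_threshold")
  check_prob(pli_min, "pli_min")
  if (!identical(essentiality_threshold, "fit") &&
      !is.numeric(essentiality_threshold)) {
    fusil_stop("`essentiality_threshold` must be numeric or \"fit\"",
               class = "fusil_config_error")
  }
  structure(as.list(environment()), class = "fusil_pipeline_config")
}

read_dataset_bundle <- function(paths) {
  required <- c("crosses", "scores", "orthology", "constraints",
                "disease", "evidence")
  missing <- setdiff(required, names(paths))
  if (length(missing) > 0) {
    fusil_stop(sprintf("`paths` is missing table(s): %s",
                       paste(missing, collapse = ", ")),
               class = "fusil_config_error")
  }
  bundle <- lapply(paths, read_fusil_tsv)
  for (nm in intersect(c("scores", "expression"), names(bundle))) {
    df <- as.data.frame(bundle[[nm]])
    rownames(df) <- df$gene_id
    bundle[[nm]] <- as.matrix(df[setdiff(names(df), "gene_id")])
  }
  bundle
}

#' Run the full FUSIL pipeline
#'
#' Executes simulate (or load) -> viability -> orthology -> essentiality
#' -> binning -> enrichment -> features -> prioritisation, logs per-stage
#' gene counts, optionally writes per-stage TSVs, and returns the report
#' bundle.  When the input is simulated, a truth-vs-called comparison is
#' included.
#'
#' @param config a [fusil_pipeline_config()].
#' @param quiet suppress progress messages (default `FALSE`).
#' @return named list: `viability`, `orthology`, `means`,
#'   `essentiality_threshold`, `threshold_search` (when fitted),
#'   `assignments`, `summary`, `enrichment`, `features`,
#'   `prioritisation`, and `truth_report` (simulated inputs only).
#' @export
run_fusil_pipeline <- function(config = fusil_pipeline_config(),
                               quiet = FALSE) {
  if (!inherits(config, "fusil_pipeline_config")) {
    fusil_stop("`config` must come from fusil_pipeline_config()",
               class = "fusil_config_error")
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  bundle <- if (!is.null(config$simulate)) {
    say("simulate: generating dataset (%d genes, seed %d)",
        config$simulate$n_genes, config$simulate$seed)
    generate_dataset(config$simulate)
  } else {
    read_dataset_bundle(config$paths)
  }

  # stage: viability --------------------------------------------------------
  viability <- gene_viability_calls(bundle$crosses, alpha = config$alpha,
                                    min_pups = config$min_pups)
  say("viability: %d genes called (%d lethal, %d subviable, %d viable)",
      nrow(viability), sum(viability$call == "lethal"),
      sum(viability$call == "subviable"), sum(viability$call == "viable"))

  # stage: orthology ---------------------------------------------------------
  accepted <- select_one_to_one(bundle$orthology)
  say("orthology: %d of %d edges accepted as one-to-one",
      nrow(accepted), nrow(bundle$orthology))

  # stage: essentiality ------------------------------------------------------
  means <- gene_mean_scores(bundle$scores)
  threshold_search <- NULL
  threshold <- config$essentiality_threshold
  if (identical(threshold, "fit")) {
    if (is.null(bundle$reference_labels)) {
      fusil_stop("threshold fitting requires a reference labelling",
                 class = "fusil_config_error")
    }
    threshold_search <- select_threshold_f1(means, bundle$reference_labels)
    threshold <- threshold_search$selected
    say("essentiality: F1-selected threshold %.2f", threshold)
  }
  means$essentiality <- classify_essential(means$mean_score, threshold)

  # stage: binning -----------------------------------------------------------
  pheno <- bundle$crosses |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      procedures_total = max(.data$procedures_total),
      procedures_done = max(.data$procedures_done),
      n_significant_phenotypes = max(.data$n_significant_phenotypes),
      .groups = "drop")
  binned_input <- viability |>
    dplyr::filter(.data$call %in% c("lethal", "subviable", "viable"),
                  .data$gene_id %in% accepted$human_id) |>
    dplyr::inner_join(means, by = "gene_id") |>
    dplyr::inner_join(pheno, by = "gene_id")
  assignments <- assign_fusil(
    binned_input$gene_id, binned_input$call, binned_input$essentiality,
    binned_input$n_significant_phenotypes, binned_input$procedures_done,
    binned_input$procedures_total,
    completeness_threshold = config$completeness_threshold)
  bin_summary <- summarize_bins(assignments)
  say("binning: %s",
      paste(sprintf("%s=%d", FUSIL_BINS,
                    vapply(FUSIL_BINS, function(b) {
                      sum(assignments$bin == b)
                    }, numeric(1))), collapse = " "))

  # stage: enrichment --------------------------------------------------------
  disease_sets <- split(bundle$disease$gene_id, bundle$disease$resource)
  disease_sets <- c(disease_sets,
                    list(any = unique(bundle$disease$gene_id)))
  enrichment <- bin_disease_enrichment(assignments, disease_sets)

  # stage: features ----------------------------------------------------------
  features <- list()
  if (!is.null(bundle$recomb_map) && !is.null(bundle$gene_positions)) {
    features$recombination <- average_recombination_per_gene(
      bundle$recomb_map, bundle$gene_positions)
  }
  if (!is.null(bundle$expression)) {
    features$retained_tissues <- drop_correlated_columns(
      bundle$expression, rho_max = config$rho_max)
  }
  if (!is.null(bundle$edges)) {
    features$network <- network_node_stats(
      bundle$edges, min_score = config$network_min_score)
  }
  if (!is.null(bundle$paralogues)) {
    features$paralogue_free <- paralogue_free_rate(
      assignments, bundle$paralogues,
      cutoff = config$paralogue_identity_cutoff)
  }
  if (!is.null(bundle$onset)) {
    features$onset <- earliest_onset(bundle$onset)
  }
  if (!is.null(bundle$systems)) {
    features$systems <- count_affected_systems(bundle$systems)
  }

  # stage: prioritisation ----------------------------------------------------
  dl_disease_sets <- disease_sets[setdiff(names(disease_sets), "any")]
  candidates <- filter_dl_candidates(
    assignments, dl_disease_sets, bundle$constraints,
    hi_max = config$hi_max, loeuf_max = config$loeuf_max,
    pli_min = config$pli_min)
  overlap <- consortium_overlap(candidates, bundle$evidence)
  final <- final_candidates(
    overlap$matrix |>
      dplyr::inner_join(
        bundle$evidence |>
          dplyr::select("gene_id", "variant_in_gnomad", "oe_missense"),
        by = "gene_id"),
    oe_missense_max = config$oe_missense_max)
  n_dl <- sum(assignments$bin == "DL")
  dl_nondisease <- setdiff(
    assignments$gene_id[assignments$bin == "DL"],
    unlist(dl_disease_sets, use.names = FALSE))
  funnel <- tibble::tibble(
    stage = c("DL", "DL_non_disease", "constraint_filtered",
              "any_consortium", "final"),
    n = c(n_dl, length(dl_nondisease), length(candidates),
          unname(overlap$regions["any"]), length(final)))
  say("prioritisation funnel: %s",
      paste(sprintf("%s=%d", funnel$stage, funnel$n), collapse = " -> "))
  prioritisation <- list(candidates = candidates, overlap = overlap,
                         final = final, funnel = funnel)

  # truth comparison ---------------------------------------------------------
  truth_report <- NULL
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth |>
      dplyr::left_join(dplyr::select(assignments, "gene_id", "bin"),
                       by = "gene_id")
    eligible <- tr$latent_class %in% c(FUSIL_BINS, "V.insuffProcedures") &
      !tr$is_borderline
    recovered <- !is.na(tr$bin) & tr$bin == tr$latent_class
    confusion <- tr |>
      dplyr::filter(!is.na(.data$bin)) |>
      dplyr::count(.data$latent_class, .data$bin)
    truth_report <- list(
      confusion = confusion,
      recovery_non_borderline = mean(recovered[eligible]),
      recovery_all = mean(
        recovered[tr$latent_class %in%
                    c(FUSIL_BINS, "V.insuffProcedures")]),
      n_non_borderline = sum(eligible))
    say("truth: non-borderline recovery %.4f (n=%d), overall %.4f",
        truth_report$recovery_non_borderline,
        truth_report$n_non_borderline, truth_report$recovery_all)
  }

  report <- list(viability = viability, orthology = accepted,
                 means = means, essentiality_threshold = threshold,
                 threshold_search = threshold_search,
                 assignments = assignments, summary = bin_summary,
                 enrichment = enrichment, features = features,
                 prioritisation = prioritisation,
                 truth_report = truth_report)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fusil_tsv(viability, file.path(config$out_dir, "viability.tsv"))
    write_fusil_tsv(assignments,
                    file.path(config$out_dir, "assignments.tsv"))
    write_fusil_tsv(bin_summary, file.path(config$out_dir, "summary.tsv"))
    write_fusil_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
    write_fusil_tsv(funnel, file.path(config$out_dir, "funnel.tsv"))
    write_fusil_tsv(tibble::tibble(gene_id = final),
                    file.path(config$out_dir, "final_candidates.tsv"))
    if (!is.null(truth_report)) {
      write_fusil_tsv(truth_report$confusion,
                      file.path(config$out_dir, "truth_confusion.tsv"))
    }
  }
  invisible(report)
}
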