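# Synthetic dataset generator with latent ground truth.
#
# Every input table the pipeline consumes is generated from a latent FUSIL
# class per gene, so parameter recovery (viability calls, threshold
# selection, enrichment odds ratios, prioritisation recall) can be tested
# against known truth without any external download.  Schemas are the
# package's own documented TSV dialects, not reproductions of any
# resource's native layout.

default_class_proportions <- c(
  CL = 0.09, DL = 0.17, SV = 0.09, VP = 0.42, VN = 0.07,
  V.insuffProcedures = 0.14, SV.outlier = 0.01, V.outlier = 0.01)

#' Synthetic dataset configuration
#'
#' Builds and validates the configuration for [generate_dataset()].  The
#' defaults encode the study conditions the pipeline is meant to operate
#' under: class proportions close to the real cross-tabulation margins,
#' Mendelian homozygote rates (0 for lethal classes, 0.25 for viable,
#' 1-8% for subviable), litters of 28 plus a Poisson(20) excess,
#' essential/non-essential mean proliferation scores of -1/0 with
#' between-gene spread 0.2 and cell-line noise 0.3, a 20% baseline disease
#' prevalence, and a 2.6-fold disease odds ratio for the DL bin.
#'
#' @param n_genes number of genes (default 5000).
#' @param n_cell_lines number of cell lines in the score matrix.
#' @param class_proportions named fractions over the latent classes
#'   (five bins, `V.insuffProcedures`, `SV.outlier`, `V.outlier`); must
#'   sum to 1.
#' @param hom_rate_lethal,hom_rate_viable homozygote birth rates for
#'   lethal-class and viable-class genes.
#' @param hom_rate_subviable_range interval from which subviable-class
#'   homozygote rates are drawn uniformly.
#' @param litter_min,litter_pois_mean genotyped litter size is
#'   `litter_min + Poisson(litter_pois_mean)`.
#' @param small_litter_fraction fraction of lines forced below
#'   `litter_min` pups (exercises the insufficient-sample path).
#' @param hemizygous_rate,conflicting_rate fractions of genes planted as
#'   hemizygous lines or with deliberately conflicting per-line calls.
#' @param score_mean_essential,score_mean_nonessential latent mean
#'   proliferation scores of essential and non-essential genes.
#' @param score_sd_between,score_sd_within between-gene and within-gene
#'   (across cell lines) standard deviations of the scores.
#' @param essentiality_threshold the cut-off the outlier classes are
#'   planted against (default -0.45).
#' @param outlier_offset_max outlier-class latent means are drawn in
#'   `(threshold - outlier_offset_max, threshold]`, i.e. just below the
#'   cut-off.
#' @param disease_baseline_prevalence baseline disease probability.
#' @param true_bin_or named odds ratios per bin; unlisted bins sit at the
#'   baseline.
#' @param orthology_ambiguity_rate fraction of genes given a duplicated
#'   maximum-support orthology edge (rejected by the one-to-one filter).
#' @param candidate_rate fraction of DL genes planted as true
#'   developmental-disorder candidates.
#' @param consortium_hit_rates list with elements `candidate` and
#'   `background`, each named probabilities for `in_100kgp`, `in_ddd`,
#'   `in_cmg`.
#' @param embryo_data_fraction fraction of lethal genes with embryo
#'   records; `embryo_incomplete_fraction` of those have a stage gap that
#'   leaves the window unassigned.
#' @param embryo_incomplete_fraction see above.
#' @param n_tissues,n_correlated_tissues expression tissues, plus extra
#'   near-duplicate columns exercising the decorrelation filter.
#' @param borderline_err a gene is marked borderline in the truth table
#'   when its analytic probability of misclassification (from its latent
#'   parameters and realized litter size) exceeds this value (default
#'   0.01: the gene itself cannot support a 99% recovery target).
#' @param alpha significance level of the subviability test (used for the
#'   borderline computation).
#' @param seed integer seed; the same configuration and seed reproduce
#'   the bundle exactly.
#' @return validated configuration object (class `fusil_sim_config`).
#' @export
fusil_sim_config <- function(
    n_genes = 5000,
    n_cell_lines = 100,
    class_proportions = default_class_proportions,
    hom_rate_lethal = 0,
    hom_rate_subviable_range = c(0.01, 0.08),
    hom_rate_viable = 0.25,
    litter_min = 28,
    litter_pois_mean = 20,
    small_litter_fraction = 0.02,
    hemizygous_rate = 0.003,
    conflicting_rate = 0.007,
    score_mean_essential = -1,
    score_mean_nonessential = 0,
    score_sd_between = 0.2,
    score_sd_within = 0.3,
    essentiality_threshold = -0.45,
    outlier_offset_max = 0.02,
    disease_baseline_prevalence = 0.2,
    true_bin_or = c(DL = 2.6),
    orthology_ambiguity_rate = 0.02,
    candidate_rate = 0.03,
    consortium_hit_rates = list(
      candidate = c(in_100kgp = 0.9, in_ddd = 0.7, in_cmg = 0.6),
      background = c(in_100kgp = 0.05, in_ddd = 0.05, in_cmg = 0.05)),
    embryo_data_fraction = 0.45,
    embryo_incomplete_fraction = 0.2,
    n_tissues = 8,
    n_correlated_tissues = 2,
    borderline_err = 0.01,
    alpha = 0.05,
    seed = 1L) {
  cfg <- as.list(environment())
  check_count(n_genes, "n_genes", min = 1)
  check_count(n_cell_lines, "n_cell_lines", min = 1)
  if (is.null(names(class_proportions)) ||
      !setequal(names(class_proportions), names(default_class_proportions))) {
    fusil_stop("`class_proportions` must be named over the latent classes",
               class = "fusil_config_error")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    fusil_stop("`class_proportions` must sum to 1",
               class = "fusil_config_error")
  }
  for (f in c("hom_rate_lethal", "hom_rate_viable", "small_litter_fraction",
              "hemizygous_rate", "conflicting_rate",
              "disease_baseline_prevalence", "orthology_ambiguity_rate",
              "candidate_rate", "embryo_data_fraction",
              "embryo_incomplete_fraction", "borderline_err", "alpha")) {
    check_prob(cfg[[f]], f)
  }
  check_prob(hom_rate_subviable_range, "hom_rate_subviable_range")
  if (length(hom_rate_subviable_range) != 2 ||
      diff(hom_rate_subviable_range) < 0) {
    fusil_stop("`hom_rate_subviable_range` must be an increasing interval",
               class = "fusil_config_error")
  }
  if (hom_rate_viable > 0.25 || max(hom_rate_subviable_range) > 0.25) {
    fusil_stop("homozygote rates cannot exceed the Mendelian expectation 0.25",
               class = "fusil_config_error")
  }
  if (any(true_bin_or <= 0)) {
    fusil_stop("`true_bin_or` entries must be positive odds ratios",
               class = "fusil_config_error")
  }
  for (side in c("candidate", "background")) {
    check_prob(consortium_hit_rates[[side]],
               paste0("consortium_hit_rates$", side))
  }
  check_count(abs(as.integer(seed)), "seed")
  structure(cfg, class = "fusil_sim_config")
}

#' Simulate one heterozygote-intercross genotyping outcome
#'
#' Homozygote count is Binomial(`total_pups`, `p_hom`); the remaining pups
#' split heterozygous : wild-type as 2:1 of the residual mass (the
#' Mendelian ratio among non-homozygotes).  Uses the current RNG state;
#' vectorised over `p_hom` / `total_pups`.
#'
#' @param p_hom homozygote birth probability, at most the Mendelian 0.25.
#' @param total_pups litter size(s), >= 1.
#' @return tibble with columns `n_total`, `n_hom`, `n_het`, `n_wt`.
#' @export
generate_cross <- function(p_hom, total_pups) {
  check_prob(p_hom, "p_hom")
  if (any(p_hom > 0.25)) {
    fusil_stop("p_hom exceeds the Mendelian expectation of 0.25",
               class = "fusil_config_error")
  }
  check_count(total_pups, "total_pups", min = 1)
  n <- pmax(length(p_hom), length(total_pups))
  p_hom <- rep_len(p_hom, n)
  total_pups <- rep_len(total_pups, n)
  n_hom <- rbinom(n, total_pups, p_hom)
  n_het <- rbinom(n, total_pups - n_hom, 2 / 3)
  tibble::tibble(n_total = total_pups, n_hom = n_hom, n_het = n_het,
                 n_wt = total_pups - n_hom - n_het)
}

#' Simulate per-gene disease status with configured bin odds ratios
#'
#' For a gene in bin `b` with target odds ratio `r`, the disease
#' probability solves `odds(p_b) = r * odds(baseline)`; genes in bins not
#' listed in `true_bin_or` use the baseline.  Uses the current RNG state.
#'
#' @param bins character vector of per-gene bins.
#' @param baseline baseline disease prevalence in (0, 1).
#' @param true_bin_or named positive odds ratios.
#' @return logical vector of disease status.
#' @export
generate_disease_flags <- function(bins, baseline, true_bin_or) {
  check_prob(baseline, "baseline")
  if (baseline <= 0 || baseline >= 1) {
    fusil_stop("`baseline` must lie strictly inside (0, 1)",
               class = "fusil_config_error")
  }
  if (length(true_bin_or) > 0 &&
      (is.null(names(true_bin_or)) || any(true_bin_or <= 0))) {
    fusil_stop("`true_bin_or` must be a named vector of positive odds ratios",
               class = "fusil_config_error")
  }
  odds0 <- baseline / (1 - baseline)
  r <- true_bin_or[bins]
  r[is.na(r)] <- 1
  odds_b <- as.numeric(r) * odds0
  p <- odds_b / (1 + odds_b)
  runif(length(bins)) < p
}

# largest homozygote count that still supports a subviable call at litter
# size n: fraction strictly below 12.5% and lower-tail binomial P < alpha
subviable_k_max <- function(n, alpha = 0.05) {
  vapply(n, function(nn) {
    kmax <- ceiling(0.125 * nn) - 1
    if (kmax < 0) return(-1L)
    ks <- 0:kmax
    ok <- pbinom(ks, nn, 0.25) < alpha
    if (!any(ok)) -1L else max(ks[ok])
  }, numeric(1))
}

# analytic misclassification probability given latent parameters; the
# essentiality side uses the sampling sd of the mean over L cell lines
analytic_misclass_prob <- function(latent_class, p_hom, n_total, latent_mean,
                                   threshold, sd_within, n_lines,
                                   alpha = 0.05, litter_min = 28) {
  kstar <- subviable_k_max(n_total, alpha)
  se <- sd_within / sqrt(n_lines)
  p_ess_called <- pnorm((threshold - latent_mean) / se)

  err_v <- numeric(length(latent_class))
  small <- n_total < litter_min
  lethal <- latent_class %in% c("CL", "DL")
  sv <- latent_class %in% c("SV", "SV.outlier")
  vi <- !lethal & !sv
  # lethal classes: always 0 homozygotes, so only small litters fail
  err_v[lethal] <- ifelse(small[lethal], 1, 0)
  # subviable: correct call requires 1 <= X <= kstar
  p_sub <- pbinom(kstar, n_total, p_hom) - dbinom(0, n_total, p_hom)
  err_v[sv] <- ifelse(small[sv] | kstar[sv] < 0, 1, 1 - p_sub[sv])
  # viable: miscalled when X <= kstar (lethal or subviable); small litters
  # are viable only when X >= 4
  err_v[vi] <- ifelse(small[vi],
                      pbinom(3, n_total[vi], p_hom[vi]),
                      ifelse(kstar[vi] < 0, 0,
                             pbinom(kstar[vi], n_total[vi], p_hom[vi])))

  essential_cls <- latent_class %in% c("CL", "SV.outlier", "V.outlier")
  err_e <- ifelse(essential_cls, 1 - p_ess_called, p_ess_called)
  1 - (1 - err_v) * (1 - err_e)
}

#' Generate the full synthetic dataset bundle
#'
#' Draws a latent FUSIL class per gene and emits every pipeline input
#' table plus the truth table.  The same configuration (including its
#' seed) always reproduces the identical bundle.
#'
#' @param config a [fusil_sim_config()] object.
#' @return a `fusil_bundle`: named list of tibbles/matrices with elements
#'   `truth`, `crosses`, `embryo`, `scores`, `reference_labels`,
#'   `orthology`, `constraints`, `disease`, `evidence`, `gene_positions`,
#'   `recomb_map`, `edges`, `complexes`, `paralogues`, `expression`,
#'   `onset`, `systems`, `families`, `pathways`, `reference_dd_genes`,
#'   and `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "fusil_sim_config")) {
    fusil_stop("`config` must come from fusil_sim_config()",
               class = "fusil_config_error")
  }
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  classes <- names(config$class_proportions)
  latent_class <- sample(classes, n, replace = TRUE,
                         prob = config$class_proportions)

  # latent homozygote rates ------------------------------------------------
  p_hom <- numeric(n)
  lethal <- latent_class %in% c("CL", "DL")
  sv <- latent_class %in% c("SV", "SV.outlier")
  p_hom[lethal] <- config$hom_rate_lethal
  p_hom[sv] <- runif(sum(sv), config$hom_rate_subviable_range[1],
                     config$hom_rate_subviable_range[2])
  p_hom[!lethal & !sv] <- config$hom_rate_viable

  # litters and crosses ----------------------------------------------------
  n_total <- config$litter_min + rpois(n, config$litter_pois_mean)
  small <- runif(n) < config$small_litter_fraction
  n_total[small] <- sample(10:(config$litter_min - 1), sum(small),
                           replace = TRUE)
  cross <- generate_cross(p_hom, n_total)

  hemizygous <- runif(n) < config$hemizygous_rate
  conflicting <- !hemizygous & runif(n) < config$conflicting_rate

  # phenotyping completeness and significant-phenotype counts
  procedures_total <- rep(20L, n)
  completeness <- runif(n, 0.55, 1)
  completeness[latent_class == "V.insuffProcedures"] <- runif(
    sum(latent_class == "V.insuffProcedures"), 0.05, 0.45)
  procedures_done <- as.integer(floor(completeness * procedures_total))
  n_sig <- integer(n)
  n_sig[latent_class == "VP"] <- 1L + rpois(sum(latent_class == "VP"), 2)
  n_sig[lethal | sv] <- rpois(sum(lethal | sv), 1)

  crosses <- tibble::tibble(
    line_id = paste0(gene_id, "_L1"),
    gene_id = gene_id,
    zygosity_class = ifelse(hemizygous, "hemizygous", "autosomal"),
    cross,
    procedures_total = procedures_total,
    procedures_done = procedures_done,
    n_significant_phenotypes = n_sig
  )
  # conflicting genes get a second line engineered to disagree: a Mendelian
  # (viable-looking) cross for lethal/subviable genes, a zero-homozygote
  # (lethal-looking) cross for viable genes
  if (any(conflicting)) {
    idx <- which(conflicting)
    litt <- config$litter_min + rpois(length(idx), config$litter_pois_mean)
    ls_idx <- lethal[idx] | sv[idx]
    # exact Mendelian counts look viable; zero homozygotes look lethal
    n_hom2 <- ifelse(ls_idx, round(0.25 * litt), 0L)
    n_het2 <- round((litt - n_hom2) * 2 / 3)
    second <- tibble::tibble(n_total = litt, n_hom = as.integer(n_hom2),
                             n_het = as.integer(n_het2),
                             n_wt = as.integer(litt - n_hom2 - n_het2))
    crosses <- dplyr::bind_rows(crosses, tibble::tibble(
      line_id = paste0(gene_id[idx], "_L2"),
      gene_id = gene_id[idx],
      zygosity_class = "autosomal",
      second,
      procedures_total = procedures_total[idx],
      procedures_done = procedures_done[idx],
      n_significant_phenotypes = n_sig[idx]
    ))
  }

  # windows of lethality and embryo records --------------------------------
  latent_window <- rep("none", n)
  latent_window[latent_class == "CL"] <- sample(
    c("early", "mid", "late"), sum(latent_class == "CL"), replace = TRUE,
    prob = c(0.8, 0.15, 0.05))
  latent_window[latent_class == "DL"] <- sample(
    c("early", "mid", "late"), sum(latent_class == "DL"), replace = TRUE,
    prob = c(0.25, 0.35, 0.4))
  embryo <- local({
    has_embryo <- lethal & runif(n) < config$embryo_data_fraction
    idx <- which(has_embryo)
    if (length(idx) == 0) {
      return(tibble::tibble(gene_id = character(0), stage = character(0),
                            n_scored = integer(0), n_live_hom = integer(0)))
    }
    recs <- lapply(idx, function(i) {
      w <- latent_window[i]
      last_alive <- switch(w, early = 0L, mid = 1L, late = 3L)
      stages <- seq_len(min(last_alive + 1L, 4L))
      n_scored <- 28L + rpois(length(stages), 4)
      n_live <- ifelse(seq_along(stages) <= last_alive,
                       1L + rbinom(length(stages), 8, 0.5), 0L)
      tibble::tibble(gene_id = gene_id[i], stage = EMBRYO_STAGES[stages],
                     n_scored = n_scored, n_live_hom = as.integer(n_live))
    })
    out <- dplyr::bind_rows(recs)
    # a fraction of genes lose an intermediate stage, leaving the window
    # ambiguous
    incomplete <- gene_id[idx][runif(length(idx)) <
                                 config$embryo_incomplete_fraction]
    drop <- out$gene_id %in% incomplete & out$stage %in%
      c("E9.5", "E12.5") & out$n_live_hom > 0
    out[!drop, , drop = FALSE]
  })

  # proliferation scores ----------------------------------------------------
  essential_cls <- latent_class %in% c("CL", "SV.outlier", "V.outlier")
  latent_mean <- rnorm(
    n,
    ifelse(essential_cls, config$score_mean_essential,
           config$score_mean_nonessential),
    config$score_sd_between)
  outlier <- latent_class %in% c("SV.outlier", "V.outlier")
  latent_mean[outlier] <- config$essentiality_threshold -
    runif(sum(outlier), 0, config$outlier_offset_max)
  scores <- matrix(
    rnorm(n * config$n_cell_lines, mean = rep(latent_mean,
                                              config$n_cell_lines),
          sd = config$score_sd_within),
    nrow = n, ncol = config$n_cell_lines,
    dimnames = list(gene_id, sprintf("cell_line_%03d",
                                     seq_len(config$n_cell_lines))))
  # reference essentiality labelling, as an earlier study would provide:
  # latent means observed with small noise, thresholded at the cut-off
  reference_labels <- tibble::tibble(
    gene_id = gene_id,
    label = ifelse(latent_mean + rnorm(n, 0, 0.05) <=
                     config$essentiality_threshold,
                   "essential", "non_essential"))

  # orthology ---------------------------------------------------------------
  n_methods <- sample(9:12, n, replace = TRUE)
  orthology <- tibble::tibble(
    human_id = gene_id,
    mouse_id = paste0("m", gene_id),
    n_methods = n_methods,
    human_coding = TRUE,
    mouse_coding = TRUE)
  ambiguous <- runif(n) < config$orthology_ambiguity_rate
  if (any(ambiguous)) {
    idx <- which(ambiguous)
    orthology <- dplyr::bind_rows(orthology, tibble::tibble(
      human_id = paste0("dup_", gene_id[idx]),
      mouse_id = paste0("m", gene_id[idx]),
      n_methods = n_methods[idx],          # duplicated maximum: both rejected
      human_coding = TRUE,
      mouse_coding = TRUE))
  }

  # disease status and resources --------------------------------------------
  main_bin <- ifelse(latent_class %in% FUSIL_BINS, latent_class,
                     ifelse(latent_class == "SV.outlier", "SV", "VP"))
  is_disease <- generate_disease_flags(main_bin,
                                       config$disease_baseline_prevalence,
                                       config$true_bin_or)
  # planted candidates: DL genes forced disease-free.  Candidates are
  # drawn from genes not simultaneously planted as exclusions (hemizygous,
  # conflicting, duplicated-orthologue) and with clearly non-essential
  # latent scores, so that funnel recall probes the prioritisation logic
  # itself rather than upstream dropout.
  dl_idx <- which(latent_class == "DL" & !hemizygous & !conflicting &
                    !ambiguous & latent_mean > -0.35 &
                    n_total >= config$litter_min)
  n_cand <- round(config$candidate_rate * sum(latent_class == "DL"))
  n_cand <- min(n_cand, length(dl_idx))
  cand_idx <- sample(dl_idx, n_cand)
  is_candidate <- seq_len(n) %in% cand_idx
  is_disease[is_candidate] <- FALSE

  resources <- c("OMIM", "ORPHANET", "DECIPHER")
  disease <- local({
    idx <- which(is_disease)
    member <- matrix(runif(length(idx) * 3) < rep(c(0.7, 0.5, 0.3),
                                                  each = length(idx)),
                     ncol = 3, dimnames = list(NULL, resources))
    none <- rowSums(member) == 0
    member[cbind(which(none), sample(3, sum(none), replace = TRUE))] <- TRUE
    tibble::tibble(
      gene_id = rep(gene_id[idx], 3),
      resource = rep(resources, each = length(idx)),
      member = as.vector(member)) |>
      dplyr::filter(.data$member) |>
      dplyr::select("gene_id", "resource")
  })

  # constraint scores: lethal classes more intolerant; planted candidates
  # are forced past the haploinsufficiency filter
  constrained <- lethal | latent_class == "SV"
  constraints <- tibble::tibble(
    gene_id = gene_id,
    pli = ifelse(constrained, rbeta(n, 8, 2), rbeta(n, 2, 8)),
    loeuf = ifelse(constrained, runif(n, 0.05, 0.6), runif(n, 0.4, 1.6)),
    hi_percentile = ifelse(constrained, runif(n, 0, 40), runif(n, 15, 100)),
    oe_missense = ifelse(constrained, runif(n, 0.2, 0.9),
                         runif(n, 0.5, 1.4)),
    prob_mutation = runif(n, 0, 1e-4),
    transcript_length_max = as.integer(round(rlnorm(n, 8, 0.6))),
    gims = ifelse(constrained, rnorm(n, 1, 0.3), rnorm(n, 0, 0.3)))
  constraints$pli[is_candidate] <- runif(n_cand, 0.95, 1)

  # consortium evidence -----------------------------------------------------
  hit <- function(rates, m) {
    out <- matrix(FALSE, nrow = m, ncol = 3,
                  dimnames = list(NULL, c("in_100kgp", "in_ddd", "in_cmg")))
    for (f in colnames(out)) out[, f] <- runif(m) < rates[[f]]
    out
  }
  ev <- hit(config$consortium_hit_rates$background, n)
  ev[cand_idx, ] <- hit(config$consortium_hit_rates$candidate, n_cand)
  evidence <- tibble::tibble(
    gene_id = gene_id,
    in_100kgp = ev[, "in_100kgp"],
    in_ddd = ev[, "in_ddd"],
    in_cmg = ev[, "in_cmg"],
    variant_in_gnomad = ifelse(is_candidate, FALSE, runif(n) < 0.5),
    oe_missense = ifelse(is_candidate, runif(n, 0.2, 0.7),
                         constraints$oe_missense))

  # genome layout and recombination map -------------------------------------
  n_chrom <- 19L
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
  gene_start <- integer(n)
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    gene_start[i] <- cumsum(5000L + rpois(length(i), 45000))
  }
  gene_len <- 2000L + rpois(n, 20000)
  gene_positions <- tibble::tibble(
    gene_id = gene_id, chrom = chrom,
    start = gene_start, end = gene_start + gene_len)
  recomb_map <- local({
    m <- 2L * n
    rc <- sample(unique(chrom), m, replace = TRUE)
    span <- tapply(gene_positions$end, gene_positions$chrom, max)
    st <- as.integer(floor(runif(m) * pmax(span[rc] - 10000, 1)))
    tibble::tibble(chrom = rc, start = st, end = st + 10000L,
                   rate = rlnorm(m, meanlog = 0, sdlog = 0.8))
  })

  # interaction network: lethal-class genes draw more edges -----------------
  w <- ifelse(latent_class == "CL", 3, ifelse(latent_class == "DL", 2, 1))
  n_edges <- 3L * n
  ga <- sample(gene_id, n_edges, replace = TRUE, prob = w)
  gb <- sample(gene_id, n_edges, replace = TRUE, prob = w)
  keep <- ga != gb
  edges <- tibble::tibble(gene_a = pmin(ga[keep], gb[keep]),
                          gene_b = pmax(ga[keep], gb[keep]),
                          score = runif(sum(keep), 0.3, 1)) |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)

  # complexes, paralogues, expression, onset, systems -----------------------
  p_complex <- ifelse(latent_class == "CL", 0.6,
                      ifelse(latent_class == "DL", 0.35, 0.15))
  in_complex <- runif(n) < p_complex
  complexes <- tibble::tibble(
    gene_id = gene_id[in_complex],
    complex_id = sprintf("CPX%04d",
                         sample(ceiling(n / 20), sum(in_complex),
                                replace = TRUE)))

  p_para <- ifelse(lethal, 0.35, 0.7)
  has_para <- runif(n) < p_para
  paralogues <- tibble::tibble(
    gene_id = gene_id[has_para],
    partner_id = sample(gene_id, sum(has_para), replace = TRUE),
    identity = runif(sum(has_para), 5, 95))

  expr_base <- c(CL = 5, DL = 4.5, SV = 4, VP = 3.5, VN = 3,
                 V.insuffProcedures = 3.5, SV.outlier = 4.5,
                 V.outlier = 4.5)[latent_class]
  tis <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  expression <- matrix(rnorm(n * config$n_tissues, expr_base, 1),
                       nrow = n, dimnames = list(gene_id, tis))
  if (config$n_correlated_tissues > 0) {
    dup <- expression[, seq_len(config$n_correlated_tissues), drop = FALSE] +
      rnorm(n * config$n_correlated_tissues, 0, 0.05)
    colnames(dup) <- sprintf("tissue_dup_%02d",
                             seq_len(config$n_correlated_tissues))
    expression <- cbind(expression, dup)
  }

  onset_w <- list(
    CL = c(6, 3, 2, 1, 1, 1, 1), DL = c(6, 3, 2, 1, 1, 1, 1),
    SV = c(3, 3, 2, 2, 1, 1, 1), VP = c(1, 1, 2, 2, 2, 3, 1),
    VN = c(1, 1, 1, 2, 2, 3, 2))
  onset <- local({
    idx <- which(is_disease)
    picks <- vapply(idx, function(i) {
      sample(ONSET_LEVELS, 1, prob = onset_w[[main_bin[i]]])
    }, character(1))
    extra <- idx[runif(length(idx)) < 0.3]
    tibble::tibble(
      gene_id = c(gene_id[idx], gene_id[extra]),
      onset = c(picks, sample(ONSET_LEVELS, length(extra), replace = TRUE)))
  })

  system_pool <- sprintf("system_%02d", 1:20)
  lam <- c(CL = 3, DL = 3, SV = 2.5, VP = 2, VN = 1.5)[main_bin]
  systems <- local({
    idx <- which(is_disease)
    ns <- 1L + rpois(length(idx), lam[idx])
    tibble::tibble(
      gene_id = rep(gene_id[idx], ns),
      system = unlist(lapply(ns, function(k) {
        sample(system_pool, min(k, length(system_pool)))
      })))
  })

  families <- tibble::tibble(
    gene_id = gene_id,
    family = sprintf("FAM%04d", sample(300, n, replace = TRUE)))
  pathways <- tibble::tibble(
    gene_id = gene_id,
    pathway = sprintf("PTH%04d", sample(200, n, replace = TRUE)))
  reference_dd_genes <- sample(gene_id[is_disease],
                               min(100, sum(is_disease)))

  # truth table with the ex-ante borderline flag ----------------------------
  err <- analytic_misclass_prob(
    latent_class, p_hom, n_total, latent_mean,
    config$essentiality_threshold, config$score_sd_within,
    config$n_cell_lines, alpha = config$alpha,
    litter_min = config$litter_min)
  err[hemizygous | conflicting] <- NA_real_
  truth <- tibble::tibble(
    gene_id = gene_id,
    latent_class = latent_class,
    latent_window = latent_window,
    latent_hom_rate = p_hom,
    latent_mean_score = latent_mean,
    is_disease_gene = is_disease,
    is_true_candidate = is_candidate,
    is_hemizygous = hemizygous,
    is_conflicting = conflicting,
    is_ambiguous_orthology = ambiguous,
    misclass_prob = err,
    is_borderline = is.na(err) | err > config$borderline_err |
      ambiguous | latent_class %in% c("SV.outlier", "V.outlier")
  )

  structure(list(
    truth = truth, crosses = crosses, embryo = embryo, scores = scores,
    reference_labels = reference_labels, orthology = orthology,
    constraints = constraints, disease = disease, evidence = evidence,
    gene_positions = gene_positions, recomb_map = recomb_map,
    edges = edges, complexes = complexes, paralogues = paralogues,
    expression = expression, onset = onset, systems = systems,
    families = families, pathways = pathways,
    reference_dd_genes = reference_dd_genes,
    config = config), class = "fusil_bundle")
}

#' Write a dataset bundle to TSV files with a manifest
#'
#' One TSV per table (matrices gain a leading `gene_id` column) plus a
#' JSON manifest recording the configuration, seed and per-file MD5
#' checksums.
#'
#' @param bundle a `fusil_bundle` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_dataset_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "fusil_bundle")) {
    fusil_stop("`bundle` must come from generate_dataset()",
               class = "fusil_config_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- bundle[setdiff(names(bundle), "config")]
  files <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.matrix(x)) {
      x <- tibble::as_tibble(x, rownames = "gene_id")
    } else if (is.atomic(x)) {
      x <- tibble::tibble(gene_id = x)
    }
    path <- file.path(dir, paste0(nm, ".tsv"))
    write_fusil_tsv(x, path)
    files[nm] <- path
  }
  manifest <- list(
    config = unclass(bundle$config),
    seed = bundle$config$seed,
    checksums = as.list(tools::md5sum(unname(files))))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
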