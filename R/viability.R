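# Mouse knockout primary viability calling and windows of lethality.
#
# A knockout line is genotyped from a heterozygote intercross; under
# Mendelian segregation 25% of pups are expected to be homozygous null.
# Absence of live homozygotes calls the gene lethal; a significant deficit
# (< 12.5% homozygotes, i.e. half the expectation, with a one-sided exact
# binomial P < alpha) calls it subviable; otherwise viable.  Lines with
# fewer than 28 genotyped pups are only informative when at least 4
# homozygotes were seen (>= 14% of a 28-pup litter), which supports a
# viable call; otherwise the sample is insufficient.

#' Call primary viability for knockout lines
#'
#' Applies the primary viability decision rule to per-line genotyping
#' counts.  The decision order is: (1) hemizygous lines are excluded;
#' (2) lines with fewer than `min_pups` genotyped pups are called viable
#' when `n_hom >= 4`, otherwise insufficient; (3) zero homozygotes calls
#' lethal; (4) a homozygote fraction below half the Mendelian expectation
#' (`< 0.125`) together with a one-sided lower-tail exact binomial
#' `P(X <= n_hom; n_total, 0.25) < alpha` calls subviable; (5) anything
#' else is viable.
#'
#' @param obs data frame with columns `line_id`, `gene_id`,
#'   `zygosity_class` (`"autosomal"` or `"hemizygous"`), `n_total`, `n_hom`.
#' @param alpha significance level for the subviability binomial test.
#' @param min_pups minimum genotyped litter size for a fully informative
#'   line (default 28).
#' @return tibble with one row per line: `line_id`, `gene_id`, `call`,
#'   `hom_fraction`, `binom_p` (`NA` where the test was not evaluated).
#' @examples
#' obs <- tibble::tibble(line_id = "L1", gene_id = "G1",
#'                       zygosity_class = "autosomal",
#'                       n_total = 28, n_hom = 0)
#' call_primary_viability(obs)
#' @export
call_primary_viability <- function(obs, alpha = 0.05, min_pups = 28) {
  check_columns(obs, c("line_id", "gene_id", "zygosity_class",
                       "n_total", "n_hom"), "viability observations")
  if (any(obs$n_hom > obs$n_total)) {
    fusil_stop("n_hom exceeds n_total for at least one line",
               class = "fusil_data_error")
  }
  if (any(obs$n_total < 1)) {
    fusil_stop("n_total must be >= 1", class = "fusil_data_error")
  }
  check_prob(alpha, "alpha")

  n <- obs$n_total
  k <- obs$n_hom
  frac <- k / n
  pval <- pbinom(k, n, 0.25)

  call <- rep("viable", nrow(obs))
  call[frac < 0.125 & pval < alpha] <- "subviable"
  call[k == 0] <- "lethal"
  small <- n < min_pups
  call[small] <- ifelse(k[small] >= 4, "viable", "insufficient")
  hemi <- obs$zygosity_class == "hemizygous"
  call[hemi] <- "excluded_hemizygous"

  tibble::tibble(
    line_id = obs$line_id,
    gene_id = obs$gene_id,
    call = call,
    hom_fraction = frac,
    binom_p = ifelse(small | hemi, NA_real_, pval)
  )
}

#' Resolve per-line viability calls to a single gene-level call
#'
#' Hemizygous lines exclude the gene outright.  Insufficient lines carry no
#' category and are dropped.  The remaining substantive calls (lethal,
#' subviable, viable) must be unanimous; genes appearing in more than one
#' category are excluded as conflicting.
#'
#' @param calls character vector of per-line calls for one gene.
#' @return single character call.
#' @export
resolve_gene_calls <- function(calls) {
  if (length(calls) == 0) {
    fusil_stop("no viability calls supplied", class = "fusil_data_error")
  }
  bad <- setdiff(calls, VIABILITY_CALLS)
  if (length(bad) > 0) {
    fusil_stop(sprintf("unknown viability call(s): %s",
                       paste(bad, collapse = ", ")),
               class = "fusil_data_error")
  }
  if (any(calls == "excluded_hemizygous")) return("excluded_hemizygous")
  substantive <- unique(calls[calls %in% c("lethal", "subviable", "viable")])
  if (length(substantive) == 0) return("insufficient")
  if (length(substantive) > 1) return("excluded_conflicting")
  substantive
}

#' Gene-level viability calls from raw observations
#'
#' Convenience wrapper: applies [call_primary_viability()] per line and
#' [resolve_gene_calls()] per gene.
#'
#' @inheritParams call_primary_viability
#' @return tibble with columns `gene_id`, `call`, `n_lines`.
#' @export
gene_viability_calls <- function(obs, alpha = 0.05, min_pups = 28) {
  line_calls <- call_primary_viability(obs, alpha = alpha, min_pups = min_pups)
  line_calls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(call = resolve_gene_calls(.data$call),
                     n_lines = dplyr::n(), .groups = "drop")
}

#' Assign a window of lethality from staged embryo viability
#'
#' Lethal lines enter a secondary screen scoring live homozygous embryos
#' (heartbeat at dissection) at E9.5, E12.5, E14.5/E15.5 and E18.5.  A gene
#' is dead at a stage when no live homozygotes were found among at least
#' `min_scored` scored embryos, and alive when any live homozygote was seen
#' (any sample size).  The fine window between the last alive stage and the
#' first dead stage is collapsed into three groups: prior to E9.5 is early;
#' E9.5--E12.5 and E12.5--E14.5/15.5 are mid; everything later, including
#' lines still alive at E18.5 but lethal preweaning, is late.  Stage gaps
#' that leave the window spanning more than one fine interval are
#' unassigned.
#'
#' @param records data frame for one gene with columns `stage` (one of
#'   `r paste(EMBRYO_STAGES, collapse = ", ")`), `n_scored`, `n_live_hom`.
#' @param min_scored minimum embryos scored for a dead-at-stage call.
#' @return one of `"early"`, `"mid"`, `"late"`, `"unassigned"`.
#' @export
assign_lethality_window <- function(records, min_scored = 28) {
  check_columns(records, c("stage", "n_scored", "n_live_hom"),
                "embryo records")
  if (nrow(records) == 0) return("unassigned")
  if (any(records$n_live_hom > records$n_scored)) {
    fusil_stop("n_live_hom exceeds n_scored", class = "fusil_data_error")
  }
  if (anyDuplicated(records$stage)) {
    st <- split(records, records$stage)
    contradictory <- vapply(st, function(d) {
      length(unique(d$n_live_hom > 0)) > 1
    }, logical(1))
    if (any(contradictory)) {
      fusil_stop("contradictory embryo records for the same stage",
                 class = "fusil_data_error")
    }
  }
  idx <- match(records$stage, EMBRYO_STAGES)
  if (anyNA(idx)) {
    fusil_stop("unknown embryo stage", class = "fusil_data_error")
  }
  alive <- records$n_live_hom > 0
  dead <- records$n_live_hom == 0 & records$n_scored >= min_scored

  last_alive <- if (any(alive)) max(idx[alive]) else 0L
  first_dead <- if (any(dead)) min(idx[dead]) else NA_integer_

  if (!is.na(first_dead) && first_dead <= last_alive) return("unassigned")

  if (is.na(first_dead)) {
    # no dead stage observed: only alive-at-E18.5 pins the (late) window
    if (last_alive == 4L) return("late")
    return("unassigned")
  }
  # window is the interval (last_alive, first_dead]; unambiguous only when
  # the stages are adjacent (or death at the first stage with nothing before)
  if (first_dead - last_alive != 1L) return("unassigned")
  switch(first_dead, "early", "mid", "mid", "late")
}
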