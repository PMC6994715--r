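# Independent oracles used across the suite.  Each re-evaluates a rule
# directly from its definition, separately from the package's
# implementation path.

# literal transcription of the primary viability rule for a single
# autosomal line
oracle_viability <- function(n_total, n_hom, alpha = 0.05) {
  if (n_total < 28) {
    if (n_hom >= 4) return("viable") else return("insufficient")
  }
  if (n_hom == 0) return("lethal")
  if (n_hom / n_total < 0.125 &&
      pbinom(n_hom, n_total, 0.25) < alpha) return("subviable")
  "viable"
}

# brute-force one-to-one orthologue selection: for every edge, re-apply
# the definition against all other surviving edges
oracle_one_to_one <- function(edges, min_support = 5) {
  surv <- edges[edges$n_methods >= min_support &
                  (edges$human_coding | edges$mouse_coding), , drop = FALSE]
  if (nrow(surv) == 0) return(surv)
  keep <- vapply(seq_len(nrow(surv)), function(i) {
    h <- surv$human_id[i]; m <- surv$mouse_id[i]; s <- surv$n_methods[i]
    rivals_h <- surv$n_methods[surv$human_id == h & surv$mouse_id != m]
    rivals_m <- surv$n_methods[surv$mouse_id == m & surv$human_id != h]
    all(s > rivals_h) && all(s > rivals_m)
  }, logical(1))
  surv[keep, , drop = FALSE]
}

# direct BH step-up formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive grid F1 evaluation with the same tie-break definition
oracle_threshold_f1 <- function(means, labels, grid) {
  f1 <- vapply(grid, function(t) {
    pred <- means <= t
    tp <- sum(pred & labels == "essential")
    fp <- sum(pred & labels != "essential")
    fn <- sum(!pred & labels == "essential")
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  best <- which(f1 == max(f1))
  mid <- mean(range(best))
  grid[best[which.min(abs(best - mid))]]
}

# all-pairs interval-to-gene assignment (0-based half-open coordinates)
oracle_recombination <- function(intervals, genes) {
  interval_gene <- integer(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    same <- which(genes$chrom == intervals$chrom[i])
    if (length(same) == 0) {
      interval_gene[i] <- NA_integer_
      next
    }
    d <- vapply(same, function(j) {
      # gap between [s1,e1) and [s2,e2); 0 if overlapping or abutting
      max(0, max(intervals$start[i], genes$start[j]) -
            min(intervals$end[i], genes$end[j]))
    }, numeric(1))
    cand <- same[d == min(d)]
    interval_gene[i] <- cand[which.min(genes$start[cand])]
  }
  ok <- !is.na(interval_gene)
  agg <- tapply(intervals$rate[ok], genes$gene_id[interval_gene[ok]], mean)
  tibble::tibble(gene_id = names(agg), recomb_rate = as.numeric(agg))
}

# topological coefficient straight from the definition, via neighbour sets
oracle_topo_coeff <- function(adj_list) {
  nodes <- names(adj_list)
  vapply(nodes, function(n) {
    nb <- adj_list[[n]]
    k <- length(nb)
    if (k < 2) return(0)
    others <- setdiff(nodes, n)
    j <- vapply(others, function(m) {
      shared <- length(intersect(nb, adj_list[[m]]))
      if (shared == 0) return(NA_real_)
      shared + as.numeric(m %in% nb)
    }, numeric(1))
    j <- j[!is.na(j)]
    if (length(j) == 0) return(0)
    mean(j / k)
  }, numeric(1))
}

# small random 2x2 tables with bounded margins
random_table <- function(max_margin = 30) {
  n <- sample(4:max_margin, 1)
  a <- sample(0:n, 1); b <- sample(0:(max_margin - 1), 1)
  c_ <- sample(0:(max_margin - 1), 1); d <- sample(0:(max_margin - 1), 1)
  c(a = a, b = b, c = c_, d = d)
}

small_sim_config <- function(n_genes = 400, seed = 11, ...) {
  fusil_sim_config(n_genes = n_genes, n_cell_lines = 25, seed = seed, ...)
}
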