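test_that("Wald odds ratio and normal-approximation interval are exact", {
  expect_equal(odds_ratio_wald(10, 10, 10, 10)$or_hat, 1)
  res <- odds_ratio_wald(20, 10, 10, 20)
  expect_equal(res$or_hat, 4)
  se <- sqrt(0.3)
  expect_equal(res$ci_low, exp(log(4) - qnorm(0.975) * se))
  expect_equal(res$ci_high, exp(log(4) + qnorm(0.975) * se))
  expect_equal(round(res$ci_low, 3), 1.367)
  expect_equal(round(res$ci_high, 2), 11.70)
  # zero cells flag degenerate estimates unless Haldane-corrected
  z <- odds_ratio_wald(0, 5, 5, 5)
  expect_true(z$degenerate)
  expect_equal(z$or_hat, 0)
  expect_equal(odds_ratio_wald(5, 5, 0, 5)$or_hat, Inf)
  h <- odds_ratio_wald(0, 5, 5, 5, haldane = TRUE)
  expect_false(h$degenerate)
  expect_equal(h$or_hat, (0.5 * 5.5) / (5.5 * 5.5))
  expect_error(odds_ratio_wald(-1, 1, 1, 1), class = "fusil_data_error")
})

test_that("two-sided Fisher p matches enumeration and the stats oracle", {
  expect_equal(fisher_two_sided(3, 1, 1, 3), 34 / 70)
  expect_equal(fisher_two_sided(0, 0, 5, 5), 1)  # degenerate margins
  set.seed(99)
  for (i in 1:1000) {
    t <- random_table(30)
    got <- fisher_two_sided(t["a"], t["b"], t["c"], t["d"])
    want <- fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(got, min(want, 1), tolerance = 1e-12,
                 label = paste(t, collapse = ","))
  }
})

test_that("Fisher p is invariant under transposition and row/column swaps", {
  set.seed(12)
  for (i in 1:100) {
    t <- random_table(25)
    p <- fisher_two_sided(t["a"], t["b"], t["c"], t["d"])
    expect_equal(fisher_two_sided(t["a"], t["c"], t["b"], t["d"]), p)
    expect_equal(fisher_two_sided(t["c"], t["d"], t["a"], t["b"]), p)
    expect_equal(fisher_two_sided(t["b"], t["a"], t["d"], t["c"]), p)
  }
})

test_that("BH adjustment matches the step-up formula and preserves order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # order-preserving
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "fusil_data_error")
})

test_that("bin enrichment builds resource-vs-clean tables and recovers OR", {
  set.seed(1234)
  bins <- sample(FUSIL_BINS, 5000, replace = TRUE,
                 prob = c(0.1, 0.19, 0.1, 0.47, 0.14))
  flags <- generate_disease_flags(bins, 0.20, c(DL = 2.6))
  asg <- tibble::tibble(gene_id = paste0("G", seq_along(bins)), bin = bins)
  res <- bin_disease_enrichment(
    asg, list(mendelian = asg$gene_id[flags]))
  dl <- res[res$bin == "DL", ]
  expect_equal(dl$a + dl$b, sum(bins == "DL"))
  expect_gt(dl$or_hat, 1.8)
  expect_lt(dl$or_hat, 3.5)
  expect_lt(dl$p_adjusted, 0.001)
  expect_true(all(res$p_adjusted >= res$p_fisher - 1e-15))
  # genes annotated only in other resources leave that resource's table
  two <- bin_disease_enrichment(
    asg[1:100, ], list(r1 = asg$gene_id[1:10], r2 = asg$gene_id[11:30]))
  r1 <- two[two$resource == "r1", ]
  # 10 resource genes + 70 clean genes; the 20 r2-only genes are excluded
  expect_equal(unique(r1$a + r1$b + r1$c + r1$d), 80)
})

test_that("bin identical to the disease set gives an infinite flagged OR", {
  asg <- tibble::tibble(gene_id = paste0("G", 1:40),
                        bin = rep(c("DL", "VN"), each = 20))
  res <- bin_disease_enrichment(asg, list(r = asg$gene_id[1:20]))
  dl <- res[res$bin == "DL", ]
  expect_true(dl$degenerate)
  expect_equal(dl$or_hat, Inf)
})

test_that("term over-representation matches hypergeometric enumeration", {
  universe <- paste0("G", 1:40)
  study <- universe[1:10]
  # study equal to the universe: nothing can be enriched
  res_all <- term_overrepresentation(universe,
                                     list(t1 = universe[1:5]), universe)
  expect_equal(res_all$p_hyper, 1)
  # fully nested term equal to the study set: point-mass tail
  res <- term_overrepresentation(study, list(t = study), universe)
  expect_equal(res$p_hyper, 1 / choose(40, 10))
  # small random instances against an exhaustive tail sum
  set.seed(21)
  for (i in 1:50) {
    N <- sample(10:25, 1)
    uni <- paste0("G", 1:N)
    st <- sample(uni, sample(2:(N - 1), 1))
    tg <- sample(uni, sample(1:N, 1))
    got <- term_overrepresentation(st, list(t = tg), uni)$p_hyper
    x <- length(intersect(st, tg))
    want <- sum(vapply(x:min(length(tg), length(st)), function(j) {
      choose(length(tg), j) * choose(N - length(tg), length(st) - j) /
        choose(N, length(st))
    }, numeric(1)))
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(term_overrepresentation(c("X"), list(t = "G1"), "G1"),
               class = "fusil_data_error")
})

test_that("null disease flags give calibrated uniform-ish adjusted p", {
  set.seed(61)
  hits <- 0; reps <- 40
  for (i in seq_len(reps)) {
    bins <- sample(FUSIL_BINS, 2000, replace = TRUE)
    flags <- generate_disease_flags(bins, 0.2, c(DL = 1))
    asg <- tibble::tibble(gene_id = paste0("G", seq_along(bins)),
                          bin = bins)
    res <- bin_disease_enrichment(asg,
                                  list(r = asg$gene_id[flags]))
    hits <- hits + any(res$p_fisher < 0.05 / 5)  # Bonferroni-level check
  }
  expect_lte(hits / reps, 0.15)
})
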