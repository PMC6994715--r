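test_that("recombination intervals map to the closest gene, ties upstream", {
  genes <- tibble::tibble(gene_id = c("A", "B"), chrom = "chr1",
                          start = c(100, 500), end = c(200, 600))
  # interval inside gene A
  iv <- tibble::tibble(chrom = "chr1", start = 120, end = 150, rate = 2.5)
  out <- average_recombination_per_gene(iv, genes)
  expect_equal(out$recomb_rate[out$gene_id == "A"], 2.5)
  # two intervals nearest to the same gene average their rates
  iv2 <- tibble::tibble(chrom = "chr1", start = c(90, 210),
                        end = c(95, 220), rate = c(1, 3))
  out2 <- average_recombination_per_gene(iv2, genes)
  expect_equal(out2$recomb_rate[out2$gene_id == "A"], 2)
  # equidistant interval goes to the upstream (lower-coordinate) gene
  iv3 <- tibble::tibble(chrom = "chr1", start = 345, end = 355, rate = 7)
  out3 <- average_recombination_per_gene(iv3, genes)
  expect_equal(out3$gene_id, "A")
  # intervals on geneless chromosomes are dropped with a warning
  expect_warning(
    average_recombination_per_gene(
      dplyr::bind_rows(iv, tibble::tibble(chrom = "chrX", start = 1,
                                          end = 10, rate = 9)),
      genes),
    "no genes")
})

test_that("random layouts equal the brute-force all-pairs assignment", {
  set.seed(14)
  for (i in 1:30) {
    ng <- sample(3:12, 1); ni <- sample(3:20, 1)
    genes <- tibble::tibble(
      gene_id = paste0("G", 1:ng),
      chrom = sample(c("c1", "c2"), ng, replace = TRUE),
      start = sample(0:5000, ng))
    genes$end <- genes$start + sample(50:500, ng, replace = TRUE)
    iv <- tibble::tibble(
      chrom = sample(c("c1", "c2"), ni, replace = TRUE),
      start = sample(0:5000, ni))
    iv$end <- iv$start + sample(20:200, ni, replace = TRUE)
    iv$rate <- runif(ni, 0, 5)
    if (!all(iv$chrom %in% genes$chrom)) next
    got <- average_recombination_per_gene(iv, genes)
    want <- oracle_recombination(iv, genes)
    got <- got[order(got$gene_id), ]
    want <- want[order(want$gene_id), ]
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$recomb_rate, want$recomb_rate, tolerance = 1e-12)
    # conservation: every interval lands on exactly one gene
    expect_equal(sum(got$n_intervals), ni)
  }
})

test_that("greedy tissue decorrelation drops near-duplicates, keeps rest", {
  set.seed(3)
  x <- matrix(rnorm(500 * 4), ncol = 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  dup <- cbind(x, t5 = x[, 1])            # exact copy of t1
  expect_equal(drop_correlated_columns(dup), paste0("t", 1:4))
  expect_equal(drop_correlated_columns(dup, rho_max = 1),
               colnames(dup))
  # independent columns are all retained
  expect_equal(drop_correlated_columns(x, rho_max = 0.8), colnames(x))
  cst <- cbind(x, t6 = rep(1, 500))
  expect_warning(keep <- drop_correlated_columns(cst), "constant")
  expect_true("t6" %in% keep)
})

test_that("network stats follow the topological-coefficient definition", {
  tri <- tibble::tibble(gene_a = c("a", "b", "c"),
                        gene_b = c("b", "c", "a"), score = 0.9)
  out <- network_node_stats(tri)
  expect_equal(out$degree, rep(2L, 3))
  expect_equal(out$topo_coeff, rep(1, 3))
  star <- tibble::tibble(gene_a = "hub", gene_b = paste0("leaf", 1:5),
                         score = 0.9)
  s <- network_node_stats(star)
  expect_equal(s$degree[s$gene_id == "hub"], 5L)
  expect_true(all(s$topo_coeff[s$gene_id != "hub"] == 0))  # k < 2 rule
  # edges at or below the cut-off and self-loops are excluded
  mix <- dplyr::bind_rows(tri,
                          tibble::tibble(gene_a = "a", gene_b = "z",
                                         score = 0.5),
                          tibble::tibble(gene_a = "a", gene_b = "a",
                                         score = 0.95))
  expect_warning(m <- network_node_stats(mix), "self-loop")
  expect_false("z" %in% m$gene_id)
  expect_equal(m$degree[m$gene_id == "a"], 2L)
})

test_that("random graphs match the definitional oracle", {
  set.seed(90)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    nodes <- paste0("n", 1:n)
    ne <- sample(3:(n * (n - 1) / 2), 1)
    pairs <- t(combn(nodes, 2))
    pick <- sample(nrow(pairs), ne)
    edges <- tibble::tibble(gene_a = pairs[pick, 1],
                            gene_b = pairs[pick, 2], score = 0.9)
    out <- network_node_stats(edges)
    adj <- lapply(setNames(nm = out$gene_id), function(v) {
      unique(c(edges$gene_b[edges$gene_a == v],
               edges$gene_a[edges$gene_b == v]))
    })
    want <- oracle_topo_coeff(adj)
    expect_equal(out$topo_coeff, unname(want[out$gene_id]),
                 tolerance = 1e-12)
    expect_true(all(out$topo_coeff >= 0 & out$topo_coeff <= 1))
    expect_equal(sum(out$degree), 2L * nrow(edges))
  }
})

test_that("paralogue-free percentages respect the identity cutoff", {
  asg <- tibble::tibble(gene_id = paste0("G", 1:4),
                        bin = c("CL", "CL", "VN", "VN"))
  par <- tibble::tibble(gene_id = c("G1", "G3", "G4"),
                        partner_id = c("P1", "P2", "P3"),
                        identity = c(29, 90, 45))
  out <- paralogue_free_rate(asg, par, cutoff = 30)
  expect_equal(out$pct_paralogue_free[out$bin == "CL"], 100)  # 29% < 30
  expect_equal(out$pct_paralogue_free[out$bin == "VN"], 0)
  # cutoff 0: only genes with no partner rows at all are paralogue-free
  out0 <- paralogue_free_rate(asg, par, cutoff = 0)
  expect_equal(out0$pct_paralogue_free[out0$bin == "CL"], 50)
})

test_that("earliest onset and affected-system counts", {
  on <- tibble::tibble(gene_id = c("G1", "G1", "G2", "G3", "G3"),
                       onset = c("adult", "neonatal", "antenatal",
                                 "elderly", "childhood"))
  out <- earliest_onset(on)
  expect_equal(as.character(out$onset_earliest[match(c("G1", "G2", "G3"),
                                                     out$gene_id)]),
               c("neonatal", "antenatal", "childhood"))
  expect_error(earliest_onset(tibble::tibble(gene_id = "G", onset = "x")),
               class = "fusil_data_error")
  sys <- tibble::tibble(gene_id = c("G1", "G1", "G1", "G2"),
                        system = c("nervous", "nervous", "cardiac",
                                   "renal"))
  cnt <- count_affected_systems(sys)
  expect_equal(cnt$n_systems[cnt$gene_id == "G1"], 2L)  # duplicates once
  expect_equal(cnt$n_systems[cnt$gene_id == "G2"], 1L)
})

test_that("pairwise bin tests are symmetric, null-calibrated and powered", {
  set.seed(55)
  n <- 200
  asg <- tibble::tibble(gene_id = paste0("G", 1:(3 * n)),
                        bin = rep(c("CL", "DL", "VN"), each = n))
  vals <- setNames(c(rnorm(n), rnorm(n), rnorm(n, 1)), asg$gene_id)
  m <- pairwise_bin_tests(vals, asg)
  expect_true(isSymmetric(m))
  expect_true(all(is.na(diag(m))))
  # same distribution: no strong rejection; shifted bin: strong rejection
  expect_lt(m["CL", "VN"], 0.001)
  expect_lt(m["DL", "VN"], 0.001)
  expect_gt(m["CL", "DL"], 0.01)
  # small bins are skipped with a warning
  asg2 <- dplyr::bind_rows(asg, tibble::tibble(gene_id = "tiny1",
                                               bin = "SV"))
  vals2 <- c(vals, tiny1 = 0.5)
  expect_warning(m2 <- pairwise_bin_tests(vals2, asg2), "small bin")
  expect_true(is.na(m2["SV", "CL"]))
})
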