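test_that("Fisher scoring: worked examples and the brute-force oracle", {
  genomes <- sprintf("g%d", 1:10)
  trait <- setNames(rep(c(1L, 0L), each = 5), genomes)
  perfect <- setNames(trait == 1, genomes)
  sc <- score_family(perfect, trait)
  expect_equal(sc$sensitivity, 100)
  expect_equal(sc$specificity, 100)
  expect_equal(sc$p_naive, 2 / choose(10, 5))  # ~0.00794
  ## 2x2 = [[2,0],[0,2]]
  g4 <- sprintf("g%d", 1:4)
  t4 <- setNames(c(1L, 1L, 0L, 0L), g4)
  p4 <- setNames(c(TRUE, TRUE, FALSE, FALSE), g4)
  expect_equal(score_family(p4, t4)$p_naive, 2 / 6, tolerance = 1e-12)
  ## constant column flagged
  all_on <- setNames(rep(TRUE, 10), genomes)
  sca <- score_family(all_on, trait)
  expect_true(sca$constant)
  expect_equal(sca$p_naive, 1)
  expect_equal(sca$specificity, 0)
  expect_error(score_family(perfect, setNames(rep(1L, 10), genomes)), "0 and 1")
  ## oracle: equals stats::fisher.test two-sided on random tables
  set.seed(14)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    gg <- sprintf("g%d", 1:n)
    tt <- setNames(sample(c(0L, 1L), n, TRUE), gg)
    if (length(unique(tt)) < 2) next
    pp <- setNames(sample(c(TRUE, FALSE), n, TRUE), gg)
    if (length(unique(pp)) < 2) next
    ours <- score_family(pp, tt)$p_naive
    ref <- stats::fisher.test(table(pp, tt))$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("empirical p: tail bound, determinism, null uniformity", {
  genomes <- sprintf("g%d", 1:10)
  trait <- setNames(rep(c(1L, 0L), each = 5), genomes)
  perfect <- setNames(trait == 1, genomes)
  p <- empirical_p(perfect, trait, n_permutations = 1000, seed = 5)
  expect_lte(p, 0.01)
  expect_identical(p, empirical_p(perfect, trait, n_permutations = 1000,
                                  seed = 5))
  ## independent gene: randomized-tie p uniform, inclusive p valid
  sim_ps <- function(ties) vapply(1:200, function(i) {
    set.seed(15 + i)
    pres <- setNames(sample(c(TRUE, FALSE), 20, TRUE), sprintf("g%d", 1:20))
    tr <- setNames(sample(rep(c(1L, 0L), each = 10)), sprintf("g%d", 1:20))
    if (all(pres) || !any(pres)) return(NA_real_)
    empirical_p(pres, tr, n_permutations = 99, seed = 2000 + i, ties = ties)
  }, numeric(1))
  pr <- sim_ps("randomized")
  ks <- suppressWarnings(stats::ks.test(pr[!is.na(pr)], "punif"))
  expect_gt(ks$p.value, 0.01)
  ## the conventional inclusive rule is conservative, never anti-conservative
  pi_ <- sim_ps("inclusive")
  expect_lte(mean(pi_[!is.na(pi_)] <= 0.05), 0.07)
  expect_true(all(pi_[!is.na(pi_)] >= pr[!is.na(pr)] - 1e-9))
})

test_that("multiple-testing arithmetic and strict thresholds", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(p.adjust(p, "bonferroni"), c(0.04, 0.08, 0.12, 0.16))
  ## sens 71 / spec 69 is rejected regardless of p
  m <- matrix(c(rep(TRUE, 71), rep(FALSE, 29),    # trait-positives
                rep(TRUE, 31), rep(FALSE, 69)),   # trait-negatives
              ncol = 1, dimnames = list(sprintf("g%d", 1:200), "fam1"))
  ## add a second, variable family so correction has a universe
  m <- cbind(m, fam2 = rep(c(TRUE, FALSE), 100))
  trait <- setNames(c(rep(1L, 100), rep(0L, 100)), rownames(m))
  res <- select_specific_genes(hostflux:::new_presence_matrix(m),
                               list(t1 = trait), n_permutations = 50,
                               seed = 1)
  r1 <- res[res$family == "fam1", ]
  expect_equal(r1$sensitivity, 71)
  expect_equal(r1$specificity, 69)
  expect_false(r1$specific)
})

test_that("decisions are invariant to genome and family ordering", {
  cfg <- tiny_config(seed = 61)
  ds <- simulate_dataset(cfg)
  traits <- list(L1 = setNames(as.integer(ds$metadata$lineage == "L1"),
                               ds$metadata$genome))
  r1 <- select_specific_genes(ds$matrix, traits, n_permutations = 100,
                              seed = 9)
  m2 <- ds$matrix[rev(rownames(ds$matrix)), rev(colnames(ds$matrix))]
  r2 <- select_specific_genes(hostflux:::new_presence_matrix(m2), traits,
                              n_permutations = 100, seed = 9)
  r2o <- r2[match(r1$family, r2$family), ]
  expect_equal(r1$specific, r2o$specific)
  expect_equal(r1$p_naive, r2o$p_naive)
})

test_that("lineage-specific innovations are recovered from the truth log", {
  cfg <- sim_config(n_genomes = 30, n_lineages = 3, root_family_count = 300,
                    gain_rate = 0.05, loss_rate = 0.05,
                    innovation_rate = 120, host_linked_families = 0,
                    n_core_genes = 2, seed = 71)
  at <- simulate_host_phylogeny(cfg)
  gc_ <- simulate_gene_content(at, cfg)
  lin <- at$lineage[rownames(gc_$matrix)]
  traits <- lapply(c("L1", "L2", "L3"), function(l)
    setNames(as.integer(lin == l), names(lin)))
  names(traits) <- c("L1", "L2", "L3")
  res <- select_specific_genes(gc_$matrix, traits, n_permutations = 200,
                               seed = 3)
  ## ground truth: families whose carriers sit in one lineage, cover > 70%
  ## of it, and are absent from > 70% of the rest
  truth_specific <- function(l) {
    tips_in <- names(lin)[lin == l]
    cnt_in <- colSums(gc_$matrix[tips_in, , drop = FALSE])
    cnt_out <- colSums(gc_$matrix) - cnt_in
    colnames(gc_$matrix)[cnt_in / length(tips_in) > 0.7 &
                           (30 - length(tips_in) - cnt_out) /
                             (30 - length(tips_in)) > 0.7]
  }
  for (l in c("L1", "L2", "L3")) {
    truth <- truth_specific(l)
    called <- res$family[res$trait == l & res$specific]
    expect_gte(length(intersect(called, truth)) / length(truth), 0.9)
    expect_lte(length(setdiff(called, truth)) / max(length(called), 1), 0.05)
  }
})
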