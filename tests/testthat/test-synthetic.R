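test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_genomes = 2), "n_genomes")
  expect_error(sim_config(loss_rate = -1), "loss_rate")
  expect_error(sim_config(recombination_fraction = 1.5),
               "recombination_fraction")
  expect_error(sim_config(gene_length = 20), "gene_length")
  expect_error(sim_config(n_lineages = 50, n_genomes = 10), "n_lineages")
  expect_error(sim_config(root_host = "whale"), "root_host")
})

test_that("host phylogeny: structure, zero-rate labels, determinism", {
  cfg <- tiny_config(host_switch_rate = 0)
  at <- simulate_host_phylogeny(cfg)
  expect_s3_class(at$tree, "phylo")
  expect_true(ape::is.ultrametric(at$tree, tol = 1e-6))
  expect_equal(ape::Ntip(at$tree), 12)
  expect_equal(length(unique(at$lineage)), 3)
  ## zero switch rate: every node keeps the root host
  expect_true(all(at$host == "rodent"))
  expect_equal(nrow(at$truth$host_switches), 0)
  ## same config twice gives identical Newick strings
  at2 <- simulate_host_phylogeny(cfg)
  expect_identical(ape::write.tree(at$tree), ape::write.tree(at2$tree))
  ## different seed gives a different tree
  at3 <- simulate_host_phylogeny(tiny_config(seed = 99, host_switch_rate = 0))
  expect_false(identical(ape::write.tree(at$tree), ape::write.tree(at3$tree)))
})

test_that("host-switch event counts match the Poisson expectation", {
  rate <- 0.5
  counts <- numeric(200)
  lens <- numeric(200)
  for (i in seq_len(200)) {
    at <- simulate_host_phylogeny(
      sim_config(n_genomes = 20, n_lineages = 2, host_switch_rate = rate,
                 seed = 1000 + i))
    counts[i] <- nrow(at$truth$host_switches)
    lens[i] <- sum(at$tree$edge.length)
  }
  expected <- rate * mean(lens)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("gene content: degenerate rates and replay oracle", {
  at <- simulate_host_phylogeny(tiny_config())
  ## all rates zero: every tip carries exactly the root families
  cfg0 <- tiny_config(gain_rate = 0, loss_rate = 0, innovation_rate = 0,
                      host_linked_families = 0, root_family_count = 100)
  g0 <- simulate_gene_content(at, cfg0)
  expect_equal(ncol(g0$matrix), 100)
  expect_true(all(g0$matrix))
  ## heavy loss, no innovation: genomes contract
  cfgl <- tiny_config(gain_rate = 0, loss_rate = 3, innovation_rate = 0,
                      host_linked_families = 0, root_family_count = 100)
  gl <- simulate_gene_content(at, cfgl)
  expect_true(all(rowSums(gl$matrix) < 100))
  ## replay: tip set equals root set edited by the logged events
  cfg <- tiny_config()
  g <- simulate_gene_content(at, cfg)
  for (tip in rownames(g$matrix)) {
    replayed <- hostflux:::replay_gene_content(at, g$truth, tip)
    observed <- sort(colnames(g$matrix)[g$matrix[tip, ]])
    expect_identical(replayed[replayed %in% colnames(g$matrix)], observed)
  }
})

test_that("core alignments: zero clock, mosaics, JC expectation", {
  cfg <- tiny_config(clock_rate = 0, recombination_fraction = 0)
  at <- simulate_host_phylogeny(cfg)
  al <- simulate_core_alignments(at, cfg)
  for (a in al$alignments) expect_equal(length(unique(a)), 1L)
  expect_equal(nrow(al$truth$recombination), 0)
  ## mosaics logged when requested
  cfg2 <- tiny_config(recombination_fraction = 0.5)
  al2 <- simulate_core_alignments(at, cfg2)
  expect_equal(nrow(al2$truth$recombination), 3)  # 0.5 * 6 genes
  ## expected pairwise difference matches the substitution model
  cfg3 <- sim_config(n_genomes = 6, n_lineages = 2, n_core_genes = 100,
                     gene_length = 500, clock_rate = 1e-5,
                     recombination_fraction = 0, seed = 3)
  at3 <- simulate_host_phylogeny(cfg3)
  al3 <- simulate_core_alignments(at3, cfg3)
  tips <- at3$tree$tip.label
  a <- names(at3$lineage)[at3$lineage == "L1"][1]
  b <- names(at3$lineage)[at3$lineage == "L2"][1]
  mrca_age <- hostflux:::node_ages(at3$tree)[ape::getMRCA(at3$tree, c(a, b))]
  t_years <- 2 * mrca_age * cfg3$tree_age
  expected_p <- 0.75 * (1 - exp(-4 / 3 * cfg3$clock_rate * t_years))
  pdist <- vapply(al3$alignments, function(aln) {
    x <- strsplit(aln[[a]], "")[[1]]; y <- strsplit(aln[[b]], "")[[1]]
    mean(x != y)
  }, numeric(1))
  se <- sd(pdist) / sqrt(length(pdist))
  expect_lt(abs(mean(pdist) - expected_p), 3 * se)
})

test_that("prophages: transfers share exact >= 5 kb fragments, rates order", {
  cfg <- sim_config(n_genomes = 16, n_lineages = 2,
                    prophage_within_rate = 2, prophage_between_rate = 0.1,
                    prophage_mean_per_genome = 2, seed = 21)
  at <- simulate_host_phylogeny(cfg)
  pp <- simulate_prophage_repertoires(at, cfg)
  tr <- pp$truth$transfers
  expect_gt(nrow(tr), 0)
  ## rate ordering: many more intra than inter transfers
  expect_gt(sum(tr$type == "intra"), sum(tr$type == "inter"))
  ## every logged transfer pair shares an exact common substring >= 5000 bp
  for (i in seq_len(min(nrow(tr), 5))) {
    lcs <- longest_common_substring(pp$prophages$sequences[[tr$donor_id[i]]],
                                    pp$prophages$sequences[[tr$new_id[i]]],
                                    method = "dp")
    expect_gte(lcs, 5000)
  }
  ## decoys exist: some too short or bacterial-only
  info <- pp$prophages$info
  expect_true(any(info$length < 5000 |
                    (info$bacterial_genes > 0 & info$viral_genes == 0)))
})

test_that("adhesion assay: exact values at sd 0, determinism, separation", {
  strains <- sprintf("s%02d", 1:20)
  groups <- setNames(rep(c("g1", "g2"), each = 10), strains)
  cfg <- tiny_config(adhesion_sd = 0, adhesion_high_mean = 7.6)
  a0 <- simulate_adhesion_assay(strains, groups, "g1", cfg)
  expect_true(all(a0$log10_cfu_g[a0$group == "g1"] == 7.6))
  cfg2 <- tiny_config(adhesion_sd = 0.1, adhesion_high_mean = 7.6,
                      adhesion_low_mean = 6.0)
  a2 <- simulate_adhesion_assay(strains, groups, "g1", cfg2)
  expect_identical(a2, simulate_adhesion_assay(strains, groups, "g1", cfg2))
  ## downstream classification separates the two groups
  cls <- classify_adhesion(a2$log10_cfu_g[match(strains, a2$strain)])
  expect_true(all(cls[groups == "g1"] == "effective"))
  expect_true(all(cls[groups == "g2"] == "ineffective"))
})

test_that("full dataset generation is deterministic end to end", {
  cfg <- tiny_config(seed = 17)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(unclass(d1$matrix), unclass(d2$matrix))
  expect_identical(d1$alignments, d2$alignments)
  expect_identical(d1$prophages$sequences, d2$prophages$sequences)
  expect_identical(d1$metadata, d2$metadata)
})
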