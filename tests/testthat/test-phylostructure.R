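test_that("SNP distances: column rules and metric property", {
  aln <- c(s1 = "ACGT", s2 = "ACGA", s3 = "ACGN")
  d <- snp_distances(aln)
  expect_equal(d["s1", "s2"], 1)
  expect_equal(d["s3", "s2"], 0)   # ambiguity ignored
  expect_equal(d["s1", "s1"], 0)
  expect_error(snp_distances(c(a = "ACGT", b = "ACG")), "ragged")
  expect_error(snp_distances(c(a = "ACGT")), "2 sequences")
  ## metric on unambiguous sequences
  set.seed(5)
  for (i in 1:20) {
    aln3 <- setNames(vapply(1:3, function(j) rand_dna(60), ""), c("a", "b", "c"))
    dd <- snp_distances(aln3)
    expect_lte(dd["a", "c"], dd["a", "b"] + dd["b", "c"])
  }
})

test_that("core identity agrees algebraically with SNP distances", {
  aln <- c(a = paste(rep("A", 100), collapse = ""),
           b = paste(c(rep("A", 99), "C"), collapse = ""))
  ani <- core_identity(aln)
  expect_equal(ani["a", "b"], 99)
  expect_equal(ani["a", "a"], 100)
  set.seed(8)
  aln2 <- setNames(vapply(1:4, function(j) rand_dna(200), ""), letters[1:4])
  ani2 <- core_identity(aln2)
  snp2 <- snp_distances(aln2)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(ani2[i, j], 100 * (1 - snp2[i, j] / 200))
})

test_that("PHI: non-testable genes, C++ statistic matches the R oracle", {
  ## constant alignment: no informative sites
  aln <- setNames(rep(paste(rep("A", 50), collapse = ""), 5), letters[1:5])
  r <- phi_recombination_test(aln)
  expect_false(r$testable)
  expect_equal(r$p_value, 1)
  expect_error(phi_recombination_test(aln[1:3]), "4 sequences")
  ## dual route: compiled statistic equals the reference implementation
  set.seed(11)
  for (i in 1:15) {
    a <- do.call(rbind, strsplit(vapply(1:8, function(j) rand_dna(80), ""), ""))
    rownames(a) <- sprintf("s%d", 1:8)
    ## add shared mutations so some sites are informative
    a[sample(8, 4), sample(80, 6)] <- "T"
    inf <- which(hostflux:::informative_sites(a))
    if (length(inf) < 2) next
    code <- matrix(match(a[, inf], c("A", "C", "G", "T"), nomatch = 0L),
                   nrow = nrow(a))
    cpp <- hostflux:::phi_stat_cpp(code, inf, 100)
    ref <- hostflux:::phi_statistic(a, inf, 100)
    expect_equal(cpp, ref, tolerance = 1e-12)
  }
})

test_that("PHI calibration: clonal genes pass, deep mosaics are caught", {
  cfg <- sim_config(n_genomes = 14, n_lineages = 2, n_core_genes = 50,
                    gene_length = 600, clock_rate = 2e-5,
                    recombination_fraction = 0, seed = 31)
  at <- simulate_host_phylogeny(cfg)
  al <- simulate_core_alignments(at, cfg)
  p <- vapply(names(al$alignments), function(g)
    phi_recombination_test(al$alignments[[g]], seed = op_seed(31, g))$p_value,
    numeric(1))
  expect_gte(mean(p >= 0.05), 0.9)
  ## positive control: transplanted half-gene across deep lineages
  cfg2 <- sim_config(n_genomes = 14, n_lineages = 2, n_core_genes = 10,
                     gene_length = 600, clock_rate = 2e-5,
                     recombination_fraction = 1, seed = 32)
  al2 <- simulate_core_alignments(at, cfg2)
  p2 <- vapply(names(al2$alignments), function(g)
    phi_recombination_test(al2$alignments[[g]], seed = op_seed(32, g))$p_value,
    numeric(1))
  expect_gte(mean(p2 < 0.05), 0.7)
})

test_that("recombination-free concatenation keeps exactly the passing genes", {
  aln <- list(gA = c(s1 = "AAAA", s2 = "AAAA", s3 = "AAAA", s4 = "AAAA"),
              gB = c(s1 = "CCCC", s2 = "CCCC", s3 = "CCCC", s4 = "CCCC"),
              gC = c(s1 = "GGGG", s2 = "GGGG", s3 = "GGGG", s4 = "GGGG"))
  out <- concatenate_recombination_free(aln, c(gA = 0.5, gB = 0.01, gC = 0.9))
  expect_equal(unname(nchar(out[1])), 8)
  parts <- attr(out, "partitions")
  expect_setequal(parts$gene, c("gA", "gC"))
  expect_equal(attr(out, "excluded"), "gB")
  ## all pass: concatenated length is the sum of gene lengths
  out2 <- concatenate_recombination_free(aln, c(gA = 1, gB = 1, gC = 1))
  expect_equal(unname(nchar(out2[1])), 12)
  expect_error(
    concatenate_recombination_free(aln, c(gA = 0, gB = 0, gC = 0)),
    "rejected")
  ## trim rule: mostly-gap columns removed
  gap <- list(g = c(s1 = "A-AA", s2 = "A-AA", s3 = "ACAA", s4 = "A-AA"))
  out3 <- concatenate_recombination_free(gap, c(g = 1))
  expect_equal(unname(nchar(out3[1])), 3)
})

test_that("simulated mosaic fraction drives the exclusion rate", {
  cfg <- sim_config(n_genomes = 14, n_lineages = 2, n_core_genes = 60,
                    gene_length = 600, clock_rate = 2e-5,
                    recombination_fraction = 0.2, seed = 33)
  at <- simulate_host_phylogeny(cfg)
  al <- simulate_core_alignments(at, cfg)
  phi <- lapply(names(al$alignments), function(g)
    phi_recombination_test(al$alignments[[g]], seed = op_seed(33, g)))
  names(phi) <- names(al$alignments)
  out <- concatenate_recombination_free(al$alignments, phi)
  n_exc <- length(attr(out, "excluded"))
  ## expect about 20% of 60 genes, within 3 SE of a binomial (plus the
  ## test's own ~5% false-positive allowance)
  se <- sqrt(60 * 0.2 * 0.8)
  expect_lt(abs(n_exc - 12), 3 * se + 0.05 * 48)
})

test_that("UPGMA agglomeration: worked example, fixed point, bootstrap", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- distance_tree(d, method = "upgma")
  cd <- cophenetic(tr)
  expect_equal(cd["A", "B"], 2)
  expect_equal(cd["A", "C"], 4)
  expect_equal(cd["B", "C"], 4)
  ## ultrametric input reproduced exactly; output always ultrametric
  ages <- hostflux:::node_ages(tr)
  expect_lt(max(ages[1:3]) - min(ages[1:3]), 1e-9)
  expect_error(distance_tree(matrix(c(0, 1, 2, 0), 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b")))),
               "3 labels")
  dd <- d; dd[1, 2] <- 5
  expect_error(distance_tree(dd), "symmetric")
  ## clonal simulation: true deep clades get high bootstrap support
  cfg <- sim_config(n_genomes = 10, n_lineages = 2, n_core_genes = 10,
                    gene_length = 500, clock_rate = 2e-5,
                    recombination_fraction = 0, seed = 41)
  at <- simulate_host_phylogeny(cfg)
  al <- simulate_core_alignments(at, cfg)
  cat_aln <- concatenate_recombination_free(
    al$alignments, setNames(rep(1, 10), names(al$alignments)))
  tr2 <- distance_tree(snp_distances(cat_aln), method = "upgma",
                       alignment = cat_aln, n_bootstrap = 100, seed = 42)
  l1 <- names(at$lineage)[at$lineage == "L1"]
  key <- hostflux:::bipart_key(l1, tr2$tip.label)
  tu <- hostflux:::tips_under(tr2)
  n <- ape::Ntip(tr2)
  support <- NA
  for (nd in (n + 1):(n + tr2$Nnode)) {
    side <- tr2$tip.label[tu[[nd]]]
    if (length(side) >= 2 && length(side) <= n - 2 &&
        hostflux:::bipart_key(side, tr2$tip.label) == key)
      support <- as.numeric(tr2$node.label[nd - n])
  }
  expect_gt(support, 90)
})

test_that("NJ with outgroup rooting recovers the stated root", {
  d <- matrix(c(0, 2, 8, 8, 2, 0, 8, 8, 8, 8, 0, 4, 8, 8, 4, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- distance_tree(d, method = "nj", outgroup = "d")
  expect_true(ape::is.rooted(tr))
  expect_true("d" %in% tr$tip.label)
})

test_that("lineage delineation: clean clusters, degenerate input", {
  cfg <- tiny_config(seed = 51)
  ds <- simulate_dataset(cfg)
  cat_aln <- concatenate_recombination_free(
    ds$alignments, setNames(rep(1, length(ds$alignments)),
                            names(ds$alignments)))
  snp <- snp_distances(cat_aln)
  lin <- delineate_lineages(snp)
  expect_equal(lin$n_lineages, 3)
  expect_equal(ari(lin$labels[names(ds$tree$lineage)], ds$tree$lineage), 1)
  ## all-equal distances raise
  deq <- matrix(5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(deq) <- 0
  deq2 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(delineate_lineages(deq2), "degenerate|unimodal")
  ## explicit threshold bypasses the density scan
  lin2 <- delineate_lineages(deq, threshold = 1)
  expect_true(all(lin2$labels == "unassigned"))
  ## small components flagged unassigned
  lin3 <- delineate_lineages(snp, min_size = 99)
  expect_true(all(lin3$labels == "unassigned"))
})
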