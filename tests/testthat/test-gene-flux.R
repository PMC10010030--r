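test_that("parsimony reconstruction: worked examples", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  pres <- setNames(c(TRUE, TRUE, FALSE, FALSE), c("A", "B", "C", "D"))
  f <- parsimony_reconstruct(tr, pres, mode = "fitch")
  expect_equal(f$n_changes, 1)
  d <- parsimony_reconstruct(tr, pres, mode = "dollo")
  expect_equal(sum(d$events$type == "gain"), 1)
  expect_equal(sum(d$events$type == "loss"), 0)
  ## the single gain sits on the (A,B) stem
  ab <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(d$events$child[d$events$type == "gain"], ab)
  ## everywhere-present family: no events
  all1 <- setNames(rep(TRUE, 4), c("A", "B", "C", "D"))
  expect_equal(parsimony_reconstruct(tr, all1)$n_changes, 0)
  expect_true(all(parsimony_reconstruct(tr, all1)$states == 1))
  ## single-carrier family: pendant gain in both modes
  one <- setNames(c(FALSE, FALSE, TRUE, FALSE), c("A", "B", "C", "D"))
  for (mode in c("fitch", "dollo")) {
    r <- parsimony_reconstruct(tr, one, mode = mode)
    expect_equal(r$events$type, "gain")
    expect_equal(r$events$child, match("C", tr$tip.label))
  }
  expect_error(parsimony_reconstruct(tr, pres[1:3]), "cover")
})

test_that("Fitch length equals brute-force minimum changes on small trees", {
  brute_min_changes <- function(tree, x) {
    nint <- tree$Nnode
    best <- Inf
    for (code in 0:(2^nint - 1)) {
      anc <- as.integer(intToBits(code))[seq_len(nint)]
      st <- c(x, anc)
      ch <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
      best <- min(best, ch)
    }
    best
  }
  set.seed(18)
  for (i in 1:25) {
    nt <- sample(4:6, 1)
    tr <- random_small_tree(nt)
    x <- sample(c(0L, 1L), nt, TRUE)
    pres <- setNames(as.logical(x), tr$tip.label)
    f <- parsimony_reconstruct(tr, pres, mode = "fitch")
    expect_equal(f$n_changes, brute_min_changes(tr, x))
  }
})

test_that("pruning likelihood equals exhaustive enumeration", {
  set.seed(19)
  for (i in 1:20) {
    nt <- sample(3:6, 1)
    tr <- random_small_tree(nt)
    g <- runif(1, 0.05, 2); l <- runif(1, 0.05, 2)
    X <- matrix(sample(c(0, 1), nt * 5, TRUE), nt, 5,
                dimnames = list(tr$tip.label, sprintf("f%d", 1:5)))
    X[, colSums(X) == 0] <- 1  # keep families observable
    r <- list(gain = rep(g, nrow(tr$edge)), loss = rep(l, nrow(tr$edge)))
    pr <- hostflux:::prune_2state(tr, X, r)
    pi_ <- c(l, g) / (g + l)
    lik_prune <- as.numeric(pr$L[[nt + 1L]] %*% pi_)
    for (fam in 1:5) {
      lik_enum <- exp(hostflux:::enumerate_2state_loglik(
        tr, X[, fam, drop = FALSE], g, l, condition = FALSE))
      expect_lt(abs(lik_prune[fam] - lik_enum), 1e-10)
    }
  }
})

test_that("gain/loss ML fit recovers generating rates", {
  cfg <- sim_config(n_genomes = 60, n_lineages = 4, root_family_count = 1500,
                    gain_rate = 0.3, loss_rate = 0.5, innovation_rate = 0,
                    host_linked_families = 0, n_core_genes = 2, seed = 81)
  at <- simulate_host_phylogeny(cfg)
  gc_ <- simulate_gene_content(at, cfg)
  flux <- ml_gain_loss_fit(at$tree, gc_$matrix)
  expect_lt(abs(flux$rates$gain[1] - 0.3) / 0.3, 0.2)
  expect_lt(abs(flux$rates$loss[1] - 0.5) / 0.5, 0.2)
  ## expected events are non-negative
  expect_true(all(flux$branch_events$gains >= -1e-9))
  expect_true(all(flux$branch_events$losses >= -1e-9))
})

test_that("loss-free gain process: no inferred losses, root below tips", {
  cfg <- sim_config(n_genomes = 25, n_lineages = 3, root_family_count = 200,
                    gain_rate = 0, loss_rate = 0, innovation_rate = 120,
                    host_linked_families = 0, n_core_genes = 2, seed = 82)
  at <- simulate_host_phylogeny(cfg)
  gc_ <- simulate_gene_content(at, cfg)
  flux <- ml_gain_loss_fit(at$tree, gc_$matrix)
  anc <- ancestral_content(flux)
  expect_lt(sum(flux$branch_events$losses), 0.05 * ncol(gc_$matrix))
  expect_lte(anc$node_counts[26], min(anc$node_counts[1:25]) + 1)
})

test_that("ancestral content: thresholds and truth recovery", {
  cfg <- sim_config(n_genomes = 20, n_core_genes = 2, seed = 83)
  at <- simulate_host_phylogeny(cfg)
  gc_ <- simulate_gene_content(at, cfg)
  flux <- ml_gain_loss_fit(at$tree, gc_$matrix)
  anc <- ancestral_content(flux)
  ## boundary thresholds
  expect_equal(length(ancestral_content(flux, threshold = -1)$root_families),
               ncol(gc_$matrix))
  expect_equal(length(ancestral_content(flux, threshold = 1)$root_families), 0)
  ## innovation-rich default: genome expansion, root close to the truth
  expect_true(anc$expansion)
  truth_root <- intersect(gc_$truth$root_families, colnames(gc_$matrix))
  jac <- length(intersect(anc$root_families, truth_root)) /
    length(union(anc$root_families, truth_root))
  expect_gte(jac, 0.95)
})

test_that("origin classification separates gains from inherited families", {
  ## classification contract on a controlled flux report: fam_gain absent
  ## at the root, fam_lca at the root and kept by all L1 tips, fam_part at
  ## the root but kept by only part of L1
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);")
  lineages <- setNames(c("L1", "L1", "L2", "L2", "L3", "L3"),
                       c("A", "B", "C", "D", "E", "F"))
  m <- cbind(fam_gain = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
             fam_lca = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
             fam_part = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  rownames(m) <- c("A", "B", "C", "D", "E", "F")
  pm <- hostflux:::new_presence_matrix(m)
  marg <- matrix(0, 11, 3, dimnames = list(NULL, colnames(m)))
  root <- 7L
  marg[root, ] <- c(0.05, 0.95, 0.95)
  flux <- structure(list(marginals = marg, tree = tr,
                         families = colnames(m)), class = "flux_report")
  spec <- data.frame(trait = c("L1", "L1", "L1"),
                     family = c("fam_gain", "fam_lca", "fam_part"))
  orig <- classify_specific_origins(spec, flux, pm, lineages)
  expect_equal(orig$origin[orig$family == "fam_gain"], "gained-on-lineage")
  expect_equal(orig$origin[orig$family == "fam_lca"],
               "LCA-inherited-retained")
  expect_equal(orig$origin[orig$family == "fam_part"],
               "LCA-inherited-partially-retained")
  tal <- attr(orig, "tally")
  expect_equal(sum(tal), 3)
  expect_error(classify_specific_origins(
    data.frame(trait = "L1", family = "nope"), flux, pm, lineages), "absent")
})

test_that("classified gained fraction tracks the truth log", {
  cfg <- sim_config(n_genomes = 24, n_lineages = 3, root_family_count = 250,
                    gain_rate = 0.05, loss_rate = 0.1, innovation_rate = 100,
                    host_linked_families = 0, n_core_genes = 2, seed = 85)
  at <- simulate_host_phylogeny(cfg)
  gc_ <- simulate_gene_content(at, cfg)
  lin <- at$lineage[rownames(gc_$matrix)]
  traits <- lapply(c("L1", "L2", "L3"), function(l)
    setNames(as.integer(lin == l), names(lin)))
  names(traits) <- c("L1", "L2", "L3")
  res <- select_specific_genes(gc_$matrix, traits, n_permutations = 100,
                               seed = 4)
  spec <- res[res$specific, c("trait", "family")]
  flux <- ml_gain_loss_fit(at$tree, gc_$matrix)
  orig <- classify_specific_origins(spec, flux, gc_$matrix, lin)
  true_gained <- mean(!(orig$family %in% gc_$truth$root_families))
  est_gained <- mean(orig$origin == "gained-on-lineage")
  expect_lt(abs(est_gained - true_gained), 0.05)
})
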