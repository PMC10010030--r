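## shared fixtures and small utilities for the test suite

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genomes = 12, n_lineages = 3, n_core_genes = 6,
         root_family_count = 120, innovation_rate = 40,
         clock_rate = 1e-5, seed = seed),
    list(...))
  do.call(sim_config, args)
}

## adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

## random rooted binary tree with branch lengths, <= 6 tips (oracle trees)
random_small_tree <- function(ntip) {
  tr <- ape::rtree(ntip, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  tr
}

## override host states lineage-wise on a simulated tree, keeping the
## TruthLog switch list consistent (switches placed mid-stem)
force_hosts <- function(atree, lineage_hosts, root_host = "rodent") {
  tree <- atree$tree
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  tu <- hostflux:::tips_under(tree)
  lin_of_tip <- atree$lineage[tree$tip.label]
  host <- character(nn)
  for (nd in seq_len(nn)) {
    lins <- unique(lin_of_tip[tu[[nd]]])
    host[nd] <- if (length(lins) == 1) lineage_hosts[[lins]] else root_host
  }
  sw <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (host[p] != host[ch])
      sw[[length(sw) + 1L]] <- data.frame(
        branch = ch, from = host[p], to = host[ch],
        age = (atree$ages[p] + atree$ages[ch]) / 2)
  }
  atree$host <- host
  atree$truth$host_switches <- if (length(sw)) do.call(rbind, sw) else
    data.frame(branch = integer(0), from = character(0),
               to = character(0), age = numeric(0))
  atree
}

## random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
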