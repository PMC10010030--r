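## Gene-content clustering diagnostics: NMDS by isotonic regression plus
## Guttman majorization, ANOSIM with a permutation test, and topology
## comparison between the core-genome tree and the gene-content tree.

kruskal_stress1 <- function(dconf, dhat) {
  sqrt(sum((dconf - dhat)^2) / sum(dconf^2))
}

nmds_once <- function(dv, n, k, x0, max_iter, tol = 1e-7) {
  ord <- order(dv)
  X <- x0
  stress_trace <- numeric(0)
  stress <- Inf
  for (it in seq_len(max_iter)) {
    dc <- as.numeric(dist(X))
    dhat <- numeric(length(dv))
    dhat[ord] <- isoreg(dc[ord])$yf   # monotone disparities vs rank of input
    s <- kruskal_stress1(dc, dhat)
    if (length(stress_trace) && s > stress + 1e-12) break
    stress_trace <- c(stress_trace, s)
    if (is.finite(stress) && stress - s < tol) { stress <- s; break }
    stress <- s
    ## Guttman transform with the current disparities
    B <- matrix(0, n, n)
    idx <- which(upper.tri(B))
    ratio <- ifelse(dc > 0, dhat / dc, 0)
    B[idx] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
  }
  list(points = X, stress = stress, trace = stress_trace)
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Alternates isotonic regression of configuration distances on the rank
#' order of the input dissimilarities with Guttman-transform configuration
#' updates. The first restart starts from classical metric scaling of the
#' input, the rest from random configurations; the best restart is returned.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k embedding dimension (default 2).
#' @param n_restarts restarts (default 20).
#' @param max_iter iterations per restart (default 200).
#' @param seed integer seed.
#' @return list (class `ordination_result`): `points` (n x k), `stress`,
#'   `n_restarts`, `converged`, `trace` (per-iteration stress of the winner).
#' @export
nmds_embed <- function(d, k = 2, n_restarts = 20, max_iter = 200, seed = 1) {
  if (nrow(d) < 4) stop_input("need at least 4 points for NMDS")
  if (any(!is.finite(d))) stop_input("non-finite distances")
  n <- nrow(d)
  dv <- as.numeric(as.dist(d))  # same pair ordering as dist(X) below
  with_seed(op_seed(seed, "nmds"), {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      x0 <- if (r == 1) {
        cm <- cmdscale(as.dist(d), k = k)
        if (ncol(cm) < k) cbind(cm, matrix(0, n, k - ncol(cm))) else cm
      } else matrix(rnorm(n * k), n, k)
      res <- nmds_once(dv, n, k, x0, max_iter)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
    rownames(best$points) <- rownames(d)
    structure(list(points = best$points, stress = best$stress,
                   n_restarts = n_restarts,
                   converged = length(best$trace) < max_iter,
                   trace = best$trace),
              class = "ordination_result")
  })
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean between-group rank - mean within-group rank) / (M/2), with
#' M = n(n-1)/2 pairwise distances and midpoint-tied ranks; the p-value is
#' a permutation tail probability over random relabelings,
#' p = (1 + #\{perm R >= observed\}) / (n_permutations + 1).
#'
#' @param d symmetric distance matrix.
#' @param groups group label per row of `d` (>= 2 groups, each >= 2 members).
#' @param n_permutations label permutations (default 999).
#' @param seed integer seed.
#' @return list (class `anosim_result`): `R`, `p_value`, `n_permutations`,
#'   `group_sizes`, `permuted_R`.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = 1) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop_input("need at least 2 groups")
  if (any(sizes < 2)) stop_input("group of size 1: %s",
                                 names(sizes)[sizes < 2][1])
  n <- nrow(d)
  iu <- which(upper.tri(d))
  rk <- rank(d[iu])  # midpoint ties
  pair_i <- row(d)[iu]; pair_j <- col(d)[iu]
  M <- length(rk)
  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  obs <- stat(groups)
  with_seed(op_seed(seed, "anosim"), {
    perm <- vapply(seq_len(n_permutations),
                   function(b) stat(sample(groups)), numeric(1))
    structure(list(R = obs,
                   p_value = (1 + sum(perm >= obs)) / (n_permutations + 1),
                   n_permutations = n_permutations,
                   group_sizes = as.integer(sizes),
                   permuted_R = perm),
              class = "anosim_result")
  })
}

#' Compare two tree topologies on the same tips
#'
#' Reports the Robinson-Foulds distance, its normalization by the maximum
#' 2(n-3), the cophenetic correlation, and the bipartitions unique to each
#' tree.
#'
#' @param tree_a,tree_b ape `phylo` objects with identical tip sets.
#' @return list: `rf`, `rf_normalized`, `cophenetic_correlation`,
#'   `unique_to_a`, `unique_to_b`.
#' @export
compare_trees <- function(tree_a, tree_b) {
  miss <- c(setdiff(tree_a$tip.label, tree_b$tip.label),
            setdiff(tree_b$tip.label, tree_a$tip.label))
  if (length(miss))
    stop_input("tip sets differ: %s", paste(miss, collapse = ", "))
  ba <- tree_biparts(tree_a)
  bb <- tree_biparts(tree_b)
  rf <- length(setdiff(ba, bb)) + length(setdiff(bb, ba))
  n <- ape::Ntip(tree_a)
  ca <- cophenetic(tree_a)
  cb <- cophenetic(tree_b)[rownames(ca), colnames(ca)]
  list(rf = rf,
       rf_normalized = if (n > 3) rf / (2 * (n - 3)) else 0,
       cophenetic_correlation = cor(ca[upper.tri(ca)], cb[upper.tri(cb)]),
       unique_to_a = setdiff(ba, bb),
       unique_to_b = setdiff(bb, ba))
}

#' Cut gene-content structure into content groups
#'
#' Cuts the average-linkage (UPGMA) clustering of a gene-content distance
#' matrix into `k` groups, the operational version of "clearly separated"
#' content groups.
#'
#' @param d gene-content (Jaccard) distance matrix.
#' @param k number of groups (default 4).
#' @return named integer group labels.
#' @export
gene_content_groups <- function(d, k = 4) {
  h <- hclust(as.dist(d), method = "average")
  cutree(h, k = k)
}
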