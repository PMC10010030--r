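## Sequence-level distances, recombination screening (pairwise homoplasy
## index with a permutation test), distance-based trees with bootstrap, and
## lineage delineation from the pairwise SNP-distance distribution.

## named character vector of equal-length sequences -> character matrix
aln_matrix <- function(aln) {
  lens <- nchar(aln)
  if (length(unique(lens)) != 1)
    stop_input("ragged alignment: sequence lengths %s",
               paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Pairwise SNP distances from an alignment
#'
#' Counts columns where both rows carry an unambiguous A/C/G/T and differ;
#' gaps and N are ignored.
#'
#' @param aln named character vector of aligned sequences (equal length).
#' @return symmetric integer matrix, `metric` attribute "snp".
#' @export
snp_distances <- function(aln) {
  if (length(aln) < 2) stop_input("need at least 2 sequences")
  m <- aln_matrix(aln)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp])
  }
  attr(d, "metric") <- "snp"
  d
}

#' Core-alignment nucleotide identity (ANI proxy, percent)
#'
#' 100 x matching / comparable unambiguous columns over the (concatenated)
#' core alignment; diagonal is 100. Pairs with zero comparable columns get
#' NA and are flagged in the `undefined_pairs` attribute.
#'
#' @param aln named character vector of aligned sequences.
#' @return symmetric matrix of percent identities, `metric` attribute "ani".
#' @export
core_identity <- function(aln) {
  if (length(aln) < 2) stop_input("need at least 2 sequences")
  m <- aln_matrix(aln)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  n <- nrow(m)
  d <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  undef <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0) {
      d[i, j] <- d[j, i] <- NA_real_
      undef <- c(undef, paste(rownames(m)[i], rownames(m)[j], sep = ":"))
    } else d[i, j] <- d[j, i] <- 100 * sum(m[i, comp] == m[j, comp]) / nc
  }
  attr(d, "metric") <- "ani"
  attr(d, "undefined_pairs") <- undef
  d
}

## ---- pairwise homoplasy index ------------------------------------------

## parsimony-informative columns: >= 2 states each seen >= 2 times
## (ambiguous characters treated as missing)
informative_sites <- function(m) {
  apply(m, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(col)
    sum(tab >= 2) >= 2
  })
}

## incompatibility score of two columns: excess joint states beyond what a
## homoplasy-free pair can show (0 = compatible)
pair_incompat <- function(c1, c2) {
  keep <- c1 %in% c("A", "C", "G", "T") & c2 %in% c("A", "C", "G", "T")
  if (sum(keep) < 4) return(0)
  c1 <- c1[keep]; c2 <- c2[keep]
  k1 <- length(unique(c1)); k2 <- length(unique(c2))
  j <- length(unique(paste(c1, c2)))
  max(0, j - (k1 + k2 - 1))
}

## reference implementation of the statistic (oracle for the C++ path)
phi_statistic <- function(m, positions, window) {
  k <- length(positions)
  if (k < 2) return(NA_real_)
  scores <- numeric(0)
  for (i in seq_len(k - 1)) {
    jmax <- i
    while (jmax < k && positions[jmax + 1] - positions[i] <= window)
      jmax <- jmax + 1
    if (jmax > i)
      for (j in (i + 1):jmax)
        scores <- c(scores, pair_incompat(m[, positions[i]], m[, positions[j]]))
  }
  if (!length(scores)) return(NA_real_)
  mean(scores)
}

#' Pairwise homoplasy index (PHI) recombination test
#'
#' Mean incompatibility score over pairs of parsimony-informative sites
#' within `window` alignment positions of each other; significance by
#' permuting the order of the informative sites `n_permutations` times,
#' p = (1 + # permutations <= observed) / (n + 1). Genes with fewer than two
#' informative sites (or no in-window pair) are non-testable and return
#' p = 1.
#'
#' @param aln named character vector of aligned sequences (>= 4).
#' @param window window width in alignment positions (default 100).
#' @param n_permutations permutations (default 100, the conventional count).
#' @param seed integer seed for the permutation draw.
#' @return list: `statistic`, `p_value`, `n_informative`, `testable`.
#' @export
phi_recombination_test <- function(aln, window = 100, n_permutations = 100,
                                   seed = 1) {
  if (length(aln) < 4) stop_input("need at least 4 sequences for PHI")
  m <- aln_matrix(aln)
  inf <- which(informative_sites(m))
  if (length(inf) < 2)
    return(list(statistic = NA_real_, p_value = 1,
                n_informative = length(inf), testable = FALSE))
  code <- matrix(match(m[, inf, drop = FALSE], c("A", "C", "G", "T"),
                       nomatch = 0L),
                 nrow = nrow(m))
  obs <- phi_stat_cpp(code, inf, window)
  if (obs < 0)
    return(list(statistic = NA_real_, p_value = 1,
                n_informative = length(inf), testable = FALSE))
  with_seed(op_seed(seed, "phi"), {
    cnt <- 0L
    for (b in seq_len(n_permutations)) {
      stat <- phi_stat_cpp(code[, sample.int(length(inf)), drop = FALSE],
                           inf, window)
      if (stat <= obs) cnt <- cnt + 1L
    }
    list(statistic = obs, p_value = (1 + cnt) / (n_permutations + 1),
         n_informative = length(inf), testable = TRUE)
  })
}

#' Concatenate recombination-free genes
#'
#' Keeps exactly the genes whose PHI p-value is >= `alpha`, trims columns
#' that are gap/N in at least half the rows, and concatenates, recording
#' per-gene partition boundaries.
#'
#' @param alignments named list of gene alignments (named character vectors).
#' @param phi_results named list of [phi_recombination_test()] results (or a
#'   numeric vector of p-values) parallel to `alignments`.
#' @param alpha exclusion threshold on the PHI p-value (default 0.05).
#' @return named character vector (concatenated alignment) with attributes
#'   `partitions` (data.frame gene/start/end) and `excluded` (gene ids).
#' @export
concatenate_recombination_free <- function(alignments, phi_results,
                                           alpha = 0.05) {
  if (!length(alignments)) stop_input("empty gene set")
  pvals <- if (is.numeric(phi_results)) phi_results
           else vapply(phi_results, function(x) x$p_value, numeric(1))
  pvals <- pvals[names(alignments)]
  keep <- names(alignments)[pvals >= alpha]
  if (!length(keep))
    stop_input("all %d genes rejected at alpha = %g; nothing to concatenate",
               length(alignments), alpha)
  pieces <- list()
  parts <- list()
  pos <- 0L
  for (g in keep) {
    m <- aln_matrix(alignments[[g]])
    bad <- colMeans(m == "-" | m == "N") >= 0.5
    m <- m[, !bad, drop = FALSE]
    if (!ncol(m)) next
    pieces[[g]] <- m
    parts[[g]] <- data.frame(gene = g, start = pos + 1L,
                             end = pos + ncol(m))
    pos <- pos + ncol(m)
  }
  big <- do.call(cbind, pieces)
  out <- setNames(apply(big, 1, paste, collapse = ""), rownames(big))
  attr(out, "partitions") <- do.call(rbind, parts)
  attr(out, "excluded") <- setdiff(names(alignments), keep)
  out
}

## ---- distance trees -----------------------------------------------------

#' Distance-based phylogeny (UPGMA or NJ) with optional bootstrap
#'
#' UPGMA (average-linkage agglomeration) yields an ultrametric rooted tree;
#' NJ yields an additive tree, rooted at `outgroup` if given. Bootstrap
#' support is the percentage of alignment-column-resampled replicates
#' containing each internal bipartition.
#'
#' @param d symmetric distance matrix with labels.
#' @param method "upgma" or "nj".
#' @param alignment optional alignment (named character vector) for
#'   bootstrapping; distances are recomputed with `dist_fun` per replicate.
#' @param n_bootstrap number of replicates (0 = none).
#' @param dist_fun function(alignment) -> distance matrix (default
#'   [snp_distances()]).
#' @param outgroup optional tip for rooting NJ trees.
#' @param seed integer seed for resampling.
#' @return an ape `phylo`; bootstrap percentages in `node.label`.
#' @export
distance_tree <- function(d, method = c("upgma", "nj"), alignment = NULL,
                          n_bootstrap = 0, dist_fun = snp_distances,
                          outgroup = NULL, seed = 1) {
  method <- match.arg(method)
  if (nrow(d) < 3) stop_input("need at least 3 labels")
  if (max(abs(d - t(d))) > 1e-8) stop_input("distance matrix not symmetric")
  build <- function(dd) {
    if (method == "upgma") {
      h <- hclust(as.dist(dd), method = "average")
      ape::as.phylo(h)
    } else {
      tr <- ape::nj(as.dist(dd))
      if (!is.null(outgroup)) tr <- ape::root(tr, outgroup, resolve.root = TRUE)
      tr
    }
  }
  tree <- build(d)
  if (n_bootstrap > 0) {
    if (is.null(alignment))
      stop_input("bootstrap requested but no alignment given")
    m <- aln_matrix(alignment)
    bp <- with_seed(op_seed(seed, "bootstrap"), {
      ref_keys <- tree_biparts(tree)
      counts <- setNames(numeric(length(ref_keys)), ref_keys)
      for (b in seq_len(n_bootstrap)) {
        cols <- sample.int(ncol(m), replace = TRUE)
        res <- m[, cols, drop = FALSE]
        alnb <- setNames(apply(res, 1, paste, collapse = ""), rownames(res))
        keys <- tree_biparts(build(dist_fun(alnb)))
        hit <- ref_keys %in% keys
        counts[hit] <- counts[hit] + 1
      }
      round(100 * counts / n_bootstrap)
    })
    ## attach support to internal nodes by matching bipartitions
    n <- ape::Ntip(tree)
    tu <- tips_under(tree)
    lab <- rep(NA_character_, tree$Nnode)
    for (nd in (n + 1L):(n + tree$Nnode)) {
      side <- tree$tip.label[tu[[nd]]]
      if (length(side) >= 2 && length(side) <= n - 2) {
        key <- bipart_key(side, tree$tip.label)
        if (key %in% names(bp)) lab[nd - n] <- as.character(bp[[key]])
      }
    }
    tree$node.label <- lab
  }
  tree
}

#' Delineate lineages from the pairwise SNP-distance distribution
#'
#' Finds the valley of a kernel-density estimate between the two largest
#' modes of the pairwise distances, links genome pairs below that threshold
#' (single linkage), and labels the connected components. Components with
#' fewer than `min_size` genomes are flagged "unassigned".
#'
#' @param d symmetric distance matrix (e.g. SNP distances).
#' @param min_size minimum component size to receive a lineage label.
#' @param threshold optional explicit threshold, bypassing the density scan.
#' @return list: `labels` (named), `threshold`, `n_lineages`.
#' @export
delineate_lineages <- function(d, min_size = 4, threshold = NULL) {
  v <- d[upper.tri(d)]
  if (is.null(threshold)) {
    if (max(v) - min(v) < .Machine$double.eps * 100)
      stop_input("degenerate distance distribution (all equal); %s",
                 "supply an explicit threshold")
    dens <- density(v)
    y <- dens$y
    is_peak <- which(diff(sign(diff(y))) == -2) + 1L
    is_peak <- is_peak[y[is_peak] >= 0.02 * max(y)]
    if (length(is_peak) < 2)
      stop_input("pairwise distance distribution is unimodal; %s",
                 "supply an explicit threshold")
    ## the dividing line between intra- and inter-lineage values is the
    ## deepest relative valley: among valleys between adjacent modes, take
    ## the one with the smallest density relative to its smaller flank
    best <- NULL
    for (j in seq_len(length(is_peak) - 1L)) {
      lo <- is_peak[j]; hi <- is_peak[j + 1L]
      vy <- lo + which.min(y[lo:hi]) - 1L
      ratio <- y[vy] / min(y[lo], y[hi])
      if (is.null(best) || ratio < best$ratio)
        best <- list(ratio = ratio, at = vy)
    }
    if (best$ratio > 0.95)
      stop_input("pairwise distance distribution is unimodal; %s",
                 "supply an explicit threshold")
    threshold <- dens$x[best$at]
  }
  pairs <- which(d < threshold & upper.tri(d), arr.ind = TRUE)
  comp <- uf_components(nrow(d), pairs)
  comp <- match(comp, unique(comp))
  sizes <- table(comp)
  labels <- sprintf("lineage_%d", comp)
  labels[sizes[as.character(comp)] < min_size] <- "unassigned"
  ## renumber assigned lineages consecutively in order of appearance
  keep <- labels != "unassigned"
  labels[keep] <- sprintf("lineage_%d",
                          match(labels[keep], unique(labels[keep])))
  names(labels) <- rownames(d)
  list(labels = labels, threshold = threshold,
       n_lineages = length(unique(labels[keep])))
}
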