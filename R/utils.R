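#' @useDynLib hostflux, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rexp rnorm runif rpois rbinom density optim setNames
#'   cmdscale isoreg dist cophenetic p.adjust dhyper cor sd cutree hclust
#'   as.dist quantile median
#' @importFrom utils read.delim write.table read.csv write.csv head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a deterministic sub-seed for one operation
#'
#' All randomness in the package flows from one user seed; each operation
#' draws from a substream obtained by hashing the operation name, so that
#' adding draws to one stage never perturbs another.
#'
#' @param seed integer master seed.
#' @param op character operation name.
#' @return integer in [0, 2^31 - 2].
#' @keywords internal
op_seed <- function(seed, op) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(op)) h <- (h * 69069 + k) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## ---- phylo traversal helpers -------------------------------------------

#' Node ages (time before present) of an ultrametric rooted tree
#' @param tree a rooted `phylo` with branch lengths.
#' @return numeric vector indexed by ape node number (tips then internals).
#' @keywords internal
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

## edges of a phylo in preorder (root first); returns edge-row indices
preorder_edges <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  out <- integer(0)
  stack <- as.character(root)
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    rows <- children[[nd]]
    if (is.null(rows)) next
    out <- c(out, rows)
    stack <- c(stack, as.character(tree$edge[rows, 2]))
  }
  out
}

## postorder edge-row indices (children before parents)
postorder_edges <- function(tree) rev(preorder_edges(tree))

## tip indices descending from each node (list indexed by node number)
tips_under <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  out <- vector("list", n + m)
  for (i in seq_len(n)) out[[i]] <- i
  for (e in postorder_edges(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

## edge rows on the root-to-tip path of each tip
root_paths <- function(tree) {
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ape::Ntip(tree) + 1L
  lapply(seq_len(ape::Ntip(tree)), function(tip) {
    path <- integer(0)
    nd <- tip
    while (nd != root) {
      e <- parent_edge[nd]
      path <- c(e, path)
      nd <- tree$edge[e, 1]
    }
    path
  })
}

## simple union-find for single-linkage components
uf_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

## canonical string for an unrooted bipartition given one side's tip labels
bipart_key <- function(side, all_tips) {
  other <- setdiff(all_tips, side)
  a <- paste(sort(side), collapse = ",")
  b <- paste(sort(other), collapse = ",")
  if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

## non-trivial bipartitions of a (possibly rooted) tree as canonical keys
tree_biparts <- function(tree) {
  tree <- ape::unroot(tree)
  n <- ape::Ntip(tree)
  tu <- tips_under(tree)
  keys <- character(0)
  for (nd in (n + 1L):(n + tree$Nnode)) {
    side <- tree$tip.label[tu[[nd]]]
    if (length(side) >= 2 && length(side) <= n - 2)
      keys <- c(keys, bipart_key(side, tree$tip.label))
  }
  unique(keys)
}
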