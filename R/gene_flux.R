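## Ancestral gene-content reconstruction on a fixed tree: Fitch and Dollo
## parsimony, a two-state gain/loss continuous-time Markov chain fitted by
## maximum likelihood (pruning recursion, ascertainment-corrected for
## families unobservable when absent from every tip), expected per-branch
## gain/loss events, and origin classification of lineage-specific families.

#' Parsimony reconstruction of one family's history
#'
#' Fitch: minimum-change state sets bottom-up, resolved top-down with ties
#' broken toward the configured state (default absent, conservative against
#' inflating the ancestral genome). Dollo: a single gain at the most recent
#' common ancestor of the carrier tips, losses on the stems of carrier-free
#' subtrees below it.
#'
#' @param tree rooted ape `phylo`.
#' @param presence named logical/0-1 vector over the tips.
#' @param mode "fitch" or "dollo".
#' @param tie_break state used for Fitch root/downpass ties ("absent" or
#'   "present").
#' @return list: `states` (0/1 per node), `events` (data.frame edge, child,
#'   type), `n_changes`.
#' @export
parsimony_reconstruct <- function(tree, presence,
                                  mode = c("fitch", "dollo"),
                                  tie_break = c("absent", "present")) {
  mode <- match.arg(mode)
  tie_break <- match.arg(tie_break)
  n <- ape::Ntip(tree)
  if (!all(tree$tip.label %in% names(presence)))
    stop_input("presence vector does not cover all tips")
  x <- as.integer(as.logical(presence[tree$tip.label]))
  nn <- n + tree$Nnode
  states <- integer(nn)
  if (mode == "fitch") {
    sets <- vector("list", nn)
    for (i in seq_len(n)) sets[[i]] <- x[i]
    for (e in postorder_edges(tree)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sets[[p]] <- if (is.null(sets[[p]])) sets[[ch]] else {
        inter <- intersect(sets[[p]], sets[[ch]])
        if (length(inter)) inter else union(sets[[p]], sets[[ch]])
      }
    }
    pick <- function(s) {
      if (length(s) == 1) s else if (tie_break == "absent") 0L else 1L
    }
    root <- n + 1L
    states[root] <- pick(sets[[root]])
    for (e in preorder_edges(tree)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      states[ch] <- if (states[p] %in% sets[[ch]]) states[p]
                    else pick(sets[[ch]])
    }
  } else {
    carriers <- which(x == 1)
    if (length(carriers) == 0) {
      states[] <- 0L
    } else {
      mrca <- if (length(carriers) == 1) carriers else
        ape::getMRCA(tree, tree$tip.label[carriers])
      tu <- tips_under(tree)
      ## a node is inside the MRCA subtree iff its tip set is a subset
      in_sub <- vapply(seq_len(nn), function(nd)
        all(tu[[nd]] %in% tu[[mrca]]), logical(1))
      has_carrier <- vapply(seq_len(nn), function(nd)
        any(x[tu[[nd]]] == 1), logical(1))
      states <- as.integer(in_sub & has_carrier)
    }
  }
  ev <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (states[p] != states[ch])
      ev[[length(ev) + 1L]] <- data.frame(
        edge = e, child = ch,
        type = if (states[ch] == 1) "gain" else "loss",
        stringsAsFactors = FALSE)
  }
  ## Dollo: a family carried by tips but absent at the root gains on the
  ## MRCA stem; when the MRCA is the root itself the gain predates the tree.
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(edge = integer(0), child = integer(0), type = character(0),
               stringsAsFactors = FALSE)
  list(states = states, events = events, n_changes = nrow(events))
}

## ---- two-state CTMC machinery ------------------------------------------

## transition probabilities for gain a (0->1), loss b (1->0) over time t
p2 <- function(a, b, t) {
  s <- a + b
  if (s == 0) return(matrix(c(1, 0, 0, 1), 2))
  e <- exp(-s * t)
  matrix(c((b + a * e) / s, b * (1 - e) / s,
           a * (1 - e) / s, (a + b * e) / s), 2)
  ## column-major: [P00, P10, P01, P11] -> rows = from, cols = to
}

## pruning pass; X: tips x families 0/1 matrix. Returns list of per-node
## partial-likelihood matrices (families x 2) and per-edge P matrices.
prune_2state <- function(tree, X, rates_edge) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  nf <- ncol(X)
  L <- vector("list", nn)
  for (i in seq_len(n)) {
    x <- X[tree$tip.label[i], ]
    L[[i]] <- cbind(1 - x, x)
  }
  Pm <- vector("list", nrow(tree$edge))
  M <- vector("list", nrow(tree$edge))  # M_e = L_child %*% t(P_e)
  for (e in postorder_edges(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    Pe <- p2(rates_edge$gain[e], rates_edge$loss[e], tree$edge.length[e])
    Pm[[e]] <- Pe
    Me <- L[[ch]] %*% t(Pe)
    M[[e]] <- Me
    L[[p]] <- if (is.null(L[[p]])) Me else L[[p]] * Me
  }
  list(L = L, P = Pm, M = M)
}

#' Maximum-likelihood gain/loss rate fit and ancestral content
#'
#' Fits a two-state (absent/present) continuous-time Markov chain to a
#' presence/absence matrix on a fixed tree, with one gain and one loss rate
#' per branch class. The likelihood uses the pruning recursion and is
#' conditioned on each family being observed in at least one tip
#' (ascertainment correction); the root prior is the stationary
#' distribution of the branch-length-weighted mean rates. Returns marginal
#' ancestral presence probabilities, expected per-branch gain/loss events
#' (posterior probability of differing endpoint states), and per-node
#' expected gene counts.
#'
#' @param tree rooted ape `phylo` with positive branch lengths.
#' @param mat a `presence_matrix` whose genomes are the tips.
#' @param branch_classes integer class per edge (default all 1).
#' @param n_starts optimizer restarts (default 3).
#' @param root_prior "estimated" (root presence probability fitted as a free
#'   parameter; robust when the true root genome is far from stationarity)
#'   or "stationary" (stationary distribution of the fitted mean rates).
#' @return a `flux_report`: `rates` (per class, per unit tree height —
#'   branch lengths are height-normalized before fitting), `loglik`,
#'   `marginals`
#'   (nodes x families presence probability), `node_counts`,
#'   `branch_events` (edge, child, expected gains/losses), `tree`.
#' @export
ml_gain_loss_fit <- function(tree, mat, branch_classes = NULL, n_starts = 3,
                             root_prior = c("estimated", "stationary")) {
  root_prior <- match.arg(root_prior)
  if (!all(tree$tip.label %in% rownames(mat)))
    stop_input("matrix does not cover all tips")
  if (any(tree$edge.length <= 0))
    stop_input("tree must have positive branch lengths")
  ne <- nrow(tree$edge)
  cls <- branch_classes %||% rep(1L, ne)
  if (length(cls) != ne) stop_input("branch_classes must have one entry per edge")
  cls <- as.integer(factor(cls))
  ncls <- max(cls)
  ## fit on a height-normalized tree so rates are per unit tree height and
  ## the optimizer starts in a sane region whatever the input units
  height <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / height
  X <- mat[tree$tip.label, , drop = FALSE] * 1
  keep <- colSums(X) > 0
  X <- X[, keep, drop = FALSE]
  nf <- ncol(X)
  n <- ape::Ntip(tree)
  root <- n + 1L
  wlen <- tapply(tree$edge.length, cls, sum)

  edge_rates <- function(theta) {
    g <- exp(theta[seq_len(ncls)]); l <- exp(theta[ncls + seq_len(ncls)])
    list(gain = g[cls], loss = l[cls],
         gbar = sum(g * wlen) / sum(wlen), lbar = sum(l * wlen) / sum(wlen))
  }
  root_pi <- function(theta, r) {
    if (root_prior == "estimated") {
      p <- stats::plogis(theta[2 * ncls + 1])
      c(1 - p, p)
    } else c(r$lbar, r$gbar) / (r$gbar + r$lbar)
  }
  loglik_fun <- function(theta) {
    r <- edge_rates(theta)
    pr <- prune_2state(tree, X, r)
    pi_ <- root_pi(theta, r)
    lik <- pr$L[[root]] %*% pi_
    ## ascertainment: probability of the all-absent pattern
    X0 <- matrix(0, n, 1, dimnames = list(tree$tip.label, "z"))
    p0 <- (prune_2state(tree, X0, r)$L[[root]] %*% pi_)[1]
    sum(log(pmax(lik, 1e-300))) - nf * log(max(1 - p0, 1e-300))
  }
  extra <- if (root_prior == "estimated") 0 else NULL
  starts <- list(c(log(rep(c(0.5, 0.5), each = ncls)), extra),
                 c(log(rep(c(0.05, 0.2), each = ncls)), extra),
                 c(log(rep(c(1.0, 0.2), each = ncls)), extra))
  best <- NULL
  for (s in seq_len(min(n_starts, length(starts)))) {
    fit <- tryCatch({
      f1 <- optim(starts[[s]], function(th) -loglik_fun(th),
                  method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-10))
      ## gradient polish off the simplex's resting point
      f2 <- optim(f1$par, function(th) -loglik_fun(th), method = "BFGS",
                  control = list(maxit = 200, reltol = 1e-12))
      if (f2$value < f1$value) f2 else f1
    }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_input("gain/loss optimization failed to converge")
  theta <- best$par
  r <- edge_rates(theta)
  pr <- prune_2state(tree, X, r)
  pi_ <- root_pi(theta, r)

  ## up-down pass: above-likelihoods per node
  nn <- n + tree$Nnode
  A <- vector("list", nn)
  A[[root]] <- matrix(pi_, nf, 2, byrow = TRUE)
  children_of <- split(seq_len(ne), tree$edge[, 1])
  for (e in preorder_edges(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sibs <- setdiff(children_of[[as.character(p)]], e)
    Ap <- A[[p]]
    for (se in sibs) Ap <- Ap * pr$M[[se]]
    A[[ch]] <- Ap %*% pr$P[[e]]
  }
  marg <- matrix(NA_real_, nn, nf)
  for (nd in seq_len(nn)) {
    w <- A[[nd]] * pr$L[[nd]]
    marg[nd, ] <- w[, 2] / rowSums(w)
  }
  colnames(marg) <- colnames(X)
  lik <- as.numeric(pr$L[[root]] %*% pi_)
  ## expected endpoint-state changes per branch
  gains <- losses <- numeric(ne)
  for (e in seq_len(ne)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sibs <- setdiff(children_of[[as.character(p)]], e)
    Ap <- A[[p]]
    for (se in sibs) Ap <- Ap * pr$M[[se]]
    Pe <- pr$P[[e]]
    j01 <- Ap[, 1] * Pe[1, 2] * pr$L[[ch]][, 2] / lik
    j10 <- Ap[, 2] * Pe[2, 1] * pr$L[[ch]][, 1] / lik
    gains[e] <- sum(j01)
    losses[e] <- sum(j10)
  }
  rates <- data.frame(class = seq_len(ncls),
                      gain = exp(theta[seq_len(ncls)]),
                      loss = exp(theta[ncls + seq_len(ncls)]))
  structure(list(
    rates = rates, loglik = -best$value,
    marginals = marg,
    node_counts = rowSums(marg),
    branch_events = data.frame(edge = seq_len(ne),
                               child = tree$edge[, 2],
                               gains = gains, losses = losses),
    branch_classes = cls, tree = tree, families = colnames(X)),
    class = "flux_report")
}

## brute-force likelihood over all ancestral state assignments (test oracle)
enumerate_2state_loglik <- function(tree, X, gain, loss, condition = TRUE) {
  n <- ape::Ntip(tree)
  nint <- tree$Nnode
  root <- n + 1L
  pi_ <- c(loss, gain) / (gain + loss)
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e)
    p2(gain, loss, tree$edge.length[e]))
  pattern_lik <- function(x_tips) {
    tot <- 0
    for (code in 0:(2^nint - 1)) {
      anc <- as.integer(intToBits(code))[seq_len(nint)]
      st <- c(x_tips, anc)
      pr <- pi_[st[root] + 1]
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        pr <- pr * Pm[[e]][st[p] + 1, st[ch] + 1]
      }
      tot <- tot + pr
    }
    tot
  }
  liks <- apply(X[tree$tip.label, , drop = FALSE], 2, pattern_lik)
  p0 <- pattern_lik(rep(0L, n))
  if (condition) sum(log(liks)) - ncol(X) * log(1 - p0) else sum(log(liks))
}

#' Ancestral gene content from a fitted flux report
#'
#' @param flux a `flux_report`.
#' @param threshold presence-probability cutoff (default 0.5, strict >).
#' @return list: `root_families`, `node_counts` (families above threshold
#'   per node), `expansion` (TRUE iff root count < mean tip count).
#' @export
ancestral_content <- function(flux, threshold = 0.5) {
  n <- ape::Ntip(flux$tree)
  root <- n + 1L
  content <- flux$marginals > threshold
  counts <- rowSums(content)
  list(root_families = flux$families[content[root, ]],
       node_counts = counts,
       expansion = counts[root] < mean(counts[seq_len(n)]))
}

#' Classify the origin of lineage-specific families
#'
#' A lineage-specific family is "gained-on-lineage" iff absent from the
#' reconstructed root genome; families present at the root are
#' "LCA-inherited-retained" when every tip of the target lineage carries
#' them, otherwise "LCA-inherited-partially-retained".
#'
#' @param specific data.frame with columns `trait` (lineage label) and
#'   `family` (from [select_specific_genes()], rows with `specific = TRUE`).
#' @param flux a `flux_report` on the same tree/matrix.
#' @param mat the `presence_matrix`.
#' @param lineages named tip -> lineage labels matching `trait` values.
#' @param threshold root-presence probability cutoff (default 0.5).
#' @return data.frame (trait, family, origin) plus per-lineage tallies in
#'   attribute `tally`.
#' @export
classify_specific_origins <- function(specific, flux, mat, lineages,
                                      threshold = 0.5) {
  if (!all(specific$family %in% flux$families))
    stop_input("family absent from flux report: %s",
               setdiff(specific$family, flux$families)[1])
  root <- ape::Ntip(flux$tree) + 1L
  origin <- character(nrow(specific))
  for (i in seq_len(nrow(specific))) {
    f <- specific$family[i]
    at_root <- flux$marginals[root, f] > threshold
    if (!at_root) origin[i] <- "gained-on-lineage"
    else {
      tips <- names(lineages)[lineages == specific$trait[i]]
      origin[i] <- if (all(mat[tips, f]))
        "LCA-inherited-retained" else "LCA-inherited-partially-retained"
    }
  }
  out <- data.frame(trait = specific$trait, family = specific$family,
                    origin = origin, stringsAsFactors = FALSE)
  attr(out, "tally") <- table(out$trait, out$origin)
  out
}
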