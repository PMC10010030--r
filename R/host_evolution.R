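## Strict-clock least-squares dating with a single calibration, and
## ancestral host-state reconstruction (Fitch parsimony or an asymmetric
## k-state CTMC fitted by maximum likelihood), with host-switch enumeration.

## least-squares node "positions" u (= rate * age) for fixed tip/root values
solve_ls_ages <- function(tree, b, fixed) {
  nn <- ape::Ntip(tree) + tree$Nnode
  unknown <- setdiff(seq_len(nn), which(!is.na(fixed)))
  idx <- match(seq_len(nn), unknown)
  A <- matrix(0, length(unknown), length(unknown))
  rhs <- numeric(length(unknown))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    for (nd in c(p, ch)) {
      i <- idx[nd]
      if (is.na(i)) next
      sign_b <- if (nd == p) 1 else -1
      other <- if (nd == p) ch else p
      A[i, i] <- A[i, i] + 1
      if (is.na(idx[other])) rhs[i] <- rhs[i] + fixed[other]
      else A[i, idx[other]] <- A[i, idx[other]] - 1
      rhs[i] <- rhs[i] + sign_b * b[e]
    }
  }
  u <- fixed
  if (length(unknown)) u[unknown] <- solve(A, rhs)
  u
}

#' Strict-clock dating by least squares
#'
#' Estimates node ages minimizing the squared difference between observed
#' branch lengths (substitutions/site) and rate x duration, with all tips
#' contemporaneous at age 0. Calibrate with either a fixed root age (the
#' rate is then estimated jointly) or a fixed rate.
#'
#' @param tree rooted ape `phylo` with substitution branch lengths.
#' @param root_age root calibration in years (exactly one of `root_age`,
#'   `rate`).
#' @param rate substitution rate (subs/site/year).
#' @return a `dated_tree`: `tree` (branch lengths in years), `ages` (years
#'   before present per node), `rate`, `calibration`, `residual`, `flagged`.
#' @export
strict_clock_date <- function(tree, root_age = NULL, rate = NULL) {
  if (!ape::is.rooted(tree)) stop_input("tree must be rooted")
  if (is.null(root_age) == is.null(rate))
    stop_input("give exactly one of root_age or rate")
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  root <- n + 1L
  b <- tree$edge.length
  fixed <- rep(NA_real_, nn)
  fixed[seq_len(n)] <- 0
  if (!is.null(rate)) {
    u <- solve_ls_ages(tree, b, fixed)
    ages <- u / rate
  } else {
    ## alternate between solving positions with the root pinned at
    ## rate*root_age and updating the rate estimate
    depth <- ape::node.depth.edgelength(tree)
    r <- mean(depth[seq_len(n)]) / root_age
    for (it in 1:100) {
      fx <- fixed
      fx[root] <- r * root_age
      u <- solve_ls_ages(tree, b, fx)
      ages <- u / r
      dt <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
      r_new <- sum(b * dt) / sum(dt^2)
      if (abs(r_new - r) < 1e-14 * r) { r <- r_new; break }
      r <- r_new
    }
    fx <- fixed
    fx[root] <- r * root_age
    ages <- solve_ls_ages(tree, b, fx) / r
    rate <- r
  }
  ## enforce parent >= child >= 0 (flag when the projection changes anything)
  flagged <- FALSE
  if (any(ages < -1e-9)) { flagged <- TRUE; ages[ages < 0] <- 0 }
  for (e in preorder_edges(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (ch > n && ages[ch] > ages[p] + 1e-12) {
      ages[ch] <- ages[p]
      flagged <- TRUE
    }
  }
  dated <- tree
  dated$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  resid <- sum((b - rate * dated$edge.length)^2)
  structure(list(tree = dated, ages = ages, rate = rate,
                 calibration = if (is.null(root_age)) "rate" else "root_age",
                 residual = resid, flagged = flagged),
            class = "dated_tree")
}

## ---- ancestral host states ---------------------------------------------

stationary_dist <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  pi_ <- qr.solve(A, c(rep(0, k), 1))
  pi_ <- pmax(pi_, 0)
  pi_ / sum(pi_)
}

## pruning likelihood for a k-state chain; tips: integer state per tip
prune_kstate <- function(tree, tip_state, Q, pi_) {
  k <- nrow(Q)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  L <- vector("list", nn)
  for (i in seq_len(n)) {
    v <- numeric(k); v[tip_state[i]] <- 1
    L[[i]] <- v
  }
  Pm <- vector("list", nrow(tree$edge))
  M <- vector("list", nrow(tree$edge))
  for (e in postorder_edges(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    Pe <- ape::matexpo(Q * tree$edge.length[e])
    Pm[[e]] <- Pe
    Me <- as.numeric(Pe %*% L[[ch]])
    M[[e]] <- Me
    L[[p]] <- if (is.null(L[[p]])) Me else L[[p]] * Me
  }
  list(L = L, P = Pm, M = M,
       lik = sum(pi_ * L[[n + 1L]]))
}

build_Q <- function(theta, k) {
  Q <- matrix(0, k, k)
  Q[row(Q) != col(Q)] <- exp(theta)
  diag(Q) <- -rowSums(Q)
  Q
}

#' Ancestral host-state reconstruction
#'
#' `model = "parsimony"`: Fitch state sets with ambiguity retained (modal
#' state by fixed host-label order, flagged). `model = "ctmc_asymmetric"`:
#' a k-state rate matrix with independent off-diagonal rates fitted by
#' maximum likelihood via the pruning recursion (root prior = stationary
#' distribution of the fitted matrix); marginal state probabilities per
#' node by the up-down pass.
#'
#' @param dated a `dated_tree` (or any rooted `phylo` in a list with
#'   `$tree`), times in years.
#' @param tip_hosts named host label per tip.
#' @param model "ctmc_asymmetric" or "parsimony".
#' @return a `host_history`: `states` (modal per node), `probs`
#'   (nodes x states, CTMC only), `ambiguous`, `Q`, `loglik`, `host_levels`.
#' @export
ancestral_hosts <- function(dated, tip_hosts,
                            model = c("ctmc_asymmetric", "parsimony")) {
  model <- match.arg(model)
  tree <- if (inherits(dated, "phylo")) dated else dated$tree
  if (!all(tree$tip.label %in% names(tip_hosts)))
    stop_input("unlabelled tip: %s",
               setdiff(tree$tip.label, names(tip_hosts))[1])
  hosts <- as.character(tip_hosts[tree$tip.label])
  lev <- sort(unique(hosts))
  k <- length(lev)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  if (k == 1) {
    return(structure(list(
      states = rep(lev, nn), probs = NULL, ambiguous = rep(FALSE, nn),
      Q = NULL, loglik = 0, host_levels = lev, model = model),
      class = "host_history"))
  }
  if (model == "parsimony") {
    sets <- vector("list", nn)
    for (i in seq_len(n)) sets[[i]] <- hosts[i]
    for (e in postorder_edges(tree)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sets[[p]] <- if (is.null(sets[[p]])) sets[[ch]] else {
        inter <- intersect(sets[[p]], sets[[ch]])
        if (length(inter)) inter else union(sets[[p]], sets[[ch]])
      }
    }
    states <- character(nn)
    amb <- logical(nn)
    root <- n + 1L
    states[root] <- lev[min(match(sets[[root]], lev))]
    amb[root] <- length(sets[[root]]) > 1
    for (e in preorder_edges(tree)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (states[p] %in% sets[[ch]]) states[ch] <- states[p]
      else {
        states[ch] <- lev[min(match(sets[[ch]], lev))]
        amb[ch] <- length(sets[[ch]]) > 1
      }
    }
    return(structure(list(states = states, probs = NULL, ambiguous = amb,
                          Q = NULL, loglik = NA_real_, host_levels = lev,
                          model = model),
                     class = "host_history"))
  }
  tip_state <- match(hosts, lev)
  scale <- max(node_ages(tree))
  tre <- tree
  tre$edge.length <- tree$edge.length / scale  # rates in per-tree-height units
  init_rate <- max(length(unique(hosts)) - 1, 1) / sum(tre$edge.length)
  nllk <- function(theta) {
    Q <- build_Q(theta, k)
    pi_ <- stationary_dist(Q)
    pr <- prune_kstate(tre, tip_state, Q, pi_)
    -log(max(pr$lik, 1e-300))
  }
  best <- NULL
  for (s in c(1, 0.3)) {
    fit <- tryCatch(
      optim(rep(log(init_rate * s), k * (k - 1)), nllk, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_input("host CTMC optimization failed")
  Q <- build_Q(best$par, k)
  pi_ <- stationary_dist(Q)
  pr <- prune_kstate(tre, tip_state, Q, pi_)
  ## up-down marginals
  children_of <- split(seq_len(nrow(tre$edge)), tre$edge[, 1])
  A <- vector("list", nn)
  A[[n + 1L]] <- pi_
  for (e in preorder_edges(tre)) {
    p <- tre$edge[e, 1]; ch <- tre$edge[e, 2]
    Ap <- A[[p]]
    for (se in setdiff(children_of[[as.character(p)]], e))
      Ap <- Ap * pr$M[[se]]
    A[[ch]] <- as.numeric(t(pr$P[[e]]) %*% Ap)
  }
  probs <- matrix(NA_real_, nn, k, dimnames = list(NULL, lev))
  for (nd in seq_len(nn)) {
    w <- A[[nd]] * pr$L[[nd]]
    probs[nd, ] <- w / sum(w)
  }
  mx <- apply(probs, 1, max)
  states <- lev[apply(probs, 1, which.max)]
  amb <- apply(probs, 1, function(p) sum(abs(p - max(p)) < 1e-9) > 1)
  structure(list(states = states, probs = probs, ambiguous = amb,
                 Q = Q / scale, loglik = -best$value, host_levels = lev,
                 model = model),
            class = "host_history")
}

## brute-force k-state likelihood over ancestral assignments (test oracle)
enumerate_kstate_lik <- function(tree, tip_state, Q, pi_) {
  n <- ape::Ntip(tree)
  nint <- tree$Nnode
  k <- nrow(Q)
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e)
    ape::matexpo(Q * tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    st <- c(tip_state, grid[r, ])
    pr <- pi_[st[n + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * Pm[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    tot <- tot + pr
  }
  tot
}

#' Enumerate host-switch events
#'
#' One row per branch whose endpoint modal states differ: origin and
#' destination host and the time interval bracketing the switch, sorted
#' oldest first.
#'
#' @param history a `host_history`.
#' @param dated a `dated_tree` on the same topology (ages in years).
#' @return data.frame: edge, from, to, age_older, age_younger.
#' @export
enumerate_host_switches <- function(history, dated) {
  tree <- dated$tree
  ages <- dated$ages
  rows <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (history$states[p] != history$states[ch])
      rows[[length(rows) + 1L]] <- data.frame(
        edge = e, from = history$states[p], to = history$states[ch],
        age_older = ages[p], age_younger = ages[ch],
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(edge = integer(0), from = character(0), to = character(0),
               age_older = numeric(0), age_younger = numeric(0))
  out[order(-out$age_older), , drop = FALSE]
}
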