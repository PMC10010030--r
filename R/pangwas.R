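## Pan-GWAS: lineage-/group-specific gene detection by joint
## sensitivity/specificity thresholds and three p-values (naive Fisher,
## multiplicity-adjusted, and label-permutation empirical).

## two-sided Fisher exact p by hypergeometric enumeration: sum of
## probabilities of tables (with the observed margins) no more likely than
## the observed one
fisher_p <- function(tp, fp, fn, tn) {
  m <- tp + fn        # trait-positive genomes
  n_ <- fp + tn       # trait-negative genomes
  k <- tp + fp        # genomes carrying the gene
  x <- 0:min(k, m)
  probs <- dhyper(x, m, n_, k)
  obs <- dhyper(tp, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Score one gene family against a binary trait
#'
#' Builds the 2x2 presence-by-trait table; sensitivity = 100*TP/(TP+FN)
#' (trait-positives carrying the gene), specificity = 100*TN/(TN+FP)
#' (trait-negatives lacking it); `p_naive` is the two-sided Fisher exact
#' probability. A constant presence column is flagged and given p = 1.
#'
#' @param presence named logical/0-1 vector (gene presence per genome).
#' @param trait named binary vector (1 = member of the tested lineage/group),
#'   with at least one 0 and one 1.
#' @return list: counts `tp/fp/fn/tn`, `sensitivity`, `specificity`,
#'   `p_naive`, `constant` flag.
#' @export
score_family <- function(presence, trait) {
  trait <- trait[names(presence)]
  if (any(is.na(trait))) stop_input("trait missing for some genomes")
  if (!any(trait == 1) || !any(trait == 0))
    stop_input("trait must contain both 0 and 1")
  pres <- as.logical(presence)
  tp <- sum(pres & trait == 1); fn <- sum(!pres & trait == 1)
  fp <- sum(pres & trait == 0); tn <- sum(!pres & trait == 0)
  constant <- all(pres) || all(!pres)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       p_naive = if (constant) 1 else fisher_p(tp, fp, fn, tn),
       constant = constant)
}

#' Empirical p-value by trait-label permutation
#'
#' Permutes the trait labels `n_permutations` times and reports
#' p = (1 + #\{permuted Fisher p <= observed\}) / (n_permutations + 1).
#'
#' @inheritParams score_family
#' @param n_permutations default 1000.
#' @param seed integer seed.
#' @param ties "inclusive" counts permutations tied with the observed
#'   Fisher p as extreme (the conventional, conservative rule);
#'   "randomized" breaks ties uniformly at random, which makes the p-value
#'   exactly uniform under the permutation null (used for calibration
#'   checks; the Fisher p is discrete, so the inclusive rule alone cannot
#'   be uniform).
#' @return numeric p-value.
#' @export
empirical_p <- function(presence, trait, n_permutations = 1000, seed = 1,
                        ties = c("inclusive", "randomized")) {
  ties <- match.arg(ties)
  obs <- score_family(presence, trait)$p_naive
  trait <- trait[names(presence)]
  with_seed(op_seed(seed, "empirical_p"), {
    cnt_less <- 0L
    cnt_tie <- 0L
    for (b in seq_len(n_permutations)) {
      pb <- score_family(presence, setNames(sample(trait),
                                            names(trait)))$p_naive
      if (pb <= obs - 1e-12) cnt_less <- cnt_less + 1L
      else if (abs(pb - obs) <= 1e-12) cnt_tie <- cnt_tie + 1L
    }
    if (ties == "inclusive")
      (1 + cnt_less + cnt_tie) / (n_permutations + 1)
    else  # observed value takes a uniform rank among its ties
      (cnt_less + sample.int(cnt_tie + 1L, 1L)) / (n_permutations + 1)
  })
}

#' Select trait-specific gene families
#'
#' For each trait, scores every non-constant family, applies
#' Benjamini-Hochberg and Bonferroni corrections across the families tested
#' for that trait, computes the permutation empirical p, and calls a family
#' specific iff sensitivity > `sens_min`, specificity > `spec_min`, and the
#' naive, selected adjusted, and empirical p-values are all < `alpha`
#' (strict inequalities throughout).
#'
#' @param mat a `presence_matrix`.
#' @param traits named list of binary trait vectors (one per tested
#'   lineage/group), or a single such vector.
#' @param sens_min,spec_min percent thresholds (default 70).
#' @param alpha significance threshold (default 0.05).
#' @param adjust which adjusted p gates the decision: "bh" or "bonferroni".
#' @param n_permutations permutations for the empirical p (default 1000).
#' @param seed integer seed.
#' @return data.frame with one row per (trait, family): counts, sensitivity,
#'   specificity, `p_naive`, `p_bh`, `p_bonferroni`, `p_empirical`,
#'   `specific`.
#' @export
select_specific_genes <- function(mat, traits, sens_min = 70, spec_min = 70,
                                  alpha = 0.05,
                                  adjust = c("bh", "bonferroni"),
                                  n_permutations = 1000, seed = 1) {
  adjust <- match.arg(adjust)
  if (!is.list(traits)) traits <- list(trait = traits)
  out <- list()
  for (tn in names(traits)) {
    trait <- traits[[tn]]
    cnt <- colSums(mat)
    testable <- colnames(mat)[cnt > 0 & cnt < nrow(mat)]
    if (!length(testable)) {
      warning(sprintf("no testable families for trait '%s'", tn))
      next
    }
    rows <- lapply(testable, function(f) {
      sc <- score_family(mat[, f], trait)
      data.frame(trait = tn, family = f, tp = sc$tp, fp = sc$fp,
                 fn = sc$fn, tn_count = sc$tn,
                 sensitivity = sc$sensitivity, specificity = sc$specificity,
                 p_naive = sc$p_naive, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$p_bh <- p.adjust(df$p_naive, method = "BH")
    df$p_bonferroni <- p.adjust(df$p_naive, method = "bonferroni")
    ## empirical p only where the cheap gates can still pass (the decision
    ## for other rows cannot change); full permutation otherwise
    p_adj <- if (adjust == "bh") df$p_bh else df$p_bonferroni
    gate <- df$sensitivity > sens_min & df$specificity > spec_min &
      df$p_naive < alpha & p_adj < alpha
    df$p_empirical <- NA_real_
    for (i in which(gate))
      df$p_empirical[i] <- empirical_p(mat[, df$family[i]], trait,
                                       n_permutations,
                                       seed = op_seed(seed, df$family[i]))
    df$specific <- gate & !is.na(df$p_empirical) & df$p_empirical < alpha
    out[[tn]] <- df
  }
  if (!length(out))
    return(data.frame(trait = character(0), family = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
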