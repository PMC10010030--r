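## Prophage exchange: retention filtering, directional shared-sequence
## percentages between lineages via maximal exact common substrings
## (k-mer seeding + extension; an O(nm) dynamic-programming oracle lives in
## src/ for verification), and the exchange-network summary.

new_prophage_set <- function(sequences, info, genes) {
  stopifnot(all(names(sequences) == info$id))
  structure(list(sequences = sequences, info = info, genes = genes),
            class = "prophage_set")
}

#' Filter prophage sequences by length and gene content
#'
#' Keeps sequences of at least 5000 bp that have at least one viral gene or
#' no bacterial genes; everything else is discarded with a logged reason.
#'
#' @param ps a `prophage_set`.
#' @param min_length minimum length in bp (default 5000; "shorter than 5 kb"
#'   is read strictly).
#' @return filtered `prophage_set` with attribute `discarded`
#'   (data.frame id, reason).
#' @export
filter_prophages <- function(ps, min_length = 5000) {
  info <- ps$info
  too_short <- info$length < min_length
  no_viral <- info$bacterial_genes > 0 & info$viral_genes == 0
  keep <- !too_short & !no_viral
  reason <- ifelse(too_short, "shorter_than_min",
                   ifelse(no_viral, "bacterial_only", NA))
  out <- new_prophage_set(ps$sequences[info$id[keep]],
                          info[keep, , drop = FALSE],
                          ps$genes[ps$genes$id %in% info$id[keep], ,
                                   drop = FALSE])
  attr(out, "discarded") <- data.frame(id = info$id[!keep],
                                       reason = reason[!keep],
                                       stringsAsFactors = FALSE)
  out
}

## per-sequence match cache: character vector plus exact 2-bit k-mer codes
## (k <= 16 so codes < 4^16 are exact in doubles); code collisions cannot
## occur for k = 16 and are in any case validated by extension
seq_cache <- function(s, k = 16L) {
  ns <- nchar(s)
  sc <- strsplit(s, "")[[1]]
  codes <- numeric(0)
  if (ns >= k) {
    ints <- match(sc, c("A", "C", "G", "T")) - 1
    ints[is.na(ints)] <- 0
    codes <- numeric(ns - k + 1L)
    for (j in seq_len(k)) codes <- codes * 4 + ints[j:(ns - k + j)]
  }
  list(n = ns, chars = sc, codes = codes, k = k)
}

## maximal exact common substring length via k-mer seeding + extension;
## q, s: raw strings or seq_cache objects
seed_extend_lcs <- function(q, s, min_fragment = 5000, k = 16L) {
  k <- min(k, min_fragment + 1L)
  if (is.character(q)) q <- seq_cache(q, k)
  if (is.character(s)) s <- seq_cache(s, k)
  stopifnot(q$k == k, s$k == k)
  nq <- q$n; ns <- s$n
  if (nq < k || ns < k) return(0L)
  stride <- max(1L, min_fragment + 2L - k)
  probes <- unique(c(seq(1L, nq - k + 1L, by = stride), nq - k + 1L))
  qc <- q$chars
  sc <- s$chars
  run_len <- function(eq) {  # leading run of TRUE
    if (!length(eq)) 0L else {
      m <- match(FALSE, eq)
      if (is.na(m)) length(eq) else m - 1L
    }
  }
  best <- 0L
  seen_diag <- integer(0)
  for (qi in probes) {
    hits <- which(s$codes == q$codes[qi])
    for (sj in hits) {
      dg <- qi - sj
      if (dg %in% seen_diag) next
      seen_diag <- c(seen_diag, dg)
      nl <- min(qi, sj) - 1L
      l <- if (nl > 0)
        run_len(rev(qc[(qi - nl):(qi - 1L)]) == rev(sc[(sj - nl):(sj - 1L)]))
      else 0L
      nr <- min(nq - qi, ns - sj) - k + 1L
      r <- if (nr > 0)
        run_len(qc[(qi + k):(qi + k - 1L + nr)] ==
                  sc[(sj + k):(sj + k - 1L + nr)])
      else 0L
      best <- max(best, k + l + r)
      if (best > min_fragment) return(best)
    }
  }
  best
}

#' Longest exact common substring of two sequences
#'
#' @param a,b character scalars (DNA sequences).
#' @param method "seed" (k-mer seeding + maximal extension, the production
#'   path) or "dp" (O(nm) dynamic programming in C++, the oracle).
#' @param min_fragment early-exit threshold for the seed method; matches at
#'   or below this length may be reported conservatively.
#' @return integer length of the longest common substring found.
#' @export
longest_common_substring <- function(a, b, method = c("seed", "dp"),
                                     min_fragment = 5000) {
  method <- match.arg(method)
  if (method == "dp") lcs_length_dp(a, b)
  else seed_extend_lcs(a, b, min_fragment)
}

#' Directed shared-prophage percentage between two sequence sets
#'
#' A query counts iff it shares a maximal exact common substring strictly
#' longer than `min_fragment` bp with at least one subject sequence;
#' the result is 100 x counted / submitted.
#'
#' @param queries,subjects character vectors of prophage sequences.
#' @param min_fragment fragment threshold in bp (default 5000, strict >).
#' @return percentage, with attribute `counted`.
#' @export
directed_shared_fraction <- function(queries, subjects, min_fragment = 5000) {
  if (!length(queries)) stop_input("empty query set")
  if (!length(subjects)) stop_input("empty subject set")
  k <- min(16L, min_fragment + 1L)
  if (is.character(queries)) queries <- lapply(queries, seq_cache, k = k)
  if (is.character(subjects)) subjects <- lapply(subjects, seq_cache, k = k)
  hit <- vapply(queries, function(q) {
    for (s in subjects)
      if (seed_extend_lcs(q, s, min_fragment, k) > min_fragment) return(TRUE)
    FALSE
  }, logical(1))
  structure(100 * sum(hit) / length(hit), counted = sum(hit))
}

#' Directional prophage-exchange summary over all lineages
#'
#' Builds the full directed lineage x lineage matrix of shared-prophage
#' percentages (queries from the origin lineage searched in the destination
#' lineage), the per-genome intra-lineage sharing (each genome's prophages
#' searched in its lineage mates), and the intra/inter ratio.
#'
#' @param ps a filtered `prophage_set`.
#' @param min_fragment fragment threshold (default 5000).
#' @return list (class `exchange_matrix`): `matrix` (directed percentages,
#'   NA diagonal), `counts` (retained prophages per lineage), `intra_mean`,
#'   `inter_mean`, `ratio`, `edges` (lineage_from, lineage_to, percent).
#' @export
exchange_summary <- function(ps, min_fragment = 5000) {
  info <- ps$info
  lins <- sort(unique(info$lineage))
  if (length(lins) < 2) stop_input("need at least 2 lineages")
  k <- min(16L, min_fragment + 1L)
  caches <- lapply(ps$sequences, seq_cache, k = k)
  seq_of <- function(ids) caches[ids]
  m <- matrix(NA_real_, length(lins), length(lins),
              dimnames = list(lins, lins))
  for (a in lins) for (b in lins) {
    if (a == b) next
    qa <- info$id[info$lineage == a]
    sb <- info$id[info$lineage == b]
    m[a, b] <- if (length(qa) && length(sb))
      as.numeric(directed_shared_fraction(seq_of(qa), seq_of(sb),
                                          min_fragment))
    else NA_real_
  }
  ## intra: genome-vs-lineage-mates
  intra <- c()
  for (g in unique(info$genome)) {
    qg <- info$id[info$genome == g]
    mates <- info$id[info$lineage == info$lineage[info$id == qg[1]] &
                       info$genome != g]
    if (length(qg) && length(mates))
      intra <- c(intra, as.numeric(
        directed_shared_fraction(seq_of(qg), seq_of(mates), min_fragment)))
  }
  intra_mean <- if (length(intra)) mean(intra) else NA_real_
  inter_vals <- m[!is.na(m)]
  inter_mean <- if (length(inter_vals)) mean(inter_vals) else NA_real_
  ratio <- if (!is.na(inter_mean) && inter_mean == 0) Inf
           else intra_mean / inter_mean
  edges <- do.call(rbind, lapply(lins, function(a)
    do.call(rbind, lapply(setdiff(lins, a), function(b)
      data.frame(lineage_from = a, lineage_to = b, percent = m[a, b],
                 stringsAsFactors = FALSE)))))
  structure(list(matrix = m,
                 counts = table(info$lineage),
                 intra_mean = intra_mean, inter_mean = inter_mean,
                 ratio = ratio, edges = edges),
            class = "exchange_matrix")
}
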