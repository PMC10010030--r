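## Pan-genome: presence/absence matrix, core/accessory/singleton partition,
## accumulation curve with Heaps-law fit, and gene-content Jaccard distances.

new_presence_matrix <- function(mat, provenance = "unknown") {
  stopifnot(is.matrix(mat), is.logical(mat))
  structure(mat, provenance = provenance, class = c("presence_matrix", "matrix"))
}

#' Build a presence/absence matrix from per-genome family lists
#'
#' @param family_lists named list: genome id -> character vector of family ids.
#' @return a `presence_matrix` (genomes x families, logical).
#' @export
build_presence_matrix <- function(family_lists) {
  if (!length(family_lists)) stop_input("empty input: no genomes")
  ids <- names(family_lists)
  if (is.null(ids) || any(ids == "")) stop_input("genome lists must be named")
  if (anyDuplicated(ids)) stop_input("duplicate genome id: %s",
                                     ids[duplicated(ids)][1])
  fams <- sort(unique(unlist(family_lists)))
  mat <- matrix(FALSE, length(ids), length(fams), dimnames = list(ids, fams))
  for (g in ids) mat[g, unique(family_lists[[g]])] <- TRUE
  new_presence_matrix(mat, provenance = "built")
}

#' Partition families into core, accessory and singleton
#'
#' A family is core iff its prevalence is strictly greater than
#' `core_threshold` (the ">95% of genomes" rule), accessory iff at or below
#' the threshold but present in more than one genome, singleton iff present
#' in exactly one genome.
#'
#' @param mat a `presence_matrix`.
#' @param core_threshold prevalence fraction, default 0.95.
#' @return list (class `pan_partition`): `core`, `accessory`, `singleton`
#'   family ids and the threshold.
#' @export
partition_core_accessory <- function(mat, core_threshold = 0.95) {
  if (!(core_threshold > 0 && core_threshold < 1))
    stop_input("core_threshold must be in (0, 1)")
  n <- nrow(mat)
  cnt <- colSums(mat)
  if (any(cnt == 0)) stop_input("families absent from every genome: %s",
                                colnames(mat)[cnt == 0][1])
  core <- colnames(mat)[cnt / n > core_threshold]
  singleton <- colnames(mat)[cnt == 1]
  accessory <- setdiff(colnames(mat)[cnt / n <= core_threshold & cnt > 1],
                       singleton)
  structure(list(core = core, accessory = accessory, singleton = singleton,
                 core_threshold = core_threshold),
            class = "pan_partition")
}

#' Pan-genome accumulation curve and Heaps-law openness
#'
#' Mean cumulative pan-genome size over random genome orderings, with a
#' Heaps-law fit n(N) = kappa * N^gamma by least squares on logs of the
#' permutation-mean curve. The pan-genome is called open iff gamma > 0.
#'
#' @param mat a `presence_matrix`.
#' @param n_permutations number of random orderings (default 100).
#' @param seed integer seed.
#' @return list: `curve` (mean cumulative sizes), `gamma`, `kappa`, `open`.
#' @export
pan_accumulation <- function(mat, n_permutations = 100, seed = 1) {
  n <- nrow(mat)
  if (n < 3) stop_input("need at least 3 genomes, got %d", n)
  with_seed(op_seed(seed, "pan_accumulation"), {
    acc <- matrix(0, n_permutations, n)
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(n)
      seen <- rep(FALSE, ncol(mat))
      for (i in seq_len(n)) {
        seen <- seen | mat[ord[i], ]
        acc[p, i] <- sum(seen)
      }
    }
    curve <- colMeans(acc)
    fit <- stats::lm(log(curve) ~ log(seq_len(n)))
    gamma <- unname(coef(fit)[2])
    kappa <- exp(unname(coef(fit)[1]))
    list(curve = curve, gamma = gamma, kappa = kappa, open = gamma > 0)
  })
}

#' Gene-content Jaccard distance matrix
#'
#' `mode = "standard"`: JD = 1 - |A&B| / |A|B| (the usual Jaccard distance).
#' `mode = "paper_literal"` preserves a published variant that denominates by
#' the symmetric difference, JD = 1 - |A&B| / |A xor B|, defined as 0 when
#' the symmetric difference is empty. The standard mode is the default used
#' downstream; the literal mode is provided only to reproduce that reading.
#'
#' @param mat a `presence_matrix`.
#' @param basis family ids to compute over (typically the accessory set).
#' @param mode "standard" or "paper_literal".
#' @return symmetric distance matrix with `metric` attribute "jaccard".
#' @export
jaccard_distances <- function(mat, basis = colnames(mat),
                              mode = c("standard", "paper_literal")) {
  mode <- match.arg(mode)
  basis <- intersect(basis, colnames(mat))
  if (!length(basis)) stop_input("empty family basis for Jaccard distances")
  m <- mat[, basis, drop = FALSE] * 1L
  inter <- m %*% t(m)
  sums <- rowSums(m)
  uni <- outer(sums, sums, "+") - inter
  if (mode == "standard") {
    d <- 1 - inter / uni
    d[uni == 0] <- 0
  } else {
    sdiff <- uni - inter
    d <- 1 - inter / sdiff
    d[sdiff == 0] <- 0
  }
  diag(d) <- if (mode == "standard") 0 else diag(d)
  dimnames(d) <- list(rownames(mat), rownames(mat))
  attr(d, "metric") <- "jaccard"
  d
}

## ---- TSV round trip (Rtab-style: rows = families, columns = genomes) ----

#' Write / read a presence-absence TSV (Rtab-style)
#'
#' First column is the family id, remaining columns genomes, cells 0/1.
#'
#' @param mat a `presence_matrix`.
#' @param path file path.
#' @export
write_presence_matrix <- function(mat, path) {
  df <- data.frame(Gene = colnames(mat), t(mat * 1L), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @return `read_presence_matrix`: a `presence_matrix`.
#' @export
read_presence_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fams <- df[[1]]
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  if (anyDuplicated(rownames(m))) stop_input("duplicate genome id in %s", path)
  if (anyDuplicated(fams)) stop_input("duplicate family id in %s", path)
  colnames(m) <- fams
  new_presence_matrix(m == 1, provenance = path)
}
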