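## Standard-format round trips: FASTA (Biostrings), Newick (ape),
## square distance TSV, presence/absence TSV (pangenome.R), CSV, JSON.

#' Read / write FASTA sequence sets
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read / write a labelled square distance matrix as TSV
#'
#' @param d symmetric matrix with dimnames.
#' @param path file path.
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(id = rownames(d), as.data.frame(unclass(d)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write Newick trees (support values preserved as node labels)
#'
#' @param tree an ape `phylo`.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
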