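## Pipeline orchestration: runs the stages in dependency order on a
## simulated dataset, writes per-stage outputs under an output directory,
## and produces a deterministic JSON summary (no timestamps, so identical
## configurations give byte-identical summaries).

#' Pipeline configuration
#'
#' All analysis defaults are the published values: core threshold 0.95, PHI
#' window 100 / 100 permutations / alpha 0.05, sensitivity and specificity
#' 70, 1000 GWAS permutations, 5000-bp prophage fragment threshold. Unknown
#' keys are rejected by name.
#'
#' @param ... overrides of the defaults listed above, plus `sim` (a
#'   [sim_config()]), `content_groups`, `nmds_restarts`, `adjust`,
#'   `tree_method`, and `seed`.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sim = NULL, seed = 1L,
    core_threshold = 0.95,
    phi_window = 100, phi_permutations = 100, phi_alpha = 0.05,
    tree_method = "upgma",
    content_groups = 4L, nmds_restarts = 10L,
    gwas_alpha = 0.05, sens_min = 70, spec_min = 70,
    gwas_permutations = 1000L, gwas_adjust = "bh",
    min_fragment = 5000,
    root_age = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop_input("unknown configuration key: %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (is.null(cfg$sim)) cfg$sim <- sim_config(seed = cfg$seed)
  if (is.null(cfg$root_age)) cfg$root_age <- cfg$sim$tree_age
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Stages, in dependency order: simulate, pangenome, structure, ordination,
#' gwas, flux, hosts, prophage, adhesion. Each stage writes its outputs
#' under `outdir` and contributes a block to the JSON summary. Re-running
#' with an identical configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return the summary list, invisibly; written to `outdir`/summary.json.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile()) {
  if (!inherits(config, "pipeline_config"))
    stop_input("config must be a pipeline_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  summary <- list()
  logf <- file.path(outdir, "run.log")
  logline <- function(fmt, ...)
    cat(sprintf("%s %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                sprintf(fmt, ...)), file = logf, append = TRUE)
  write_json_report(config[setdiff(names(config), "sim")],
                    file.path(outdir, "effective_config.json"))

  ## -- simulate ----------------------------------------------------------
  logline("stage simulate: seed %d", config$sim$seed)
  ds <- simulate_dataset(config$sim)
  write_newick(ds$tree$tree, file.path(outdir, "true_tree.nwk"))
  write_presence_matrix(ds$matrix, file.path(outdir, "presence_absence.tsv"))
  write.csv(ds$metadata, file.path(outdir, "metadata.csv"), row.names = FALSE)
  aln_dir <- file.path(outdir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (g in names(ds$alignments))
    write_fasta(ds$alignments[[g]], file.path(aln_dir, paste0(g, ".fasta")))
  write_fasta(ds$prophages$sequences, file.path(outdir, "prophages.fasta"))
  write.table(ds$prophages$genes,
              file.path(outdir, "prophage_annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_json_report(
    list(host_switches = ds$truth$host_switches,
         n_root_families = length(ds$truth$root_families),
         n_gene_events = nrow(ds$truth$events),
         recombination = ds$truth$recombination,
         prophage_transfers = ds$truth$transfers),
    file.path(outdir, "truth.json"))
  summary$simulate <- list(
    n_genomes = nrow(ds$matrix), n_families = ncol(ds$matrix),
    n_core_genes = length(ds$alignments),
    n_prophage_sequences = length(ds$prophages$sequences),
    n_host_switch_events = nrow(ds$truth$host_switches))

  ## -- pangenome ---------------------------------------------------------
  logline("stage pangenome")
  part <- partition_core_accessory(ds$matrix, config$core_threshold)
  acc <- pan_accumulation(ds$matrix, n_permutations = 50, seed = seed)
  jd <- jaccard_distances(ds$matrix, basis = part$accessory)
  write_distance_tsv(jd, file.path(outdir, "jaccard.tsv"))
  summary$pangenome <- list(
    core = length(part$core), accessory = length(part$accessory),
    singleton = length(part$singleton),
    heaps_gamma = acc$gamma, open = acc$open)

  ## -- structure ---------------------------------------------------------
  logline("stage structure: PHI on %d genes", length(ds$alignments))
  phi <- lapply(names(ds$alignments), function(g)
    phi_recombination_test(ds$alignments[[g]], window = config$phi_window,
                           n_permutations = config$phi_permutations,
                           seed = op_seed(seed, g)))
  names(phi) <- names(ds$alignments)
  core_aln <- concatenate_recombination_free(ds$alignments, phi,
                                             alpha = config$phi_alpha)
  snp <- snp_distances(core_aln)
  ani <- core_identity(core_aln)
  core_tree <- distance_tree(snp, method = config$tree_method)
  lin <- delineate_lineages(snp)
  write_distance_tsv(snp, file.path(outdir, "snp_distances.tsv"))
  write_newick(core_tree, file.path(outdir, "core_tree.nwk"))
  summary$structure <- list(
    genes_excluded = length(attr(core_aln, "excluded")),
    alignment_length = unname(nchar(core_aln[1])),
    min_ani = min(ani, na.rm = TRUE),
    lineage_threshold = lin$threshold, n_lineages = lin$n_lineages)

  ## -- ordination --------------------------------------------------------
  logline("stage ordination")
  nm <- nmds_embed(jd, n_restarts = config$nmds_restarts, seed = seed)
  an <- anosim(jd, lin$labels[rownames(jd)], seed = seed)
  content_tree <- distance_tree(jd, method = "upgma")
  cmp <- compare_trees(core_tree, content_tree)
  groups <- gene_content_groups(jd, k = config$content_groups)
  write_newick(content_tree, file.path(outdir, "content_tree.nwk"))
  utils::write.csv(data.frame(genome = rownames(nm$points), nm$points,
                              group = groups[rownames(nm$points)]),
                   file.path(outdir, "nmds.csv"), row.names = FALSE)
  summary$ordination <- list(
    stress = nm$stress, anosim_R = an$R, anosim_p = an$p_value,
    rf_core_vs_content = cmp$rf, n_content_groups = config$content_groups)

  ## -- gwas --------------------------------------------------------------
  logline("stage gwas")
  lineage_traits <- lapply(
    setdiff(unique(lin$labels), "unassigned"),
    function(l) setNames(as.integer(lin$labels == l), names(lin$labels)))
  names(lineage_traits) <- setdiff(unique(lin$labels), "unassigned")
  gwas <- select_specific_genes(
    ds$matrix, lineage_traits, sens_min = config$sens_min,
    spec_min = config$spec_min, alpha = config$gwas_alpha,
    adjust = config$gwas_adjust,
    n_permutations = config$gwas_permutations, seed = seed)
  write.table(gwas, file.path(outdir, "gwas.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary$gwas <- list(
    traits_tested = length(lineage_traits),
    families_tested = length(unique(gwas$family)),
    specific = sum(gwas$specific))

  ## -- flux --------------------------------------------------------------
  logline("stage flux")
  flux <- ml_gain_loss_fit(core_tree, ds$matrix)
  anc <- ancestral_content(flux)
  spec_rows <- gwas[gwas$specific & gwas$family %in% flux$families, ,
                    drop = FALSE]
  orig <- if (nrow(spec_rows))
    classify_specific_origins(spec_rows, flux, ds$matrix, lin$labels)
  else NULL
  write.table(flux$branch_events, file.path(outdir, "branch_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary$flux <- list(
    gain_rate = flux$rates$gain[1], loss_rate = flux$rates$loss[1],
    root_families = length(anc$root_families),
    mean_tip_families = mean(anc$node_counts[seq_len(nrow(ds$matrix))]),
    expansion = anc$expansion,
    gained_on_lineage = if (!is.null(orig))
      sum(orig$origin == "gained-on-lineage") else 0,
    lca_inherited = if (!is.null(orig))
      sum(orig$origin != "gained-on-lineage") else 0)

  ## -- hosts -------------------------------------------------------------
  logline("stage hosts")
  tree_persite <- core_tree  # SNP counts -> substitutions per site
  tree_persite$edge.length <- core_tree$edge.length / nchar(core_aln[1])
  dated <- strict_clock_date(tree_persite, root_age = config$root_age)
  hosts <- setNames(ds$metadata$host, ds$metadata$genome)
  hh <- ancestral_hosts(dated, hosts, model = "ctmc_asymmetric")
  sw <- enumerate_host_switches(hh, dated)
  write_newick(dated$tree, file.path(outdir, "dated_tree.nwk"))
  write.table(sw, file.path(outdir, "host_switches.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary$hosts <- list(
    clock_rate = dated$rate,
    root_host = hh$states[nrow(ds$matrix) + 1L],
    n_switches = nrow(sw))

  ## -- prophage ----------------------------------------------------------
  logline("stage prophage")
  kept <- filter_prophages(ds$prophages, min_length = config$min_fragment)
  ex <- exchange_summary(kept, min_fragment = config$min_fragment)
  write.table(ex$edges, file.path(outdir, "prophage_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary$prophage <- list(
    retained = length(kept$sequences),
    discarded = nrow(attr(kept, "discarded")),
    intra_mean = ex$intra_mean, inter_mean = ex$inter_mean,
    ratio = if (is.infinite(ex$ratio)) "Inf" else ex$ratio)

  ## -- adhesion ----------------------------------------------------------
  logline("stage adhesion")
  host_frac <- tapply(ds$metadata$host[match(names(groups),
                                             ds$metadata$genome)] %in%
                        config$sim$host_linked_hosts, groups, mean)
  rodent_group <- names(which.max(host_frac))
  assay <- simulate_adhesion_assay(names(groups),
                                   setNames(as.character(groups),
                                            names(groups)),
                                   rodent_group, config$sim)
  cls <- classify_adhesion_table(assay, config$sim$adhesion_reference)
  write.csv(cls, file.path(outdir, "adhesion.csv"), row.names = FALSE)
  summary$adhesion <- list(
    rodent_type_group = rodent_group,
    effective = sum(cls$class == "effective"),
    intermediate = sum(cls$class == "intermediate"),
    ineffective = sum(cls$class == "ineffective"))

  write_json_report(summary, file.path(outdir, "summary.json"))
  logline("done")
  invisible(summary)
}

#' Command-line entry point
#'
#' `hostflux <stage> [--seed N] [--outdir DIR]` where stage is one of
#' simulate, pangenome, structure, ordination, gwas, flux, hosts, prophage,
#' adhesion, or all. Stages always run with their upstream dependencies;
#' `all` runs everything.
#'
#' @param args character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
hostflux_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- c("simulate", "pangenome", "structure", "ordination", "gwas",
              "flux", "hosts", "prophage", "adhesion", "all")
  if (!length(args) || !(args[1] %in% stages)) {
    message("usage: hostflux <", paste(stages, collapse = "|"),
            "> [--seed N] [--outdir DIR]")
    return(invisible(1L))
  }
  getopt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(getopt("--seed", "1"))
  outdir <- getopt("--outdir", file.path(tempdir(), "hostflux_run"))
  cfg <- pipeline_config(seed = seed)
  run_pipeline(cfg, outdir)
  message("outputs written to ", outdir)
  invisible(0L)
}
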