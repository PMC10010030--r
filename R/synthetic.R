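## Synthetic data generator: produces every pipeline input with the
## statistical structure the downstream analysis assumes, plus a ground-truth
## event log (TruthLog) so that parameter-recovery tests can compare
## estimates against the generating process.

#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generator. Defaults describe
#' a desk-scale symbiont dataset: a handful of deep lineages, a rodent root
#' host, a clock rate of 3e-6 substitutions/site/year and a species age of
#' 9100 years (both at the scale reported for rodent gut lactobacilli),
#' moderate gene turnover with innovation-driven genome expansion, prophage
#' exchange predominantly within lineages, and adhesion assays bimodal by
#' gene-content group.
#'
#' @param n_genomes number of genomes (tips).
#' @param n_lineages number of deep clades.
#' @param host_labels possible host-species groups.
#' @param root_host host state at the root.
#' @param host_switch_rate host switch events per unit tree height.
#' @param root_family_count gene families present at the root.
#' @param gain_rate,loss_rate per-family re-gain/loss rates per unit time.
#' @param innovation_rate new families originating per unit time.
#' @param clock_rate substitutions per site per year.
#' @param tree_age age of the root in years (converts tree height to time).
#' @param n_core_genes number of single-copy core genes to simulate.
#' @param gene_length gene length in bp (>= 50).
#' @param recombination_fraction proportion of core genes made mosaic.
#' @param host_linked_families count of families tracking the host state
#'   (generates convergent gene content across phylogenetically distant
#'   clades that share a host, the structure gene-content ordination detects).
#' @param host_linked_hosts host states carrying the linked families.
#' @param prophage_within_rate,prophage_between_rate prophage transfer events
#'   per unit total branch length, within and between lineages.
#' @param prophage_mean_per_genome mean resident prophages per genome.
#' @param adhesion_high_mean,adhesion_low_mean,adhesion_sd log10 CFU/g adhesion
#'   distribution for rodent-type and other strains.
#' @param adhesion_reference reference-strain log10 CFU/g (fixed).
#' @param crown_height,backbone_min depth structure of the two-level tree:
#'   within-lineage splits below `crown_height`, between-lineage splits above
#'   `backbone_min` (tree height 1).
#' @param seed master seed; every operation derives a substream from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genomes = 40L,
                       n_lineages = 4L,
                       host_labels = c("rodent", "bird", "human", "pig",
                                       "primate", "herbivore"),
                       root_host = "rodent",
                       host_switch_rate = 0.15,
                       root_family_count = 600L,
                       gain_rate = 0.1,
                       loss_rate = 0.15,
                       innovation_rate = 150,
                       clock_rate = 3e-6,
                       tree_age = 9100,
                       n_core_genes = 50L,
                       gene_length = 900L,
                       recombination_fraction = 0.2,
                       host_linked_families = 120L,
                       host_linked_hosts = "rodent",
                       prophage_within_rate = 2,
                       prophage_between_rate = 0.1,
                       prophage_mean_per_genome = 1.5,
                       adhesion_high_mean = 7.6,
                       adhesion_low_mean = 6.0,
                       adhesion_sd = 0.3,
                       adhesion_reference = 7.6,
                       crown_height = 0.35,
                       backbone_min = 0.6,
                       seed = 1L) {
  cfg <- list(
    n_genomes = as.integer(n_genomes), n_lineages = as.integer(n_lineages),
    host_labels = as.character(host_labels), root_host = root_host,
    host_switch_rate = host_switch_rate,
    root_family_count = as.integer(root_family_count),
    gain_rate = gain_rate, loss_rate = loss_rate,
    innovation_rate = innovation_rate,
    clock_rate = clock_rate, tree_age = tree_age,
    n_core_genes = as.integer(n_core_genes),
    gene_length = as.integer(gene_length),
    recombination_fraction = recombination_fraction,
    host_linked_families = as.integer(host_linked_families),
    host_linked_hosts = as.character(host_linked_hosts),
    prophage_within_rate = prophage_within_rate,
    prophage_between_rate = prophage_between_rate,
    prophage_mean_per_genome = prophage_mean_per_genome,
    adhesion_high_mean = adhesion_high_mean,
    adhesion_low_mean = adhesion_low_mean,
    adhesion_sd = adhesion_sd, adhesion_reference = adhesion_reference,
    crown_height = crown_height, backbone_min = backbone_min,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!isTRUE(ok)) stop_input("invalid configuration field '%s': %s", field, msg)
  chk(cfg$n_genomes >= 3, "n_genomes", "need at least 3 genomes")
  chk(cfg$n_lineages >= 1 && cfg$n_lineages <= cfg$n_genomes,
      "n_lineages", "must be in [1, n_genomes]")
  chk(cfg$root_host %in% cfg$host_labels, "root_host",
      "must be one of host_labels")
  for (f in c("host_switch_rate", "gain_rate", "loss_rate", "innovation_rate",
              "clock_rate", "prophage_within_rate", "prophage_between_rate",
              "prophage_mean_per_genome", "adhesion_sd"))
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 0,
        f, "must be a non-negative number")
  chk(cfg$recombination_fraction >= 0 && cfg$recombination_fraction <= 1,
      "recombination_fraction", "must be in [0, 1]")
  chk(cfg$gene_length >= 50, "gene_length", "must be at least 50 bp")
  chk(cfg$tree_age > 0, "tree_age", "must be positive")
  chk(cfg$crown_height > 0 && cfg$backbone_min > cfg$crown_height &&
        cfg$backbone_min < 1, "backbone_min",
      "need 0 < crown_height < backbone_min < 1")
  chk(is.finite(cfg$seed), "seed", "must be a finite integer")
  invisible(cfg)
}

## ---- tree construction --------------------------------------------------

## random coalescent-style merge of clusters at given ascending ages;
## clusters: list of list(str=, age=); returns single cluster
merge_clusters <- function(clusters, ages) {
  fmt <- function(x) sprintf("%.10f", x)
  for (a in sort(ages)) {
    i <- sample.int(length(clusters), 2L)
    c1 <- clusters[[i[1]]]; c2 <- clusters[[i[2]]]
    merged <- list(
      str = sprintf("(%s:%s,%s:%s)", c1$str, fmt(a - c1$age),
                    c2$str, fmt(a - c2$age)),
      age = a)
    clusters[i] <- NULL
    clusters[[length(clusters) + 1L]] <- merged
  }
  stopifnot(length(clusters) == 1L)
  clusters[[1]]
}

#' Simulate the host phylogeny
#'
#' Builds a rooted ultrametric tree of unit height with a two-level
#' pure-birth structure (deep lineage backbone, shallow within-lineage
#' crowns) and evolves host labels along it by a continuous-time Markov
#' switch process started from the root host.
#'
#' @param config a [sim_config()].
#' @return an `annotated_tree`: list with `tree` (ape phylo), `ages` (node
#'   ages, tree height 1), `host` (per-node state), `lineage` (tip ->
#'   lineage), and `truth` (host-switch event log, `TruthLog` component).
#' @export
simulate_host_phylogeny <- function(config) {
  validate_sim_config(config)
  with_seed(op_seed(config$seed, "host_phylogeny"), {
    n <- config$n_genomes; nl <- config$n_lineages
    sizes <- rep(n %/% nl, nl)
    extra <- n %% nl
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    tip_names <- sprintf("g%03d", seq_len(n))
    lineage <- rep(sprintf("L%d", seq_len(nl)), sizes)
    names(lineage) <- tip_names

    ## crowns: within-lineage coalescences below crown_height
    crowns <- vector("list", nl)
    idx <- split(tip_names, lineage)[sprintf("L%d", seq_len(nl))]
    for (i in seq_len(nl)) {
      tips <- idx[[i]]
      cl <- lapply(tips, function(x) list(str = x, age = 0))
      if (length(tips) > 1) {
        ages <- runif(length(tips) - 1L, 0.02, config$crown_height)
        crowns[[i]] <- merge_clusters(cl, ages)
      } else crowns[[i]] <- cl[[1]]
    }
    ## backbone: between-lineage coalescences in [backbone_min, 1], root at 1
    if (nl > 1) {
      bb_ages <- c(if (nl > 2) runif(nl - 2L, config$backbone_min, 0.97), 1)
      top <- merge_clusters(crowns, bb_ages)
    } else {  # one lineage: plain coalescent with the root at height 1
      cl <- lapply(tip_names, function(x) list(str = x, age = 0))
      top <- merge_clusters(cl, c(if (n > 2) runif(n - 2L, 0.02, 0.95), 1))
    }
    tree <- ape::read.tree(text = paste0(top$str, ";"))
    ages <- node_ages(tree)

    ## host states by a CTMC along branches
    k <- length(config$host_labels)
    nnode <- ape::Ntip(tree) + tree$Nnode
    host <- character(nnode)
    root <- ape::Ntip(tree) + 1L
    host[root] <- config$root_host
    sw <- list()
    rate <- config$host_switch_rate
    for (e in preorder_edges(tree)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      t_len <- tree$edge.length[e]
      s <- host[p]
      if (rate > 0 && k > 1) {
        tau <- rexp(1, rate)
        while (tau < t_len) {
          new <- sample(setdiff(config$host_labels, s), 1L)
          sw[[length(sw) + 1L]] <- data.frame(
            branch = ch, from = s, to = new, age = ages[p] - tau)
          s <- new
          tau <- tau + rexp(1, rate)
        }
      }
      host[ch] <- s
    }
    switches <- if (length(sw)) do.call(rbind, sw) else
      data.frame(branch = integer(0), from = character(0),
                 to = character(0), age = numeric(0))
    structure(list(tree = tree, ages = ages, host = host, lineage = lineage,
                   truth = list(host_switches = switches)),
              class = "annotated_tree")
  })
}

## ---- gene content -------------------------------------------------------

## simulate a two-state (absent/present) flip process for `state` over time t;
## returns new state and a data.frame of flip events (offset from branch start)
flip_process <- function(state, t_len, gain, loss) {
  nf <- length(state)
  events <- list()
  pos <- rep(0, nf)
  active <- seq_len(nf)
  while (length(active)) {
    rate <- ifelse(state[active], loss, gain)
    dt <- rep(Inf, length(active))
    pos_rate <- rate > 0
    if (any(pos_rate)) dt[pos_rate] <- rexp(sum(pos_rate), rate[pos_rate])
    nxt <- pos[active] + dt
    hit <- nxt < t_len
    if (!any(hit)) break
    fl <- active[hit]
    state[fl] <- !state[fl]
    events[[length(events) + 1L]] <- data.frame(
      family = fl, type = ifelse(state[fl], "gain", "loss"),
      offset = nxt[hit])
    pos[fl] <- nxt[hit]
    active <- fl
  }
  list(state = state,
       events = if (length(events)) do.call(rbind, events) else NULL)
}

#' Simulate gene-family content along a tree
#'
#' The root carries `root_family_count` families; along each branch families
#' are lost at `loss_rate`, re-gained at `gain_rate`, and new families
#' originate at `innovation_rate` (Dollo-like: an innovation exists only
#' within the subtree it arose in). A block of `host_linked_families` follows
#' the host state deterministically, flipping at the logged host switches.
#' Every event is logged so tip states can be replayed exactly.
#'
#' @param atree an `annotated_tree` from [simulate_host_phylogeny()].
#' @param config the same [sim_config()].
#' @return list with `matrix` (a `presence_matrix`), and `truth`: `events`
#'   (branch, family, type, offset from branch start), `root_families`.
#' @export
simulate_gene_content <- function(atree, config) {
  validate_sim_config(config)
  tree <- atree$tree
  n <- ape::Ntip(tree)
  with_seed(op_seed(config$seed, "gene_content"), {
    nF <- config$root_family_count
    fam_root <- sprintf("F%04d", seq_len(nF))
    linked <- config$host_linked_families > 0
    fam_h <- if (linked) sprintf("H%04d", seq_len(config$host_linked_families))
             else character(0)
    root_linked_on <- atree$host[n + 1L] %in% config$host_linked_hosts
    root_families <- c(fam_root, if (root_linked_on) fam_h)

    events <- list()
    tip_content <- vector("list", n)
    innov_counter <- 0L

    sw <- atree$truth$host_switches
    linked_set <- config$host_linked_hosts

    ## depth-first with explicit stack carrying (node, state-environment)
    recurse <- function(node, fstate) {
      ## fstate: list(ids = character, present = logical) over tracked families
      if (node <= n) {
        tip_content[[node]] <<- fstate$ids[fstate$present]
        return(invisible(NULL))
      }
      rows <- which(tree$edge[, 1] == node)
      for (e in rows) {
        ch <- tree$edge[e, 2]
        t_len <- tree$edge.length[e]
        st <- fstate
        ## stochastic turnover of ordinary (F + innovation) families
        ord <- !startsWith(st$ids, "H")
        if (any(ord) && (config$gain_rate > 0 || config$loss_rate > 0)) {
          fp <- flip_process(st$present[ord], t_len,
                             config$gain_rate, config$loss_rate)
          st$present[ord] <- fp$state
          if (!is.null(fp$events)) {
            fp$events$family <- st$ids[ord][fp$events$family]
            fp$events$branch <- ch
            events[[length(events) + 1L]] <<- fp$events
          }
        }
        ## innovations originate uniformly on the branch, may be lost before end
        if (config$innovation_rate > 0) {
          k <- rpois(1, config$innovation_rate * t_len)
          if (k > 0) {
            u <- sort(runif(k, 0, t_len))
            ids_new <- sprintf("I%05d", innov_counter + seq_len(k))
            innov_counter <<- innov_counter + k
            keep <- logical(k)
            for (j in seq_len(k)) {
              events[[length(events) + 1L]] <<- data.frame(
                family = ids_new[j], type = "gain", offset = u[j], branch = ch)
              fp <- flip_process(TRUE, t_len - u[j],
                                 config$gain_rate, config$loss_rate)
              if (!is.null(fp$events)) {
                fp$events$family <- ids_new[j]
                fp$events$offset <- fp$events$offset + u[j]
                fp$events$branch <- ch
                events[[length(events) + 1L]] <<- fp$events
              }
              keep[j] <- fp$state
            }
            st$ids <- c(st$ids, ids_new)
            st$present <- c(st$present, keep)
          }
        }
        ## host-linked families flip at the logged host switches on this branch
        if (linked) {
          hrows <- sw[sw$branch == ch, , drop = FALSE]
          if (nrow(hrows)) {
            hrows <- hrows[order(-hrows$age), , drop = FALSE]
            hidx <- startsWith(st$ids, "H")
            p_age <- atree$ages[node]
            for (r in seq_len(nrow(hrows))) {
              was <- hrows$from[r] %in% linked_set
              is_ <- hrows$to[r] %in% linked_set
              if (was != is_) {
                st$present[hidx] <- is_
                events[[length(events) + 1L]] <<- data.frame(
                  family = st$ids[hidx],
                  type = if (is_) "gain" else "loss",
                  offset = p_age - hrows$age[r], branch = ch)
              }
            }
          }
        }
        recurse(ch, st)
      }
      invisible(NULL)
    }

    init <- list(ids = c(fam_root, fam_h),
                 present = c(rep(TRUE, nF),
                             rep(root_linked_on, length(fam_h))))
    recurse(n + 1L, init)

    all_fams <- sort(unique(unlist(tip_content)))
    mat <- matrix(FALSE, nrow = n, ncol = length(all_fams),
                  dimnames = list(tree$tip.label, all_fams))
    for (i in seq_len(n)) mat[i, tip_content[[i]]] <- TRUE
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(family = character(0), type = character(0),
                 offset = numeric(0), branch = integer(0))
    rownames(ev) <- NULL
    list(matrix = new_presence_matrix(mat, provenance = "simulated"),
         truth = list(events = ev, root_families = root_families))
  })
}

## replay TruthLog events along the root-to-tip path; used by tests
replay_gene_content <- function(atree, truth, tip) {
  tree <- atree$tree
  tipno <- match(tip, tree$tip.label)
  path <- root_paths(tree)[[tipno]]
  fams <- truth$root_families
  for (e in path) {
    ch <- tree$edge[e, 2]
    ev <- truth$events[truth$events$branch == ch, , drop = FALSE]
    if (!nrow(ev)) next
    ev <- ev[order(ev$offset), , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      if (ev$type[r] == "gain") fams <- union(fams, ev$family[r])
      else fams <- setdiff(fams, ev$family[r])
    }
  }
  sort(fams)
}

## ---- core-gene alignments ----------------------------------------------

mutate_seq <- function(seq, p) {
  hit <- which(runif(length(seq)) < p)
  if (length(hit))
    seq[hit] <- ((seq[hit] + sample.int(3L, length(hit), replace = TRUE) - 1L)
                 %% 4L) + 1L
  seq
}

int2dna <- function(x) paste(c("A", "C", "G", "T")[x], collapse = "")

#' Simulate clock-like core-gene alignments
#'
#' Each gene evolves site-independently under a one-parameter (Jukes-Cantor
#' style) substitution process at `clock_rate` substitutions/site/year, with
#' branch times `edge.length * tree_age`. A `recombination_fraction` of genes
#' is made mosaic: a contiguous half-gene segment from a donor genome in one
#' lineage replaces the homologous segment in a single recipient genome of
#' another lineage (strain-level mosaic, which creates the conflicting site
#' patterns a homoplasy test detects).
#'
#' @param atree an `annotated_tree`.
#' @param config the same [sim_config()].
#' @return list with `alignments` (list of named character vectors, one per
#'   gene) and `truth$recombination` (gene, donor, recipient, start, end).
#' @export
simulate_core_alignments <- function(atree, config) {
  validate_sim_config(config)
  if (config$gene_length < 50)
    stop_input("invalid configuration field 'gene_length': must be >= 50")
  tree <- atree$tree
  n <- ape::Ntip(tree)
  len <- config$gene_length
  with_seed(op_seed(config$seed, "core_alignment"), {
    pre <- preorder_edges(tree)
    t_years <- tree$edge.length * config$tree_age
    p_sub <- 0.75 * (1 - exp(-4 / 3 * config$clock_rate * t_years))
    aln <- vector("list", config$n_core_genes)
    for (g in seq_len(config$n_core_genes)) {
      seqs <- vector("list", n + tree$Nnode)
      seqs[[n + 1L]] <- sample.int(4L, len, replace = TRUE)
      for (e in pre) {
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        seqs[[ch]] <- mutate_seq(seqs[[p]], p_sub[e])
      }
      aln[[g]] <- setNames(vapply(seqs[seq_len(n)], int2dna, character(1)),
                           tree$tip.label)
    }
    names(aln) <- sprintf("core%03d", seq_len(config$n_core_genes))
    ## recombination mosaics
    rec <- data.frame(gene = character(0), donor = character(0),
                      recipient = character(0), start = integer(0),
                      end = integer(0))
    n_rec <- round(config$recombination_fraction * config$n_core_genes)
    if (n_rec > 0 && length(unique(atree$lineage)) >= 2) {
      pick <- sample(names(aln), n_rec)
      lin <- atree$lineage
      for (g in pick) {
        ls <- sample(unique(lin), 2L)
        donor <- sample(names(lin)[lin == ls[1]], 1L)
        recipient <- sample(names(lin)[lin == ls[2]], 1L)
        seg <- round(0.5 * len)
        start <- sample.int(len - seg + 1L, 1L)
        end <- start + seg - 1L
        s <- strsplit(aln[[g]][c(donor, recipient)], "")
        r <- s[[2]]
        r[start:end] <- s[[1]][start:end]
        aln[[g]][recipient] <- paste(r, collapse = "")
        rec <- rbind(rec, data.frame(gene = g, donor = donor,
                                     recipient = recipient,
                                     start = start, end = end))
      }
    }
    list(alignments = aln, truth = list(recombination = rec))
  })
}

## ---- prophages ----------------------------------------------------------

random_dna <- function(len) int2dna(sample.int(4L, len, replace = TRUE))


#' Simulate prophage repertoires with within/between-lineage exchange
#'
#' Each genome carries a Poisson number of resident prophages (6-40 kb,
#' per-gene viral/bacterial labels) plus occasional decoys (< 5 kb, or
#' bacterial-genes-only) that the downstream filter must discard. Prophages
#' are then copied between genomes: within lineages at
#' `prophage_within_rate` and across lineages at `prophage_between_rate`
#' (per unit total branch length). A transferred copy is an exact full-length
#' copy, so donor and recipient share an exact fragment of at least 5 kb.
#'
#' @param atree an `annotated_tree` (supplies lineage labels and tree length).
#' @param config the same [sim_config()].
#' @return list with `prophages` (a `prophage_set`) and `truth$transfers`.
#' @export
simulate_prophage_repertoires <- function(atree, config) {
  validate_sim_config(config)
  genomes <- atree$tree$tip.label
  lin <- atree$lineage[genomes]
  with_seed(op_seed(config$seed, "prophage"), {
    seqs <- character(0)
    recs <- list()    # per-sequence metadata rows
    genes <- list()   # per-sequence gene-label tables
    add_seq <- function(id, genome, s, labels) {
      seqs[id] <<- s
      recs[[id]] <<- data.frame(
        id = id, genome = genome, lineage = unname(lin[genome]),
        length = nchar(s), viral_genes = sum(labels == "viral"),
        bacterial_genes = sum(labels == "bacterial"),
        stringsAsFactors = FALSE)
      genes[[id]] <<- data.frame(id = id, index = seq_along(labels),
                                 label = labels, stringsAsFactors = FALSE)
    }
    for (g in genomes) {
      np <- rpois(1, config$prophage_mean_per_genome)
      for (i in seq_len(np)) {
        l <- sample(6000:40000, 1L)
        ng <- max(1L, l %/% 1000L)
        labels <- c("viral",
                    sample(c("viral", "bacterial"), ng - 1L, replace = TRUE))
        add_seq(sprintf("%s_p%d", g, i), g, random_dna(l), labels)
      }
      if (runif(1) < 0.3)   # too-short decoy
        add_seq(sprintf("%s_short", g), g,
                random_dna(sample(1000:4999, 1L)), "viral")
      if (runif(1) < 0.3) { # bacterial-genes-only decoy
        l <- sample(6000:12000, 1L)
        add_seq(sprintf("%s_bact", g), g, random_dna(l),
                rep("bacterial", max(1L, l %/% 2000L)))
      }
    }
    total_len <- sum(atree$tree$edge.length)
    n_within <- rpois(1, config$prophage_within_rate * total_len)
    n_between <- rpois(1, config$prophage_between_rate * total_len)
    transfers <- list()
    copy_counter <- 0L
    do_transfer <- function(type) {
      tab <- do.call(rbind, recs)
      cand <- tab$id[tab$length >= 5000 & tab$viral_genes > 0]
      if (type == "intra") {
        multi <- names(table(lin))[table(lin) >= 2]
        cand <- cand[tab$lineage[match(cand, tab$id)] %in% multi]
      }
      if (!length(cand)) return(invisible(NULL))
      pid <- if (length(cand) == 1L) cand else sample(cand, 1L)
      donor <- tab$genome[tab$id == pid]
      pool <- if (type == "intra")
        setdiff(genomes[lin == lin[donor]], donor)
      else genomes[lin != lin[donor]]
      if (!length(pool)) return(invisible(NULL))
      recipient <- if (length(pool) == 1L) pool else sample(pool, 1L)
      copy_counter <<- copy_counter + 1L
      new_id <- sprintf("%s_t%d", recipient, copy_counter)
      add_seq(new_id, recipient, seqs[[pid]], genes[[pid]]$label)
      transfers[[length(transfers) + 1L]] <<- data.frame(
        donor = donor, recipient = recipient, donor_id = pid,
        new_id = new_id, type = type, stringsAsFactors = FALSE)
      invisible(NULL)
    }
    for (i in seq_len(n_within)) do_transfer("intra")
    for (i in seq_len(n_between)) do_transfer("inter")
    tl <- if (length(transfers)) do.call(rbind, transfers) else
      data.frame(donor = character(0), recipient = character(0),
                 donor_id = character(0), new_id = character(0),
                 type = character(0), stringsAsFactors = FALSE)
    rownames(tl) <- NULL
    ps <- new_prophage_set(seqs, do.call(rbind, recs),
                           do.call(rbind, genes))
    list(prophages = ps, truth = list(transfers = tl))
  })
}

#' Simulate an epithelial-adhesion assay
#'
#' Strains in the designated rodent-type content group draw log10 CFU/g from
#' Normal(`adhesion_high_mean`, `adhesion_sd`), all others from
#' Normal(`adhesion_low_mean`, `adhesion_sd`); the positive-control reference
#' strain is fixed at `adhesion_reference`.
#'
#' @param strains character vector of strain ids.
#' @param groups named group label per strain.
#' @param rodent_group the group label treated as rodent-type.
#' @param config a [sim_config()].
#' @return data.frame (strain, group, log10_cfu_g) with a `reference`
#'   attribute, reference strain included as "reference_100_23".
#' @export
simulate_adhesion_assay <- function(strains, groups, rodent_group, config) {
  validate_sim_config(config)
  groups <- groups[strains]
  with_seed(op_seed(config$seed, "adhesion"), {
    mu <- ifelse(groups == rodent_group,
                 config$adhesion_high_mean, config$adhesion_low_mean)
    val <- rnorm(length(strains), mu, config$adhesion_sd)
    out <- data.frame(strain = c(strains, "reference_100_23"),
                      group = c(unname(groups), rodent_group),
                      log10_cfu_g = c(val, config$adhesion_reference),
                      stringsAsFactors = FALSE)
    attr(out, "reference") <- config$adhesion_reference
    out
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs every simulator with substreams of one seed and collects the inputs
#' and the full TruthLog.
#'
#' @param config a [sim_config()].
#' @return list: `tree` (annotated_tree), `matrix` (presence_matrix),
#'   `alignments`, `prophages`, `metadata` (genome, host, lineage), and
#'   `truth` (all event logs).
#' @export
simulate_dataset <- function(config = sim_config()) {
  atree <- simulate_host_phylogeny(config)
  gc_ <- simulate_gene_content(atree, config)
  al <- simulate_core_alignments(atree, config)
  pp <- simulate_prophage_repertoires(atree, config)
  tips <- atree$tree$tip.label
  md <- data.frame(genome = tips,
                   host = atree$host[seq_along(tips)],
                   lineage = unname(atree$lineage[tips]),
                   stringsAsFactors = FALSE)
  list(tree = atree, matrix = gc_$matrix, alignments = al$alignments,
       prophages = pp$prophages, metadata = md,
       truth = c(atree$truth, gc_$truth, al$truth, pp$truth,
                 list(config = config)))
}
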