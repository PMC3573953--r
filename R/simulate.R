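#' Multispecies-coalescent simulation settings
#'
#' Defaults emulate the study design this package targets: a dozen
#' deeply divergent species sampled with 1-10 specimens each
#' (singletons included), three markers — two mitochondrial loci
#' sharing one genealogy with a fast substitution rate, one slower
#' nuclear locus — and complete mitochondrial-COI dropout for three
#' species (universal barcoding primers failing on some lineages).
#' Time is measured in expected substitutions per site at the nuclear
#' rate.  With the defaults the maximum intraspecific p-distance on
#' mitochondrial markers is around 2-5% and the minimum interspecific
#' p-distance around 15-30%, the regime of an old radiation with
#' shallow within-species coalescence.
#'
#' @param n_species Number of species (default 12).
#' @param samples_per_species Either a range `c(min, max)` from which
#'   each species' sample size is drawn uniformly (default `c(1, 10)`),
#'   or an explicit integer vector of length `n_species`.
#' @param birth_rate Speciation rate of the species-level Yule process.
#' @param theta Population-mutation parameter: within-species pairwise
#'   coalescence has rate `2/theta` per pair (default 0.002).
#' @param tau_scale Species-tree root age (default 0.04, i.e. a
#'   separation ratio `tau_scale/theta` of 20).
#' @param min_depth_frac All interspecific divergences are at least
#'   this fraction of the root age (default 0.5): the emulated
#'   radiation is old, with no near-present species splits.  Set to 0
#'   for an unconstrained Yule tree.
#' @param markers Data frame with columns `name`, `length`, `model`
#'   (`"JC69"` or `"K80"`), `kappa`, `rate` (rate multiplier relative
#'   to nuclear), `linkage` (loci in one linkage group share one
#'   genealogy).
#' @param dropout Named list: for each marker name, either a
#'   per-specimen dropout probability or `list(n_species = k)` to drop
#'   the marker entirely for `k` randomly chosen species.
#' @param seed Integer seed; identical seed gives an identical dataset.
#' @return A list of class `msc_sim_settings`.
#' @export
msc_sim_settings <- function(n_species = 12L,
                             samples_per_species = c(1L, 10L),
                             birth_rate = 1,
                             theta = 0.002,
                             tau_scale = 0.04,
                             min_depth_frac = 0.5,
                             markers = default_markers(),
                             dropout = list(COI = list(n_species = 3L)),
                             seed = 1L) {
  stopifnot(n_species >= 2, theta > 0, tau_scale > 0,
            min_depth_frac >= 0, min_depth_frac < 1,
            all(markers$length > 0), all(markers$rate > 0))
  structure(list(n_species = as.integer(n_species),
                 samples_per_species = samples_per_species,
                 birth_rate = birth_rate, theta = theta,
                 tau_scale = tau_scale, min_depth_frac = min_depth_frac,
                 markers = markers, dropout = dropout,
                 seed = as.integer(seed)),
            class = "msc_sim_settings")
}

#' Default marker table for the benchmark simulator
#'
#' Three markers shaped like the study's loci: nuclear 28S (~950 bp,
#' slow, JC69), mitochondrial 16S (~440 bp) and COI (~655 bp), the two
#' mitochondrial loci linked (one genealogy) and five times faster
#' than the nuclear locus, evolving under K80 with kappa = 4.
#'
#' @param lengths Integer vector of the three marker lengths.
#' @return A data.frame understood by [msc_sim_settings()].
#' @export
default_markers <- function(lengths = c(950L, 440L, 655L)) {
  data.frame(name = c("28S", "16S", "COI"),
             length = as.integer(lengths),
             model = c("JC69", "K80", "K80"),
             kappa = c(NA, 4, 4),
             rate = c(1, 5, 5),
             linkage = c("nuc", "mt", "mt"),
             stringsAsFactors = FALSE)
}

#' Simulate a species tree
#'
#' A Yule (pure-birth) tree with `n_species` tips, rescaled so the
#' root age equals `tau_scale`.  With `min_depth_frac > 0` the node
#' ages are affinely compressed into
#' `[min_depth_frac, 1] x tau_scale`, keeping their order: every
#' species split is then at least that deep, emulating an old
#' radiation with no recent speciation.
#'
#' @param n_species Number of tips.
#' @param birth_rate Speciation rate.
#' @param tau_scale Root age after rescaling.
#' @param seed Integer seed (uses R's RNG deterministically).
#' @param min_depth_frac Minimum node age as a fraction of the root.
#' @return An ultrametric `phylo` with tips `sp01`, `sp02`, ...
#' @export
sim_species_tree <- function(n_species, birth_rate = 1, tau_scale = 1,
                             seed = NULL, min_depth_frac = 0) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_species >= 2)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  ages <- node_ages(tr)
  root_age <- max(ages)
  new_ages <- ages / root_age
  ix_int <- seq(n_species + 1L, n_species + tr$Nnode)
  new_ages[ix_int] <- min_depth_frac + (1 - min_depth_frac) *
    new_ages[ix_int]
  new_ages <- new_ages * tau_scale
  new_ages[seq_len(n_species)] <- 0
  tr$edge.length <- new_ages[tr$edge[, 1L]] - new_ages[tr$edge[, 2L]]
  tr
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One coalescent genealogy per linkage group: lineages sampled within
#' each species coalesce only within the species-tree branches, at
#' rate `2/theta` per lineage pair, with uncoalesced lineages handed
#' up to the ancestral population (deep coalescence produces
#' incomplete lineage sorting when internodes are short relative to
#' theta).  Gene-tree branch lengths are in the species-tree time
#' units.
#'
#' @param species_tree Ultrametric `phylo` from [sim_species_tree()].
#' @param theta Population-mutation parameter (same for all
#'   populations).
#' @param samples_per_species Named integer vector (names = species
#'   tip labels) of specimens per species.
#' @param linkage_groups Character vector of group names (one gene
#'   tree each).
#' @param seed Optional integer seed.
#' @return Named list of `phylo` gene trees; tips are specimen ids
#'   `<species>_i<k>`.
#' @export
sim_gene_trees <- function(species_tree, theta, samples_per_species,
                           linkage_groups = "locus1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- species_tree$tip.label
  stopifnot(all(sp %in% names(samples_per_species)))
  out <- lapply(linkage_groups, function(g)
    msc_one_tree(species_tree, theta, samples_per_species))
  names(out) <- linkage_groups
  out
}

# simulate a single MSC genealogy (structured Kingman coalescent along
# the species tree); returns a phylo over specimen ids
msc_one_tree <- function(species_tree, theta, samples) {
  ntip_sp <- length(species_tree$tip.label)
  ages <- node_ages(species_tree)
  n_total <- sum(samples[species_tree$tip.label])
  # lineage bookkeeping: each active lineage is a node id in the gene
  # tree being built; edges collected as (parent, child, length)
  next_id <- n_total + 1L          # internal gene-tree ids
  tip_ids <- character(n_total)
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  birth_time <- numeric(2L * n_total)   # age at which each node starts
  k <- 0L
  lineages_in <- vector("list", ntip_sp + species_tree$Nnode)
  for (i in seq_len(ntip_sp)) {
    spname <- species_tree$tip.label[i]
    m <- samples[[spname]]
    ids <- integer(m)
    for (j in seq_len(m)) {
      k <- k + 1L
      ids[j] <- k
      tip_ids[k] <- sprintf("%s_i%d", spname, j)
      birth_time[k] <- 0
    }
    lineages_in[[i]] <- ids
  }
  # process species-tree nodes tips-upward by age
  coalesce_in <- function(lin, t_start, t_end) {
    # t_end = Inf at the root population
    t <- t_start
    while (length(lin) > 1L) {
      rate <- length(lin) * (length(lin) - 1L) / theta  # 2/theta per pair
      t_next <- t + stats::rexp(1L, rate)
      if (t_next > t_end) break
      pair <- sample(length(lin), 2L)
      anc <- next_id
      next_id <<- next_id + 1L
      birth_time[anc] <<- t_next
      for (chd in lin[pair]) {
        parent <<- c(parent, anc)
        child <<- c(child, chd)
        elen <<- c(elen, t_next - birth_time[chd])
      }
      lin <- c(lin[-pair], anc)
      t <- t_next
    }
    lin
  }
  node_order <- order(ages[seq(ntip_sp + 1L, ntip_sp + species_tree$Nnode)])
  root_sp <- ntip_sp + 1L
  for (nd in (ntip_sp + seq_len(species_tree$Nnode))[node_order]) {
    kids <- species_tree$edge[species_tree$edge[, 1L] == nd, 2L]
    lin <- integer(0)
    for (kd in kids) {
      lin <- c(lin, coalesce_in(lineages_in[[kd]], ages[kd], ages[nd]))
    }
    lineages_in[[nd]] <- lin
  }
  final <- coalesce_in(lineages_in[[root_sp]], ages[root_sp], Inf)
  stopifnot(length(final) == 1L)
  # assemble phylo: renumber so tips are 1..n, root = n+1, in ape order
  n_int <- next_id - 1L - n_total
  old_root <- final
  remap <- integer(next_id - 1L)
  remap[seq_len(n_total)] <- seq_len(n_total)
  internals <- seq(n_total + 1L, next_id - 1L)
  # root must get n_total + 1; order the rest by decreasing age
  others <- setdiff(internals, old_root)
  others <- others[order(-birth_time[others])]
  remap[old_root] <- n_total + 1L
  remap[others] <- n_total + 1L + seq_along(others)
  tr <- list(edge = cbind(remap[parent], remap[child]),
             edge.length = elen,
             tip.label = tip_ids,
             Nnode = n_int)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Simulate a marker alignment on a gene tree
#'
#' Sites evolve independently along the tree under JC69 or K80, the
#' root sequence drawn uniformly over {A,C,G,T}; branch lengths times
#' `rate` are expected substitutions per site.
#'
#' @param gene_tree A `phylo` genealogy.
#' @param length Number of sites.
#' @param model `"JC69"` or `"K80"`.
#' @param kappa Transition/transversion rate ratio for K80.
#' @param rate Rate multiplier applied to all branches.
#' @param seed Optional integer seed.
#' @param marker_name Locus name for the returned alignment.
#' @return A [marker_alignment()].
#' @export
sim_alignment <- function(gene_tree, length, model = c("JC69", "K80"),
                          kappa = 4, rate = 1, seed = NULL,
                          marker_name = "locus") {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  Q <- if (model == "K80") c(1, kappa, 1, 1, kappa, 1) else rep(1, 6)
  sim <- phangorn::simSeq(gene_tree, l = length, Q = Q,
                          bf = rep(0.25, 4), rate = rate)
  m <- toupper(as.character(sim))
  marker_alignment(m, marker_name)
}

#' Build a benchmark multilocus dataset with known species boundaries
#'
#' Simulates a species tree, per-linkage-group coalescent gene trees
#' and per-marker alignments, applies marker dropout, and returns the
#' dataset together with its ground truth.  Fully deterministic under
#' `settings$seed`.  When `outdir` is given, writes one FASTA per
#' marker, the truth partition as a TSV partition table and a JSON
#' provenance record of the settings.
#'
#' @param settings A [msc_sim_settings()].
#' @param outdir Optional output directory.
#' @return A list of class `msc_benchmark`: `alignments` (named list of
#'   [marker_alignment()] after dropout), `truth` (a
#'   [new_partition()] of all specimens by true species),
#'   `species_tree`, `gene_trees`, `specimens` (a [specimen_table()]),
#'   `dropped` (named list of specimen ids per marker), `settings`.
#' @export
build_benchmark_dataset <- function(settings = msc_sim_settings(),
                                    outdir = NULL) {
  set.seed(settings$seed)
  ns <- settings$n_species
  sptree <- sim_species_tree(ns, settings$birth_rate, settings$tau_scale,
                             seed = NULL,
                             min_depth_frac = settings$min_depth_frac)
  spp <- sptree$tip.label
  sps <- settings$samples_per_species
  samples <- if (length(sps) == ns && !is.null(names(sps))) {
    sps[spp]
  } else if (length(sps) == ns) {
    stats::setNames(as.integer(sps), spp)
  } else {
    stats::setNames(sample(seq(sps[1L], sps[2L]), ns, replace = TRUE), spp)
  }
  groups <- unique(settings$markers$linkage)
  gtrees <- sim_gene_trees(sptree, settings$theta, samples,
                           linkage_groups = groups, seed = NULL)
  specimen_ids <- sort(gtrees[[1L]]$tip.label)
  truth_assign <- sub("_i\\d+$", "", specimen_ids)
  names(truth_assign) <- specimen_ids
  truth <- new_partition(truth_assign, method = "truth",
                         parameters = list(seed = settings$seed))

  alignments <- list()
  dropped <- list()
  for (r in seq_len(nrow(settings$markers))) {
    mk <- settings$markers[r, ]
    aln <- sim_alignment(gtrees[[mk$linkage]], mk$length,
                         model = mk$model,
                         kappa = if (is.na(mk$kappa)) 4 else mk$kappa,
                         rate = mk$rate, marker_name = mk$name)
    drop_ids <- character(0)
    dr <- settings$dropout[[mk$name]]
    if (!is.null(dr)) {
      if (is.list(dr) && !is.null(dr$n_species)) {
        drop_sp <- sample(spp, dr$n_species)
        drop_ids <- specimen_ids[truth_assign %in% drop_sp]
      } else if (is.numeric(dr) && dr > 0) {
        drop_ids <- specimen_ids[stats::runif(length(specimen_ids)) < dr]
      }
    }
    keep <- setdiff(specimen_ids, drop_ids)
    if (length(keep) < 2L) {
      warning(sprintf("dropout removed marker '%s' entirely; marker omitted",
                      mk$name))
      dropped[[mk$name]] <- drop_ids
      next
    }
    aln <- marker_alignment(aln$seq[keep, , drop = FALSE], mk$name)
    alignments[[mk$name]] <- aln
    dropped[[mk$name]] <- drop_ids
  }
  markers_present <- lapply(specimen_ids, function(s)
    settings$markers$name[!vapply(settings$markers$name, function(m)
      s %in% dropped[[m]], TRUE)])
  specimens <- specimen_table(specimen_ids,
                              locality = truth_assign,
                              markers_present = markers_present,
                              marker_names = settings$markers$name)
  out <- structure(list(alignments = alignments, truth = truth,
                        species_tree = sptree, gene_trees = gtrees,
                        specimens = specimens, dropped = dropped,
                        settings = settings),
                   class = "msc_benchmark")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(alignments))
      write_alignment(alignments[[nm]], file.path(outdir,
                                                  paste0(nm, ".fasta")))
    write_partition(truth, file.path(outdir, "truth.tsv"))
    prov <- settings
    prov$markers <- as.list(settings$markers)
    jsonlite::write_json(unclass(prov), file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.msc_benchmark <- function(x, ...) {
  cat(sprintf("<msc_benchmark> %d species, %d specimens, %d markers (seed %d)\n",
              x$settings$n_species, length(partition_specimens(x$truth)),
              length(x$alignments), x$settings$seed))
  invisible(x)
}
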