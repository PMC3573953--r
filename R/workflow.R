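#' Pipeline configuration
#'
#' Settings for the end-to-end delimitation run.  Defaults mirror the
#' analysis design this package implements: ABGD and statistical
#' parsimony on each mitochondrial marker, a fixed 11% single-linkage
#' threshold on COI (the published congeneric mean divergence for
#' Mollusca), and a single-threshold GMYC fit on a UPGMA tree built
#' from the concatenated p-distance matrix.
#'
#' @param mito_markers Names of the mitochondrial markers (used by
#'   ABGD, parsimony networks and the fixed threshold).
#' @param methods Subset of `c("gmyc", "abgd", "parsnet", "threshold")`.
#' @param abgd An [abgd_settings()]; the default uses `X = 1.2`.
#' @param abgd_P Prior limit to intraspecific divergence for the
#'   reported ABGD partition.
#' @param parsnet_confidence Parsimony confidence (default 0.95).
#' @param threshold Fixed clustering threshold (default 0.11).
#' @param threshold_markers Markers the fixed threshold is applied to;
#'   default the first mitochondrial marker.
#' @param gmyc_trees `"concat"` (fit on the concatenated-matrix UPGMA
#'   tree), or a character vector of marker names, or both.
#' @param dist_model Distance model for ABGD matrices (`"JC69"` by
#'   default; the fixed threshold and summaries always use
#'   uncorrected p-distances).
#' @param bpp_partitions Optional list of externally produced
#'   partitions (e.g. Bayesian delimitation results read with
#'   [read_partition()] or built with [bpp_partition()]) entered into
#'   the consensus unweighted, like every other method.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mito_markers = c("16S", "COI"),
                            methods = c("gmyc", "abgd", "parsnet",
                                        "threshold"),
                            abgd = abgd_settings(X = 1.2),
                            abgd_P = 0.01,
                            parsnet_confidence = 0.95,
                            threshold = 0.11,
                            threshold_markers = mito_markers[
                              length(mito_markers)],
                            gmyc_trees = "concat",
                            dist_model = "JC69",
                            bpp_partitions = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!length(methods) && is.null(bpp_partitions))
    stop("at least one delimitation method must be enabled")
  structure(list(mito_markers = mito_markers, methods = methods,
                 abgd = abgd, abgd_P = abgd_P,
                 parsnet_confidence = parsnet_confidence,
                 threshold = threshold,
                 threshold_markers = threshold_markers,
                 gmyc_trees = gmyc_trees, dist_model = dist_model,
                 bpp_partitions = bpp_partitions),
            class = "pipeline_config")
}

#' Concatenate marker alignments
#'
#' Pads specimens missing from a marker with gap columns, so pairwise
#' deletion handles marker dropout naturally.
#'
#' @param alignments Named list of [marker_alignment()] objects.
#' @return A [marker_alignment()] named `"concat"` over the union of
#'   specimens.
#' @export
concat_alignments <- function(alignments) {
  ids <- sort(unique(unlist(lapply(alignments, alignment_specimens))))
  blocks <- lapply(alignments, function(a) {
    m <- matrix("-", length(ids), a$length,
                dimnames = list(ids, NULL))
    m[alignment_specimens(a), ] <- a$seq
    m
  })
  marker_alignment(do.call(cbind, blocks), "concat")
}

# extend a partition to the full universe, padding with NO_DATA
extend_partition <- function(part, universe) {
  a <- rep(NA_character_, length(universe))
  names(a) <- universe
  common <- intersect(universe, names(part$assignment))
  a[common] <- part$assignment[common]
  new_partition(a, method = part$method, parameters = part$parameters)
}

#' Run the full delimitation pipeline
#'
#' Executes the enabled stages in dependency order — distance
#' matrices, per-method candidate partitions, then the minimum
#' consensus — and returns one report.  Stages communicate through
#' partitions over the common specimen universe, so any stage can be
#' replaced by an external tool's partition table.  A failed stage
#' aborts the run with an error naming the stage; when `outdir` is
#' given, partitions already computed remain on disk.
#'
#' @param alignments Named list of [marker_alignment()] objects.
#' @param config A [pipeline_config()].
#' @param outdir Optional directory for partition tables, the SSH and
#'   the JSON report.
#' @param seed Integer seed recorded in the report (the pipeline
#'   itself is deterministic given its inputs).
#' @return A list of class `delim_report`: `partitions` (named list),
#'   `n_entities` (named integer), `consensus` (the
#'   [minimum_consensus()] report), `ssh`, `settings`, `seed`.
#' @export
run_pipeline <- function(alignments, config = pipeline_config(),
                         outdir = NULL, seed = NA_integer_) {
  universe <- sort(unique(unlist(lapply(alignments,
                                        alignment_specimens))))
  mito <- intersect(config$mito_markers, names(alignments))
  parts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  add_part <- function(label, p) {
    p$method <- label
    parts[[label]] <<- extend_partition(p, universe)
    if (!is.null(outdir))
      write_partition(parts[[label]],
                      file.path(outdir, paste0(label, ".tsv")))
  }
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  pdist <- stage("distances", lapply(alignments[mito], distance_matrix,
                                     params = dist_params("p")))
  if ("abgd" %in% config$methods) {
    cdist <- stage("distances",
                   lapply(alignments[mito], distance_matrix,
                          params = dist_params(config$dist_model)))
    for (m in mito)
      add_part(paste0("abgd.", m),
               stage(paste0("abgd.", m),
                     abgd_partition(cdist[[m]], config$abgd_P,
                                    config$abgd)))
  }
  if ("parsnet" %in% config$methods) {
    for (m in mito)
      add_part(paste0("parsnet.", m),
               stage(paste0("parsnet.", m),
                     parsnet_partition(alignments[[m]],
                                       config$parsnet_confidence)))
  }
  if ("threshold" %in% config$methods) {
    for (m in intersect(config$threshold_markers, mito))
      add_part(paste0("threshold.", m),
               stage(paste0("threshold.", m),
                     threshold_cluster(pdist[[m]], config$threshold)))
  }
  gmyc_fits <- list()
  if ("gmyc" %in% config$methods) {
    targets <- config$gmyc_trees
    for (tgt in targets) {
      aln <- if (tgt == "concat") concat_alignments(alignments)
             else alignments[[tgt]]
      fit <- stage(paste0("gmyc.", tgt), {
        dmat <- distance_matrix(aln, dist_params("p"))
        gmyc_delimit(dmat)
      })
      gmyc_fits[[tgt]] <- fit
      add_part(paste0("gmyc.", tgt), fit$clusters)
    }
  }
  for (nm in names(config$bpp_partitions))
    add_part(nm, config$bpp_partitions[[nm]])
  if (!length(parts)) stop("no partitions produced; enable a method")
  cons <- stage("consensus", minimum_consensus(parts))
  report <- structure(list(partitions = parts,
                           n_entities = vapply(parts, n_clusters, 0L),
                           consensus = cons, ssh = cons$ssh,
                           gmyc_fits = gmyc_fits,
                           settings = config, seed = seed),
                      class = "delim_report")
  if (!is.null(outdir)) {
    write_partition(cons$ssh, file.path(outdir, "ssh.tsv"))
    jsonlite::write_json(report_json(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# machine-readable twin of the rendered report
report_json <- function(report) {
  list(n_entities = as.list(report$n_entities),
       ssh_units = n_clusters(report$ssh),
       contested_boundaries = nrow(report$consensus$contested),
       evidence_free_pairs = report$consensus$evidence_free_pairs,
       seed = report$seed,
       methods = report$consensus$methods)
}

#' Render a pipeline report
#'
#' Produces the unit-by-method corroboration table (split / lump /
#' no-data cells, mirroring a method-by-entity matrix figure) together
#' with its machine-readable JSON twin.
#'
#' @param report A [run_pipeline()] result.
#' @return A list of class `rendered_report`: `matrix` (data.frame),
#'   `entity_counts`, `json` (list), `text` (character vector).
#' @export
render_report <- function(report) {
  cor <- corroboration_report(report$consensus, report$partitions)
  js <- report_json(report)
  txt <- c(sprintf("Secondary species hypothesis: %d candidate species",
                   js$ssh_units),
           sprintf("Methods: %s", paste(js$methods, collapse = ", ")),
           sprintf("Per-method entities: %s",
                   paste(sprintf("%s=%d", names(report$n_entities),
                                 report$n_entities), collapse = ", ")),
           sprintf("Contested boundaries: %d", js$contested_boundaries))
  structure(list(matrix = cor$matrix, entity_counts = cor$entity_counts,
                 json = js, text = txt),
            class = "rendered_report")
}

#' @export
print.rendered_report <- function(x, ...) {
  writeLines(x$text)
  cat("\nUnit x method corroboration matrix:\n")
  print(x$matrix)
  invisible(x)
}

#' @export
print.delim_report <- function(x, ...) {
  cat(sprintf("<delim_report> %d methods, SSH with %d units\n",
              length(x$partitions), n_clusters(x$ssh)))
  invisible(x)
}
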