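#' The c-value grid of clustering runs
#'
#' Inclusive arithmetic grid of alignment-coverage cutoffs, formatted to one
#' decimal. The default grid `0.0 .. 0.8` in steps of `0.1` enumerates the
#' nine standard clustering stringencies.
#'
#' @param start,stop,step grid parameters; `stop >= start`, `step > 0`.
#' @return Character vector of labels, e.g. `"0.0" ... "0.8"`.
#' @examples
#' cGrid()          # nine labels
#' cGrid(0, 0.8, 0.5)
#' @export
cGrid <- function(start = 0, stop = 0.8, step = 0.1) {
  if (step <= 0) stop("step must be positive")
  if (stop < start) stop("stop must be >= start")
  vals <- seq(start, stop + step / 2, by = step)
  vals <- vals[vals <= stop + 1e-09]
  sprintf("%.1f", vals)
}

#' Run the full gain/loss and enrichment pipeline over clustering runs
#'
#' Orchestrates the package over one tree, one or more cluster files (each
#' tagged with a c-value label), a species map, an annotation table and a set
#' of focal species: reads and filters the families, infers the Dollo events
#' per focal lineage, writes event, profile and enrichment tables keyed by
#' `(focal, c_value)`, and a flat key-value run manifest. Reruns with an
#' identical configuration produce identical tables.
#'
#' @param treeFile Newick tree path.
#' @param clusterFiles named character vector: c-value label -> cluster file
#'   path. Labels must be unique.
#' @param clusterDialect `"mmseqs"` or `"mcl"`.
#' @param speciesMap protein->species TSV path, or `NULL` under the prefix
#'   convention.
#' @param speciesConvention `"map"` or `"prefix"`.
#' @param annotationFile protein->term TSV path, or `NULL` to skip
#'   enrichment.
#' @param focal character vector of focal species.
#' @param outDir output directory.
#' @param alpha significance threshold for adjusted p-values.
#' @param transferMode `"any"` or `"fraction"` annotation transfer.
#' @param universe `"all"` or `"lost_only"` enrichment universe.
#' @param bhScope `"joint"` or `"per_term"`.
#' @return Invisibly, a list with the per-run objects and the manifest path.
#' @export
runPipeline <- function(treeFile, clusterFiles, clusterDialect = "mmseqs",
                        speciesMap = NULL, speciesConvention = "map",
                        annotationFile = NULL, focal, outDir,
                        alpha = 0.05, transferMode = "any",
                        universe = "all", bhScope = "joint") {
  for (p in c(treeFile, unname(clusterFiles), speciesMap, annotationFile))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  if (is.null(names(clusterFiles)) || anyDuplicated(names(clusterFiles)))
    stop("clusterFiles must be uniquely named by their c-value labels")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  phy <- readPhylogeny(treeFile)
  reader <- switch(clusterDialect, mmseqs = readMMseqsClusters,
                   mcl = readMCLClusters,
                   stop("unknown cluster dialect: ", clusterDialect))
  results <- list()
  manifest <- c(
    tree = treeFile, n_leaves = sum(phy@isLeaf),
    cluster_dialect = clusterDialect, alpha = alpha,
    transfer_mode = transferMode, universe = universe, bh_scope = bhScope,
    focal = paste(focal, collapse = ","))
  for (cLabel in names(clusterFiles)) {
    fams <- reader(clusterFiles[[cLabel]],
                   cValue = suppressWarnings(as.numeric(cLabel)))
    fams <- attachSpecies(fams, speciesMap, speciesConvention)
    nBefore <- nFamilies(fams)
    fams <- dropTerminalSingletons(fams)
    ann <- if (!is.null(annotationFile))
      transferAnnotations(fams, annotationFile, transferMode) else NULL
    for (f in focal) {
      lin <- focalLineage(phy, f)
      ev <- lineageEvents(fams, phy, lin)
      tag <- paste0(f, "_c", cLabel)
      eventTableExport(ev, lin,
                       file = file.path(outDir, paste0("events_", tag, ".tsv")))
      profileExport(ev, lin, cValue = suppressWarnings(as.numeric(cLabel)),
                    file = file.path(outDir, paste0("profile_", tag, ".tsv")))
      run <- list(events = ev, lineage = lin, families = fams)
      if (!is.null(ann)) {
        recs <- lapply(c("gain", "loss"), function(d)
          enrich(ev, ann, d, alpha = alpha, universe = universe,
                 bhScope = bhScope))
        names(recs) <- c("gain", "loss")
        for (d in names(recs)) {
          df <- recs[[d]]
          df <- cbind(focal_species = rep(f, nrow(df)),
                      c_value = rep(cLabel, nrow(df)), df)
          utils::write.table(df,
            file.path(outDir, paste0("enrichment_", d, "_", tag, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
        summ <- do.call(rbind, lapply(names(recs), function(d)
          cbind(focal_species = f, c_value = cLabel, direction = d,
                enrichmentFrequency(recs[[d]]))))
        utils::write.table(summ,
          file.path(outDir, paste0("enrichment_summary_", tag, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        run$enrichment <- recs
      }
      manifest[paste0("n_families_considered_", tag)] <- nBefore
      manifest[paste0("n_families_retained_", tag)] <- nFamilies(fams)
      manifest[paste0("n_excluded_immediate_loss_", tag)] <-
        nrow(excludedFamilies(ev))
      manifest[paste0("n_events_", tag)] <- nrow(events(ev))
      results[[tag]] <- run
    }
  }
  manifestPath <- file.path(outDir, "manifest.txt")
  writeLines(paste0(names(manifest), "\t", unname(manifest)), manifestPath)
  invisible(c(results, list(manifest = manifestPath)))
}
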