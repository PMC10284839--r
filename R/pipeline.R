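#' PipelineConfig: one config object driving every stage
#'
#' Holds every tunable of the pipeline with defaults matching the
#' analysis's canonical parameter values: median window 3, artifact
#' distance 15 px, normalization percentile 99, 100 graph neighbours for
#' phenotyping, 20-cell CN windows, k = 15 CNs, tensor rank 4. Serializes
#' losslessly to YAML via [writePipelineConfig()] /
#' [readPipelineConfig()].
#'
#' @slot params named list of parameters; see [pipelineConfig()].
#' @export
setClass("PipelineConfig", representation(params = "list"),
  validity = function(object) {
    p <- object@params
    need <- names(.defaultParams())
    miss <- setdiff(need, names(p))
    if (length(miss))
      return(paste("missing parameters:", paste(miss, collapse = ", ")))
    if (p$medianWindow %% 2 == 0) return("medianWindow must be odd")
    if (p$alpha <= 0 || p$alpha >= 1) return("alpha must be in (0,1)")
    TRUE
  })

.defaultParams <- function() list(
  seed = 1L,
  # image preprocessing
  medianWindow = 3L, saturation = 0.01,
  # segmentation
  threshold = "otsu", minArea = 3L, artifactMaxDist = 15,
  dilationRadius = 3,
  # phenotyping
  normPercentile = 99, kNeighbors = 100L,
  # neighborhoods
  window = 20L, kCN = 15L,
  # spatial statistics
  kSpatial = 20L, nPerm = 1000L, alpha = 0.01,
  # tensor: NA = full (unreduced) patient mode
  tensorRanks = c(NA, 4, 4),
  # simulation defaults (the bundled small cohort)
  simulate = list(nRois = 12L, cellsPerRoi = 500L, nTypes = 17L,
                  nPatients = 12L),
  stages = c("simulate", "preprocess", "segment", "phenotype",
             "neighborhoods", "interactions", "tensor", "report"))

#' @rdname PipelineConfig-class
#' @param ... named parameter overrides of the defaults (unknown names are
#'   an error).
#' @export
pipelineConfig <- function(...) {
  p <- .defaultParams()
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  new("PipelineConfig", params = p)
}

#' @rdname PipelineConfig-class
#' @param x a `PipelineConfig`; `configParams` returns the parameter list.
#' @export
configParams <- function(x) {
  stopifnot(is(x, "PipelineConfig"))
  x@params
}

setMethod("show", "PipelineConfig", function(object) {
  p <- object@params
  cat("PipelineConfig: median", p$medianWindow, "| artifact",
      p$artifactMaxDist, "px | percentile", p$normPercentile, "| kNN",
      p$kNeighbors, "| window", p$window, "| kCN", p$kCN, "| rank",
      p$tensorRanks[2], "| seed", p$seed, "\n")
  cat("  stages:", paste(p$stages, collapse = " -> "), "\n")
})

#' @rdname imcTopo-io
#' @export
writePipelineConfig <- function(x, path) {
  stopifnot(is(x, "PipelineConfig"))
  yaml::write_yaml(x@params, path)
  invisible(path)
}

#' @rdname imcTopo-io
#' @export
readPipelineConfig <- function(path) {
  p <- yaml::read_yaml(path)
  ints <- c("seed", "medianWindow", "minArea", "kNeighbors", "window",
            "kCN", "kSpatial", "nPerm")
  for (f in ints) p[[f]] <- as.integer(p[[f]])
  p$tensorRanks <- as.numeric(p$tensorRanks)
  p$simulate <- lapply(p$simulate, function(v)
    if (is.numeric(v)) as.integer(v) else v)
  new("PipelineConfig", params = p)
}

# stage dependency table: what must exist before a stage can run
.stageNeeds <- c(preprocess = "simulate", segment = "preprocess",
                 phenotype = "segment", neighborhoods = "phenotype",
                 interactions = "neighborhoods", tensor = "neighborhoods",
                 report = "tensor")

#' Run the pipeline
#'
#' Executes the requested stages in pipeline order (simulate, preprocess,
#' segment, phenotype, neighborhoods, interactions, tensor, report), each
#' writing its artifacts under `outDir`, and emits a run manifest
#' (`manifest.json`) recording the config hash, seeds, per-stage wall
#' clock, object counts and output checksums. Re-running an identical
#' config reproduces identical checksums for every artifact.
#'
#' A stage whose upstream artifact is missing stops with an error naming
#' the stage to run first. The phenotype stage consumes the segmented cell
#' table when the segment stage has run (in this call or a previous one
#' into the same `outDir`), falling back to the simulated table otherwise.
#'
#' @param config a [PipelineConfig].
#' @param outDir output directory (created if needed).
#' @param spec optional [TissueSpec] overriding the config's `simulate`
#'   block.
#' @return (invisibly) the manifest list.
#' @export
runPipeline <- function(config, outDir, spec = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  p <- config@params
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- intersect(.defaultParams()$stages, p$stages)  # pipeline order
  manifest <- list(configHash = digest::digest(p), seed = p$seed,
                   stages = list(), checksums = list())
  art <- function(f) file.path(outDir, f)
  need <- function(stage, file) {
    if (!file.exists(art(file)))
      stop("stage '", stage, "' needs ", file, "; run stage '",
           .stageNeeds[[stage]], "' first")
  }
  if (is.null(spec))
    spec <- do.call(tissueSpec, c(p$simulate, list(seed = p$seed)))
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    res <- force(expr)
    manifest$stages[[stage]]$seconds <<-
      unname(round(proc.time()[3] - t0, 2))
    res
  }

  for (stage in stages) {
    switch(stage,
    simulate = tick("simulate", {
      sim <- generateCohort(spec)
      writeCellTable(sim$cells, art("cells_simulated.csv"))
      rois <- unique(cellData(sim$cells)[, c("roi_id", "patient_id", "group")])
      jsonlite::write_json(rois, art("rois.json"))
      stacks <- rasterize(sim$cells, spec)
      for (rid in names(stacks))
        writeChannelStack(stacks[[rid]], art(paste0("stack_", rid, ".tif")))
      writeSpillover(spec@spillover, art("spillover.csv"))
      manifest$stages$simulate$cells <- nCells(sim$cells)
    }),
    preprocess = tick("preprocess", {
      need("preprocess", "spillover.csv")
      S <- readSpillover(art("spillover.csv"))
      files <- list.files(outDir, "^stack_.*\\.tif$")
      for (f in files) {
        st <- readChannelStack(art(f))
        st <- preprocessStack(st, S, p$medianWindow, p$saturation)
        writeChannelStack(st, art(sub("^stack_", "pre_", f)))
      }
      manifest$stages$preprocess$stacks <- length(files)
    }),
    segment = tick("segment", {
      need("segment", "rois.json")
      rois <- jsonlite::read_json(art("rois.json"), simplifyVector = TRUE)
      files <- list.files(outDir, "^pre_.*\\.tif$")
      if (!length(files))
        stop("stage 'segment' needs preprocessed stacks; run stage ",
             "'preprocess' first")
      tabs <- lapply(files, function(f) {
        st <- readChannelStack(art(f))
        i <- match(roiId(st), rois$roi_id)
        segmentStack(st, threshold = p$threshold, minArea = p$minArea,
                     dilationRadius = p$dilationRadius,
                     patientId = rois$patient_id[i], group = rois$group[i])
      })
      ct <- Reduce(rbind2, tabs)
      writeCellTable(ct, art("cells_segmented.csv"))
      manifest$stages$segment$cells <- nCells(ct)
    }),
    phenotype = tick("phenotype", {
      src <- if (file.exists(art("cells_segmented.csv")))
        "cells_segmented.csv" else "cells_simulated.csv"
      need("phenotype", src)
      ct <- readCellTable(art(src))
      ct <- rangeNormalize(ct, p$normPercentile)
      ct <- alignBatches(ct)
      ph <- clusterPhenotypes(ct, p$kNeighbors, seed = p$seed)
      writeCellTable(ph$cells, art("cells_phenotyped.csv"))
      prof <- clusterProfile(ph$model)
      data.table::fwrite(data.frame(cluster = rownames(prof), prof),
                         art("phenotype_profile.csv"))
      jsonlite::write_json(
        list(k = nrow(prof), modularity = ph$model@graphInfo$modularity,
             patientFreq = ph$model@patientFreq),
        art("phenotype_model.json"), digits = NA, matrix = "rowmajor")
      manifest$stages$phenotype$clusters <- nrow(prof)
    }),
    neighborhoods = tick("neighborhoods", {
      need("neighborhoods", "cells_phenotyped.csv")
      ct <- readCellTable(art("cells_phenotyped.csv"))
      fit <- fitNeighborhoods(ct, p$window, p$kCN, seed = p$seed)
      writeCellTable(fit$cells, art("cells_cn.csv"))
      jsonlite::write_json(
        list(k = fit$model@k, w = fit$model@windowSize,
             sizes = fit$model@sizes, abundance = fit$model@abundance,
             patientFreq = fit$model@patientFreq),
        art("cn_model.json"), digits = NA, matrix = "rowmajor")
      vm <- voronoiMap(fit$cells, cellData(fit$cells)$roi_id[1],
                       spec@roiSize)
      jsonlite::write_json(
        list(cn = vm$cn, polygons = lapply(vm$polygons, unclass)),
        art("voronoi_roi1.json"), digits = NA, matrix = "rowmajor")
      manifest$stages$neighborhoods$cns <- sum(fit$model@sizes > 0)
    }),
    interactions = tick("interactions", {
      need("interactions", "cells_cn.csv")
      ct <- readCellTable(art("cells_cn.csv"))
      res <- testInteractions(ct, p$kSpatial, p$nPerm, seed = p$seed)
      data.table::fwrite(interactionResults(res),
                         art("interactions.csv"))
      summ <- summarizeCohort(res, ct, p$alpha)
      data.table::fwrite(summ, art("interaction_summary.csv"))
      manifest$stages$interactions$rois <-
        length(unique(interactionResults(res)$roi))
    }),
    tensor = tick("tensor", {
      need("tensor", "cells_cn.csv")
      ct <- readCellTable(art("cells_cn.csv"))
      for (g in c("normal", "disease")) {
        tt <- buildTensor(ct, g)
        fit <- ntd(tt, ranks = p$tensorRanks, seed = p$seed)
        mg <- moduleGraph(fit)
        jsonlite::write_json(
          list(group = g, normalization = tt@normalization,
               ranks = fit@ranks, finalLoss = tail(lossTrace(fit), 1),
               relError = relativeError(fit, tt), edges = mg$edges,
               core = tuckerCore(fit), factors = tuckerFactors(fit)),
          art(paste0("tensor_", g, ".json")), digits = NA,
          matrix = "rowmajor")
      }
      manifest$stages$tensor$groups <- 2
    }),
    report = tick("report", {
      need("report", "tensor_normal.json")
      renderReport(outDir)
    }))
  }
  for (f in list.files(outDir, "\\.(csv|json)$"))
    manifest$checksums[[f]] <- digest::digest(file = art(f))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Render a markdown summary report of a pipeline run
#'
#' Writes `report.md` summarizing the run: phenotype cluster count and
#' per-group CN abundance comparison, the CN composition heatmap values
#' (column-scaled abundances, passed through verbatim), the interaction
#' summary (significant-ROI fractions, which size the circles of an
#' interaction plot), and the tensor module edges. When the `pheatmap` and
#' `png` packages are available, heatmap and Voronoi PNGs are written
#' alongside.
#'
#' @param outDir a directory populated by [runPipeline()].
#' @return (invisibly) the report path.
#' @export
renderReport <- function(outDir) {
  art <- function(f) file.path(outDir, f)
  lines <- c("# Pipeline report", "")
  if (file.exists(art("phenotype_model.json"))) {
    pm <- jsonlite::read_json(art("phenotype_model.json"),
                              simplifyVector = TRUE)
    lines <- c(lines, sprintf("Phenotype clusters: %d (modularity %.3f)",
                              pm$k, pm$modularity), "")
  }
  if (file.exists(art("cn_model.json"))) {
    cm <- jsonlite::read_json(art("cn_model.json"), simplifyVector = TRUE)
    lines <- c(lines, sprintf("Cellular neighborhoods: %d of %d occupied",
                              sum(cm$sizes > 0), cm$k), "",
               "## CN x phenotype abundance (column scaled)", "")
    ab <- cm$abundance
    lines <- c(lines, paste("|CN|", paste(colnames(ab), collapse = "|"), "|"),
               paste0("|", paste(rep("---", ncol(ab) + 1), collapse = "|"), "|"))
    for (i in seq_len(nrow(ab)))
      lines <- c(lines, paste0("|CN", i, "|",
                               paste(sprintf("%.2f", ab[i, ]), collapse = "|"),
                               "|"))
    lines <- c(lines, "")
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(art("cn_heatmap.png"), 900, 600)
      pheatmap::pheatmap(ab, cluster_rows = FALSE, cluster_cols = FALSE,
                         main = "CN composition (column scaled)")
      grDevices::dev.off()
      lines <- c(lines, "![CN heatmap](cn_heatmap.png)", "")
    }
  }
  if (file.exists(art("cells_cn.csv")) &&
      file.exists(art("voronoi_roi1.json"))) {
    ct <- readCellTable(art("cells_cn.csv"))
    comp <- cnGroupAbundance(ct)
    lines <- c(lines, "## CN abundance, normal vs disease", "",
               "|CN|mean normal|mean disease|p|",
               "|---|---|---|---|")
    for (i in seq_len(nrow(comp)))
      lines <- c(lines, sprintf("|CN%d|%.4f|%.4f|%.3g|", comp$cn[i],
                                comp$freq_normal[i], comp$freq_disease[i],
                                comp$p[i]))
    lines <- c(lines, "")
  }
  if (file.exists(art("interaction_summary.csv"))) {
    s <- as.data.frame(data.table::fread(art("interaction_summary.csv")))
    topi <- s[order(-s$sigInt), ][seq_len(min(10, nrow(s))), ]
    lines <- c(lines, "## Strongest interactions (fraction of significant ROIs)",
               "", "|group|center|neighbor|sig. fraction|Pearson r|",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(topi)))
      lines <- c(lines, sprintf("|%s|PT%d|PT%d|%.2f|%.2f|", topi$group[i],
                                topi$center[i], topi$neighbor[i],
                                topi$sigInt[i], topi$r[i]))
    lines <- c(lines, "")
  }
  for (g in c("normal", "disease")) {
    f <- art(paste0("tensor_", g, ".json"))
    if (!file.exists(f)) next
    tj <- jsonlite::read_json(f, simplifyVector = TRUE)
    ed <- head(tj$edges, 5)
    lines <- c(lines, paste0("## Tissue modules (", g, ")"), "",
               "|CN module|CT module|weight|", "|---|---|---|")
    for (i in seq_len(nrow(ed)))
      lines <- c(lines, sprintf("|%d|%d|%.3f|", ed$cnModule[i],
                                ed$ctModule[i], ed$weight[i]))
    lines <- c(lines, "")
  }
  writeLines(lines, art("report.md"))
  invisible(art("report.md"))
}
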