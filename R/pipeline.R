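## End-to-end pipeline orchestration: validated config, staged execution,
## reproducible run manifest with output checksums.

.stageCatalog <- c("simulate_complex", "simulate_links", "filter_fdr",
                   "deduplicate", "map_links", "network", "simulate_silac",
                   "silac_enrichment", "simulate_images", "colocalization",
                   "simulate_membrane", "membrane_ratio")

#' Default synthetic end-to-end pipeline configuration
#'
#' A full run over every input class: simulate a complex and a cross-link
#' table, map and report distances, build the network, run the SILAC
#' statistics and the co-localization / membrane-ratio quantification.
#'
#' @param seed Master seed for every stochastic stage.
#' @param outdir Output directory.
#' @return Config list accepted by \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(seed = 1L, outdir = "xlms-run") {
    list(seed = seed, outdir = outdir, stages = list(
        list(stage = "simulate_complex", nProteins = 2L, copies = 1L,
             residuesPerChain = 200L),
        list(stage = "simulate_links", nSatisfying = 40L, nViolating = 10L,
             nDecoyPairs = 5L, maxDistance = 35),
        list(stage = "map_links", maxDistance = 35),
        list(stage = "network", minLinks = 1L),
        list(stage = "simulate_silac", nProteins = 300L, nEnriched = 20L,
             effectLog2 = 2, noiseSd = 0.25, nReplicates = 3L),
        list(stage = "silac_enrichment", mode = "two_group"),
        list(stage = "simulate_images", overlapFraction = 0.5),
        list(stage = "colocalization"),
        list(stage = "simulate_membrane", enrichmentRatio = 4),
        list(stage = "membrane_ratio")
    ))
}

.validateConfig <- function(config) {
    errs <- character()
    bad <- function(...) errs <<- c(errs, sprintf(...))
    if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed))))
        bad("seed: must be an integer")
    if (is.null(config$outdir) || !nzchar(config$outdir))
        bad("outdir: must be a non-empty path")
    if (is.null(config$stages) || length(config$stages) == 0L)
        bad("stages: at least one stage is required")
    for (i in seq_along(config$stages)) {
        st <- config$stages[[i]]
        nm <- st$stage
        if (is.null(nm) || !nm %in% .stageCatalog) {
            bad("stages[%d].stage: unknown stage '%s'", i,
                if (is.null(nm)) "<missing>" else nm)
            next
        }
        chk <- function(field, test, msg) {
            v <- st[[field]]
            if (!is.null(v) && !test(v))
                bad("stages[%d].%s: %s (got %s)", i, field, msg,
                    paste(v, collapse = ","))
        }
        chk("maxDistance", function(v) is.numeric(v) && v > 0, "must be > 0")
        chk("threshold", function(v) is.numeric(v) && v >= 0 && v <= 1,
            "must be in [0, 1]")
        chk("minLinks", function(v) v >= 1, "must be >= 1")
        chk("overlapFraction", function(v) v >= 0 && v <= 1,
            "must be in [0, 1]")
        chk("noiseSd", function(v) v > 0, "must be > 0")
        chk("nProteins", function(v) v >= 1, "must be >= 1")
        chk("enrichmentRatio", function(v) v > 0, "must be > 0")
    }
    if (length(errs))
        stop("invalid pipeline configuration:\n  ",
             paste(errs, collapse = "\n  "), call. = FALSE)
    invisible(TRUE)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

.writeMatrixTsv <- function(m, path) {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
}

#' Run the pipeline described by a config
#'
#' Stages execute in the listed order, sharing state (a simulated complex
#' feeds the link simulation, which feeds mapping, and so on); a stage
#' whose inputs are missing aborts the run naming the stage. The manifest
#' records stage order, parameters, output files with MD5 checksums, and
#' warnings; identical config and seed give identical checksums.
#'
#' @param config Config list (see \code{\link{defaultPipelineConfig}}) or
#'   path to a YAML file with the same structure.
#' @param outdir Optional override of \code{config$outdir}.
#' @return The manifest (list), invisibly; also written as
#'   \code{manifest.json} in the output directory.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (!is.null(outdir)) config$outdir <- outdir
    .validateConfig(config)
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(config$seed)
    env <- new.env(parent = emptyenv())
    manifest <- list(seed = seed, stages = list())
    warns <- character()
    need <- function(what, stage) {
        if (!exists(what, envir = env))
            stop(sprintf("stage '%s' failed: required upstream result '%s' missing",
                         stage, what), call. = FALSE)
        get(what, envir = env)
    }
    out <- function(...) file.path(config$outdir, ...)
    for (st in config$stages) {
        nm <- st$stage
        p <- st[setdiff(names(st), "stage")]
        files <- withCallingHandlers(
            switch(nm,
            simulate_complex = {
                cx <- do.call(makeComplex, c(p, list(seed = seed)))
                assign("complex", cx, envir = env)
                c(.writeTsv(cx$structure@atoms, out("complex_atoms.tsv")),
                  .writeTsv(data.frame(accession = names(cx$sequences),
                                       sequence = unname(cx$sequences)),
                            out("sequences.tsv")))
            },
            simulate_links = {
                sim <- do.call(sampleCrossLinks,
                               c(list(complex = need("complex", nm)), p,
                                 list(seed = seed)))
                assign("links", sim$links, envir = env)
                assign("truth", sim$truth, envir = env)
                assign("assignment", sim$assignment, envir = env)
                c(writeCrossLinkTable(sim$links, out("links.tsv")),
                  .writeTsv(sim$truth, out("links_truth.tsv")))
            },
            filter_fdr = {
                lk <- filterFDR(need("links", nm), p$threshold)
                assign("links", lk, envir = env)
                writeCrossLinkTable(lk, out("links_filtered.tsv"))
            },
            deduplicate = {
                lk <- deduplicateUniquePairs(need("links", nm))
                assign("links", lk, envir = env)
                writeCrossLinkTable(lk, out("links_dedup.tsv"))
            },
            map_links = {
                maxD <- if (is.null(p$maxDistance)) 35 else p$maxDistance
                cx <- need("complex", nm)
                mapped <- mapCrossLinks(need("links", nm), cx$structure,
                                        need("assignment", nm), maxD)
                assign("mapped", mapped, envir = env)
                rep <- satisfactionReport(mapped, maxD, cx$structure@id)
                hist <- distanceDistribution(mapped)
                c(.writeTsv(as.data.frame(mapped), out("mapped_links.tsv")),
                  { jsonlite::write_json(list(
                        complexId = rep@complexId, nInput = rep@nInput,
                        nMapped = rep@nMapped, nSatisfied = rep@nSatisfied,
                        agreement = rep@agreement,
                        maxDistance = rep@maxDistance,
                        histBreaks = hist$breaks, histCounts = hist$counts),
                        out("distance_report.json"), auto_unbox = TRUE,
                        digits = NA)
                    out("distance_report.json") })
            },
            network = {
                net <- buildNetwork(need("links", nm),
                                    minLinks = if (is.null(p$minLinks)) 1L
                                               else p$minLinks)
                c(exportGraph(net, out("network.graphml"), "graphml"),
                  .writeTsv(residueEdgeTable(net), out("residue_edges.tsv")))
            },
            simulate_silac = {
                fw <- do.call(makeSilacDataset,
                              c(p, list(seed = seed,
                                        orientation = "forward")))
                rv <- do.call(makeSilacDataset,
                              c(p, list(seed = seed + 1L,
                                        orientation = "reverse")))
                assign("silacForward", fw, envir = env)
                assign("silacReverse", rv, envir = env)
                c(.writeTsv(fw$records, out("silac_forward.tsv")),
                  .writeTsv(rv$records, out("silac_reverse.tsv")),
                  .writeTsv(fw$truth, out("silac_truth.tsv")))
            },
            silac_enrichment = {
                mode <- if (is.null(p$mode)) "two_group" else p$mode
                fw <- testEnrichment(need("silacForward", nm)$records, mode)
                rv <- testEnrichment(need("silacReverse", nm)$records, mode)
                conc <- labelSwapConcordance(fw, rv)
                c(.writeTsv(fw, out("enrichment_forward.tsv")),
                  .writeTsv(rv, out("enrichment_reverse.tsv")),
                  { jsonlite::write_json(list(r = conc$r,
                        signAgreement = conc$signAgreement),
                        out("label_swap.json"), auto_unbox = TRUE,
                        digits = NA)
                    out("label_swap.json") })
            },
            simulate_images = {
                im <- do.call(makeColocImages, c(p, list(seed = seed)))
                assign("colocImages", im, envir = env)
                c(.writeMatrixTsv(round(im$channelA, 6), out("channelA.tsv")),
                  .writeMatrixTsv(round(im$channelB, 6), out("channelB.tsv")))
            },
            colocalization = {
                im <- need("colocImages", nm)
                ma <- otsuThreshold(im$channelA)$mask
                mb <- otsuThreshold(im$channelB)$mask
                mm <- manders(im$channelA, ma, im$channelB, mb)
                .writeTsv(data.frame(M1 = mm$M1, M2 = mm$M2,
                                     nMaskA = mm$nMaskA, nMaskB = mm$nMaskB,
                                     truthOverlap = im$truth$overlap),
                          out("colocalization.tsv"))
            },
            simulate_membrane = {
                mem <- do.call(makeMembraneImage, c(p, list(seed = seed)))
                assign("membraneImage", mem, envir = env)
                .writeMatrixTsv(round(mem$channel, 6), out("membrane.tsv"))
            },
            membrane_ratio = {
                mem <- need("membraneImage", nm)
                ratio <- membraneCytosolRatio(mem$channel,
                                              mem$rois$membrane,
                                              mem$rois$cytosol)
                .writeTsv(data.frame(ratio = ratio, truth = mem$truth),
                          out("membrane_ratio.tsv"))
            },
            stop("unhandled stage: ", nm)),
            warning = function(w) {
                warns <<- c(warns, sprintf("%s: %s", nm,
                                           conditionMessage(w)))
                invokeRestart("muffleWarning")
            })
        manifest$stages[[length(manifest$stages) + 1L]] <-
            list(stage = nm, params = p, outputs = basename(files))
    }
    allFiles <- unlist(lapply(manifest$stages, `[[`, "outputs"))
    sums <- tools::md5sum(file.path(config$outdir, allFiles))
    manifest$checksums <- as.list(stats::setNames(unname(sums), allFiles))
    manifest$warnings <- warns
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
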