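## End-to-end orchestration: simulate -> descriptive statistics ->
## clustering -> assignment/migration -> bottleneck -> matrix association,
## with a JSON run manifest and delimited-text reports.

stageSeeds <- function(seed, stages) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max %/% 2L, length(stages)), stages)
}

#' Run the full vector-connectivity analysis pipeline
#'
#' Executes, in order: panel simulation (or ingestion), per-site and
#' per-cluster diversity summaries, pairwise F_ST, advisory Gibbs
#' clustering with Evanno delta-K, Rannala-Mountain assignment and the
#' directional migration matrix, per-cluster bottleneck tests, and the
#' Mantel correlation table over F_ST, geographic distance, migration, and
#' the vector (shipping) network - the latter run both on the full label
#' set and with `excludeCluster` dropped. Every stage draws its randomness
#' from a named substream of the single `seed`. A JSON manifest is updated
#' before and after each stage.
#'
#' @param config a [simConfig()] object describing the synthetic study (its
#'   `seed` field is overridden by the pipeline substream).
#' @param seed master integer seed.
#' @param outDir output directory (created if needed).
#' @param network optional directed vector matrix; simulated via
#'   [generateVectorNetwork()] when `NULL`.
#' @param coordinates optional named alongshore coordinates for the demes;
#'   defaults to the [studyDesign()] layout when labels match, otherwise
#'   equally spaced positions.
#' @param genotypes optional path to a GENEPOP file or a
#'   [GenotypePanel-class]; when given, simulation is skipped and
#'   `config$siteCluster` assigns clusters.
#' @param excludeCluster cluster label(s) for the exclusion variant of the
#'   correlation table (default: the configured outlier deme).
#' @param nPerm Mantel permutations.
#' @param doCluster run the (slow) clustering stage?
#' @param clusterKs,clusterReps,clusterBurnIn,clusterIters clustering
#'   controls.
#' @param bottleneckSims accepted equilibrium replicates per locus.
#' @return A list with elements `panel`, `diversitySite`, `diversityCluster`,
#'   `fst`, `evanno`, `clusterRuns`, `assignments`, `migration`,
#'   `bottleneck`, `mantel`, `network`, `distance`, `manifest` (path).
#' @export
runPipeline <- function(config, seed, outDir,
                        network = NULL, coordinates = NULL, genotypes = NULL,
                        excludeCluster = config$outlierDeme,
                        nPerm = 9999L, doCluster = TRUE,
                        clusterKs = NULL, clusterReps = 3L,
                        clusterBurnIn = 300L, clusterIters = 1000L,
                        bottleneckSims = 500L) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- c(
    "network", "simulate", "stats", "cluster", "assign",
    "bottleneck", "mantel"
  )
  seeds <- stageSeeds(seed, stages)
  manifestPath <- file.path(outDir, "manifest.json")
  manifest <- list(
    tool = paste("vecgen", as.character(utils::packageVersion("vecgen"))),
    seed = seed, stageSeeds = as.list(seeds),
    config = unclass(config), started = format(Sys.time()),
    outputs = list(), digests = list(), completed = character(0)
  )
  writeManifest <- function() {
    jsonlite::write_json(manifest, manifestPath,
      auto_unbox = TRUE, pretty = TRUE, force = TRUE, digits = NA
    )
  }
  addOutput <- function(stage, name, path) {
    manifest$outputs[[name]] <<- path
    manifest$digests[[name]] <<- unname(tools::md5sum(path))
  }
  finishStage <- function(stage) {
    manifest$completed <<- c(manifest$completed, stage)
    writeManifest()
  }
  runStage <- function(stage, fn) {
    manifest$current <<- stage
    writeManifest()
    tryCatch(fn(), error = function(e) {
      stop(
        "pipeline stage '", stage, "' failed: ", conditionMessage(e),
        "\ncompleted stages: ", paste(manifest$completed, collapse = ", "),
        call. = FALSE
      )
    })
  }
  out <- list(manifest = manifestPath)

  ## --- network -------------------------------------------------------
  runStage("network", function() {
    if (is.null(network)) {
      network <<- generateVectorNetwork(config$demes, seed = seeds[["network"]])
    }
    if (is.null(coordinates)) {
      d <- studyDesign()
      coordinates <<- if (setequal(config$demes, names(d$coordinates))) {
        d$coordinates[config$demes]
      } else {
        setNames(seq_along(config$demes) * 100, config$demes)
      }
    }
    distance <- distanceMatrixFromLayout(coordinates)
    out$network <<- network
    out$distance <<- distance
    writeLabeledMatrix(network, file.path(outDir, "shipping_network.tsv"))
    writeLabeledMatrix(distance, file.path(outDir, "distance.tsv"))
    addOutput("network", "shipping_network", file.path(outDir, "shipping_network.tsv"))
    addOutput("network", "distance", file.path(outDir, "distance.tsv"))
  })
  finishStage("network")

  ## --- simulate / ingest --------------------------------------------
  runStage("simulate", function() {
    panel <- if (is.null(genotypes)) {
      cfg <- config
      cfg$seed <- seeds[["simulate"]]
      simulatePanel(cfg, network)
    } else if (is(genotypes, "GenotypePanel")) {
      genotypes
    } else {
      p <- readGenepop(genotypes)
      clusters(p) <- config$siteCluster
      p
    }
    out$panel <<- panel
    gp <- file.path(outDir, "genotypes.gen")
    writeGenepop(panel, gp)
    addOutput("simulate", "genotypes", gp)
  })
  finishStage("simulate")
  panel <- out$panel

  ## --- descriptive statistics ---------------------------------------
  runStage("stats", function() {
    out$diversitySite <<- diversitySummary(panel, by = "site")
    out$diversityCluster <<- diversitySummary(panel, by = "cluster")
    out$fst <<- pairwiseFst(panel, by = "cluster")
    for (nm in c("diversitySite", "diversityCluster")) {
      p <- file.path(outDir, paste0(nm, ".tsv"))
      write.table(out[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
      addOutput("stats", nm, p)
    }
    writeLabeledMatrix(out$fst, file.path(outDir, "fst.tsv"))
    addOutput("stats", "fst", file.path(outDir, "fst.tsv"))
  })
  finishStage("stats")

  ## --- clustering (advisory) ----------------------------------------
  runStage("cluster", function() {
    if (!doCluster) {
      return(invisible(NULL))
    }
    Ks <- if (is.null(clusterKs)) seq_len(length(config$demes) + 2L) else clusterKs
    runs <- clusterScan(panel,
      Ks = Ks, nReps = clusterReps,
      burnIn = clusterBurnIn, iters = clusterIters,
      seed = seeds[["cluster"]]
    )
    ev <- evannoSelect(runs)
    out$clusterRuns <<- runs
    out$evanno <<- ev
    p <- file.path(outDir, "evanno.tsv")
    write.table(ev, p, sep = "\t", quote = FALSE, row.names = FALSE)
    addOutput("cluster", "evanno", p)
    selK <- attr(ev, "selectedK")
    if (!is.na(selK)) {
      best <- alignLabels(runs[[as.character(selK)]])[[1L]]
      mp <- file.path(outDir, "memberships.tsv")
      write.table(
        data.frame(
          individual = indNames(panel), cluster = clusters(panel),
          memberships(best)
        ),
        mp, sep = "\t", quote = FALSE, row.names = FALSE
      )
      addOutput("cluster", "memberships", mp)
    }
  })
  finishStage("cluster")

  ## --- assignment & migration ---------------------------------------
  runStage("assign", function() {
    asg <- assignIndividuals(panel, by = "cluster", leaveOneOut = TRUE)
    out$assignments <<- asg
    out$migration <<- migrationMatrix(asg)
    p <- file.path(outDir, "assignments.tsv")
    write.table(asg, p, sep = "\t", quote = FALSE, row.names = FALSE)
    addOutput("assign", "assignments", p)
    writeLabeledMatrix(out$migration, file.path(outDir, "migration.tsv"))
    addOutput("assign", "migration", file.path(outDir, "migration.tsv"))
  })
  finishStage("assign")

  ## --- bottleneck ----------------------------------------------------
  runStage("bottleneck", function() {
    set.seed(seeds[["bottleneck"]])
    bt <- bottleneckTest(panel,
      by = "cluster",
      pMultistep = config$pMultistep,
      multistepVariance = config$multistepVariance,
      nSims = bottleneckSims
    )
    out$bottleneck <<- bt
    tab <- do.call(rbind, lapply(names(bt), function(g) {
      data.frame(
        cluster = g, p_excess = bt[[g]]$p["excess"],
        p_deficit = bt[[g]]$p["deficit"],
        p_two_sided = bt[[g]]$p["two.sided"],
        mode_shift = bt[[g]]$modeShift
      )
    }))
    p <- file.path(outDir, "bottleneck.tsv")
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    addOutput("bottleneck", "bottleneck", p)
  })
  finishStage("bottleneck")

  ## --- matrix association --------------------------------------------
  runStage("mantel", function() {
    mats <- list(
      FST = out$fst,
      Distance = out$distance[config$demes, config$demes],
      Migration = out$migration,
      Shipping = out$network[config$demes, config$demes]
    )
    mt <- correlationTable(mats,
      nPerm = nPerm, tail = "greater",
      seed = seeds[["mantel"]],
      exclude = if (is.null(excludeCluster)) character(0) else excludeCluster
    )
    out$mantel <<- mt
    if (!is.null(excludeCluster)) {
      writeLabeledMatrix(mt$full$table, file.path(outDir, "mantel_full.tsv"))
      writeLabeledMatrix(mt$excluded$table, file.path(outDir, "mantel_excluded.tsv"))
      addOutput("mantel", "mantel_full", file.path(outDir, "mantel_full.tsv"))
      addOutput("mantel", "mantel_excluded", file.path(outDir, "mantel_excluded.tsv"))
    } else {
      writeLabeledMatrix(mt$table, file.path(outDir, "mantel_full.tsv"))
      addOutput("mantel", "mantel_full", file.path(outDir, "mantel_full.tsv"))
    }
  })
  manifest$finished <- format(Sys.time())
  finishStage("mantel")
  invisible(out)
}
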