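#' @include AllClasses.R
NULL

KNOWN_ANALYSES <- c("occupancy", "profile", "density2d", "angle",
                    "structureReport")

#' Read and validate a run configuration
#'
#' Configurations are YAML files (or equivalent named lists) with keys
#' \code{topology} (GRO/PDB path), \code{replicates} (list of frame-table
#' CSV paths), \code{outputDir}, optional \code{structure} (PDB path for
#' the static report), optional \code{seed}, and an \code{analyses} map
#' whose sub-keys switch on the individual analyses with their parameters.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  need <- c("topology", "replicates", "outputDir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop(sprintf("config schema violation: missing key(s) %s",
                 paste(miss, collapse = ", ")))
  unknown <- setdiff(names(config),
                     c(need, "structure", "seed", "analyses", "quiet"))
  if (length(unknown))
    stop(sprintf("config schema violation: unknown key(s) %s",
                 paste(unknown, collapse = ", ")))
  if (!is.null(config$analyses)) {
    bad <- setdiff(names(config$analyses), KNOWN_ANALYSES)
    if (length(bad))
      stop(sprintf("config schema violation: unknown analysis key(s) %s",
                   paste(bad, collapse = ", ")))
  }
  for (p in c(config$topology, unlist(config$replicates), config$structure))
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  config
}

pipeLog <- function(quiet, fmt, ...) {
  if (!isTRUE(quiet)) message(sprintf(fmt, ...))
}

writeTableWithSidecar <- function(df, path, meta) {
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

#' Run the full analysis pipeline
#'
#' Reads the topology and replicate frame tables, runs every enabled
#' analysis, and writes plain CSV tables with JSON sidecars plus a
#' \code{manifest.json} recording the configuration verbatim, input file
#' checksums and the package version.  Outputs are deterministic given
#' inputs and seed (no timestamps).  Failure of one analysis aborts with an
#' error, leaving the outputs written so far intact.
#'
#' @param config path to a YAML config or a named list
#'   (see \code{\link{readRunConfig}}).
#' @return invisibly, named character vector of written files.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  quiet <- isTRUE(cfg$quiet)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))

  topoPath <- cfg$topology
  topo <- if (grepl("\\.pdb$", topoPath, ignore.case = TRUE))
    readPDB(topoPath) else readGRO(topoPath)
  pipeLog(quiet, "topology: %d atoms from %s", nAtoms(topo), topoPath)
  trajs <- lapply(unlist(cfg$replicates), readFrameTable, topology = topo)
  pipeLog(quiet, "replicates: %d trajectories", length(trajs))

  inputs <- c(topoPath, unlist(cfg$replicates), cfg$structure)
  manifest <- list(
    package = "memBAR",
    version = as.character(utils::packageVersion("memBAR")),
    config = cfg,
    inputs = as.list(stats::setNames(
      as.character(tools::md5sum(inputs)), basename(inputs))))
  manifestPath <- file.path(cfg$outputDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifestHash <- as.character(tools::md5sum(manifestPath))
  meta0 <- list(manifest_md5 = manifestHash)
  written <- c(manifest = manifestPath)

  an <- cfg$analyses
  enabled <- function(key) isTRUE(an[[key]]$enabled)
  getp <- function(key, name, default) {
    v <- an[[key]][[name]]
    if (is.null(v)) default else v
  }

  if (enabled("occupancy")) {
    classes <- unlist(getp("occupancy", "classes", "ALL"))
    cutoff <- getp("occupancy", "cutoff", 0.4)
    rows <- list()
    for (cl in classes) {
      profs <- lapply(trajs, function(tr)
        occupancyProfile(contactSeries(tr, cl, cutoff = cutoff)))
      agg <- aggregateOccupancy(profs)
      rows[[cl]] <- asTable(agg)
    }
    tb <- do.call(rbind, rows)
    rownames(tb) <- NULL
    written["occupancy"] <- writeTableWithSidecar(
      tb, file.path(cfg$outputDir, "occupancy.csv"),
      c(meta0, list(analysis = "occupancy", cutoff_nm = cutoff,
                    classes = as.list(classes),
                    n_replicates = length(trajs))))
    pipeLog(quiet, "occupancy: %d rows", nrow(tb))
  }

  if (enabled("profile")) {
    leaflet <- getp("profile", "leaflet", "upper")
    binNm <- getp("profile", "binNm", 1.0)
    stride <- getp("profile", "sampleEveryPs", 200)
    profs <- lapply(trajs, heightProfile, leaflet = leaflet, binNm = binNm,
                    sampleEveryPs = stride)
    agg <- aggregateProfiles(profs)
    tb <- asTable(agg)
    written["profile"] <- writeTableWithSidecar(
      tb, file.path(cfg$outputDir, "height_profile.csv"),
      c(meta0, list(analysis = "profile", leaflet = leaflet,
                    bin_nm = binNm, sample_every_ps = stride,
                    n_replicates = length(trajs))))
    kap <- curvatureEstimate(agg)
    written["curvature"] <- writeTableWithSidecar(
      kap, file.path(cfg$outputDir, "curvature.csv"),
      c(meta0, list(analysis = "curvature", sign_convention =
                      "bulge toward protein (+z) positive")))
    pipeLog(quiet, "profile: %d bins (%d missing)", length(agg@binCenters),
            sum(agg@missing))
  }

  if (enabled("density2d")) {
    cl <- getp("density2d", "class", "POPC")
    win <- getp("density2d", "windowPs", 1e5)
    binNm <- getp("density2d", "binNm", 0.2)
    alignment <- getp("density2d", "alignment", "protein_aligned")
    maps <- lapply(trajs, densityMap2D, lipidClass = cl, windowPs = win,
                   binNm = binNm, alignment = alignment)
    grid <- Reduce(`+`, lapply(maps, function(m) m@grid)) / length(maps)
    avg <- maps[[1]]
    avg@grid <- grid
    tb <- asTable(avg)
    written["density2d"] <- writeTableWithSidecar(
      tb, file.path(cfg$outputDir, sprintf("density2d_%s.csv", cl)),
      c(meta0, list(analysis = "density2d", class = cl, window_ps = win,
                    bin_nm = binNm, alignment = alignment,
                    xedges_nm = avg@xedges, yedges_nm = avg@yedges,
                    n_replicates = length(maps))))
    pipeLog(quiet, "density2d[%s]: %d x %d bins", cl, nrow(grid), ncol(grid))
  }

  if (enabled("angle")) {
    groups <- defaultAngleGroups()
    series <- lapply(trajs, angleSeries, groups = groups)
    agg <- aggregateAngles(series)
    tb <- asTable(agg)
    written["angle"] <- writeTableWithSidecar(
      tb, file.path(cfg$outputDir, "angle.csv"),
      c(meta0, list(analysis = "angle",
                    groups = lapply(groups, function(g)
                      list(chain = g$chain, resseq = range(g$resseq))),
                    n_replicates = length(series))))
    pipeLog(quiet, "angle: %d frames", nrow(tb))
  }

  if (enabled("structureReport")) {
    if (is.null(cfg$structure))
      stop("structureReport analysis needs a 'structure' input path")
    s <- readPDB(cfg$structure)
    rep <- structureReport(s,
                           chainsA = getp("structureReport", "chainsA", "A"),
                           chainsB = getp("structureReport", "chainsB", "B"))
    out <- list(
      interhelix_angles_deg = rep$interhelixAngles,
      length_angstrom = rep$extent$length,
      bundle_diameter_angstrom = rep$extent$bundleDiameter,
      buried_interface_area_A2 = rep$interface$buriedArea,
      buried_interface_area_sum_A2 = rep$interface$buriedAreaSum,
      hydrophobic_buried_count = rep$interface$hydrophobicCount,
      n_hbonds = nrow(rep$hbonds),
      hbonds = rep$hbonds,
      manifest_md5 = manifestHash)
    p <- file.path(cfg$outputDir, "structure_report.json")
    jsonlite::write_json(out, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written["structureReport"] <- p
    pipeLog(quiet, "structure report written")
  }

  invisible(written)
}
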