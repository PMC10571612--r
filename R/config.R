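#' @include AllClasses.R AllGenerics.R scenarios.R sweeps.R io.R synthetic-volume.R
NULL

#' Fully resolved run configuration
#'
#' @slot command the dispatched command ("sim scenario", "sim sweep",
#'   "img synth", "img metrics")
#' @slot values named list of all resolved settings (defaults materialized)
#' @slot seed integer RNG seed
#' @slot outDir output directory
#' @slot hash md5 of the canonicalized configuration content
#' @export
setClass("RunConfig",
  slots = c(command = "character", values = "list", seed = "integer",
            outDir = "character", hash = "character")
)

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: %s (seed %d, out '%s')\n  hash %s\n",
              object@command, object@seed, object@outDir, object@hash))
})

defaultConfig <- function() {
  list(
    command = "sim scenario",
    scenario = "plus-rdna",
    scale = 0.125,          # desk-scale preset: Rc = 22.5 sigma
    seed = 1L,
    prodSteps = 250000L,
    equilSteps = 20000L,
    cX = 0.013,
    epsilon = list(),       # named overrides, e.g. list(`X-X` = 1.6)
    sweep = "phase",
    grid = numeric(),
    seeds = c(1L, 2L),
    organization = "surrounded",
    noise = 0.05,
    shellPx = 1L,
    channels = c(fib = 0L, hp1a = 1L),
    out = "."
  )
}

canonicalYaml <- function(x) {
  sortRec <- function(v) {
    if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, sortRec)
    } else {
      v
    }
  }
  yaml::as.yaml(sortRec(x))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file (optional), merges it over the package
#' defaults, applies inline overrides last, validates every key (unknown keys
#' are rejected; epsilon overrides are checked against the interaction
#' hierarchy by the scenario constructors) and computes a reproducibility
#' hash over the canonicalized content. The resolved object alone suffices to
#' reproduce a run.
#'
#' @param path YAML file, or NULL for pure defaults
#' @param overrides named list applied after the file
#' @return a \linkS4class{RunConfig}
#' @examples
#' cfg <- loadRunConfig()
#' cfg@hash == loadRunConfig()@hash
#' @export
loadRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultConfig()
  fromFile <- if (!is.null(path)) yaml::read_yaml(path) else list()
  if (is.null(fromFile)) fromFile <- list() # empty file
  for (src in list(fromFile, overrides)) {
    for (key in names(src)) {
      if (!key %in% names(cfg)) {
        stop("unknown configuration key '", key, "'")
      }
      expected <- cfg[[key]]
      value <- src[[key]]
      if (is.numeric(expected) && !is.numeric(value)) {
        stop("type mismatch for key '", key, "': numeric expected")
      }
      if (is.character(expected) && !is.character(value)) {
        stop("type mismatch for key '", key, "': character expected")
      }
      cfg[[key]] <- value
    }
  }
  if (!cfg$scenario %in% c("plus-rdna", "minus-rdna")) {
    stop("invalid value for key 'scenario': must be plus-rdna or minus-rdna")
  }
  if (cfg$scale <= 0 || cfg$scale > 1) {
    stop("invalid value for key 'scale': must lie in (0, 1]")
  }
  if (length(cfg$epsilon)) {
    # delegate hierarchy validation to the matrix constructor
    ov <- unlist(cfg$epsilon)
    if (cfg$scenario == "plus-rdna") plusRdnaMatrix(ov)
  }
  ym <- canonicalYaml(cfg)
  tmp <- tempfile()
  writeLines(ym, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  new("RunConfig",
    command = cfg$command, values = cfg, seed = as.integer(cfg$seed),
    outDir = as.character(cfg$out), hash = hash
  )
}

usageText <- function() {
  paste(
    "usage: nucleopch <command> [options]",
    "",
    "commands:",
    "  sim scenario {plus-rdna|minus-rdna}  run a named scenario",
    "  sim sweep {phase|collapse|engulf|wetting|depletion}",
    "  img synth                            generate a synthetic nucleus volume",
    "  img metrics                          compute metrics on a TIFF stack",
    "",
    "global flags: --seed N --out DIR --scale S --steps N --config FILE",
    "              --organization NAME --noise X --shell-px N --in FILE",
    "              --version",
    sep = "\n"
  )
}

parseFlags <- function(argv) {
  flags <- list()
  rest <- character()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (key == "version") {
        flags[[key]] <- TRUE
        i <- i + 1L
      } else {
        if (i == length(argv)) stop("flag ", a, " needs a value")
        flags[[key]] <- argv[i + 1L]
        i <- i + 2L
      }
    } else {
      rest <- c(rest, a)
      i <- i + 1L
    }
  }
  list(flags = flags, rest = rest)
}

writeProvenance <- function(cfg, outDir, extra = list()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    c(list(command = cfg@command, config = cfg@values, seed = cfg@seed,
           hash = cfg@hash,
           version = as.character(utils::packageVersion("nucleopch"))),
      extra),
    file.path(outDir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
}

#' Command-line entry point
#'
#' Dispatches the simulator and imaging subcommands, logs to standard error
#' and writes a provenance JSON next to the outputs. Returns (not calls) the
#' exit code: 0 on success, 2 on usage errors, 1 on runtime failure. A thin
#' Rscript wrapper is installed at \code{system.file("scripts", "nucleopch",
#' package = "nucleopch")}.
#'
#' @param argv character vector of command-line arguments
#' @return integer exit code, invisibly
#' @export
nucleopchMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  parsed <- tryCatch(parseFlags(argv), error = function(e) e)
  if (inherits(parsed, "error")) {
    message(conditionMessage(parsed))
    message(usageText())
    return(invisible(2L))
  }
  flags <- parsed$flags
  rest <- parsed$rest
  if (isTRUE(flags$version)) {
    cat(as.character(utils::packageVersion("nucleopch")), "\n")
    return(invisible(0L))
  }
  if (length(rest) < 2L) {
    message(usageText())
    return(invisible(2L))
  }
  command <- paste(rest[1], rest[2])
  if (!command %in% c("sim scenario", "sim sweep", "img synth",
                      "img metrics")) {
    message("unknown command '", command, "'")
    message(usageText())
    return(invisible(2L))
  }
  overrides <- list(command = command)
  if (length(rest) >= 3L && rest[1] == "sim" && rest[2] == "scenario") {
    overrides$scenario <- rest[3]
  }
  if (length(rest) >= 3L && rest[1] == "sim" && rest[2] == "sweep") {
    overrides$sweep <- rest[3]
  }
  if (!is.null(flags$seed)) overrides$seed <- as.integer(flags$seed)
  if (!is.null(flags$out)) overrides$out <- flags$out
  if (!is.null(flags$scale)) overrides$scale <- as.numeric(flags$scale)
  if (!is.null(flags$steps)) overrides$prodSteps <- as.integer(flags$steps)
  if (!is.null(flags$organization)) overrides$organization <- flags$organization
  if (!is.null(flags$noise)) overrides$noise <- as.numeric(flags$noise)
  if (!is.null(flags[["shell-px"]])) overrides$shellPx <- as.integer(flags[["shell-px"]])

  cfg <- tryCatch(loadRunConfig(flags$config, overrides),
                  error = function(e) e)
  if (inherits(cfg, "error")) {
    message("configuration error: ", conditionMessage(cfg))
    return(invisible(2L))
  }

  ok <- tryCatch({
    dispatchCommand(cfg, flags)
    TRUE
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    FALSE
  })
  invisible(if (ok) 0L else 1L)
}

dispatchCommand <- function(cfg, flags) {
  v <- cfg@values
  outDir <- cfg@outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (cfg@command == "sim scenario") {
    message("running scenario ", v$scenario, " at scale ", v$scale)
    res <- runScenario(v$scenario, scale = v$scale, seed = cfg@seed,
                       prodSteps = v$prodSteps, equilSteps = v$equilSteps,
                       cX = v$cX)
    writeXYZ(res$trajectory, file.path(outDir, "trajectory.xyz"))
    jsonlite::write_json(reportAsList(res$report),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeProvenance(cfg, outDir, list(verdict = verdict(res$report)))
  } else if (cfg@command == "sim sweep") {
    message("running sweep ", v$sweep)
    res <- switch(v$sweep,
      phase = fibrillarinPhaseDiagram(
        cGrid = if (length(v$grid)) v$grid else c(0.0013, 0.013),
        epsGrid = c(1.0, 1.3, 1.65, 2.0), seeds = v$seeds
      ),
      collapse = pchCollapseSweep(seq(0, 0.5, by = 0.05), seeds = v$seeds),
      engulf = rdnaEngulfmentSweep(seeds = v$seeds, scale = v$scale),
      wetting = wettingSweep(seeds = v$seeds, scale = v$scale),
      depletion = amphiphileDepletionSeries(seeds = v$seeds, scale = v$scale),
      stop("unknown sweep '", v$sweep, "'")
    )
    utils::write.csv(res@cells, file.path(outDir, "sweep_cells.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(axes = res@axes, thresholds = res@thresholds, meta = res@meta),
      file.path(outDir, "sweep.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE
    )
    writeProvenance(cfg, outDir)
  } else if (cfg@command == "img synth") {
    g <- generateNucleusVolume(v$organization, noise = v$noise,
                               seed = cfg@seed)
    writeVoxelImage(g$image, file.path(outDir, "synthetic.tif"))
    truthImg <- VoxelImage(lapply(g$truth, function(m) m * 1),
                           voxelSize = voxelSize(g$image))
    writeVoxelImage(truthImg, file.path(outDir, "truth.tif"))
    writeProvenance(cfg, outDir, list(generator = g$params))
  } else if (cfg@command == "img metrics") {
    infile <- flags[["in"]]
    if (is.null(infile)) stop("img metrics requires --in stack.tif")
    img <- readVoxelImage(infile)
    chans <- channelNames(img)
    segs <- lapply(chans, function(ch) {
      segmentChannel(img, ch, method = "otsu", gaussianSigma = 1)
    })
    names(segs) <- chans
    rows <- do.call(rbind, lapply(chans, function(ch) {
      tab <- objectTable(segs[[ch]])
      if (nrow(tab) == 0) return(NULL)
      cbind(channel = ch, tab, volume = objectVolume(segs[[ch]]))
    }))
    utils::write.csv(rows, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)
    if (length(chans) >= 2) {
      occ <- shellOccupancy(segs[[1]], segs[[2]], dilationPx = v$shellPx)
      jsonlite::write_json(
        list(shellOccupancy = occ, nucleolus = chans[1], target = chans[2],
             dilationPx = v$shellPx),
        file.path(outDir, "occupancy.json"), auto_unbox = TRUE, digits = NA
      )
    }
    writeProvenance(cfg, outDir)
  } else {
    stop("unknown command '", cfg@command, "'")
  }
  invisible(NULL)
}

reportAsList <- function(report) {
  list(
    verdict = report@verdict,
    condensed = as.list(report@condensed),
    dHF = report@dHF, dFX = report@dFX,
    rdInteriorFraction = report@rdInteriorFraction,
    xCoverage = report@xCoverage,
    xCoverageVerdict = report@xCoverageVerdict,
    radialMedians = as.list(report@radialMedians),
    flags = report@flags
  )
}
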