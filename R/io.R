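#' @include AllClasses.R AllGenerics.R engine.R imaging.R
NULL

fmtNum <- function(x) sprintf("%.17g", x)

#' Write configurations as extended XYZ
#'
#' One block per frame: bead count, a comment line carrying Rc, the frame
#' time and the column layout, then one \code{species x y z} row per bead.
#'
#' @param object a \linkS4class{SystemState} or \linkS4class{Trajectory}
#' @param path output file
#' @return invisibly, the path
#' @export
writeXYZ <- function(object, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeFrame <- function(pos, species, Rc, time) {
    writeLines(as.character(nrow(pos)), con)
    writeLines(sprintf(
      'Rc=%s time=%s Properties=species:S:1:pos:R:3', fmtNum(Rc), fmtNum(time)
    ), con)
    writeLines(paste(species, fmtNum(pos[, 1]), fmtNum(pos[, 2]),
                     fmtNum(pos[, 3])), con)
  }
  if (is(object, "SystemState")) {
    writeFrame(object@positions, object@species, object@Rc, object@time)
  } else if (is(object, "Trajectory")) {
    for (i in seq_along(object@frames)) {
      writeFrame(object@frames[[i]], object@species, object@Rc,
                 object@times[i])
    }
  } else {
    stop("object must be a SystemState or Trajectory")
  }
  invisible(path)
}

#' Read extended XYZ frames
#'
#' @param path file written by \code{\link{writeXYZ}}
#' @return a \linkS4class{Trajectory} (provenance notes the source file)
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric()
  species <- NULL
  Rc <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    header <- lines[i + 1L]
    getField <- function(key) {
      m <- regmatches(header, regexpr(paste0(key, "=[^ ]+"), header))
      if (!length(m)) return(NA_real_)
      as.numeric(sub(paste0(key, "="), "", m))
    }
    Rc <- getField("Rc")
    times <- c(times, getField("time"))
    rows <- strsplit(lines[(i + 2L):(i + 1L + n)], "[ \t]+")
    species <- vapply(rows, `[[`, character(1), 1L)
    pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- pos
    i <- i + 2L + n
  }
  new("Trajectory",
    frames = frames, times = times, species = species, Rc = Rc,
    frameInterval = 1L,
    kineticTemp = rep(NA_real_, length(frames)),
    potential = rep(NA_real_, length(frames)),
    provenance = list(source = path)
  )
}

#' Serialize a parameter set and interaction matrix as flat key/value text
#'
#' Flat \code{key = value} lines for the reduced-unit parameters followed by
#' a \code{[pairs]} section with one \code{A-B = epsilon mode} line per
#' unordered species pair. Values round-trip bit-exactly through
#' \code{\link{readParameterConfig}}.
#'
#' @param params a \linkS4class{SimulationParameters}
#' @param matrix an \linkS4class{InteractionMatrix}
#' @param path output file
#' @return invisibly, the path
#' @export
writeParameterConfig <- function(params, matrix, path) {
  pl <- paramsAsList(params)
  lines <- c(
    "# nucleopch parameter set (reduced units: lengths in sigma, energies in kBT)",
    paste(names(pl), "=", vapply(pl, fmtNum, character(1))),
    "",
    "[pairs]"
  )
  il <- interactionAsList(matrix)
  lines <- c(lines, vapply(names(il), function(nm) {
    paste(nm, "=", fmtNum(il[[nm]]$epsilon), il[[nm]]$mode)
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeParameterConfig
#' @return \code{readParameterConfig}: list with \code{params} and
#'   \code{matrix}
#' @export
readParameterConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sect <- which(lines == "[pairs]")
  if (!length(sect)) stop("missing [pairs] section")
  kv <- lines[seq_len(sect - 1L)]
  parts <- strsplit(kv, "\\s*=\\s*")
  vals <- stats::setNames(
    lapply(parts, function(p) as.numeric(p[2])),
    vapply(parts, `[[`, character(1), 1L)
  )
  params <- SimulationParameters(
    sigma = vals$sigma, kBT = vals$kBT, ks = vals$ks, rcAttr = vals$rcAttr,
    rcRep = vals$rcRep, Rc = vals$Rc, dt = vals$dt, gamma = vals$gamma,
    mass = vals$mass, kBend = vals$kBend, nSteps = vals$nSteps,
    seed = vals$seed
  )
  eps <- numeric()
  ev <- character()
  for (ln in lines[(sect + 1L):length(lines)]) {
    m <- strsplit(ln, "\\s*=\\s*|\\s+")[[1]]
    nm <- m[1]
    if (m[3] == "attractive") {
      eps[nm] <- as.numeric(m[2])
    } else {
      ev <- c(ev, nm)
    }
  }
  list(params = params, matrix = InteractionMatrix(eps, excludedVolume = ev))
}

#' Write and read multi-channel voxel images as TIFF
#'
#' Pages are channel-interleaved across z planes (channel fastest), stored as
#' 32-bit float after division by a global scale. A JSON sidecar
#' (\code{<path>.json}) records channel names, dimensions, voxel size and
#' the intensity scale; \code{readVoxelImage} uses it when present.
#'
#' @param image a \linkS4class{VoxelImage}
#' @param path output TIFF path
#' @return invisibly, the path
#' @export
writeVoxelImage <- function(image, path) {
  chs <- image@channels
  d <- dim(chs[[1]])
  if (length(d) == 2) d <- c(d, 1L)
  scale <- max(1, max(vapply(chs, max, numeric(1))))
  pages <- list()
  for (z in seq_len(d[3])) {
    for (ch in chs) {
      page <- if (length(dim(ch)) == 3) ch[, , z] else ch
      pages[[length(pages) + 1L]] <- page / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(channels = names(chs), dim = d, voxelSize = image@voxelSize,
         scale = scale),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeVoxelImage
#' @param channels named integer vector mapping channel names to 0-based
#'   page-interleave indices; unnecessary when the JSON sidecar exists
#' @param voxelSize voxel size override (micrometres)
#' @return \code{readVoxelImage}: a \linkS4class{VoxelImage}
#' @export
readVoxelImage <- function(path, channels = NULL, voxelSize = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(channels)) {
    if (is.null(meta)) stop("channel layout unknown: supply `channels`")
    channels <- stats::setNames(seq_along(meta$channels) - 1L, meta$channels)
  }
  nCh <- length(channels)
  nz <- length(pages) / nCh
  if (nz != round(nz)) stop("page count is not a multiple of channel count")
  d2 <- dim(pages[[1]])
  scale <- if (!is.null(meta)) meta$scale else 1
  chs <- lapply(channels, function(ci) {
    arr <- array(0, c(d2, nz))
    for (z in seq_len(nz)) {
      arr[, , z] <- pages[[(z - 1L) * nCh + ci + 1L]] * scale
    }
    arr
  })
  vs <- voxelSize %||% (if (!is.null(meta)) meta$voxelSize else c(0.1, 0.1, 0.1))
  VoxelImage(chs, voxelSize = vs)
}
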