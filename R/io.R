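# Plain-text file formats: tab-separated g-vector files (full double
# precision, 17 significant digits, bit-identical round trips), JSON grain
# records, and flat key = value run configurations.

.fmt17 <- function(x) sprintf("%.17g", x)

#' Write a g-vector file
#'
#' Tab-separated text with a header line: columns `gx`, `gy`, `gz`
#' (1/Angstrom) and, when the pool carries truth labels, `grain_id`,
#' `phase_id`, `h`, `k`, `l`. Numeric values are written with 17 significant
#' digits so that write / read round trips are bit-identical.
#'
#' @param pool A [GVectorPool-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGVectors <- function(pool, path) {
  G <- pool@gvec
  lab <- pool@labels
  cols <- c("gx", "gy", "gz")
  body <- cbind(.fmt17(G[, 1]), .fmt17(G[, 2]), .fmt17(G[, 3]))
  if (!is.null(lab)) {
    cols <- c(cols, "grain_id", "phase_id", "h", "k", "l")
    body <- cbind(body, as.character(lab$grain), lab$phase,
                  as.character(lab$h), as.character(lab$k),
                  as.character(lab$l))
  }
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(G)) apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a g-vector file
#'
#' Parses the tab-separated format of [writeGVectors()]. Columns `gx`, `gy`,
#' `gz` are required; truth-label columns are restored when present.
#' Malformed rows raise an error naming the offending line.
#'
#' @param path Input file path.
#' @return A [GVectorPool-class] (all reflections active).
#' @export
readGVectors <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty g-vector file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!all(c("gx", "gy", "gz") %in% header))
    stop("g-vector file must have columns gx, gy, gz")
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != length(header)))
    stop(sprintf("malformed row at line %d: expected %d columns, got %d",
                 which(nc != length(header))[1] + 1L, length(header),
                 nc[nc != length(header)][1]))
  M <- do.call(rbind, parts)
  getNum <- function(col) {
    x <- suppressWarnings(as.numeric(M[, match(col, header)]))
    if (anyNA(x))
      stop(sprintf("non-numeric value in column %s at line %d", col,
                   which(is.na(x))[1] + 1L))
    x
  }
  if (!length(body)) {
    return(GVectorPool(matrix(numeric(0), 0, 3)))
  }
  G <- cbind(getNum("gx"), getNum("gy"), getNum("gz"))
  labels <- NULL
  if (all(c("grain_id", "phase_id", "h", "k", "l") %in% header)) {
    labels <- data.frame(grain = as.integer(getNum("grain_id")),
                         phase = M[, match("phase_id", header)],
                         h = as.integer(getNum("h")),
                         k = as.integer(getNum("k")),
                         l = as.integer(getNum("l")))
  }
  GVectorPool(G, labels = labels)
}

#' Write grain records
#'
#' JSON file with one record per grain: serial, the 3 x 3 direct basis
#' (row-major, Angstrom), the derived cell parameters and volume, the
#' matched count, and the assignment table. Full numeric precision.
#'
#' @param grains List of [IndexedGrain-class] or an
#'   [IndexingResult-class].
#' @param path Output file path.
#' @param stopReason Optional run stop reason stored in the file.
#' @return `path`, invisibly.
#' @export
writeGrainRecords <- function(grains, path, stopReason = NULL) {
  if (methods::is(grains, "IndexingResult")) {
    if (is.null(stopReason)) stopReason <- grains@stopReason
    grains <- grains@grains
  }
  recs <- lapply(grains, function(g) {
    cl <- g@cell
    list(serial = g@serial,
         basis = as.numeric(t(g@basis)),
         cell = list(a = cl@a, b = cl@b, c = cl@c, alpha = cl@alpha,
                     beta = cl@beta, gamma = cl@gamma),
         volume = cellVolume(cl),
         matched_count = g@matchedCount,
         assignments = g@assignments)
  })
  jsonlite::write_json(list(stop_reason = stopReason, grains = recs), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read grain records
#'
#' @param path A file written by [writeGrainRecords()].
#' @return List of [IndexedGrain-class].
#' @export
readGrainRecords <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  recs <- obj$grains
  if (is.null(recs) || (is.data.frame(recs) && !nrow(recs)) ||
      (!is.data.frame(recs) && !length(recs))) return(list())
  n <- if (is.data.frame(recs)) nrow(recs) else length(recs)
  lapply(seq_len(n), function(i) {
    r <- if (is.data.frame(recs)) lapply(recs, function(col)
           if (is.data.frame(col)) col[i, ] else col[[i]])
         else recs[[i]]
    basis <- matrix(as.numeric(r$basis), 3, 3, byrow = TRUE)
    a <- as.data.frame(r$assignments)
    a$index <- as.integer(a$index)
    methods::new("IndexedGrain", serial = as.integer(r$serial),
                 basis = basis,
                 cell = UnitCell(r$cell$a, r$cell$b, r$cell$c, r$cell$alpha,
                                 r$cell$beta, r$cell$gamma),
                 assignments = a,
                 matchedCount = as.integer(r$matched_count))
  })
}

#' Read a flat run configuration
#'
#' Parses `key = value` lines (`#` starts a comment; values may be
#' comma-separated lists). Recognized keys mirror the simulation-study
#' parameter symbols: `phases`, `grains`, `sigma`, `q_min`, `q_max`,
#' `epsilon`, `d_star_min`, `d_star_max`, `n_u1`, `n_u2`, `n_j`,
#' `epsilon2_factor`, `top_k`, `min_angle_deg`, `min_reflections`, `n_t`,
#' `seed`. Unspecified keys fall back to the cementite-study defaults of
#' the constructors.
#'
#' @param path Configuration file path.
#' @return Named list of character vectors.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    out[[trimws(kv[1])]] <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
  }
  out
}

.cfgNum <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}

# SimulationConfig from a parsed run configuration
.configSimulation <- function(cfg, seed = NULL) {
  if (is.null(cfg$phases)) stop("config must name phases")
  phases <- builtinPhases(cfg$phases)
  grains <- as.integer(.cfgNum(cfg, "grains", 1))
  if (length(grains) == 1L) grains <- rep(grains, length(phases))
  qMax <- .cfgNum(cfg, "q_max", 0.6)
  dmin <- .cfgNum(cfg, "d_star_min", 0.1)
  SimulationConfig(unname(phases), grains,
                   qMin = .cfgNum(cfg, "q_min", dmin), qMax = qMax,
                   sigma = .cfgNum(cfg, "sigma", 1e-4),
                   seed = if (is.null(seed)) as.integer(.cfgNum(cfg, "seed", 1))
                          else as.integer(seed))
}

# IndexingConfig from a parsed run configuration
.configIndexing <- function(cfg, seed = NULL) {
  qMax <- .cfgNum(cfg, "q_max", 0.6)
  dmin <- .cfgNum(cfg, "d_star_min", 0.1)
  comb <- CombParams(epsilon = .cfgNum(cfg, "epsilon", 5e-4), qMax = qMax,
                     dstarMin = dmin, qMin = .cfgNum(cfg, "q_min", dmin),
                     dstarMax = .cfgNum(cfg, "d_star_max", qMax / 2))
  search <- SearchConfig(nU1 = .cfgNum(cfg, "n_u1", 10000),
                         nU2 = .cfgNum(cfg, "n_u2", 5000),
                         nJ = .cfgNum(cfg, "n_j", 5),
                         epsilon2Factor = .cfgNum(cfg, "epsilon2_factor", 2),
                         topK = .cfgNum(cfg, "top_k", 10),
                         minAngleDeg = .cfgNum(cfg, "min_angle_deg", 10))
  IndexingConfig(comb = comb, search = search,
                 minReflections = .cfgNum(cfg, "min_reflections", 20),
                 nT = .cfgNum(cfg, "n_t", 20),
                 seed = if (is.null(seed)) as.integer(.cfgNum(cfg, "seed", 1))
                        else as.integer(seed))
}
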