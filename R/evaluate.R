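# Ground-truth evaluation: correspondence between indexed and true grains,
# per-grain success criterion, and the four summary figures of merit.

#' Match indexed grains to true grains
#'
#' Builds all (indexed grain, true grain, shared reflections) overlaps and
#' resolves them greedily by descending shared count, so each indexed grain
#' maps to the true grain contributing the plurality of its reflections and
#' at most one indexed grain maps to each true grain.
#'
#' @param grains List of [IndexedGrain-class] (or an
#'   [IndexingResult-class]).
#' @param pool A labeled [GVectorPool-class].
#' @return Data frame with columns `indexed`, `trueGrain`, `shared`.
#' @export
matchGrains <- function(grains, pool) {
  if (methods::is(grains, "IndexingResult")) grains <- grains@grains
  labels <- truthLabels(pool)
  if (is.null(labels)) stop("pool has no ground-truth labels")
  rows <- list()
  for (i in seq_along(grains)) {
    tg <- labels$grain[grains[[i]]@assignments$index]
    tab <- table(tg)
    rows[[i]] <- data.frame(indexed = i,
                            trueGrain = as.integer(names(tab)),
                            shared = as.integer(tab))
  }
  empty <- data.frame(indexed = integer(0), trueGrain = integer(0),
                      shared = integer(0))
  if (!length(rows)) return(empty)
  df <- do.call(rbind, rows)
  df <- df[order(-df$shared, df$indexed, df$trueGrain), , drop = FALSE]
  usedI <- logical(max(df$indexed))
  usedT <- integer(0)
  keep <- logical(nrow(df))
  for (r in seq_len(nrow(df))) {
    if (!usedI[df$indexed[r]] && !(df$trueGrain[r] %in% usedT)) {
      keep[r] <- TRUE
      usedI[df$indexed[r]] <- TRUE
      usedT <- c(usedT, df$trueGrain[r])
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-grain success criterion
#'
#' A grain counts as successfully identified iff the recovered unit-cell
#' volume is within 1% of the nominal value AND the fraction of the true
#' grain's reflections correctly assigned exceeds 0.9 (strict).
#'
#' @param grain An [IndexedGrain-class].
#' @param pool A labeled [GVectorPool-class].
#' @param trueGrain True grain id matched to this indexed grain.
#' @param nominalVolume Nominal cell volume of the true grain's phase.
#' @return Logical.
#' @export
grainSuccess <- function(grain, pool, trueGrain, nominalVolume) {
  labels <- truthLabels(pool)
  if (is.null(labels)) stop("pool has no ground-truth labels")
  vf <- cellVolume(grain@cell)
  nTrue <- sum(labels$grain == trueGrain)
  nCorrect <- sum(labels$grain[grain@assignments$index] == trueGrain)
  abs(vf - nominalVolume) / nominalVolume <= 0.01 && nCorrect / nTrue > 0.9
}

#' Figures of merit against ground truth
#'
#' Computes, per indexed grain, the recovered volume, the completeness
#' (correctly assigned reflections over the matched true grain's total) and
#' the false-attribution fraction (wrongly assigned over assigned), then the
#' four summary rows: fraction of true grains successfully identified, mean
#' relative absolute volume deviation over successes, mean completeness and
#' mean false fraction over indexed grains. Indexed grains left unmatched by
#' [matchGrains()] (spurious) enter the last two means with completeness 0
#' and false fraction 1; the `alt*` slots give the same means over
#' successfully identified grains only.
#'
#' @param grains List of [IndexedGrain-class] or an
#'   [IndexingResult-class].
#' @param pool A labeled [GVectorPool-class].
#' @param phases The [PhaseSpec-class] list used in the simulation (source
#'   of nominal volumes).
#' @return A [MeritReport-class].
#' @export
figuresOfMerit <- function(grains, pool, phases) {
  if (methods::is(grains, "IndexingResult")) grains <- grains@grains
  labels <- truthLabels(pool)
  if (is.null(labels)) stop("pool has no ground-truth labels")
  trueGrains <- unique(labels$grain)
  if (!length(trueGrains)) stop("zero true grains")
  if (methods::is(phases, "PhaseSpec")) phases <- list(phases)
  vol <- vapply(phases, function(p) cellVolume(p@cell), 0)
  names(vol) <- vapply(phases, function(p) p@name, "")
  mm <- matchGrains(grains, pool)
  per <- lapply(seq_along(grains), function(i) {
    g <- grains[[i]]
    nA <- nrow(g@assignments)
    tg <- mm$trueGrain[mm$indexed == i]
    vf <- cellVolume(g@cell)
    if (length(tg)) {
      phase <- labels$phase[match(tg, labels$grain)]
      vn <- vol[[phase]]
      nTrue <- sum(labels$grain == tg)
      nCorrect <- sum(labels$grain[g@assignments$index] == tg)
      data.frame(indexed = i, trueGrain = tg, phase = phase,
                 volume = vf, nominalVolume = vn,
                 relVolDev = abs(vf - vn) / vn,
                 nAssigned = nA, nTrue = nTrue, nCorrect = nCorrect,
                 correctFraction = nCorrect / nTrue,
                 falseFraction = if (nA) (nA - nCorrect) / nA else 0,
                 success = abs(vf - vn) / vn <= 0.01 &&
                   nCorrect / nTrue > 0.9)
    } else {
      data.frame(indexed = i, trueGrain = NA_integer_,
                 phase = NA_character_, volume = vf,
                 nominalVolume = NA_real_, relVolDev = NA_real_,
                 nAssigned = nA, nTrue = NA_integer_, nCorrect = 0L,
                 correctFraction = 0, falseFraction = 1, success = FALSE)
    }
  })
  per <- if (length(per)) do.call(rbind, per)
         else data.frame(indexed = integer(0), trueGrain = integer(0),
                         phase = character(0), volume = numeric(0),
                         nominalVolume = numeric(0), relVolDev = numeric(0),
                         nAssigned = integer(0), nTrue = integer(0),
                         nCorrect = integer(0), correctFraction = numeric(0),
                         falseFraction = numeric(0), success = logical(0))
  succ <- per$success
  methods::new("MeritReport",
    fractionIdentified = sum(succ) / length(trueGrains),
    meanRelVolumeDeviation = if (any(succ)) mean(per$relVolDev[succ])
                             else NA_real_,
    meanCorrectFraction = if (nrow(per)) mean(per$correctFraction)
                          else NA_real_,
    meanFalseFraction = if (nrow(per)) mean(per$falseFraction) else NA_real_,
    altCorrectFraction = if (any(succ)) mean(per$correctFraction[succ])
                         else NA_real_,
    altFalseFraction = if (any(succ)) mean(per$falseFraction[succ])
                       else NA_real_,
    perGrain = per)
}

# plain-list form of a MeritReport, for JSON output
.reportAsList <- function(report) {
  list(fraction_identified = report@fractionIdentified,
       mean_rel_volume_deviation = report@meanRelVolumeDeviation,
       mean_correct_fraction = report@meanCorrectFraction,
       mean_false_fraction = report@meanFalseFraction,
       alt_correct_fraction = report@altCorrectFraction,
       alt_false_fraction = report@altFalseFraction,
       per_grain = report@perGrain)
}
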