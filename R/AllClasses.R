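setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))
setClassUnion("functionOrNULL", c("function", "NULL"))

#' Unit cell
#'
#' Six-parameter description of a crystal unit cell: edge lengths `a`, `b`,
#' `c` in Angstrom and angles `alpha`, `beta`, `gamma` in degrees. Validity
#' requires positive lengths, angles in (0, 180) degrees, and an angle triplet
#' admitting a positive metric determinant (so the cell volume is real).
#'
#' @slot a,b,c Edge lengths (Angstrom).
#' @slot alpha,beta,gamma Inter-axial angles (degrees).
#'
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"),
  validity = function(object) {
    p <- c(object@a, object@b, object@c,
           object@alpha, object@beta, object@gamma)
    if (length(p) != 6L || any(!is.finite(p)))
      return("all six cell parameters must be finite scalars")
    if (any(p[1:3] <= 0)) return("cell lengths must be positive")
    if (any(p[4:6] <= 0 | p[4:6] >= 180))
      return("cell angles must lie in (0, 180) degrees")
    if (.volumeArg(object@alpha, object@beta, object@gamma) <= 0)
      return("angle triplet gives a non-positive metric determinant")
    TRUE
  })

#' @param a,b,c Edge lengths (Angstrom).
#' @param alpha,beta,gamma Inter-axial angles (degrees).
#' @rdname UnitCell-class
#' @export
UnitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  methods::new("UnitCell", a = as.numeric(a), b = as.numeric(b),
               c = as.numeric(c), alpha = as.numeric(alpha),
               beta = as.numeric(beta), gamma = as.numeric(gamma))
}

#' Phase specification for the simulator
#'
#' A named crystalline phase: its unit cell and an optional reflection
#' condition encoding systematic absences. The condition, when present, is a
#' predicate receiving an integer matrix of Miller indices (columns h, k, l)
#' and returning a logical vector; by default no condition is applied
#' (primitive lattice, every nonzero integer triplet diffracts), since the
#' indexing procedure is intensity- and symmetry-agnostic.
#'
#' @slot name Phase label.
#' @slot cell A [UnitCell-class].
#' @slot condition `NULL` or a predicate on an n x 3 integer hkl matrix.
#'
#' @export
setClass("PhaseSpec",
  representation(name = "character", cell = "UnitCell",
                 condition = "functionOrNULL"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("phase name must be a nonempty string")
    TRUE
  })

#' @param name Phase label.
#' @param cell A [UnitCell-class].
#' @param condition Optional reflection-condition predicate.
#' @rdname PhaseSpec-class
#' @export
PhaseSpec <- function(name, cell, condition = NULL) {
  methods::new("PhaseSpec", name = name, cell = cell, condition = condition)
}

#' Pool of scattering vectors
#'
#' The central data container: an n x 3 matrix of g-vectors (reciprocal
#' Angstrom, Cartesian sample frame), a logical mask of reflections still
#' active (not yet claimed by an indexed grain), and, for simulated data,
#' ground-truth labels (`grain`, `phase`, `h`, `k`, `l` per row).
#'
#' @slot gvec n x 3 numeric matrix of g-vectors.
#' @slot active Logical vector of length n.
#' @slot labels `NULL` or a data frame with one row per g-vector.
#'
#' @export
setClass("GVectorPool",
  representation(gvec = "matrix", active = "logical",
                 labels = "data.frameOrNULL"),
  validity = function(object) {
    if (!is.numeric(object@gvec) || ncol(object@gvec) != 3L)
      return("gvec must be a numeric matrix with 3 columns")
    if (length(object@active) != nrow(object@gvec))
      return("active mask length must equal the number of g-vectors")
    if (!is.null(object@labels) && nrow(object@labels) != nrow(object@gvec))
      return("labels must have one row per g-vector")
    TRUE
  })

#' @param gvec n x 3 numeric matrix of g-vectors.
#' @param active Logical mask (default all active).
#' @param labels Optional truth-label data frame.
#' @rdname GVectorPool-class
#' @export
GVectorPool <- function(gvec, active = rep(TRUE, nrow(gvec)), labels = NULL) {
  gvec <- as.matrix(gvec)
  storage.mode(gvec) <- "double"
  dimnames(gvec) <- NULL
  methods::new("GVectorPool", gvec = gvec, active = active, labels = labels)
}

#' Simulation configuration
#'
#' Defines a multiphase polycrystal scene for the forward simulator: the
#' phases, the number of grains of each, the q-range of observable
#' reflections, the per-component Gaussian noise level and the seed.
#'
#' @slot phases List of [PhaseSpec-class] objects.
#' @slot grainsPerPhase Integer vector, one count per phase.
#' @slot qMin,qMax Observable g-vector length range (1/Angstrom).
#' @slot sigma Standard deviation of the noise added to each Cartesian
#'   component of every g-vector (1/Angstrom).
#' @slot seed Integer RNG seed.
#'
#' @export
setClass("SimulationConfig",
  representation(phases = "list", grainsPerPhase = "integer",
                 qMin = "numeric", qMax = "numeric", sigma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (!all(vapply(object@phases, methods::is, TRUE, "PhaseSpec")))
      return("phases must be a list of PhaseSpec objects")
    if (length(object@grainsPerPhase) != length(object@phases))
      return("grainsPerPhase must match the number of phases")
    if (any(object@grainsPerPhase < 0L)) return("grain counts must be >= 0")
    if (object@qMin < 0 || object@qMax <= object@qMin)
      return("need 0 <= qMin < qMax")
    if (object@sigma < 0) return("sigma must be >= 0")
    TRUE
  })

#' @param phases List of [PhaseSpec-class] objects.
#' @param grainsPerPhase Integer vector of grain counts, one per phase.
#' @param qMin,qMax Observable q-range (1/Angstrom).
#' @param sigma Per-component noise standard deviation (1/Angstrom).
#' @param seed Integer RNG seed.
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(phases, grainsPerPhase, qMin, qMax,
                             sigma = 1e-4, seed = 1L) {
  if (methods::is(phases, "PhaseSpec")) phases <- list(phases)
  methods::new("SimulationConfig", phases = phases,
               grainsPerPhase = as.integer(grainsPerPhase),
               qMin = as.numeric(qMin), qMax = as.numeric(qMax),
               sigma = as.numeric(sigma), seed = as.integer(seed))
}

#' Comb-filter parameters
#'
#' Parameters of the one-dimensional lattice detector: the box half-width
#' `epsilon` (chosen slightly larger than the positional error of the
#' g-vectors), the q-range of the data, and the spacing scan range
#' `[dstarMin, dstarMax]`. By default `dstarMax = qMax / 2`, the largest
#' spacing for which at least two comb nodes fit inside the data range.
#' Defaults reproduce the cementite simulation-study parameterization.
#'
#' @slot epsilon Comb box half-width (1/Angstrom).
#' @slot qMin,qMax Length range of the g-vectors (1/Angstrom).
#' @slot dstarMin,dstarMax Scanned spacing range (1/Angstrom).
#'
#' @export
setClass("CombParams",
  representation(epsilon = "numeric", qMin = "numeric", qMax = "numeric",
                 dstarMin = "numeric", dstarMax = "numeric"),
  validity = function(object) {
    if (object@epsilon <= 0) return("epsilon must be positive")
    if (2 * object@epsilon >= object@dstarMin)
      return("need 2 * epsilon < dstarMin")
    if (object@qMin < 0 || object@qMax <= object@qMin)
      return("need 0 <= qMin < qMax")
    if (object@dstarMax <= object@dstarMin)
      return("need dstarMin < dstarMax")
    TRUE
  })

#' @param epsilon Box half-width (1/Angstrom).
#' @param qMax,qMin Data q-range (1/Angstrom); `qMin` defaults to `dstarMin`.
#' @param dstarMin Smallest scanned spacing (1/Angstrom).
#' @param dstarMax Largest scanned spacing; defaults to `qMax / 2`.
#' @rdname CombParams-class
#' @export
CombParams <- function(epsilon = 5e-4, qMax = 0.6, dstarMin = 0.1,
                       qMin = dstarMin, dstarMax = qMax / 2) {
  methods::new("CombParams", epsilon = as.numeric(epsilon),
               qMin = as.numeric(qMin), qMax = as.numeric(qMax),
               dstarMin = as.numeric(dstarMin), dstarMax = as.numeric(dstarMax))
}

#' Candidate one-dimensional lattice
#'
#' Result of a comb scan along one direction: the direction, the best node
#' spacing, the raw member count, the background-subtracted score, and the
#' indices of the member reflections.
#'
#' @slot direction Unit 3-vector (possibly length 0 when the scan was run on
#'   bare projections).
#' @slot dstar Node spacing (1/Angstrom).
#' @slot rawCount Number of member reflections.
#' @slot score Count minus the random-placement expectation.
#' @slot members Integer indices of member reflections.
#'
#' @export
setClass("LatticeCandidate",
  representation(direction = "numeric", dstar = "numeric",
                 rawCount = "numeric", score = "numeric",
                 members = "integer"))

#' Direction-search configuration
#'
#' Parameters of the two-pass random-direction candidate search. Defaults
#' reproduce the cementite simulation-study parameterization.
#'
#' @slot nU1 Directions sampled in the first pass over the full pool.
#' @slot nU2 Directions sampled in the second (cleaning) pass per subset.
#' @slot nJ Number of candidate subsets kept.
#' @slot epsilon2Factor Multiplier on the box half-width in the second pass.
#' @slot topK Candidates refined by the local grid search per pass.
#' @slot minAngleDeg Exclusion cone (degrees) around the first-pass direction.
#'
#' @export
setClass("SearchConfig",
  representation(nU1 = "integer", nU2 = "integer", nJ = "integer",
                 epsilon2Factor = "numeric", topK = "integer",
                 minAngleDeg = "numeric"),
  validity = function(object) {
    if (object@nU1 < 1L || object@nU2 < 1L) return("nU1, nU2 must be >= 1")
    if (object@nJ < 1L) return("nJ must be >= 1")
    if (object@epsilon2Factor < 1) return("epsilon2Factor must be >= 1")
    if (object@topK < object@nJ) return("topK must be >= nJ")
    TRUE
  })

#' @param nU1,nU2 First- and second-pass direction counts.
#' @param nJ Candidate subsets kept.
#' @param epsilon2Factor Second-pass box half-width multiplier.
#' @param topK Candidates refined per pass.
#' @param minAngleDeg Second-pass exclusion cone (degrees).
#' @rdname SearchConfig-class
#' @export
SearchConfig <- function(nU1 = 10000L, nU2 = 5000L, nJ = 5L,
                         epsilon2Factor = 2, topK = 10L, minAngleDeg = 10) {
  methods::new("SearchConfig", nU1 = as.integer(nU1), nU2 = as.integer(nU2),
               nJ = as.integer(nJ), epsilon2Factor = as.numeric(epsilon2Factor),
               topK = as.integer(topK), minAngleDeg = as.numeric(minAngleDeg))
}

#' Candidate grain (cleaned reflection subset)
#'
#' A subset of pool reflections believed to originate predominantly from one
#' grain, together with the two (direction, spacing) pairs that selected it.
#'
#' @slot members Pool indices of the member reflections.
#' @slot provenance List with elements `first` and `second`, each a list with
#'   `direction` and `dstar`.
#'
#' @export
setClass("CandidateGrain",
  representation(members = "integer", provenance = "list"),
  validity = function(object) {
    if (length(object@members) == 0L) return("members must be non-empty")
    TRUE
  })

#' Grain hypothesis
#'
#' A direct-lattice basis with its one-to-one assignment of reciprocal
#' lattice points to pool reflections.
#'
#' @slot basis 3 x 3 direct basis, rows = lattice vectors (Angstrom).
#' @slot assignments Data frame with columns `h`, `k`, `l`, `index` (pool row)
#'   and `distance` (1/Angstrom).
#' @slot matchedCount Number of assignments.
#'
#' @export
setClass("GrainHypothesis",
  representation(basis = "matrix", assignments = "data.frame",
                 matchedCount = "integer"),
  validity = function(object) {
    if (anyDuplicated(object@assignments$index))
      return("assignments must be one-to-one in reflection index")
    TRUE
  })

#' Indexing configuration
#'
#' Full parameterization of the iterative indexing loop: comb parameters,
#' search configuration, the minimum reflection count for accepting a grain,
#' the consecutive-failure stopping limit, the sublattice indices tried by
#' the supercell check, and the seed. Defaults reproduce the cementite
#' simulation-study parameterization.
#'
#' @slot comb A [CombParams-class].
#' @slot search A [SearchConfig-class].
#' @slot minReflections Minimum matched reflections for a grain.
#' @slot nT Consecutive failed tries before stopping.
#' @slot supercellDets Allowed sublattice indices (subset of 2:3).
#' @slot seed Integer RNG seed.
#'
#' @export
setClass("IndexingConfig",
  representation(comb = "CombParams", search = "SearchConfig",
                 minReflections = "integer", nT = "integer",
                 supercellDets = "integer", seed = "integer"),
  validity = function(object) {
    if (object@nT < 1L) return("nT must be >= 1")
    if (!all(object@supercellDets %in% 2:3))
      return("supercellDets must be a subset of {2, 3}")
    if (object@minReflections < 4L) return("minReflections must be >= 4")
    TRUE
  })

#' @param comb A [CombParams-class].
#' @param search A [SearchConfig-class].
#' @param minReflections Minimum matched reflections for a grain.
#' @param nT Consecutive-failure stopping limit.
#' @param supercellDets Sublattice indices tried during the supercell check.
#' @param seed Integer RNG seed.
#' @rdname IndexingConfig-class
#' @export
IndexingConfig <- function(comb = CombParams(), search = SearchConfig(),
                           minReflections = 20L, nT = 20L,
                           supercellDets = c(2L, 3L), seed = 1L) {
  methods::new("IndexingConfig", comb = comb, search = search,
               minReflections = as.integer(minReflections),
               nT = as.integer(nT),
               supercellDets = as.integer(supercellDets),
               seed = as.integer(seed))
}

#' Indexed grain
#'
#' A grain recovered by the pipeline: refined direct basis, derived unit
#' cell, and its hkl-to-reflection assignments.
#'
#' @slot serial Discovery-order serial number.
#' @slot basis 3 x 3 direct basis (Angstrom).
#' @slot cell Derived [UnitCell-class].
#' @slot assignments Data frame `h`, `k`, `l`, `index`, `distance`.
#' @slot matchedCount Number of assigned reflections.
#'
#' @export
setClass("IndexedGrain",
  representation(serial = "integer", basis = "matrix", cell = "UnitCell",
                 assignments = "data.frame", matchedCount = "integer"),
  validity = function(object) {
    if (anyDuplicated(object@assignments$index))
      return("assignments must be one-to-one in reflection index")
    TRUE
  })

#' Result of an indexing run
#'
#' The grains found, the final pool (with claimed reflections inactive), the
#' stop reason, and a per-iteration log.
#'
#' @slot grains List of [IndexedGrain-class] in discovery order.
#' @slot pool Final [GVectorPool-class].
#' @slot stopReason Character: why the loop terminated.
#' @slot log Data frame, one row per iteration.
#'
#' @export
setClass("IndexingResult",
  representation(grains = "list", pool = "GVectorPool",
                 stopReason = "character", log = "data.frame"))

#' Figures of merit against ground truth
#'
#' The four summary rows of the evaluation: fraction of true grains
#' successfully identified, mean relative volume deviation over successes,
#' mean per-grain correct-reflection fraction (completeness) and mean
#' per-grain false-attribution fraction, plus a per-grain breakdown. The
#' `alt*` slots restrict the last two means to successfully identified grains.
#'
#' @slot fractionIdentified Successes / true grain count.
#' @slot meanRelVolumeDeviation Mean |dV|/V over successes.
#' @slot meanCorrectFraction Mean completeness over indexed grains.
#' @slot meanFalseFraction Mean false-attribution fraction over indexed grains.
#' @slot altCorrectFraction,altFalseFraction Same means over successes only.
#' @slot perGrain Per-indexed-grain breakdown table.
#'
#' @export
setClass("MeritReport",
  representation(fractionIdentified = "numeric",
                 meanRelVolumeDeviation = "numeric",
                 meanCorrectFraction = "numeric",
                 meanFalseFraction = "numeric",
                 altCorrectFraction = "numeric",
                 altFalseFraction = "numeric",
                 perGrain = "data.frame"))
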