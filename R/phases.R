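#' Built-in phase catalogue
#'
#' Unit cells of the five materials used in the simulation studies: cementite
#' (orthorhombic) and the four granite minerals quartz (trigonal), biotite
#' (monoclinic), orthoclase (monoclinic) and plagioclase (triclinic). All are
#' returned without a reflection condition (primitive enumeration): the
#' indexing procedure uses neither intensities nor symmetry, so systematic
#' absences only change how many reflections a grain contributes. Centering
#' predicates for robustness experiments can be attached via
#' [reflectionConditionCCentered()].
#'
#' @param names Which phases to return (default all five).
#' @return Named list of [PhaseSpec-class] objects.
#' @examples
#' builtinPhases("cementite")
#' @export
builtinPhases <- function(names = c("cementite", "quartz", "biotite",
                                    "orthoclase", "plagioclase")) {
  cat <- list(
    cementite   = UnitCell(4.51, 5.05, 6.73, 90, 90, 90),
    quartz      = UnitCell(4.92, 4.92, 5.40, 90, 90, 120),
    biotite     = UnitCell(5.33, 9.23, 10.17, 90, 100.16, 90),
    orthoclase  = UnitCell(8.56, 13.00, 7.19, 90, 116.02, 90),
    plagioclase = UnitCell(8.19, 12.88, 14.12, 93.30, 115.79, 91.12))
  names <- match.arg(names, several.ok = TRUE)
  out <- lapply(names, function(nm) PhaseSpec(nm, cat[[nm]]))
  stats::setNames(out, names)
}

#' C-centering reflection condition
#'
#' Predicate keeping only Miller triplets with `h + k` even, the systematic
#' absence of a C-centered lattice. Provided for robustness testing of the
#' simulator; the built-in phases ship without conditions.
#'
#' @param hkl Integer n x 3 matrix of Miller indices.
#' @return Logical vector.
#' @export
reflectionConditionCCentered <- function(hkl) (hkl[, 1] + hkl[, 2]) %% 2L == 0L
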