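#' @import methods
NULL

## Subcomplex vocabulary used throughout: the two lobes of each of the two
## IFT complexes, plus a catch-all for chains outside the train polymer.
.subcomplexLevels <- c("IFTA1", "IFTA2", "IFTB1", "IFTB2", "other")

#' AssemblyModel: an atomic assembly with per-residue confidence
#'
#' Holds the atoms of a (possibly multi-copy) assembly model in a flat table.
#' Coordinates are in Angstrom; residue numbering is author numbering, which
#' is what residue-level cross-link identifications use. The B-factor column
#' of the source file is carried as per-residue confidence (0-100), the
#' convention used by structure-prediction models that store pLDDT there.
#'
#' @slot atoms data.frame with columns `chain`, `resno` (author numbering),
#'   `resid` (residue name), `elety` (atom name), `element`, `x`, `y`, `z`
#'   (Angstrom) and `b` (confidence, 0-100 or NA).
#' @slot provenance list recording at least `source` and `model`.
#' @export
setClass("AssemblyModel",
  representation(atoms = "data.frame", provenance = "list"),
  prototype(atoms = data.frame(), provenance = list(source = NA_character_,
                                                    model = 1L)))

setValidity("AssemblyModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z", "b")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return(TRUE)
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("coordinates must be finite")
  bb <- a$b[!is.na(a$b)]
  if (length(bb) && (any(bb < 0) || any(bb > 100)))
    return("confidence (b) must lie in [0, 100]")
  ## a residue number may not name two different residues within a chain
  key <- paste(a$chain, a$resno)
  if (anyDuplicated(unique(data.frame(key = key, resid = a$resid))$key))
    return("author residue numbers must be unique within a chain")
  TRUE
})

#' ChainMap: chain identity within a polymeric assembly
#'
#' Maps every chain of an [AssemblyModel] to a protein name, a copy index and
#' a subcomplex label. An optional `unit` column assigns chains to repeating
#' units of the polymer (used by [contactGraph()] and [trainMetrics()]).
#'
#' @slot map data.frame with columns `chain`, `protein`, `copy`, `subcomplex`
#'   and optionally `unit`.
#' @export
setClass("ChainMap", representation(map = "data.frame"))

setValidity("ChainMap", function(object) {
  m <- object@map
  need <- c("chain", "protein", "copy", "subcomplex")
  if (!all(need %in% names(m)))
    return(paste("map must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$chain)) return("every chain may appear only once")
  if (anyDuplicated(paste(m$protein, m$copy)))
    return("(protein, copy) pairs must be unique")
  if (!all(m$subcomplex %in% .subcomplexLevels))
    return(paste("subcomplex labels must be one of:",
                 paste(.subcomplexLevels, collapse = ", ")))
  if (nrow(m) && any(!nzchar(trimws(m$protein))))
    return("protein names must be non-empty")
  TRUE
})

#' XLinkSet: residue-pair cross-link records
#'
#' One row per residue-level cross-link identification. The link class is
#' `self` when both endpoints are in the same protein and `heteromeric`
#' otherwise; it is derived, never stored independently of the endpoints.
#'
#' @slot links data.frame with columns `protein1`, `residue1`, `protein2`,
#'   `residue2`, `class`, `score` (NA when absent) and `id`.
#' @export
setClass("XLinkSet", representation(links = "data.frame"))

setValidity("XLinkSet", function(object) {
  l <- object@links
  need <- c("protein1", "residue1", "protein2", "residue2", "class", "score", "id")
  if (!all(need %in% names(l)))
    return(paste("links table must have columns:", paste(need, collapse = ", ")))
  if (nrow(l) == 0L) return(TRUE)
  if (any(l$residue1 <= 0) || any(l$residue2 <= 0))
    return("residue numbers must be positive")
  if (any(!nzchar(trimws(l$protein1))) || any(!nzchar(trimws(l$protein2))))
    return("protein names must be non-empty")
  selfFlag <- tolower(trimws(l$protein1)) == tolower(trimws(l$protein2))
  if (!all(l$class == ifelse(selfFlag, "self", "heteromeric")))
    return("class must be 'self' iff protein1 == protein2")
  TRUE
})

#' DensityGrid: a 3-D scalar map
#'
#' Regular grid of density values with cubic voxels, x fastest (MRC/CCP4
#' column order 1,2,3). `origin` is the position (Angstrom) of the centre of
#' voxel (1,1,1).
#'
#' @slot data 3-D numeric array.
#' @slot voxel voxel edge length in Angstrom.
#' @slot origin numeric(3), Angstrom.
#' @export
setClass("DensityGrid",
  representation(data = "array", voxel = "numeric", origin = "numeric"))

setValidity("DensityGrid", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (any(dim(object@data) < 1L)) return("grid dimensions must be >= 1")
  if (length(object@voxel) != 1L || object@voxel <= 0)
    return("voxel size must be a single positive number")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be numeric(3) and finite")
  TRUE
})

#' ThresholdPolicy: classification and rescue parameters
#'
#' @slot threshold maximum permissible Calpha-Calpha distance (Angstrom) for
#'   a satisfied link; default 35, the conventional bound for a DSSO-linked
#'   lysine pair. Classification is strict: satisfied iff distance < threshold.
#' @slot confCutoff per-residue confidence below which an endpoint counts as
#'   flexible for rescue of a violated link; default 50 (pLDDT scale).
#' @slot rescueWindow how many residues up/downstream of an endpoint (same
#'   chain) are inspected for low confidence; default 0 (endpoint only).
#' @export
setClass("ThresholdPolicy",
  representation(threshold = "numeric", confCutoff = "numeric",
                 rescueWindow = "integer"),
  prototype(threshold = 35, confCutoff = 50, rescueWindow = 0L))

setValidity("ThresholdPolicy", function(object) {
  if (object@threshold <= 0) return("threshold must be > 0")
  if (object@confCutoff < 0 || object@confCutoff > 100)
    return("confidence cutoff must lie in [0, 100]")
  if (object@rescueWindow < 0) return("rescue window must be >= 0")
  TRUE
})

#' Pose: a rigid-body placement
#'
#' The body's coordinates are centred on their centroid, rotated by the
#' quaternion, then translated so the centroid sits at `trans`.
#'
#' @slot quat numeric(4), unit quaternion (w, x, y, z).
#' @slot trans numeric(3), target centroid position in Angstrom.
#' @slot body identifier of the rigid body.
#' @export
setClass("Pose",
  representation(quat = "numeric", trans = "numeric", body = "character"),
  prototype(quat = c(1, 0, 0, 0), trans = c(0, 0, 0), body = NA_character_))

setValidity("Pose", function(object) {
  if (length(object@quat) != 4L) return("quat must be numeric(4)")
  if (length(object@trans) != 3L) return("trans must be numeric(3)")
  R <- quatToMatrix(object@quat)
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det +1)")
  TRUE
})

#' FitLibrary: clustered scored placements of one body in a map
#'
#' @slot poses data.frame with quaternion (qw..qz), translation (tx..tz),
#'   `score`, `inside` fraction, `cluster` id and `exemplar` flag. Clusters
#'   are numbered in rank order of their best member's score.
#' @slot body body identifier.
#' @slot params list of the generation parameters.
#' @export
setClass("FitLibrary",
  representation(poses = "data.frame", body = "character", params = "list"))

#' ScoreBreakdown: weighted restraint score of a configuration
#'
#' @slot terms named numeric: `em`, `xlink`, `connectivity`, `exvol`,
#'   `discrete` (raw, unweighted values).
#' @slot weights named numeric, same names; all >= 0.
#' @slot total weighted sum of terms.
#' @export
setClass("ScoreBreakdown",
  representation(terms = "numeric", weights = "numeric", total = "numeric"))

setValidity("ScoreBreakdown", function(object) {
  nm <- c("em", "xlink", "connectivity", "exvol", "discrete")
  if (!all(nm %in% names(object@terms)) || !all(nm %in% names(object@weights)))
    return("terms and weights must be named em/xlink/connectivity/exvol/discrete")
  if (any(object@weights < 0)) return("weights must be >= 0")
  tot <- sum(object@terms[nm] * object@weights[nm])
  if (abs(tot - object@total) > 1e-9 * max(1, abs(tot)))
    return("total must equal the weighted sum of terms")
  TRUE
})

#' AnnealSchedule: simulated-annealing temperature regime
#'
#' Default is the six-stage regime used for the train fitting:
#' temperatures 75000, 30000, 10000, 5000, 1000, 300 with
#' 1000, 800, 800, 500, 500, 300 Monte-Carlo steps. Temperatures are an
#' energy scale on the weighted total score (unitless).
#'
#' @slot stages data.frame with columns `temp` (strictly decreasing) and
#'   `steps` (positive integers).
#' @export
setClass("AnnealSchedule", representation(stages = "data.frame"),
  prototype(stages = data.frame(
    temp = c(75000, 30000, 10000, 5000, 1000, 300),
    steps = c(1000L, 800L, 800L, 500L, 500L, 300L))))

setValidity("AnnealSchedule", function(object) {
  s <- object@stages
  if (!all(c("temp", "steps") %in% names(s)))
    return("stages must have columns temp and steps")
  if (nrow(s) == 0L) return("schedule must have at least one stage")
  if (any(diff(s$temp) >= 0)) return("temperatures must be strictly decreasing")
  if (any(s$steps <= 0)) return("step counts must be positive")
  TRUE
})

#' SyntheticSpec: parameters of the two-state polymer generator
#'
#' The generator emulates the two polymer forms of an IFT train built from
#' one IFTA complex plus two IFTB complexes per repeating unit: a compact
#' stacked state A with sub-polymer repeats of 115 and 65 Angstrom
#' (anterograde-like), and an extended state B with a ~450 Angstrom visible
#' repeat shared by `unitsPerVisibleRepeat` repeating units and 2-fold
#' rotational symmetry perpendicular to the polymer axis (retrograde-like).
#'
#' @slot nUnits repeating units (odd values keep the global C2 exact).
#' @slot domainsPerSubcomplex pseudo-domains per subcomplex chain.
#' @slot atomsPerDomain Calpha beads per pseudo-domain.
#' @slot spacingA numeric(2): state-A repeats, IFTA and IFTB sub-polymer.
#' @slot visibleRepeatB state-B visible repeat (Angstrom).
#' @slot unitsPerVisibleRepeat repeating units per visible repeat (default 2).
#' @slot nLinks planted cross-links.
#' @slot satFrac named numeric(2) `A`, `B`: target satisfied fraction per state.
#' @slot margin minimum distance (Angstrom) between a planted link's distance
#'   and the classification threshold.
#' @slot threshold classification threshold used for planting (35).
#' @slot flexFrac fraction of residues placed in low-confidence segments.
#' @slot noise coordinate noise SD in Angstrom.
#' @slot seed integer seed recorded in output provenance.
#' @export
setClass("SyntheticSpec",
  representation(nUnits = "integer", domainsPerSubcomplex = "integer",
                 atomsPerDomain = "integer", spacingA = "numeric",
                 visibleRepeatB = "numeric", unitsPerVisibleRepeat = "integer",
                 nLinks = "integer", satFrac = "numeric", margin = "numeric",
                 threshold = "numeric", flexFrac = "numeric", noise = "numeric",
                 seed = "integer"),
  prototype(nUnits = 5L, domainsPerSubcomplex = 1L, atomsPerDomain = 50L,
            spacingA = c(IFTA = 115, IFTB = 65), visibleRepeatB = 450,
            unitsPerVisibleRepeat = 2L, nLinks = 40L,
            satFrac = c(A = 0.8, B = 0.95), margin = 5, threshold = 35,
            flexFrac = 0.1, noise = 0, seed = 1L))

setValidity("SyntheticSpec", function(object) {
  if (object@nUnits < 1L) return("nUnits must be >= 1")
  if (any(object@spacingA <= 0) || object@visibleRepeatB <= 0)
    return("spacings must be > 0")
  if (any(object@satFrac < 0) || any(object@satFrac > 1))
    return("satisfied fractions must lie in [0, 1]")
  if (!all(c("A", "B") %in% names(object@satFrac)))
    return("satFrac must be named A and B")
  if (object@margin < 0 || object@margin >= object@threshold)
    return("margin must lie in [0, threshold)")
  if (object@flexFrac < 0 || object@flexFrac > 1)
    return("flexFrac must lie in [0, 1]")
  if (object@noise < 0) return("noise SD must be >= 0")
  TRUE
})
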