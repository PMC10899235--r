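#' @import methods
#' @importFrom stats rnorm rlnorm sd pf pt rchisq setNames coef
NULL

## Central value classes. These are deliberately small: each carries one
## well-defined quantity of the analysis with a validity method enforcing the
## domain constraints (positive EC50s, unit axis vectors, ...). Tabular data
## (per-oocyte responses, panel summaries, cycle tables) stay plain
## data.frames, which is what ragged TEVC recordings actually are.

#' Ground-truth Hill parameters for simulation
#'
#' Holds the generating parameters of a variable-slope Hill (sigmoidal
#' concentration-response) curve: the half-maximal concentration EC50 (uM),
#' the Hill slope and the maximal response.
#'
#' @slot ec50 true half-maximal concentration, uM (> 0)
#' @slot hill true Hill slope, dimensionless (> 0)
#' @slot imax true maximal response, normalized current units (> 0)
#' @slot status `"functional"` or `"NR"` (no response; traces are all-zero)
#' @export
setClass("HillTruth",
  representation(ec50 = "numeric", hill = "numeric", imax = "numeric",
                 status = "character"),
  prototype(ec50 = 9.40, hill = 1.78, imax = 1, status = "functional"))

setValidity("HillTruth", function(object) {
  if (object@status == "NR") return(TRUE)
  if (length(object@ec50) != 1L || !is.finite(object@ec50) || object@ec50 <= 0)
    return("ec50 must be a single positive number")
  if (length(object@hill) != 1L || !is.finite(object@hill) || object@hill <= 0)
    return("hill must be a single positive number")
  if (length(object@imax) != 1L || !is.finite(object@imax) || object@imax <= 0)
    return("imax must be a single positive number")
  TRUE
})

#' @describeIn HillTruth constructor
#' @param ec50,hill,imax generating Hill parameters
#' @param status `"functional"` (default) or `"NR"` for a construct that gives
#'   no agonist-induced current
#' @export
hillTruth <- function(ec50 = 9.40, hill = 1.78, imax = 1,
                      status = c("functional", "NR")) {
  status <- match.arg(status)
  new("HillTruth", ec50 = as.numeric(ec50), hill = as.numeric(hill),
      imax = as.numeric(imax), status = status)
}

#' Design of a simulated TEVC concentration series
#'
#' @slot concentrations strictly increasing agonist concentrations, uM
#' @slot n_oocytes number of oocytes (replicates) per construct
#' @slot inter_oocyte_cv coefficient of variation of the lognormal
#'   oocyte-to-oocyte EC50 variability, in \[0, 1)
#' @slot noise_cv coefficient of variation of the multiplicative Gaussian
#'   measurement noise on peak currents, in \[0, 1)
#' @slot seed integer RNG seed
#' @export
setClass("DoseDesign",
  representation(concentrations = "numeric", n_oocytes = "integer",
                 inter_oocyte_cv = "numeric", noise_cv = "numeric",
                 seed = "integer"))

setValidity("DoseDesign", function(object) {
  cc <- object@concentrations
  if (length(cc) < 1L || any(!is.finite(cc)) || any(cc <= 0))
    return(sprintf("concentrations must be positive; offending value(s): %s",
                   paste(cc[!is.finite(cc) | cc <= 0], collapse = ", ")))
  if (is.unsorted(cc, strictly = TRUE))
    return("concentrations must be strictly increasing")
  if (object@n_oocytes < 1L) return("n_oocytes must be >= 1")
  for (nm in c("inter_oocyte_cv", "noise_cv")) {
    v <- slot(object, nm)
    if (v < 0 || v >= 1) return(sprintf("%s must lie in [0, 1)", nm))
  }
  TRUE
})

#' @describeIn DoseDesign constructor. When `concentrations` is `NULL` an
#'   8-point half-log grid bracketing `ec50_ref` is used (see
#'   [defaultConcGrid()]).
#' @param concentrations agonist concentrations (uM); `NULL` for the default
#'   grid around `ec50_ref`
#' @param ec50_ref reference EC50 (uM) used to centre the default grid
#' @param n_oocytes replicates per construct
#' @param inter_oocyte_cv,noise_cv variability parameters (fractions)
#' @param seed integer seed
#' @export
doseDesign <- function(concentrations = NULL, ec50_ref = 9.40, n_oocytes = 8,
                       inter_oocyte_cv = 0.19, noise_cv = 0.07, seed = 1L) {
  if (is.null(concentrations))
    concentrations <- defaultConcGrid(ec50_ref)
  new("DoseDesign", concentrations = as.numeric(concentrations),
      n_oocytes = as.integer(n_oocytes),
      inter_oocyte_cv = as.numeric(inter_oocyte_cv),
      noise_cv = as.numeric(noise_cv), seed = as.integer(seed))
}

#' Default half-log concentration grid bracketing an EC50
#'
#' Eight log-spaced concentrations from `ec50/30` to `30 * ec50`, the usual
#' TEVC design for a variable-slope sigmoid.
#'
#' @param ec50 concentration to bracket (uM)
#' @param n number of points
#' @param span one-sided bracket factor (grid runs `ec50/span` ... `span*ec50`)
#' @return numeric vector of concentrations (uM), strictly increasing
#' @export
defaultConcGrid <- function(ec50, n = 8L, span = 30) {
  stopifnot(is.finite(ec50), ec50 > 0, n >= 2L, span > 1)
  exp(seq(log(ec50 / span), log(ec50 * span), length.out = n))
}

#' A single-experiment Hill fit
#'
#' Result of fitting `I(c) = Imax * c^h / (c^h + EC50^h)` to one oocyte's
#' peak-current series.
#'
#' @slot construct construct label
#' @slot oocyte_id experiment label
#' @slot ec50 fitted EC50 (uM); `NA` for non-functional traces
#' @slot hill fitted Hill slope
#' @slot imax fitted maximal response
#' @slot rss residual sum of squares at the optimum
#' @slot converged logical convergence flag
#' @slot status `"functional"` or `"NF"` (no fit: all-zero currents)
#' @export
setClass("HillFit",
  representation(construct = "character", oocyte_id = "character",
                 ec50 = "numeric", hill = "numeric", imax = "numeric",
                 rss = "numeric", converged = "logical", status = "character"))

setValidity("HillFit", function(object) {
  if (object@status == "NF") return(TRUE)
  if (!is.finite(object@ec50) || object@ec50 <= 0)
    return("ec50 must be positive")
  if (!is.finite(object@hill) || object@hill <= 0 || object@hill > 10)
    return("hill must lie in (0, 10]")
  if (!is.finite(object@imax) || object@imax <= 0)
    return("imax must be positive")
  if (!is.finite(object@rss) || object@rss < 0)
    return("rss must be nonnegative")
  TRUE
})

#' Per-construct summary of Hill fits
#'
#' Mean and sample SD (n-1 denominator) of individually fitted EC50 and Hill
#' values, exactly as per-oocyte TEVC protocols aggregate them. Non-functional
#' constructs carry a status code instead of numbers: `NR` (no agonist
#' response), `NE` (no surface expression), `NF` (expressed, no fittable
#' response).
#'
#' @slot construct construct label
#' @slot ec50_mean,ec50_sd mean and SD of fitted EC50s (uM)
#' @slot hill_mean,hill_sd mean and SD of fitted Hill slopes
#' @slot n number of converged fits aggregated
#' @slot status one of `"functional"`, `"NR"`, `"NE"`, `"NF"`
#' @export
setClass("ConstructSummary",
  representation(construct = "character",
                 ec50_mean = "numeric", ec50_sd = "numeric",
                 hill_mean = "numeric", hill_sd = "numeric",
                 n = "integer", status = "character"))

setValidity("ConstructSummary", function(object) {
  if (!object@status %in% c("functional", "NR", "NE", "NF"))
    return("status must be one of functional/NR/NE/NF")
  if (object@status != "functional") {
    if (any(is.finite(c(object@ec50_mean, object@hill_mean))))
      return("non-functional summaries must not carry numeric estimates")
    return(TRUE)
  }
  if (object@n < 1L) return("functional summary needs n >= 1")
  if (!is.finite(object@ec50_mean) || object@ec50_mean <= 0)
    return("ec50_mean must be positive")
  if (is.finite(object@ec50_sd) && object@ec50_sd < 0)
    return("ec50_sd must be nonnegative")
  if (is.finite(object@hill_sd) && object@hill_sd < 0)
    return("hill_sd must be nonnegative")
  TRUE
})

#' @describeIn ConstructSummary constructor from summary values (e.g. a
#'   published table row)
#' @param construct construct label
#' @param ec50_mean,ec50_sd,hill_mean,hill_sd,n summary statistics
#' @param status construct status code
#' @export
constructSummary <- function(construct, ec50_mean = NA_real_,
                             ec50_sd = NA_real_, hill_mean = NA_real_,
                             hill_sd = NA_real_, n = NA_integer_,
                             status = "functional") {
  if (status != "functional") {
    ec50_mean <- ec50_sd <- hill_mean <- hill_sd <- NA_real_
    n <- 0L
  }
  new("ConstructSummary", construct = as.character(construct),
      ec50_mean = as.numeric(ec50_mean), ec50_sd = as.numeric(ec50_sd),
      hill_mean = as.numeric(hill_mean), hill_sd = as.numeric(hill_sd),
      n = as.integer(if (is.na(n)) 0L else n), status = status)
}

#' Fold change in EC50 relative to wild type
#'
#' Field convention: a loss of function (EC50 increased) is reported as
#' `mut/WT`, a gain (EC50 decreased) as `WT/mut`, so the magnitude is always
#' >= 1; direction `"none"` is used when the magnitude rounds to 1.00.
#'
#' @slot magnitude fold magnitude (>= 1)
#' @slot direction `"gain"`, `"loss"` or `"none"`
#' @export
setClass("FoldChange",
  representation(magnitude = "numeric", direction = "character"))

setValidity("FoldChange", function(object) {
  if (!is.finite(object@magnitude) || object@magnitude < 1)
    return("magnitude must be >= 1")
  if (!object@direction %in% c("gain", "loss", "none"))
    return("direction must be gain/loss/none")
  if (object@direction == "none" && round(object@magnitude, 2) != 1)
    return("direction 'none' requires magnitude rounding to 1.00")
  TRUE
})

#' A mutant cycle
#'
#' The constructs forming a (generalized) mutant cycle: wild type, k >= 2
#' single perturbations, and the construct combining all of them. A paired
#' mutation applied in two complementary subunits (e.g. the gamma and delta
#' copies of an interface residue) enters as its two single-subunit
#' constructs.
#'
#' @slot wt,combined [ConstructSummary-class] objects
#' @slot singles list of [ConstructSummary-class] objects (length k >= 2)
#' @export
setClass("CouplingCycle",
  representation(wt = "ConstructSummary", singles = "list",
                 combined = "ConstructSummary"))

setValidity("CouplingCycle", function(object) {
  if (length(object@singles) < 2L)
    return("a cycle needs at least two single perturbations")
  if (!all(vapply(object@singles, is, logical(1), "ConstructSummary")))
    return("singles must be ConstructSummary objects")
  if (object@wt@status != "functional")
    return("wild type must be functional")
  bad <- vapply(object@singles, function(s) s@status != "functional",
                logical(1))
  if (any(bad))
    return(sprintf("non-functional single(s): %s", paste(
      vapply(object@singles[bad], slot, character(1), "construct"),
      collapse = ", ")))
  TRUE
})

#' @describeIn CouplingCycle constructor
#' @param wt,combined [ConstructSummary-class] for wild type and the combined
#'   construct
#' @param singles list of [ConstructSummary-class], the individual
#'   perturbations
#' @export
couplingCycle <- function(wt, singles, combined) {
  new("CouplingCycle", wt = wt, singles = singles, combined = combined)
}

#' Result of a mutant-cycle computation
#'
#' @slot cycle_id label
#' @slot observed_fold,predicted_fold [FoldChange-class] objects (observed may
#'   be `NA`-magnitude placeholder for NR combined constructs)
#' @slot omega interaction factor (> 0); 1 means independence
#' @slot ddg coupling free energy RT ln(omega), kJ/mol
#' @slot ddg_sd propagated SD of `ddg`, kJ/mol
#' @export
setClass("CouplingResult",
  representation(cycle_id = "character", observed_fold = "FoldChange",
                 predicted_fold = "FoldChange", omega = "numeric",
                 ddg = "numeric", ddg_sd = "numeric"))

#' A channel pore axis
#'
#' A line in 3-space: anchor point plus unit direction, against which
#' perpendicular (radial) distances are measured.
#'
#' @slot anchor numeric length-3 point on the axis (Angstrom)
#' @slot direction numeric length-3 unit vector
#' @export
setClass("PoreAxis",
  representation(anchor = "numeric", direction = "numeric"))

setValidity("PoreAxis", function(object) {
  if (length(object@anchor) != 3L || any(!is.finite(object@anchor)))
    return("anchor must be a finite length-3 point")
  if (length(object@direction) != 3L ||
      abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    return("direction must be a unit length-3 vector")
  TRUE
})

#' @describeIn PoreAxis constructor (direction is normalized)
#' @param anchor point on the axis
#' @param direction axis direction (any nonzero length-3 vector)
#' @export
poreAxis <- function(anchor = c(0, 0, 0), direction = c(0, 0, 1)) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be nonzero")
  new("PoreAxis", anchor = as.numeric(anchor),
      direction = as.numeric(direction) / nrm)
}

#' Radial pore-proximal / pore-distal classification
#'
#' @slot r_query,r_reference perpendicular distances from the pore axis
#'   (Angstrom)
#' @slot epsilon tie band (Angstrom)
#' @slot verdict `"pore-proximal"`, `"pore-distal"` or `"indeterminate"`
#' @export
setClass("RadialClassification",
  representation(r_query = "numeric", r_reference = "numeric",
                 epsilon = "numeric", verdict = "character"))

setValidity("RadialClassification", function(object) {
  dv <- object@r_query - object@r_reference
  want <- if (dv < -object@epsilon) "pore-proximal"
          else if (dv > object@epsilon) "pore-distal" else "indeterminate"
  if (object@verdict != want)
    return("verdict inconsistent with distances and tie band")
  TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "HillTruth", function(object) {
  if (object@status == "NR") cat("HillTruth: NR (no response)\n")
  else cat(sprintf("HillTruth: EC50 = %g uM, Hill = %g, Imax = %g\n",
                   object@ec50, object@hill, object@imax))
})

setMethod("show", "HillFit", function(object) {
  if (object@status == "NF") {
    cat(sprintf("HillFit [%s/%s]: NF (no fittable response)\n",
                object@construct, object@oocyte_id))
  } else {
    cat(sprintf(
      "HillFit [%s/%s]: EC50 = %.3g uM, Hill = %.3g, Imax = %.3g (rss %.3g%s)\n",
      object@construct, object@oocyte_id, object@ec50, object@hill,
      object@imax, object@rss,
      if (object@converged) "" else ", NOT converged"))
  }
})

setMethod("show", "ConstructSummary", function(object) {
  if (object@status != "functional") {
    cat(sprintf("ConstructSummary [%s]: %s\n", object@construct,
                object@status))
  } else {
    cat(sprintf(
      "ConstructSummary [%s]: EC50 %.3g +/- %.3g uM, Hill %.3g +/- %.3g, n = %d\n",
      object@construct, object@ec50_mean, object@ec50_sd, object@hill_mean,
      object@hill_sd, object@n))
  }
})

setMethod("show", "FoldChange", function(object) {
  cat(sprintf("FoldChange: %.3g %s\n", object@magnitude, object@direction))
})

setMethod("show", "CouplingResult", function(object) {
  cat(sprintf(
    "CouplingResult [%s]: omega = %.3g, ddG = %.3g +/- %.3g kJ/mol\n",
    object@cycle_id, object@omega, object@ddg, object@ddg_sd))
})

setMethod("show", "PoreAxis", function(object) {
  cat(sprintf("PoreAxis: anchor (%.2f, %.2f, %.2f), direction (%.3f, %.3f, %.3f)\n",
              object@anchor[1], object@anchor[2], object@anchor[3],
              object@direction[1], object@direction[2], object@direction[3]))
})

setMethod("show", "RadialClassification", function(object) {
  cat(sprintf(
    "RadialClassification: r_query %.2f A vs r_ref %.2f A (eps %.2f) -> %s\n",
    object@r_query, object@r_reference, object@epsilon, object@verdict))
})

## ---- accessors --------------------------------------------------------

#' Extract the EC50 of a fit or summary
#' @param object a [HillFit-class] or [ConstructSummary-class]
#' @return EC50 in uM (the mean for summaries)
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))

#' @rdname ec50
#' @export
setMethod("ec50", "HillFit", function(object) object@ec50)

#' @rdname ec50
#' @export
setMethod("ec50", "ConstructSummary", function(object) object@ec50_mean)

#' Extract the Hill slope of a fit or summary
#' @param object a [HillFit-class] or [ConstructSummary-class]
#' @return Hill slope (the mean for summaries)
#' @export
setGeneric("hillSlope", function(object) standardGeneric("hillSlope"))

#' @rdname hillSlope
#' @export
setMethod("hillSlope", "HillFit", function(object) object@hill)

#' @rdname hillSlope
#' @export
setMethod("hillSlope", "ConstructSummary", function(object) object@hill_mean)

#' Extract a construct status code
#' @param object a [HillFit-class] or [ConstructSummary-class]
#' @return `"functional"`, `"NR"`, `"NE"` or `"NF"`
#' @export
setGeneric("constructStatus", function(object) standardGeneric("constructStatus"))

#' @rdname constructStatus
#' @export
setMethod("constructStatus", "HillFit", function(object) object@status)

#' @rdname constructStatus
#' @export
setMethod("constructStatus", "ConstructSummary", function(object) object@status)

#' Magnitude and direction of a fold change
#' @param object a [FoldChange-class]
#' @return numeric magnitude (>= 1) / character direction
#' @export
setGeneric("foldMagnitude", function(object) standardGeneric("foldMagnitude"))

#' @rdname foldMagnitude
#' @export
setMethod("foldMagnitude", "FoldChange", function(object) object@magnitude)

#' @rdname foldMagnitude
#' @export
setGeneric("foldDirection", function(object) standardGeneric("foldDirection"))

#' @rdname foldMagnitude
#' @export
setMethod("foldDirection", "FoldChange", function(object) object@direction)

#' Verdict of a radial classification
#' @param object a [RadialClassification-class]
#' @return `"pore-proximal"`, `"pore-distal"` or `"indeterminate"`
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname verdict
#' @export
setMethod("verdict", "RadialClassification", function(object) object@verdict)
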