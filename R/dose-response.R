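## Variable-slope Hill fitting of per-oocyte TEVC records and per-construct
## aggregation. One fit per experiment; EC50/Hill means +/- sample SD per
## construct, the protocol used for published muscle-nAChR tables.

#' Fit the variable-slope Hill model to one concentration-response experiment
#'
#' Least squares in linear response space for
#' `I(c) = Imax * c^h / (c^h + EC50^h)`, optimized over
#' `(log EC50, log h, Imax)` by Levenberg-Marquardt with box bounds
#' (`h` in `hill_bounds`, `EC50` within the measured concentration bracket
#' times `1e-2 ... 1e2`). Start values: EC50 at the geometric mean of the two
#' concentrations bracketing half-maximal response, `h = 1.5`,
#' `Imax = max(current)`.
#'
#' @param data data.frame with columns `concentration_uM` and `current` (one
#'   oocyte), or `NULL` if `concentration` / `current` vectors are given
#' @param concentration,current paired numeric vectors (used when `data` is
#'   `NULL`); >= 4 distinct positive concentrations required
#' @param construct,oocyte_id labels stored in the result
#' @param hill_bounds allowed Hill-slope range
#' @return a [HillFit-class]. All-zero current traces return a fit with
#'   status `"NF"` and no estimates; non-convergence is flagged via the
#'   `converged` slot with the best iterate retained.
#' @examples
#' cc <- defaultConcGrid(10)
#' fitHill(concentration = cc, current = cc^2 / (cc^2 + 100))
#' @export
fitHill <- function(data = NULL, concentration = data$concentration_uM,
                    current = data$current, construct = "construct",
                    oocyte_id = "oocyte", hill_bounds = c(0.2, 10)) {
  if (!is.null(data)) {
    if (!is.null(data$construct)) construct <- data$construct[1]
    if (!is.null(data$oocyte_id)) oocyte_id <- data$oocyte_id[1]
  }
  concentration <- as.numeric(concentration)
  current <- as.numeric(current)
  if (length(concentration) != length(current))
    stop("concentration and current must be paired vectors of equal length")
  if (any(!is.finite(concentration) | concentration <= 0))
    stop(sprintf("concentrations must be positive; offending value(s): %s",
                 paste(concentration[!is.finite(concentration) |
                                       concentration <= 0], collapse = ", ")))
  if (length(unique(concentration)) < 4L)
    stop("need >= 4 distinct concentrations to fit a Hill curve")
  if (all(current <= 0)) {
    return(new("HillFit", construct = as.character(construct),
               oocyte_id = as.character(oocyte_id), ec50 = NA_real_,
               hill = NA_real_, imax = NA_real_, rss = NA_real_,
               converged = FALSE, status = "NF"))
  }

  lc <- log(concentration)
  imax0 <- max(current)
  half <- imax0 / 2
  i <- which(current >= half)[1]
  ec0 <- if (is.na(i)) max(concentration)
         else if (i == 1L) concentration[1]
         else sqrt(concentration[i - 1L] * concentration[i])
  start <- c(lec50 = log(ec0), lh = log(1.5), imax = imax0)
  lower <- c(min(lc) - log(100), log(hill_bounds[1]), 0)
  upper <- c(max(lc) + log(100), log(hill_bounds[2]), Inf)

  resid_fun <- function(p) {
    current - p[3] * stats::plogis(exp(p[2]) * (lc - p[1]))
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-15, ptol = 1e-15, gtol = 0, maxiter = 500))
  p <- fit$par
  converged <- fit$info %in% 1:4
  new("HillFit", construct = as.character(construct),
      oocyte_id = as.character(oocyte_id),
      ec50 = exp(unname(p[1])), hill = exp(unname(p[2])),
      imax = unname(p[3]), rss = sum(resid_fun(p)^2),
      converged = converged, status = "functional")
}

#' Fit every oocyte in a tidy response table
#'
#' @param responses data.frame with columns `construct`, `oocyte_id`,
#'   `concentration_uM`, `current`
#' @param ... passed to [fitHill()]
#' @return named list (by construct) of lists of [HillFit-class] objects
#' @export
fitPanel <- function(responses, ...) {
  stopifnot(all(c("construct", "oocyte_id", "concentration_uM", "current")
                %in% names(responses)))
  by_con <- split(responses, responses$construct)
  lapply(by_con, function(d) {
    lapply(split(d, d$oocyte_id), fitHill, ...)
  })
}

#' Aggregate per-experiment Hill fits into a construct summary
#'
#' Mean and sample SD (n-1 denominator) of EC50 and Hill over *converged*
#' fits only; `n` counts the converged fits. A single fit reports SD 0. If no
#' fit is usable the construct is summarized as status `"NF"` (or as
#' `status_override` when given, e.g. `"NR"` / `"NE"` from the bench record).
#'
#' @param fits list of [HillFit-class] objects
#' @param construct label for the summary (defaults to the first fit's label)
#' @param status_override optional status code short-circuiting aggregation
#' @return a [ConstructSummary-class]
#' @export
summarizeConstruct <- function(fits, construct = NULL,
                               status_override = NULL) {
  if (!is.null(status_override))
    return(constructSummary(
      if (is.null(construct)) "construct" else construct,
      status = status_override))
  if (length(fits) == 0L)
    stop("no fits given and no status_override")
  stopifnot(all(vapply(fits, is, logical(1), "HillFit")))
  if (is.null(construct)) construct <- fits[[1]]@construct
  ok <- vapply(fits, function(f)
    f@status == "functional" && f@converged, logical(1))
  if (!any(ok))
    return(constructSummary(construct, status = "NF"))
  e <- vapply(fits[ok], slot, numeric(1), "ec50")
  h <- vapply(fits[ok], slot, numeric(1), "hill")
  sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
  constructSummary(construct, ec50_mean = mean(e), ec50_sd = sd0(e),
                   hill_mean = mean(h), hill_sd = sd0(h), n = sum(ok))
}

#' Summarize every construct of a fitted panel
#'
#' @param panel_fits output of [fitPanel()]
#' @return named list of [ConstructSummary-class] objects
#' @export
summarizePanel <- function(panel_fits) {
  out <- lapply(names(panel_fits), function(lab)
    summarizeConstruct(panel_fits[[lab]], construct = lab))
  setNames(out, names(panel_fits))
}

#' Fold change in EC50 between a mutant and wild type
#'
#' Convention: `r = EC50(mut) / EC50(WT)`; `r >= 1` is reported as
#' `(r, "loss")`, otherwise `(1/r, "gain")`; direction `"none"` when the
#' magnitude rounds to 1.00. Full precision is retained; rounding is for
#' display only.
#'
#' @param mutant,wt [ConstructSummary-class] objects (both functional) or
#'   positive EC50 scalars
#' @return a [FoldChange-class]
#' @examples
#' foldChange(0.600, 9.40)  # 15.7 gain
#' @export
foldChange <- function(mutant, wt) {
  get_ec50 <- function(x, who) {
    if (is(x, "ConstructSummary")) {
      if (x@status != "functional")
        stop(sprintf("fold change undefined: %s construct '%s' has status %s",
                     who, x@construct, x@status))
      x@ec50_mean
    } else {
      stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x > 0)
      x
    }
  }
  r <- get_ec50(mutant, "mutant") / get_ec50(wt, "wild-type")
  mag <- if (r >= 1) r else 1 / r
  dir <- if (round(mag, 2) == 1) "none" else if (r >= 1) "loss" else "gain"
  new("FoldChange", magnitude = mag, direction = dir)
}
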