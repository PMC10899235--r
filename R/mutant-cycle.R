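## Generalized mutant-cycle analysis on EC50 summaries: independence
## prediction, interaction factor Omega, coupling energy RT ln(Omega) at
## 298 K, and quadrature error propagation.

#' Thermal energy RT at 298 K, in kJ/mol
#'
#' `R = 8.314 J mol^-1 K^-1`, `T = 298 K`, giving `RT = 2.4776 kJ/mol`.
#' @export
RT_298K <- 8.314 * 298 / 1000

signif3 <- function(x) signif(x, 3)

# Pull EC50 means/SDs out of a CouplingCycle, optionally rounded to the
# 3 significant figures of a published table ("printed" mode).
cycle_ec50s <- function(cycle, mode = c("unrounded", "printed")) {
  mode <- match.arg(mode)
  validObject(cycle)
  f <- if (mode == "printed") signif3 else identity
  list(
    wt = f(cycle@wt@ec50_mean),
    singles = f(vapply(cycle@singles, slot, numeric(1), "ec50_mean")),
    combined = if (cycle@combined@status == "functional")
      f(cycle@combined@ec50_mean) else NA_real_,
    wt_sd = f(cycle@wt@ec50_sd),
    singles_sd = f(vapply(cycle@singles, slot, numeric(1), "ec50_sd")),
    combined_sd = if (cycle@combined@status == "functional")
      f(cycle@combined@ec50_sd) else NA_real_)
}

#' Predicted fold change under mutational independence
#'
#' If the k perturbations of a cycle influenced function independently, the
#' combined EC50 would be `EC50(WT) * prod_i (EC50_i / EC50(WT))`; the
#' predicted fold change is that product of single-mutant EC50 ratios,
#' expressed through the gain/loss convention of [foldChange()].
#'
#' @param cycle a [CouplingCycle-class]
#' @param mode `"unrounded"` (default) uses full-precision means;
#'   `"printed"` rounds every EC50 to 3 significant figures first, for
#'   reproducing published tables
#' @return a [FoldChange-class]
#' @export
predictedIndependentFold <- function(cycle,
                                     mode = c("unrounded", "printed")) {
  e <- cycle_ec50s(cycle, mode)
  r <- prod(e$singles / e$wt)
  mag <- if (r >= 1) r else 1 / r
  dir <- if (round(mag, 2) == 1) "none" else if (r >= 1) "loss" else "gain"
  new("FoldChange", magnitude = mag, direction = dir)
}

#' Generalized mutant-cycle interaction factor Omega
#'
#' For a cycle of k perturbations,
#' `Omega = EC50(WT)^(k-1) * EC50(combined) / prod_i EC50(mut_i)`,
#' which at k = 2 reduces to the classical double-mutant-cycle form
#' `EC50(WT) * EC50(mut_12) / (EC50(mut_1) * EC50(mut_2))`. `Omega = 1`
#' means the combined EC50 equals the independence prediction; deviations
#' from unity quantify energetic coupling.
#'
#' @inheritParams predictedIndependentFold
#' @return positive scalar
#' @examples
#' cyc <- couplingCycle(
#'   wt = constructSummary("WT", 9.40, 1.82, n = 8),
#'   singles = list(constructSummary("m1", 25.1, 5.5, n = 8),
#'                  constructSummary("m2", 27.1, 4.9, n = 8)),
#'   combined = constructSummary("m12", 55.8, 8.2, n = 8))
#' computeOmega(cyc)  # ~0.77
#' @export
computeOmega <- function(cycle, mode = c("unrounded", "printed")) {
  e <- cycle_ec50s(cycle, mode)
  if (is.na(e$combined))
    stop(sprintf("Omega undefined: combined construct '%s' has status %s",
                 cycle@combined@construct, cycle@combined@status))
  vals <- c(e$wt, e$singles, e$combined)
  if (any(!is.finite(vals) | vals <= 0))
    stop("all EC50s must be positive and finite")
  k <- length(e$singles)
  e$wt^(k - 1) * e$combined / prod(e$singles)
}

#' Coupling free energy from an interaction factor
#'
#' `ddG = RT * ln(Omega)` with `RT = 2.4776 kJ/mol` (298 K). Zero at
#' independence (`Omega = 1`); the sign tracks the direction of the deviation.
#' These energies compare couplings between cycles; because EC50 is a
#' composite functional readout they are not state-specific gating energies.
#'
#' @param omega positive interaction factor
#' @param rt thermal energy in kJ/mol (default [RT_298K])
#' @return energy in kJ/mol
#' @export
couplingEnergy <- function(omega, rt = RT_298K) {
  if (any(!is.finite(omega) | omega <= 0))
    stop("omega must be positive and finite")
  rt * log(omega)
}

#' Propagated SD of a coupling free energy
#'
#' Quadrature propagation of the relative EC50 SDs through
#' `ddG = RT ln(EC50_wt^(k-1) EC50_comb / prod EC50_i)`, scaled by `|ddG|`:
#' `sd = |ddG| * sqrt((k-1) (sd_wt/EC50_wt)^2 + sum_i (sd_i/EC50_i)^2 +
#' (sd_comb/EC50_comb)^2)`. The wild-type term enters `k - 1` times because
#' the wild-type EC50 appears with exponent `k - 1`. Identically zero when
#' `ddG = 0`.
#'
#' @inheritParams predictedIndependentFold
#' @param ddg coupling energy of the same cycle, kJ/mol (computed if missing)
#' @return nonnegative energy in kJ/mol
#' @export
propagateCouplingSd <- function(cycle, ddg = NULL,
                                mode = c("unrounded", "printed")) {
  e <- cycle_ec50s(cycle, mode)
  if (is.null(ddg)) ddg <- couplingEnergy(computeOmega(cycle, mode))
  sds <- c(e$wt_sd, e$singles_sd, e$combined_sd)
  if (any(!is.finite(sds)))
    stop("every cycle member must carry an EC50 SD")
  k <- length(e$singles)
  rel2 <- (k - 1) * (e$wt_sd / e$wt)^2 +
    sum((e$singles_sd / e$singles)^2) +
    (e$combined_sd / e$combined)^2
  abs(ddg) * sqrt(rel2)
}

#' Full result for one mutant cycle
#'
#' @inheritParams predictedIndependentFold
#' @param cycle_id label for the result
#' @return a [CouplingResult-class]. When the combined construct is
#'   non-functional (NR/NE/NF) only the predicted fold is defined and
#'   `omega`/`ddg`/`ddg_sd` are `NA`.
#' @export
couplingResult <- function(cycle, cycle_id = "cycle",
                           mode = c("unrounded", "printed")) {
  mode <- match.arg(mode)
  pred <- predictedIndependentFold(cycle, mode)
  if (cycle@combined@status != "functional") {
    obs <- new("FoldChange", magnitude = 1, direction = "none")
    return(new("CouplingResult", cycle_id = cycle_id, observed_fold = obs,
               predicted_fold = pred, omega = NA_real_, ddg = NA_real_,
               ddg_sd = NA_real_))
  }
  e <- cycle_ec50s(cycle, mode)
  obs_r <- e$combined / e$wt
  obs_mag <- if (obs_r >= 1) obs_r else 1 / obs_r
  obs_dir <- if (round(obs_mag, 2) == 1) "none"
             else if (obs_r >= 1) "loss" else "gain"
  omega <- computeOmega(cycle, mode)
  ddg <- couplingEnergy(omega)
  new("CouplingResult", cycle_id = cycle_id,
      observed_fold = new("FoldChange", magnitude = obs_mag,
                          direction = obs_dir),
      predicted_fold = pred, omega = omega, ddg = ddg,
      ddg_sd = propagateCouplingSd(cycle, ddg, mode))
}

#' Build a coupling table for a set of cycles
#'
#' Assembles one row per cycle definition from a pool of construct summaries:
#' combined EC50, observed and predicted fold change, Omega, ddG +/- SD.
#' Cycles whose combined construct is non-functional report only the
#' predicted column, as published tables do.
#'
#' @param summaries named list of [ConstructSummary-class] objects (names are
#'   construct labels), or a data.frame as returned by
#'   [readConstructSummaries()]
#' @param cycles list of cycle definitions, each a list with elements `id`,
#'   `wt`, `singles` (character vector of construct labels) and `combined`;
#'   see [readCycleDefinitions()]
#' @param mode `"unrounded"` or `"printed"` (3-significant-figure table
#'   reproduction mode)
#' @return data.frame with columns `cycle_id`, `k`, `ec50_combined`,
#'   `observed_fold`, `observed_dir`, `predicted_fold`, `predicted_dir`,
#'   `omega`, `ddg`, `ddg_sd`, `combined_status`
#' @export
buildCycleTable <- function(summaries, cycles,
                            mode = c("unrounded", "printed")) {
  mode <- match.arg(mode)
  if (is.data.frame(summaries)) summaries <- summariesFromTable(summaries)
  if (length(cycles) == 0L)
    return(data.frame(cycle_id = character(), k = integer(),
                      ec50_combined = numeric(), observed_fold = numeric(),
                      observed_dir = character(), predicted_fold = numeric(),
                      predicted_dir = character(), omega = numeric(),
                      ddg = numeric(), ddg_sd = numeric(),
                      combined_status = character()))
  lookup <- function(lab) {
    if (!lab %in% names(summaries))
      stop(sprintf("cycle references undefined construct '%s'", lab))
    summaries[[lab]]
  }
  rows <- lapply(cycles, function(cy) {
    stopifnot(!is.null(cy$id), !is.null(cy$wt), length(cy$singles) >= 2L,
              !is.null(cy$combined))
    cycle <- couplingCycle(wt = lookup(cy$wt),
                           singles = lapply(cy$singles, lookup),
                           combined = lookup(cy$combined))
    res <- couplingResult(cycle, cycle_id = cy$id, mode = mode)
    comb <- cycle@combined
    functional <- comb@status == "functional"
    data.frame(
      cycle_id = cy$id, k = length(cy$singles),
      ec50_combined = if (functional) comb@ec50_mean else NA_real_,
      observed_fold = if (functional) res@observed_fold@magnitude else NA_real_,
      observed_dir = if (functional) res@observed_fold@direction
                     else NA_character_,
      predicted_fold = res@predicted_fold@magnitude,
      predicted_dir = res@predicted_fold@direction,
      omega = res@omega, ddg = res@ddg, ddg_sd = res@ddg_sd,
      combined_status = comb@status)
  })
  do.call(rbind, rows)
}

## ---- table and YAML ingestion ----------------------------------------

#' Read a construct-summary CSV
#'
#' Expected columns: `construct`, `ec50_mean`, `ec50_sd`, `hill_mean`,
#' `hill_sd`, `n`, `status`. Published EC50/Hill tables can be typed into
#' this format directly; non-functional rows leave the numeric fields empty.
#'
#' @param file CSV path
#' @return data.frame (one row per construct)
#' @seealso [summariesFromTable()] to convert to summary objects,
#'   [couplingExampleFile()] for the bundled muscle-nAChR example table
#' @export
readConstructSummaries <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("construct", "ec50_mean", "ec50_sd", "hill_mean", "hill_sd",
            "n", "status")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("summary CSV is missing column(s): ", paste(miss, collapse = ", "))
  x
}

#' Convert a summary table to ConstructSummary objects
#'
#' @param tab data.frame as from [readConstructSummaries()]
#' @return named list of [ConstructSummary-class]
#' @export
summariesFromTable <- function(tab) {
  out <- lapply(seq_len(nrow(tab)), function(i) {
    constructSummary(tab$construct[i], ec50_mean = tab$ec50_mean[i],
                     ec50_sd = tab$ec50_sd[i], hill_mean = tab$hill_mean[i],
                     hill_sd = tab$hill_sd[i], n = tab$n[i],
                     status = tab$status[i])
  })
  setNames(out, tab$construct)
}

#' Read cycle definitions from YAML
#'
#' The file holds a top-level `cycles:` sequence; each entry has `id`, `wt`,
#' `singles` (sequence of construct labels; paired complementary-subunit
#' mutations are listed as their individual single-subunit constructs) and
#' `combined`.
#'
#' @param file YAML path
#' @return list of cycle definition lists, usable by [buildCycleTable()]
#' @export
readCycleDefinitions <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y$cycles)) stop("YAML must contain a top-level 'cycles' list")
  y$cycles
}

#' Path to bundled example data
#'
#' `"summaries"` is a published EC50/Hill summary table (mean +/- SD, n,
#' status) for wild-type and ECD-TMD interface mutants of the muscle-type
#' *Torpedo* nAChR measured by TEVC; `"cycles"` defines the mutant cycles
#' built from those constructs; `"pentamer_pdb"` / `"pentamer_cif"` are the
#' same synthetic C5 pentamer rendered in both structure formats.
#'
#' @param which one of `"summaries"`, `"cycles"`, `"pentamer_pdb"`,
#'   `"pentamer_cif"`
#' @return file path
#' @export
couplingExampleFile <- function(which = c("summaries", "cycles",
                                          "pentamer_pdb", "pentamer_cif")) {
  which <- match.arg(which)
  fn <- switch(which,
    summaries = "nachr_ec50_summaries.csv",
    cycles = "nachr_cycles.yaml",
    pentamer_pdb = "synthetic_pentamer.pdb",
    pentamer_cif = "synthetic_pentamer.cif")
  system.file("extdata", fn, package = "channelCoupling", mustWork = TRUE)
}
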