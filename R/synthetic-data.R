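## Seeded synthetic TEVC recordings and C5-symmetric toy pentamers.
## Everything here has closed-form ground truth so the fitting, cycle and
## geometry stages can be validated without any experimental download.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Hill response at concentration c (uM).
hill_response <- function(c, ec50, hill, imax) {
  imax * c^hill / (c^hill + ec50^hill)
}

#' Simulate per-oocyte TEVC concentration-response records
#'
#' Draws `n_oocytes` experiments for one construct. Each oocyte gets its own
#' EC50 from a lognormal distribution with median `ec50(truth)` and
#' coefficient of variation `inter_oocyte_cv` (Hill slope and Imax are held at
#' their true values; oocyte-to-oocyte spread in published EC50 tables is the
#' quantity being emulated). Peak currents follow the variable-slope Hill form
#' with multiplicative Gaussian noise of CV `noise_cv`, clipped at zero.
#'
#' @param truth a [HillTruth-class]; status `"NR"` yields all-zero traces
#' @param design a [DoseDesign-class]
#' @param construct,oocyte_prefix labels used in the output table
#' @return a tidy data.frame with columns `construct`, `oocyte_id`,
#'   `concentration_uM`, `current`; `n_oocytes * length(concentrations)` rows
#' @examples
#' d <- doseDesign(n_oocytes = 2, seed = 42)
#' simulateOocyteResponses(hillTruth(9.4, 1.78, 1), d)
#' @export
simulateOocyteResponses <- function(truth, design, construct = "WT",
                                    oocyte_prefix = construct) {
  stopifnot(is(truth, "HillTruth"), is(design, "DoseDesign"))
  validObject(truth); validObject(design)
  cc <- design@concentrations
  n <- design@n_oocytes
  ids <- sprintf("%s_oo%02d", oocyte_prefix, seq_len(n))
  if (truth@status == "NR") {
    return(data.frame(
      construct = construct,
      oocyte_id = rep(ids, each = length(cc)),
      concentration_uM = rep(cc, times = n),
      current = 0))
  }
  with_seed(design@seed, {
    sim_one <- function(id) {
      ec50_i <- if (design@inter_oocyte_cv > 0) {
        sdlog <- sqrt(log(1 + design@inter_oocyte_cv^2))
        rlnorm(1, meanlog = log(truth@ec50), sdlog = sdlog)
      } else truth@ec50
      mu <- hill_response(cc, ec50_i, truth@hill, truth@imax)
      cur <- mu * (1 + rnorm(length(cc), 0, design@noise_cv))
      data.frame(construct = construct, oocyte_id = id,
                 concentration_uM = cc, current = pmax(cur, 0))
    }
    do.call(rbind, lapply(ids, sim_one))
  })
}

#' Simulate a whole mutagenesis panel
#'
#' One set of per-oocyte records per construct, sharing a single seeded RNG
#' stream so the whole panel is reproducible run-to-run.
#'
#' @param panel_config named list of [HillTruth-class] objects, one per
#'   construct; must contain an entry named `wt_label`
#' @param design a [DoseDesign-class]; if its concentration grid should track
#'   each construct's true EC50 instead, pass `per_construct_grid = TRUE`
#' @param wt_label name of the wild-type entry (default `"WT"`)
#' @param per_construct_grid if `TRUE`, each construct is measured on
#'   [defaultConcGrid()] around its own true EC50 (as a bench scientist would
#'   choose the series); otherwise the design grid is shared
#' @return a tidy data.frame (rbind of [simulateOocyteResponses()] outputs)
#' @export
generatePanel <- function(panel_config, design, wt_label = "WT",
                          per_construct_grid = TRUE) {
  stopifnot(is.list(panel_config), is(design, "DoseDesign"))
  if (!wt_label %in% names(panel_config))
    stop(sprintf("panel_config must contain the wild-type entry '%s'",
                 wt_label))
  labs <- names(panel_config)
  with_seed(design@seed, {
    out <- lapply(labs, function(lab) {
      truth <- panel_config[[lab]]
      stopifnot(is(truth, "HillTruth"))
      d <- design
      if (per_construct_grid && truth@status != "NR")
        d@concentrations <- defaultConcGrid(truth@ec50,
                                            n = length(design@concentrations))
      # per-construct sub-seed drawn from the panel stream (keeps each
      # construct's draws independent of grid choices elsewhere)
      d@seed <- sample.int(.Machine$integer.max, 1L)
      simulateOocyteResponses(truth, d, construct = lab)
    })
    do.call(rbind, out)
  })
}

#' Write tidy per-oocyte responses to CSV
#'
#' @param responses data.frame from [simulateOocyteResponses()] /
#'   [generatePanel()]
#' @param file path
#' @export
writeResponsesCSV <- function(responses, file) {
  utils::write.csv(responses, file, row.names = FALSE, quote = FALSE)
}

#' Read tidy per-oocyte responses from CSV
#'
#' @param file path to a CSV with columns `construct`, `oocyte_id`,
#'   `concentration_uM`, `current`
#' @return data.frame
#' @export
readResponsesCSV <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("construct", "oocyte_id", "concentration_uM", "current")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("response CSV is missing column(s): ", paste(miss, collapse = ", "))
  x
}

#' Build a C5-symmetric synthetic pentamer
#'
#' Places each requested residue ring at `n_fold` symmetric azimuths about the
#' z-axis at its radius and height, one symmetry copy per chain (A, B, C, ...).
#' Each residue gets a CA atom and one pseudo side-chain atom (`CB`) at the
#' same radius, 1.5 A above, so every generated atom's perpendicular distance
#' from the z-axis equals its ring radius.
#'
#' @param rings data.frame with columns `resno` (integer), `radius` (A, >= 0),
#'   `height` (A); optional `resname` (default `"ALA"`)
#' @param n_fold symmetry order (default 5)
#' @param phase azimuthal offset of the first chain, radians
#' @return a `bio3d` `pdb` object (chains `A` ... up to `n_fold`, one model),
#'   writable with [writeStructurePDB()]
#' @examples
#' p <- buildSyntheticPentamer(data.frame(resno = 46, radius = 8, height = 0))
#' @export
buildSyntheticPentamer <- function(rings, n_fold = 5L, phase = 0) {
  stopifnot(is.data.frame(rings), all(c("resno", "radius", "height") %in%
                                        names(rings)), n_fold >= 1L)
  if (any(rings$radius < 0))
    stop(sprintf("ring radius must be nonnegative; offending value(s): %s",
                 paste(rings$radius[rings$radius < 0], collapse = ", ")))
  if (is.null(rings$resname)) rings$resname <- "ALA"
  chains <- LETTERS[seq_len(n_fold)]
  rows <- list()
  for (k in seq_len(n_fold)) {
    theta <- phase + 2 * pi * (k - 1) / n_fold
    for (j in seq_len(nrow(rings))) {
      r <- rings$radius[j]; z <- rings$height[j]
      xy <- c(r * cos(theta), r * sin(theta))
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chains[k], resno = rings$resno[j], resid = rings$resname[j],
        elety = c("CA", "CB"),
        x = xy[1], y = xy[2], z = c(z, z + 1.5))
    }
  }
  at <- do.call(rbind, rows)
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::as.pdb(xyz = xyz, type = "ATOM", resno = at$resno, resid = at$resid,
                eleno = seq_len(nrow(at)), elety = at$elety, chain = at$chain,
                elesy = "C", verbose = FALSE)
}
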