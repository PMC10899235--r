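# Shared fixture builders. Everything is generated in code; no binary data.

wt_truth <- function() hillTruth(ec50 = 9.40, hill = 1.78, imax = 1)

noiseless_design <- function(ec50 = 10, n_oocytes = 1, seed = 1L)
  doseDesign(ec50_ref = ec50, n_oocytes = n_oocytes,
             inter_oocyte_cv = 0, noise_cv = 0, seed = seed)

# Exact Hill currents on a grid
hill_currents <- function(cc, ec50, hill, imax = 1)
  imax * cc^hill / (cc^hill + ec50^hill)

# A tall M2-like C5 bundle: pore-lining rings spanning z plus a reference
# (resno 265, r = 8 A) and a query ring (resno 46) whose radius is settable,
# emulating the apo (distal, r > 8) vs agonist-bound (proximal, r < 8)
# placement of the beta1-beta2 tip relative to the M2-M3 proline.
bundle_pentamer <- function(query_radius = 11) {
  m2 <- data.frame(resno = 248:256, radius = 6, height = seq(0, 32, by = 4),
                   resname = "LEU")
  m2$resname[m2$resno == 255] <- "VAL"
  top <- data.frame(resno = c(265, 46), radius = c(8, query_radius),
                    height = c(34, 36), resname = c("PRO", "VAL"))
  buildSyntheticPentamer(rbind(m2, top))
}

# Random rotation matrix (uniform via QR of Gaussian matrix), seeded
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Replicates with exactly the requested mean, sd and n (affine-rescaled)
exact_replicates <- function(mean, sd, n, seed = 1L) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  mean + sd * x
}

table_summaries <- function()
  readConstructSummaries(couplingExampleFile("summaries"))

table_cycles <- function()
  readCycleDefinitions(couplingExampleFile("cycles"))

published_couplings <- function()
  utils::read.csv(couplingExampleFile("summaries") |>
                    dirname() |>
                    file.path("nachr_published_couplings.csv"),
                  stringsAsFactors = FALSE)
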