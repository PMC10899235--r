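## Significance machinery for construct EC50 panels: one-way ANOVA computed
## from sums of squares (so published mean/SD/n triples are first-class
## input) and Dunnett-style many-to-one comparisons against wild type with
## Monte-Carlo adjusted p values.

# Normalize group input into a summary data.frame (label, mean, sd, n).
# Accepts replicate form (label, value) or summary form (label, mean, sd, n).
as_group_summary <- function(groups) {
  stopifnot(is.data.frame(groups))
  if (all(c("label", "value") %in% names(groups))) {
    sp <- split(groups$value, groups$label)
    out <- data.frame(
      label = names(sp),
      mean = vapply(sp, mean, numeric(1)),
      sd = vapply(sp, sd, numeric(1)),
      n = vapply(sp, length, numeric(1)))
    rownames(out) <- NULL
    return(out)
  }
  if (all(c("label", "mean", "sd", "n") %in% names(groups)))
    return(groups[, c("label", "mean", "sd", "n")])
  stop("groups must have columns (label, value) or (label, mean, sd, n)")
}

#' One-way ANOVA from replicates or summary triples
#'
#' Between- and within-group sums of squares are reconstructed from group
#' means, SDs and sizes (`SSB = sum n_i (m_i - m)^2`,
#' `SSW = sum (n_i - 1) s_i^2`), so the test is computable from a published
#' summary table as well as from raw replicates; the two routes agree
#' exactly.
#'
#' @param groups data.frame in replicate form (`label`, `value`) or summary
#'   form (`label`, `mean`, `sd`, `n`)
#' @return list with `f`, `df_between`, `df_within`, `p`
#' @export
oneWayAnova <- function(groups) {
  g <- as_group_summary(groups)
  if (nrow(g) < 2L) stop("need >= 2 groups")
  if (any(g$n < 2))
    stop(sprintf("every group needs n >= 2; offending group(s): %s",
                 paste(g$label[g$n < 2], collapse = ", ")))
  N <- sum(g$n)
  grand <- sum(g$n * g$mean) / N
  ssb <- sum(g$n * (g$mean - grand)^2)
  ssw <- sum((g$n - 1) * g$sd^2)
  df1 <- nrow(g) - 1L
  df2 <- N - nrow(g)
  msb <- ssb / df1
  msw <- ssw / df2
  f <- if (msw == 0) {
    if (msb == 0) 0 else Inf
  } else msb / msw
  list(f = f, df_between = df1, df_within = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# Monte-Carlo sample of the Dunnett max-|t| null statistic for a design with
# comparison-group sizes `ns`, control size `n0` and pooled-variance df `df`.
dunnett_max_t_sample <- function(ns, n0, df, nsim, seed) {
  with_seed(seed, {
    k <- length(ns)
    m0 <- rnorm(nsim, 0, sqrt(1 / n0))
    s2 <- rchisq(nsim, df) / df
    tmax <- rep(0, nsim)
    for (j in seq_len(k)) {
      mj <- rnorm(nsim, 0, sqrt(1 / ns[j]))
      tj <- abs(mj - m0) / sqrt(s2 * (1 / ns[j] + 1 / n0))
      tmax <- pmax(tmax, tj)
    }
    tmax
  })
}

#' Monte-Carlo Dunnett critical value
#'
#' Two-sided critical value of the max-|t| statistic over `length(ns)`
#' many-to-one comparisons sharing one pooled variance estimate, from a
#' seeded Monte-Carlo sample of the null (equicorrelated multivariate t;
#' correlation 1/2 in balanced designs, plug-in correlations otherwise).
#'
#' @param ns comparison-group sizes
#' @param n0 control-group size
#' @param df pooled-variance degrees of freedom
#' @param alpha two-sided family-wise error rate
#' @param nsim Monte-Carlo draws (default 1e5)
#' @param seed RNG seed
#' @return scalar critical value
#' @export
dunnettCritical <- function(ns, n0, df, alpha = 0.05, nsim = 1e5,
                            seed = 20260929L) {
  tmax <- dunnett_max_t_sample(ns, n0, df, nsim, seed)
  unname(stats::quantile(tmax, 1 - alpha, type = 8))
}

#' Dunnett many-to-one comparisons against a control
#'
#' Each group is compared with the control by a t statistic using the pooled
#' within-group variance of *all* groups (homoscedastic one-way model). The
#' family-wise adjusted p value of group i is `P(max_j |T_j| >= |t_i|)` under
#' the joint null, estimated from a seeded Monte-Carlo sample of the max-|t|
#' distribution; adjusted p values are monotone in |t| and never smaller
#' than the unadjusted two-sided p. With a single comparison the adjusted p
#' equals the pooled two-sample t-test p exactly.
#'
#' @param groups data.frame in replicate or summary form (see
#'   [oneWayAnova()])
#' @param control label of the control (e.g. `"WT"`)
#' @param alpha significance level for the `significant` flags
#' @param nsim Monte-Carlo draws
#' @param seed RNG seed for the Monte-Carlo null
#' @return data.frame with one row per non-control group: `label`, `diff`
#'   (mean - control mean), `t`, `p_unadjusted`, `p_adjusted`, `significant`
#' @export
dunnettVsControl <- function(groups, control = "WT", alpha = 0.05,
                             nsim = 1e5, seed = 20260929L) {
  g <- as_group_summary(groups)
  if (!control %in% g$label)
    stop(sprintf("control group '%s' not present", control))
  if (any(g$n < 2))
    stop(sprintf("every group needs n >= 2; offending group(s): %s",
                 paste(g$label[g$n < 2], collapse = ", ")))
  ctrl <- g[g$label == control, ]
  cmp <- g[g$label != control, ]
  if (nrow(cmp) == 0L) stop("no comparison groups")
  df <- sum(g$n) - nrow(g)
  s2p <- sum((g$n - 1) * g$sd^2) / df
  tt <- (cmp$mean - ctrl$mean) / sqrt(s2p * (1 / cmp$n + 1 / ctrl$n))
  p_un <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  if (nrow(cmp) == 1L) {
    p_adj <- p_un
  } else {
    tmax <- dunnett_max_t_sample(cmp$n, ctrl$n, df, nsim, seed)
    # empirical exceedance probability; pmax keeps the adjusted p >= the
    # marginal p despite Monte-Carlo noise
    p_adj <- pmax(vapply(abs(tt), function(t0) mean(tmax >= t0), numeric(1)),
                  p_un)
  }
  data.frame(label = cmp$label, diff = cmp$mean - ctrl$mean, t = tt,
             p_unadjusted = p_un, p_adjusted = p_adj,
             significant = p_adj < alpha, row.names = NULL)
}
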