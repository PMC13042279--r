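## ------------------------------------------------------------------
## Phenotype statistics: 2^-ddCt relative qPCR quantification,
## Kaplan-Meier / Mantel-Cox lifespan comparison with mean-lifespan
## change, and heat-shock viability t-tests.
## ------------------------------------------------------------------

#' Relative expression by the 2^-ddCt method
#'
#' Per (sample, target): `dCt = Ct_target - Ct_housekeeping`;
#' `ddCt = dCt - mean(dCt over the reference-group samples)` for that
#' target; `fold = 2^-ddCt`. Folds are invariant to any per-sample
#' additive Ct shift applied to both target and housekeeping rows.
#'
#' @param ct data.frame with columns `sample`, `genotype`, `target`,
#'   `ct` (one housekeeping row per sample, identified by
#'   `housekeeping`).
#' @param reference_group genotype used as the calibrator (default
#'   `"WT"`).
#' @param housekeeping housekeeping gene id (a configuration value, e.g.
#'   `"cdc-42"`; never assumed).
#' @return data.frame `sample`, `genotype`, `target`, `dct`, `ddct`,
#'   `fold`.
#' @export
ddct <- function(ct, reference_group = "WT", housekeeping) {
  need <- c("sample", "genotype", "target", "ct")
  if (!all(need %in% names(ct)))
    stop_config("ct table must have columns %s", paste(need, collapse = ", "))
  hk <- ct[ct$target == housekeeping, , drop = FALSE]
  tg <- ct[ct$target != housekeeping, , drop = FALSE]
  if (nrow(hk) == 0L) stop_config("no housekeeping ('%s') rows", housekeeping)
  miss <- setdiff(unique(tg$sample), unique(hk$sample))
  if (length(miss) > 0L)
    stop_config("missing housekeeping Ct for sample(s): %s",
                paste(miss, collapse = ", "))
  hk_ct <- tapply(hk$ct, hk$sample, mean)
  tg$dct <- tg$ct - as.vector(hk_ct[tg$sample])
  out <- do.call(rbind, lapply(split(tg, tg$target), function(d) {
    ref <- d$genotype == reference_group
    if (!any(ref))
      stop_config("no reference-group ('%s') samples for target '%s'",
                  reference_group, d$target[1])
    d$ddct <- d$dct - mean(d$dct[ref])
    d$fold <- 2^(-d$ddct)
    d
  }))
  rownames(out) <- NULL
  out[, c("sample", "genotype", "target", "dct", "ddct", "fold")]
}

#' Kaplan-Meier curves, Mantel-Cox log-rank test and mean-lifespan change
#'
#' Product-limit curves and the Mantel-Cox (log-rank) chi-squared via
#' the `survival` package. "Mean lifespan" is reported two ways: the
#' KM-restricted mean (truncated at the last observed death) and the
#' arithmetic mean of uncensored death days; the headline percent
#' change uses the restricted mean.
#'
#' @param records data.frame with columns `group`, `day` (integer >= 0)
#'   and `event` (`"death"` or `"censored"`).
#' @param group_a,group_b the two groups to compare (percent change is
#'   of `group_b` relative to `group_a`).
#' @return list: `fit` (a `survfit`), `chisq`, `p_value`,
#'   `mean_restricted`, `mean_uncensored` (named by group),
#'   `percent_change`, `percent_change_uncensored`.
#' @export
km_logrank <- function(records, group_a, group_b) {
  d <- records[records$group %in% c(group_a, group_b), , drop = FALSE]
  if (any(d$day < 0)) stop_config("event days must be >= 0")
  status <- as.integer(d$event == "death")
  for (g in c(group_a, group_b))
    if (sum(status[d$group == g]) == 0L)
      stop_config("group '%s' has no deaths; log-rank undefined", g)
  grp <- factor(d$group, levels = c(group_a, group_b))
  sv <- survival::Surv(d$day, status)
  sd <- survival::survdiff(sv ~ grp)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(sv ~ grp)
  tmax <- max(d$day[status == 1L])
  tab <- summary(fit, rmean = tmax)$table
  rmean <- tab[, "rmean"]
  names(rmean) <- sub("^grp=", "", rownames(tab))
  rmean <- rmean[c(group_a, group_b)]
  muncens <- c(mean(d$day[status == 1L & d$group == group_a]),
               mean(d$day[status == 1L & d$group == group_b]))
  names(muncens) <- c(group_a, group_b)
  list(fit = fit, chisq = unname(chisq), p_value = unname(p),
       mean_restricted = rmean, mean_uncensored = muncens,
       percent_change = unname(100 * (rmean[2] - rmean[1]) / rmean[1]),
       percent_change_uncensored =
         unname(100 * (muncens[2] - muncens[1]) / muncens[1]))
}

#' Heat-shock viability comparison
#'
#' Replicate-level survival percentages compared with an unpaired
#' two-tailed t-test (equal variance by default; `welch = TRUE` for the
#' Welch variant).
#'
#' @param table data.frame with columns `replicate`, `group`,
#'   `exposed`, `alive` (0 <= alive <= exposed); exactly two groups.
#' @param welch use the Welch t-test (default `FALSE`).
#' @return list: `means` (per-group mean percentage), `t`, `df`,
#'   `p_value`, `percentages` (per replicate).
#' @export
viability_test <- function(table, welch = FALSE) {
  if (any(table$alive < 0 | table$alive > table$exposed))
    stop_config("alive must lie in [0, exposed]")
  gl <- unique(table$group)
  if (length(gl) != 2L) stop_config("exactly two groups required")
  pct <- 100 * table$alive / table$exposed
  a <- pct[table$group == gl[1]]; b <- pct[table$group == gl[2]]
  if (length(a) < 2L || length(b) < 2L)
    stop_config("need >= 2 replicates per group")
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(means = stats::setNames(c(mean(a), mean(b)), gl),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       percentages = data.frame(group = table$group,
                                replicate = table$replicate, pct = pct))
}
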