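## ------------------------------------------------------------------
## Phenotype-side simulators: censored lifespan records and qPCR Ct
## tables with recorded ground truth.
## ------------------------------------------------------------------

#' Simulate a censored lifespan assay
#'
#' Death times are Weibull; a second group's hazard is scaled by
#' `hazard_ratio` (proportional hazards; a ratio < 1 means the second
#' group lives longer). Each animal is independently censored with
#' probability `censor_rate` at a uniform day before its death, with a
#' censor reason drawn from the classic worm set (rupture, bagging,
#' walling, other). Days are integer (ceiling). Defaults encode the
#' study conditions: 150 animals per group, wild-type scale 17 days,
#' shape 4, and a mutant hazard ratio of `1.1475^-4` so the mutant mean
#' lifespan is 14.75% longer.
#'
#' @param n_per_group animals per group (default 150).
#' @param hazard_params list with `shape`, `scale` (wild-type Weibull
#'   scale in days) and `hazard_ratio` for the second group.
#' @param censor_rate per-animal censoring probability in `[0, 1)`.
#' @param seed integer seed.
#' @param groups two group labels.
#' @return data.frame of class `"survival_records"`: `animal`, `group`,
#'   `day`, `event` (`"death"`/`"censored"`), `reason` (`NA` for
#'   deaths).
#' @export
simulate_survival <- function(n_per_group = 150L,
                              hazard_params = list(shape = 4, scale = 17,
                                                   hazard_ratio = 1.1475^-4),
                              censor_rate = 0.1, seed = 1L,
                              groups = c("WT", "nova1")) {
  if (n_per_group < 1L) stop_config("n_per_group must be >= 1")
  if (censor_rate < 0 || censor_rate >= 1)
    stop_config("censor_rate must lie in [0, 1)")
  shape <- hazard_params$shape %||% 4
  scale <- hazard_params$scale %||% 17
  hr <- hazard_params$hazard_ratio %||% 1
  if (shape <= 0 || scale <= 0 || hr <= 0)
    stop_config("invalid hazard parameters")
  withr::with_seed(as.integer(seed), {
    scales <- c(scale, scale * hr^(-1 / shape))
    rows <- lapply(1:2, function(k) {
      t_death <- stats::rweibull(n_per_group, shape = shape,
                                 scale = scales[k])
      cens <- stats::runif(n_per_group) < censor_rate
      t_obs <- ifelse(cens, stats::runif(n_per_group) * t_death, t_death)
      data.frame(
        animal = paste0(groups[k], "_", seq_len(n_per_group)),
        group = groups[k],
        day = pmax(1L, as.integer(ceiling(t_obs))),
        event = ifelse(cens, "censored", "death"),
        reason = ifelse(cens,
                        sample(c("rupture", "bagging", "walling", "other"),
                               n_per_group, replace = TRUE),
                        NA_character_),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("survival_records", "data.frame")
    out
  })
}

#' Simulate an RT-qPCR Ct table with known fold changes
#'
#' Each sample gets one housekeeping Ct and one Ct per target; the
#' non-reference genotype's target Ct is shifted by `-log2(fold)` so
#' that the 2^-ddCt method recovers the configured fold change exactly
#' at zero noise.
#'
#' @param targets data.frame with columns `target` and `true_fc`
#'   (mutant/WT fold change).
#' @param genotypes two genotype labels (first = reference).
#' @param n_reps biological replicates per genotype (default 3).
#' @param housekeeping housekeeping gene id (default `"cdc-42"`).
#' @param noise_sd per-well Gaussian Ct noise (default 0.15 cycles; 0
#'   for exact recovery).
#' @param base_ct baseline target dCt relative to housekeeping
#'   (default 4).
#' @param hk_ct housekeeping Ct level (default 15).
#' @param seed integer seed.
#' @return data.frame of class `"ct_table"`: `sample`, `genotype`,
#'   `target`, `ct`, `replicate`, `housekeeping` (flag), with the truth
#'   in attribute `truth`.
#' @export
simulate_ct <- function(targets, genotypes = c("WT", "nova1"), n_reps = 3L,
                        housekeeping = "cdc-42", noise_sd = 0.15,
                        base_ct = 4, hk_ct = 15, seed = 1L) {
  stopifnot(is.data.frame(targets), all(c("target", "true_fc") %in%
                                          names(targets)))
  if (length(genotypes) < 2L) stop_config("need >= 2 genotypes")
  if (nrow(targets) < 1L) stop_config("need >= 1 target")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (g in genotypes) {
      for (r in seq_len(n_reps)) {
        smp <- paste0(g, "_", r)
        hk <- hk_ct + stats::rnorm(1, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp, genotype = g, target = housekeeping, ct = hk,
          replicate = r, housekeeping = TRUE, stringsAsFactors = FALSE)
        for (i in seq_len(nrow(targets))) {
          shift <- if (g == genotypes[1]) 0 else -log2(targets$true_fc[i])
          rows[[length(rows) + 1L]] <- data.frame(
            sample = smp, genotype = g, target = targets$target[i],
            ct = hk + base_ct + shift + stats::rnorm(1, 0, noise_sd),
            replicate = r, housekeeping = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- targets
    class(out) <- c("ct_table", "data.frame")
    out
  })
}
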