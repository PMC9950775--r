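# Ground-truth condition profiles: the per-condition true PSI of every
# planted event, gene baseline expression, and the planted transcriptional
# effects used to emulate the retrograde expression response.

#' Build the ground-truth table for a set of conditions
#'
#' Maps planted event regulation onto true per-condition PSI values:
#' retrograde treatments shift PSI by `s * delta * r` (with `r` the
#' condition's retrograde factor, 0.5 in a gun1-like genotype), and within
#' the light experiment the light term `-s * delta * lambda` is applied to
#' light-antagonistic events when the condition is light-grown or is
#' dark-grown with inactive PIFs (which mimics light). Values falling
#' outside \[0, 100\] are clipped and counted in `clip_warnings`.
#'
#' Also draws per-gene baseline expression (cRPKM scale, lognormal), a
#' planted transcriptional NF effect (enriched among genes carrying
#' repressive events), and a subcellular localization (chloroplast-enriched
#' among repressive-event genes).
#'
#' @param annotation an `as_annotation` from [generate_annotation()].
#' @param profiles condition grid, see [condition_profiles()].
#' @param params generator parameters, see [sim_params()].
#' @param seed integer seed.
#' @return list of class `as_truth` with elements `events` (event-level
#'   truth: psi0, s, delta, light_antagonistic, NMD flags, host-exon PSI),
#'   `psi` (event x condition matrix of true PSI), `genes` (baseline
#'   expression, planted expression sign, localization), `profiles`,
#'   `clip_warnings`, `params`.
#' @export
build_truth <- function(annotation, profiles = condition_profiles(params),
                        params = sim_params(), seed = 1L) {
  set.seed(seed + 1L)
  ev <- annotation$events
  n <- nrow(ev)
  s <- ifelse(ev$regulation == "up", 1L, ifelse(ev$regulation == "down",
                                                -1L, 0L))
  psi0 <- stats::runif(n, params$psi0_range[1], params$psi0_range[2])
  delta <- rep(params$delta, n)
  antagonistic <- s != 0 & stats::runif(n) < params$antagonistic_frac
  is_alt <- ev$event_type %in% c("ALT5", "ALT3")
  host_low <- is_alt & stats::runif(n) < params$host_low_frac
  host_psi0 <- ifelse(
    !is_alt, NA_real_,
    ifelse(host_low,
           stats::runif(n, params$host_psi_low_range[1],
                        params$host_psi_low_range[2]),
           stats::runif(n, params$host_psi_range[1],
                        params$host_psi_range[2])))
  stopifnot(all(psi0 + abs(s) * delta <= 100 | s <= 0),
            all(psi0 - abs(s) * delta >= 0 | s >= 0))

  clip <- 0L
  psi <- matrix(NA_real_, n, nrow(profiles),
                dimnames = list(ev$event_id, profiles$condition_id))
  for (j in seq_len(nrow(profiles))) {
    p <- profiles[j, ]
    val <- psi0
    if (p$treatment %in% c("NF", "lincomycin"))
      val <- val + s * delta * p$retrograde_factor
    light_on <- !is.na(p$light_state) &&
      (p$light_state == "light" ||
         (p$light_state == "dark" && isFALSE(p$pif_active)))
    if (light_on)
      val <- val - ifelse(antagonistic, s, 0L) * delta * params$lambda_light
    out <- val < 0 | val > 100
    clip <- clip + sum(out)
    psi[, j] <- pmin(100, pmax(0, val))
  }
  if (clip > 0)
    warning(clip, " true PSI value(s) clipped to [0,100]")

  # event-level repressive flag implied by the planted direction
  repressive <- (s == 1L & ev$nmd_on_inclusion) |
    (s == -1L & ev$nmd_on_exclusion)

  genes <- annotation$genes[, c("gene_id", "mappable_length")]
  genes$baseline_expression <- stats::rlnorm(
    nrow(genes), params$expr_lnorm[["meanlog"]], params$expr_lnorm[["sdlog"]])
  rep_gene <- genes$gene_id %in% ev$gene_id[repressive]
  p_down <- ifelse(rep_gene, params$p_expr_down_repressive,
                   params$p_expr_down_other)
  u <- stats::runif(nrow(genes))
  genes$expr_s <- ifelse(u < p_down, -1L, ifelse(u < p_down + 0.05, 1L, 0L))
  genes$expr_fold <- params$expr_fold
  p_chl <- ifelse(rep_gene, params$p_chloro_repressive,
                  params$p_chloro_other)
  u2 <- stats::runif(nrow(genes))
  genes$localization <- ifelse(
    u2 < p_chl, "chloroplast",
    sample(c("nucleus", "cytosol", "mitochondrion", "unknown"),
           nrow(genes), TRUE, c(0.35, 0.35, 0.15, 0.15)))

  events <- cbind(ev[, c("event_id", "gene_id", "event_type", "region",
                         "category", "nmd_on_inclusion", "nmd_on_exclusion",
                         "regulation")],
                  data.frame(psi0 = psi0, s = s, delta = delta,
                             light_antagonistic = antagonistic,
                             repressive = repressive,
                             host_psi0 = host_psi0))
  structure(list(events = events, psi = psi, genes = genes,
                 profiles = profiles, clip_warnings = clip, params = params),
            class = "as_truth")
}

#' @export
print.as_truth <- function(x, ...) {
  cat("AS ground truth:", nrow(x$events), "events x",
      nrow(x$profiles), "conditions;",
      sum(x$events$s != 0), "regulated,",
      sum(x$events$repressive), "repressive\n")
  invisible(x)
}
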