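# Threshold-based differential splicing / expression calling with the full
# filter cascade: coverage-tier discard, IR junction-balance binomial test,
# ALT host-exon minimum use, strict |dPSI| magnitude; joint count/cRPKM
# expression filter and the per-replicate-pair fold-change rule. No
# multiple-testing correction is applied anywhere: the caller is built on
# fixed thresholds, not FDR.

#' Exact binomial balance test of the two IR exon-intron junctions
#'
#' Two-sided exact binomial p-value for observing `inc_j1` reads at one
#' exon-intron junction out of `inc_j1 + inc_j2` at rate 0.5. IR events
#' with p below the threshold (default 0.05) are considered imbalanced and
#' fail the IR filter. A zero total makes the test inapplicable: the event
#' is retained on this filter (p = NA).
#'
#' @param inc_j1,inc_j2 junction read counts (vectorised).
#' @return two-sided p-values; NA where the total is zero.
#' @export
ir_balance_test <- function(inc_j1, inc_j2) {
  if (any(c(inc_j1, inc_j2) < 0, na.rm = TRUE))
    stop("junction counts must be non-negative")
  mapply(function(a, b) {
    if (is.na(a) || is.na(b) || a + b == 0) return(NA_real_)
    stats::binom.test(a, a + b, p = 0.5)$p.value
  }, round(inc_j1), round(inc_j2))
}

#' Host-exon minimum-use filter for ALT5/ALT3 events
#'
#' An ALT event is only evaluated if its host exon reaches a minimum PSI
#' (default 25, inclusive) in each compared (merged) sample. Missing host
#' PSI fails the filter.
#'
#' @param host_psi_a,host_psi_b host-exon PSI in the two merged samples.
#' @param min_alt_use minimum host-exon PSI.
#' @return logical pass/fail (vectorised).
#' @export
alt_use_filter <- function(host_psi_a, host_psi_b, min_alt_use = 25) {
  !is.na(host_psi_a) & !is.na(host_psi_b) &
    host_psi_a >= min_alt_use & host_psi_b >= min_alt_use
}

#' Call differentially spliced events between two merged samples
#'
#' The filter cascade: events tiered in `discard_tiers` (default N, VLOW)
#' in either sample are discarded; IR events failing the junction-balance
#' binomial test (p < `p_ir`) in either sample are discarded; ALT5/ALT3
#' events need host-exon PSI >= `min_alt_use` in both samples. Surviving
#' events are called differentially spliced iff `|dPSI| > min_dpsi`
#' (strictly; dPSI = psi_b - psi_a). Events passing every non-magnitude
#' filter but not the strict threshold form the non-regulated control set.
#'
#' @param qa,qb merged-sample quantifications from [merge_replicates()]
#'   (one condition each), sharing the same event universe.
#' @param config pipeline configuration, see [default_config()]; only
#'   `config$thresholds` is used.
#' @return data.frame per event: psi_a, psi_b, dpsi, per-filter flags,
#'   `called`, `direction` (up/down/none) and `control`.
#' @export
call_diff_splicing <- function(qa, qb, config = default_config()) {
  th <- config$thresholds
  if (!setequal(qa$event_id, qb$event_id)) {
    diff <- c(setdiff(qa$event_id, qb$event_id),
              setdiff(qb$event_id, qa$event_id))
    stop("event universe mismatch between samples: ",
         paste(utils::head(diff, 10), collapse = ", "))
  }
  qa <- qa[order(qa$event_id), ]
  qb <- qb[match(qa$event_id, qb$event_id), ]
  res <- data.frame(event_id = qa$event_id, event_type = qa$event_type,
                    psi_a = qa$psi, psi_b = qb$psi,
                    stringsAsFactors = FALSE)
  res$dpsi <- res$psi_b - res$psi_a

  res$coverage_pass <- !(qa$tier %in% th$discard_tiers) &
    !(qb$tier %in% th$discard_tiers)

  is_ir <- res$event_type == "IR"
  p_a <- rep(NA_real_, nrow(res)); p_b <- rep(NA_real_, nrow(res))
  p_a[is_ir] <- ir_balance_test(qa$inc_j1[is_ir], qa$inc_j2[is_ir])
  p_b[is_ir] <- ir_balance_test(qb$inc_j1[is_ir], qb$inc_j2[is_ir])
  res$ir_balance_p_a <- p_a
  res$ir_balance_p_b <- p_b
  res$ir_balance_pass <- !is_ir |
    ((is.na(p_a) | p_a >= th$p_ir) & (is.na(p_b) | p_b >= th$p_ir))

  is_alt <- res$event_type %in% c("ALT5", "ALT3")
  res$alt_use_pass <- !is_alt |
    alt_use_filter(qa$host_psi, qb$host_psi, th$min_alt_use)

  res$magnitude_pass <- !is.na(res$dpsi) & abs(res$dpsi) > th$min_dpsi
  pre <- res$coverage_pass & res$ir_balance_pass & res$alt_use_pass &
    !is.na(res$dpsi)
  res$called <- pre & res$magnitude_pass
  res$direction <- ifelse(!res$called, "none",
                          ifelse(res$dpsi > 0, "up", "down"))
  res$control <- pre & !res$magnitude_pass
  res
}

#' Call differentially expressed genes from replicate cRPKM/count tables
#'
#' Expression filter (joint count/cRPKM rule): under the default parse a
#' gene is kept iff at least one of the two samples has every replicate
#' passing (count >= `min_count` OR cRPKM > `min_crpkm`); under the
#' alternate parse (`expr_filter_parse = "any_sample_all_fail"`) it is
#' removed iff some sample has every replicate failing both. Kept genes
#' are called differentially expressed iff every cross-sample replicate
#' pair shows a fold change of at least `min_fc` in a consistent
#' direction, computed on (normalized) cRPKM with pseudocount
#' `pseudocount`.
#'
#' @param counts_a,counts_b gene x replicate count matrices.
#' @param crpkm_a,crpkm_b gene x replicate cRPKM matrices (quantile-
#'   normalized upstream when following the standard workflow).
#' @param config pipeline configuration, see [default_config()].
#' @return data.frame per gene: expressed_pass, min_fc (minimum pairwise
#'   magnitude in the consistent direction), called, direction.
#' @export
call_diff_expression <- function(counts_a, counts_b, crpkm_a, crpkm_b,
                                 config = default_config()) {
  th <- config$thresholds
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  crpkm_a <- as.matrix(crpkm_a); crpkm_b <- as.matrix(crpkm_b)
  stopifnot(identical(rownames(counts_a), rownames(counts_b)),
            identical(rownames(counts_a), rownames(crpkm_a)),
            identical(rownames(counts_a), rownames(crpkm_b)))
  pass_a <- counts_a >= th$min_count | crpkm_a > th$min_crpkm
  pass_b <- counts_b >= th$min_count | crpkm_b > th$min_crpkm
  if (identical(th$expr_filter_parse, "any_sample_all_fail")) {
    kept <- !(rowSums(pass_a) == 0 | rowSums(pass_b) == 0)
  } else {
    kept <- rowSums(!pass_a) == 0 | rowSums(!pass_b) == 0
  }
  eps <- th$pseudocount
  n <- nrow(counts_a)
  ratio_min <- numeric(n); ratio_max <- numeric(n)
  for (i in seq_len(n)) {
    r <- outer(crpkm_a[i, ] + eps, crpkm_b[i, ] + eps,
               function(a, b) b / a)
    ratio_min[i] <- min(r); ratio_max[i] <- max(r)
  }
  up <- ratio_min >= th$min_fc
  down <- ratio_max <= 1 / th$min_fc
  res <- data.frame(gene_id = rownames(counts_a),
                    expressed_pass = kept,
                    fc_min_up = ratio_min, fc_max_down = ratio_max,
                    called = kept & (up | down),
                    direction = ifelse(up, "up",
                                       ifelse(down, "down", "none")),
                    stringsAsFactors = FALSE)
  res$direction[!res$called] <- "none"
  rownames(res) <- NULL
  res
}

#' Percent of the wild-type response retained in a mutant
#'
#' `R = 100 * mut_delta / wt_delta`, on dPSI or log2 fold-change scale;
#' undefined (NA, excluded from summaries) when the WT delta is zero.
#' Over-reversal (opposite signs) is preserved, not clipped.
#'
#' @param wt_delta,mut_delta response magnitudes (vectorised).
#' @return list with per-item `R` and `median`/`mean` summaries over the
#'   defined values.
#' @export
percent_response <- function(wt_delta, mut_delta) {
  R <- ifelse(!is.na(wt_delta) & wt_delta != 0,
              100 * mut_delta / wt_delta, NA_real_)
  list(R = R,
       median = stats::median(R, na.rm = TRUE),
       mean = mean(R, na.rm = TRUE),
       n = sum(!is.na(R)))
}

#' Project called events onto a second comparison
#'
#' For each event called in a first comparison, reports its dPSI in a
#' second pair of merged samples without re-filtering by magnitude;
#' coverage-tier filtering still applies (insufficient coverage in either
#' projected sample yields NA).
#'
#' @param called_ids event ids called in the reference comparison.
#' @param qa,qb merged-sample quantifications of the projection comparison.
#' @param config pipeline configuration.
#' @return named numeric vector of dPSI (psi_b - psi_a), NA where
#'   unresolvable or under-covered; names are the event ids.
#' @export
project_events <- function(called_ids, qa, qb, config = default_config()) {
  th <- config$thresholds
  ia <- match(called_ids, qa$event_id)
  ib <- match(called_ids, qb$event_id)
  unresolved <- sum(is.na(ia) | is.na(ib))
  if (unresolved > 0)
    message(unresolved, " projected event id(s) unresolvable in the ",
            "second dataset")
  dpsi <- qb$psi[ib] - qa$psi[ia]
  bad <- qa$tier[ia] %in% th$discard_tiers |
    qb$tier[ib] %in% th$discard_tiers
  dpsi[bad] <- NA_real_
  stats::setNames(dpsi, called_ids)
}
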