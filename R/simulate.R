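# Replicate-level read-count simulation: Poisson depth x binomial inclusion
# for junction reads, Poisson gene counts with an NMD survival factor.

# effective inclusion fraction after NMD steady-state decay: the abundance
# of a PTC-bearing isoform is multiplied by (1 - d * eta) before PSI is
# formed
.effective_psi <- function(psi, nmd_inc, nmd_exc, d, eta) {
  surv_inc <- ifelse(nmd_inc, 1 - d * eta, 1)
  surv_exc <- ifelse(nmd_exc, 1 - d * eta, 1)
  inc <- psi / 100 * surv_inc
  exc <- (1 - psi / 100) * surv_exc
  tot <- inc + exc
  ifelse(tot > 0, 100 * inc / tot, 0)
}

.draw_depth <- function(n, depth, overdispersion) {
  if (overdispersion > 0) {
    lambda <- stats::rgamma(n, shape = 1 / overdispersion,
                            rate = 1 / (overdispersion * depth))
    stats::rpois(n, lambda)
  } else {
    stats::rpois(n, depth)
  }
}

#' Simulate per-replicate junction read counts
#'
#' For every event, condition and replicate: total informative reads
#' `n ~ Poisson(depth)`; inclusion-supporting reads
#' `inc ~ Binomial(n, p_eff / 100)` where `p_eff` is the true PSI after
#' NMD steady-state decay of PTC-bearing isoforms (decay fraction
#' `params$d_decay` scaled by the condition's NMD efficiency). For IR
#' events the inclusion support is observed at the two exon-intron
#' junctions as a `Binomial(2 * inc, 0.5)` split, so that the mean of the
#' two junction counts equals the inclusion support exactly. ALT events
#' additionally receive host-exon inclusion/exclusion counts at the
#' planted host PSI.
#'
#' @param truth an `as_truth` object from [build_truth()].
#' @param profiles conditions to simulate (default: those in `truth`).
#' @param params generator parameters.
#' @param seed integer seed.
#' @return long data.frame: event_id, event_type, condition, replicate,
#'   sample_id, inc, exc, inc_j1, inc_j2, host_inc, host_exc.
#' @export
simulate_junction_reads <- function(truth, profiles = truth$profiles,
                                    params = truth$params, seed = 1L) {
  set.seed(seed + 2L)
  ev <- truth$events
  out <- vector("list", nrow(profiles))
  for (j in seq_len(nrow(profiles))) {
    p <- profiles[j, ]
    psi <- truth$psi[ev$event_id, p$condition_id]
    p_eff <- .effective_psi(psi, ev$nmd_on_inclusion, ev$nmd_on_exclusion,
                            params$d_decay, p$nmd_efficiency)
    reps <- lapply(seq_len(p$n_replicates), function(r) {
      n <- .draw_depth(nrow(ev), p$depth, params$overdispersion)
      inc <- stats::rbinom(nrow(ev), n, p_eff / 100)
      exc <- n - inc
      is_ir <- ev$event_type == "IR"
      j1 <- rep(NA_integer_, nrow(ev)); j2 <- j1
      j1[is_ir] <- stats::rbinom(sum(is_ir), 2L * inc[is_ir], 0.5)
      j2[is_ir] <- 2L * inc[is_ir] - j1[is_ir]
      is_alt <- ev$event_type %in% c("ALT5", "ALT3")
      m <- rep(NA_integer_, nrow(ev)); h_inc <- m; h_exc <- m
      m[is_alt] <- .draw_depth(sum(is_alt), p$depth, params$overdispersion)
      h_inc[is_alt] <- stats::rbinom(sum(is_alt), m[is_alt],
                                     ev$host_psi0[is_alt] / 100)
      h_exc[is_alt] <- m[is_alt] - h_inc[is_alt]
      data.frame(event_id = ev$event_id, event_type = ev$event_type,
                 condition = p$condition_id, replicate = r,
                 sample_id = paste0(p$condition_id, "_r", r),
                 inc = inc, exc = exc, inc_j1 = j1, inc_j2 = j2,
                 host_inc = h_inc, host_exc = h_exc,
                 stringsAsFactors = FALSE)
    })
    out[[j]] <- do.call(rbind, reps)
  }
  do.call(rbind, out)
}

#' Simulate per-replicate gene read counts
#'
#' Expected count is proportional to baseline expression, the planted
#' transcriptional fold change under retrograde treatment (attenuated by
#' the condition's retrograde factor), the NMD isoform-survival factor
#' (PSI-weighted mass of isoforms remaining after decay), the gene's
#' mappable length and the library size; counts are Poisson.
#'
#' @inheritParams simulate_junction_reads
#' @return long data.frame: gene_id, condition, replicate, sample_id,
#'   count, mappable_length.
#' @export
simulate_gene_counts <- function(truth, profiles = truth$profiles,
                                 params = truth$params, seed = 1L) {
  set.seed(seed + 3L)
  genes <- truth$genes
  ev <- truth$events
  ev_by_gene <- split(seq_len(nrow(ev)), ev$gene_id)
  out <- vector("list", nrow(profiles))
  for (j in seq_len(nrow(profiles))) {
    p <- profiles[j, ]
    # NMD survival factor per gene, from its event's PSI in this condition
    surv <- rep(1, nrow(genes))
    names(surv) <- genes$gene_id
    idx <- match(names(ev_by_gene), genes$gene_id)
    for (g in seq_along(ev_by_gene)) {
      i <- ev_by_gene[[g]][1]
      psi <- truth$psi[ev$event_id[i], p$condition_id] / 100
      d_eff <- params$d_decay * p$nmd_efficiency
      surv[idx[g]] <- psi * ifelse(ev$nmd_on_inclusion[i], 1 - d_eff, 1) +
        (1 - psi) * ifelse(ev$nmd_on_exclusion[i], 1 - d_eff, 1)
    }
    fc <- rep(1, nrow(genes))
    if (p$treatment %in% c("NF", "lincomycin"))
      fc <- genes$expr_fold ^ (genes$expr_s * p$retrograde_factor)
    expected <- genes$baseline_expression * fc * surv *
      (genes$mappable_length / 1e3) * (params$library_size / 1e6)
    reps <- lapply(seq_len(p$n_replicates), function(r) {
      data.frame(gene_id = genes$gene_id, condition = p$condition_id,
                 replicate = r,
                 sample_id = paste0(p$condition_id, "_r", r),
                 count = stats::rpois(nrow(genes), expected),
                 mappable_length = genes$mappable_length,
                 stringsAsFactors = FALSE)
    })
    out[[j]] <- do.call(rbind, reps)
  }
  do.call(rbind, out)
}
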