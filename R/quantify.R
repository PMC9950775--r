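# PSI quantification from junction reads, coverage tiers, replicate
# pooling, and cRPKM expression with quantile normalization.

#' Percent spliced in from junction read counts
#'
#' `psi = 100 * inc / (inc + exc)`; undefined (NA, never 0) when both
#' counts are zero. For IR events the caller supplies `inc` as the mean of
#' the two exon-intron junction counts (see [psi_from_ir_junctions()]).
#'
#' @param inc,exc non-negative inclusion/exclusion junction read counts
#'   (vectorised).
#' @return numeric PSI in \[0, 100\], NA where inc + exc == 0.
#' @export
compute_psi <- function(inc, exc) {
  if (any(inc < 0, na.rm = TRUE) || any(exc < 0, na.rm = TRUE))
    stop("junction read counts must be non-negative")
  tot <- inc + exc
  ifelse(!is.na(tot) & tot > 0, 100 * inc / tot, NA_real_)
}

#' IR inclusion support and PSI from the two exon-intron junctions
#'
#' Inclusion support of a retained intron is the mean of its two
#' exon-intron junction counts; PSI is then formed against the exon-exon
#' (exclusion) junction count.
#'
#' @param inc_j1,inc_j2 exon-intron junction read counts.
#' @param exc exon-exon junction read count.
#' @return list with `inc` (mean junction support) and `psi`.
#' @export
psi_from_ir_junctions <- function(inc_j1, inc_j2, exc) {
  inc <- (inc_j1 + inc_j2) / 2
  list(inc = inc, psi = compute_psi(inc, exc))
}

#' Coverage quality tier of a PSI estimate
#'
#' Tiers the total junction read count into N / VLOW / LOW / OK / SOK.
#' Defaults: N below 5 reads, VLOW 5-9, LOW 10-14, OK 15-99, SOK >= 100.
#' Downstream, events tiered VLOW (or N) in either compared sample are
#' discarded by the differential caller.
#'
#' @param inc,exc junction read counts (vectorised).
#' @param tiers named numeric vector of lower bounds for VLOW/LOW/OK/SOK.
#' @return character vector of tiers, ordered factor levels
#'   N < VLOW < LOW < OK < SOK.
#' @export
score_coverage <- function(inc, exc,
                           tiers = c(VLOW = 5, LOW = 10, OK = 15,
                                     SOK = 100)) {
  n <- inc + exc
  labs <- c("N", names(tiers))
  labs[findInterval(n, tiers) + 1L]
}

#' Pool replicate junction counts of one sample group
#'
#' Counts are summed across replicates and PSI/tier recomputed from the
#' pooled counts (pooling, not averaging of per-replicate PSIs).
#'
#' @param junc long junction-count data.frame (as emitted by
#'   [simulate_junction_reads()]) for one or more conditions.
#' @param tiers tier bounds passed to [score_coverage()].
#' @return data.frame with one row per event and condition: pooled counts,
#'   `psi`, `tier`, and host-exon `host_psi` for ALT events.
#' @export
merge_replicates <- function(junc, tiers = c(VLOW = 5, LOW = 10, OK = 15,
                                             SOK = 100)) {
  if (length(unique(junc$event_id)) * length(unique(junc$condition)) == 0)
    stop("empty junction table")
  agg <- stats::aggregate(
    junc[, c("inc", "exc", "inc_j1", "inc_j2", "host_inc", "host_exc")],
    by = list(event_id = junc$event_id, event_type = junc$event_type,
              condition = junc$condition),
    FUN = function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE))
  is_ir <- agg$event_type == "IR"
  inc_eff <- ifelse(is_ir, (agg$inc_j1 + agg$inc_j2) / 2, agg$inc)
  agg$psi <- compute_psi(inc_eff, agg$exc)
  agg$tier <- score_coverage(inc_eff, agg$exc, tiers)
  agg$host_psi <- compute_psi(agg$host_inc, agg$host_exc)
  agg[order(agg$condition, agg$event_id), ]
}

#' Inclusion table: one PSI and one quality column per sample
#'
#' Wide, inclusion-table-like layout over merged samples.
#'
#' @param merged output of [merge_replicates()].
#' @return data.frame: event_id, event_type, then `<condition>` PSI and
#'   `<condition>.Q` tier columns.
#' @export
inclusion_table <- function(merged) {
  conds <- unique(merged$condition)
  base <- unique(merged[, c("event_id", "event_type")])
  base <- base[order(base$event_id), ]
  for (cn in conds) {
    sub <- merged[merged$condition == cn, ]
    base[[cn]] <- sub$psi[match(base$event_id, sub$event_id)]
    base[[paste0(cn, ".Q")]] <- sub$tier[match(base$event_id, sub$event_id)]
  }
  rownames(base) <- NULL
  base
}

#' Mappability-corrected RPKM
#'
#' `cRPKM = (count / (total mapped reads / 1e6)) / (mappable_length / 1e3)`
#' with the total taken per sample (column sums of the count matrix).
#'
#' @param counts gene x sample matrix of read counts.
#' @param mappable_length named vector of uniquely mappable positions per
#'   gene (nt), names matching `rownames(counts)`.
#' @return matrix of cRPKM values, same dimensions as `counts`.
#' @export
compute_crpkm <- function(counts, mappable_length) {
  counts <- as.matrix(counts)
  ml <- mappable_length[rownames(counts)]
  if (any(is.na(ml)))
    stop("missing mappable length for gene(s): ",
         paste(rownames(counts)[is.na(ml)], collapse = ", "))
  if (any(ml <= 0)) stop("mappable lengths must be positive")
  totals <- colSums(counts)
  out <- sweep(counts, 2, totals / 1e6, "/") / (ml / 1e3)
  out[counts == 0] <- 0          # zero iff count is zero, even at total 0
  out
}

#' Quantile normalization across samples
#'
#' Forces every column to share the same sorted value vector (the row-wise
#' mean of the sorted columns), ties averaged. Wraps
#' [limma::normalizeQuantiles()]; idempotent within floating tolerance.
#'
#' @param x numeric matrix with >= 2 columns (genes x samples).
#' @return normalized matrix of the same dimensions.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}
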