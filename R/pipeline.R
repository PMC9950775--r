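# End-to-end driver: generate synthetic data, quantify, call differential
# splicing/expression, classify ORF impact, extract features, and compute
# the convergence statistics. Every stage is also callable on its own.

.quant_condition <- function(merged, condition) {
  q <- merged[merged$condition == condition, ]
  if (nrow(q) == 0) stop("no quantification for condition ", condition)
  q
}

# merge a replicate subset of one condition (used to build a same-condition
# null comparison)
.merge_subset <- function(junc, condition, replicates, tiers) {
  sub <- junc[junc$condition == condition & junc$replicate %in% replicates, ]
  merge_replicates(sub, tiers)
}

.attrition <- function(diffres) {
  n <- nrow(diffres)
  cov <- sum(diffres$coverage_pass)
  irb <- sum(diffres$coverage_pass & diffres$ir_balance_pass)
  alt <- sum(diffres$coverage_pass & diffres$ir_balance_pass &
               diffres$alt_use_pass)
  called <- sum(diffres$called)
  data.frame(
    stage = c("input", "coverage", "ir_balance", "alt_use", "magnitude"),
    passed = c(n, cov, irb, alt, called),
    failed = c(0L, n - cov, cov - irb, irb - alt, alt - called))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates an annotation and ground truth, simulates junction and gene
#' counts under the default condition grid, quantifies PSI with replicate
#' pooling, calls NF-differential splicing and expression, computes the
#' gun1 percent-of-response, projects NF events onto the lincomycin and
#' light comparisons, classifies ORF impact and repressive events,
#' compares regulatory features of regulated vs control events, and
#' computes the enrichment / NMD-shift / light-antagonism statistics.
#' Identical seeds give identical outputs.
#'
#' @param config pipeline configuration, see [default_config()].
#' @param out_dir optional directory; when given, all stage tables and a
#'   YAML summary are written there.
#' @return list of class `as_pipeline` with all stage results and a
#'   `log` (per-filter attrition, clip warnings, seed registry).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  params <- config$generator
  seed <- config$seed

  ann <- generate_annotation(params$n_genes, params, seed = seed)
  profiles <- condition_profiles(params)
  truth <- build_truth(ann, profiles, params, seed = seed)
  junc <- simulate_junction_reads(truth, profiles, params, seed = seed)
  gene_counts <- simulate_gene_counts(truth, profiles, params, seed = seed)

  merged <- merge_replicates(junc, config$tiers)
  incl <- inclusion_table(merged)
  q <- function(cn) .quant_condition(merged, cn)

  # --- differential splicing: NF in WT, NF in gun1 ------------------------
  nf <- call_diff_splicing(q("wt_ctrl"), q("wt_nf"), config)
  gun1 <- call_diff_splicing(q("wt_ctrl"), q("gun1_nf"), config)
  light <- call_diff_splicing(q("wt_dark"), q("wt_light"), config)

  called_ids <- nf$event_id[nf$called]
  pr_splicing <- percent_response(
    nf$dpsi[match(called_ids, nf$event_id)],
    gun1$dpsi[match(called_ids, gun1$event_id)])

  # fraction of NF-regulated events lost in gun1 (|dPSI| < threshold)
  gun1_dpsi <- gun1$dpsi[match(called_ids, gun1$event_id)]
  frac_lost_gun1 <- mean(abs(gun1_dpsi) <= config$thresholds$min_dpsi,
                         na.rm = TRUE)

  linco_proj <- project_events(called_ids, q("wt_ctrl"), q("wt_linco"),
                               config)

  # --- differential expression under NF ----------------------------------
  cond_counts <- function(cn) {
    sub <- gene_counts[gene_counts$condition == cn, ]
    m <- do.call(cbind, lapply(split(sub, sub$replicate),
                               function(d) d$count[order(d$gene_id)]))
    rownames(m) <- sort(unique(sub$gene_id))
    colnames(m) <- paste0(cn, "_r", seq_len(ncol(m)))
    m
  }
  ml <- stats::setNames(ann$genes$mappable_length, ann$genes$gene_id)
  ca <- cond_counts("wt_ctrl"); cb <- cond_counts("wt_nf")
  cg <- cond_counts("gun1_nf")
  crpkm <- compute_crpkm(cbind(ca, cb, cg), ml)
  crpkm_n <- quantile_normalize(crpkm)
  na <- ncol(ca); nb <- ncol(cb)
  expr <- call_diff_expression(ca, cb,
                               crpkm_n[, seq_len(na)],
                               crpkm_n[, na + seq_len(nb)], config)
  eps <- config$thresholds$pseudocount
  l2fc <- function(m_ctrl, m_trt)
    log2((rowMeans(m_trt) + eps) / (rowMeans(m_ctrl) + eps))
  wt_l2 <- l2fc(crpkm_n[, seq_len(na)], crpkm_n[, na + seq_len(nb)])
  g1_l2 <- l2fc(crpkm_n[, seq_len(na)], crpkm_n[, na + nb + seq_len(nb)])
  expr_called <- expr$gene_id[expr$called]
  pr_expression <- percent_response(wt_l2[expr_called], g1_l2[expr_called])

  # --- ORF impact and repressive events -----------------------------------
  orf <- classify_orf_impacts(ann, config)
  nf_dir <- stats::setNames(nf$direction, nf$event_id)
  orf$nf_direction <- nf_dir[orf$event_id]
  orf$repressive <- classify_repressive(
    orf$category, ifelse(is.na(orf$nf_direction), "none", orf$nf_direction))

  universe_ids <- nf$event_id[nf$called | nf$control]
  group_of <- function(ids) {
    d <- nf_dir[ids]
    ifelse(d == "up", "up", ifelse(d == "down", "down", "control"))
  }

  # region percentages (UTR vs CDS) and category percentages per group
  region_of <- stats::setNames(orf$region, orf$event_id)
  cat_of <- stats::setNames(orf$category, orf$event_id)
  groups_u <- group_of(universe_ids)
  region_pct <- do.call(rbind, lapply(split(universe_ids, groups_u),
    function(ids) {
      r <- region_of[ids]
      data.frame(UTR5 = 100 * mean(r == "UTR5"),
                 CDS = 100 * mean(r == "CDS"),
                 UTR3 = 100 * mean(r == "UTR3"), n = length(ids))
    }))
  cat_pct <- lapply(split(universe_ids, groups_u), function(ids)
    category_percentages(cat_of[ids][region_of[ids] == "CDS"]))
  repressive_pct_called <- {
    cds_called <- called_ids[region_of[called_ids] == "CDS" &
                               !is.na(cat_of[called_ids]) &
                               cat_of[called_ids] != "degenerate"]
    100 * mean(classify_repressive(cat_of[cds_called], nf_dir[cds_called]))
  }

  # --- enrichment statistics ----------------------------------------------
  ev_gene <- stats::setNames(ann$events$gene_id, ann$events$event_id)
  universe_genes <- unique(ev_gene[universe_ids])
  as_genes <- unique(ev_gene[called_ids])
  repressive_genes <- unique(ev_gene[orf$event_id[orf$repressive]])
  enrich_utr <- fisher_enrichment(
    universe_ids[region_of[universe_ids] != "CDS"], called_ids,
    universe_ids)
  enrich_expr_down <- fisher_enrichment(
    repressive_genes, expr$gene_id[expr$called & expr$direction == "down"],
    universe_genes)
  loc <- stats::setNames(truth$genes$localization, truth$genes$gene_id)
  known <- universe_genes[loc[universe_genes] != "unknown"]
  enrich_chloro <- fisher_enrichment(
    intersect(repressive_genes, known),
    known[loc[known] == "chloroplast"], known)

  # --- NMD shift across upf genotypes -------------------------------------
  nmd_conds <- c("nmd_wt", "upf1", "upf3", "upf1upf3")
  psi_nmd <- sapply(nmd_conds, function(cn) {
    qq <- q(cn); qq$psi[match(universe_ids, qq$event_id)]
  })
  rownames(psi_nmd) <- universe_ids
  classes <- ifelse(universe_ids %in% orf$event_id[orf$repressive],
                    "repressive",
                    ifelse(cat_of[universe_ids] %in% "protein_isoform" &
                             universe_ids %in% called_ids,
                           "protein_isoform", NA))
  nmd_shift <- nmd_shift_analysis(psi_nmd, classes, wt = "nmd_wt",
                                  mutants = c("upf1", "upf3", "upf1upf3"))

  # --- light antagonism ----------------------------------------------------
  reps <- seq_len(params$n_replicates)
  odd <- reps[reps %% 2 == 1]; even <- reps[reps %% 2 == 0]
  q_dark_a <- .merge_subset(junc, "wt_dark", odd, config$tiers)
  q_dark_b <- .merge_subset(junc, "wt_dark", even, config$tiers)
  dpsi_by_cond <- list(
    wt_dark_null = project_events(called_ids, q_dark_a, q_dark_b, config),
    wt_light = project_events(called_ids, q("wt_dark"), q("wt_light"),
                              config),
    pifq_dark = project_events(called_ids, q("wt_dark"), q("pifq_dark"),
                               config),
    pifq_light = project_events(called_ids, q("wt_dark"), q("pifq_light"),
                                config))
  antagonism <- antagonism_summary(nf_dir[called_ids], dpsi_by_cond)

  # --- features -------------------------------------------------------------
  feats <- extract_features(ann, pwm_cfg = config$pwm)
  feat_cmp <- list()
  for (ty in c("IR", "ES")) {
    ids_ty <- universe_ids[ann$events$event_type[
      match(universe_ids, ann$events$event_id)] == ty]
    if (length(ids_ty) < 6) next
    sub <- feats[match(ids_ty, feats$event_id), ]
    feat_cmp[[ty]] <- compare_groups(sub, group_of(ids_ty))
  }

  log <- list(
    attrition_nf = .attrition(nf),
    attrition_light = .attrition(light),
    clip_warnings = truth$clip_warnings,
    seed = seed,
    n_events = nrow(ann$events),
    n_called_nf = length(called_ids),
    n_called_light = sum(light$called))

  res <- structure(list(
    annotation = ann, truth = truth, profiles = profiles,
    merged = merged, inclusion = incl,
    nf = nf, gun1 = gun1, light = light,
    percent_response_splicing = pr_splicing,
    percent_response_expression = pr_expression,
    frac_lost_gun1 = frac_lost_gun1,
    linco_projection = linco_proj,
    expression = expr,
    orf = orf,
    region_pct = region_pct, category_pct = cat_pct,
    repressive_pct_called = repressive_pct_called,
    enrichment = list(utr = enrich_utr, expr_down = enrich_expr_down,
                      chloroplast = enrich_chloro),
    nmd_shift = nmd_shift,
    antagonism = antagonism,
    features = feats, feature_comparison = feat_cmp,
    log = log, config = config), class = "as_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_annotation(ann, out_dir, truth = truth, junc = junc,
                     gene_counts = gene_counts)
    write_tsv_table(incl, file.path(out_dir, "inclusion_table.tsv"))
    write_tsv_table(nf, file.path(out_dir, "diff_splicing_nf.tsv"))
    write_tsv_table(gun1, file.path(out_dir, "diff_splicing_gun1.tsv"))
    write_tsv_table(light, file.path(out_dir, "diff_splicing_light.tsv"))
    write_tsv_table(expr, file.path(out_dir, "diff_expression_nf.tsv"))
    write_tsv_table(orf, file.path(out_dir, "orf_impact.tsv"))
    write_tsv_table(feats, file.path(out_dir, "features.tsv"))
    for (ty in names(feat_cmp))
      if (!is.null(feat_cmp[[ty]]))
        write_tsv_table(feat_cmp[[ty]],
                        file.path(out_dir, paste0("feature_comparison_",
                                                  ty, ".tsv")))
    if (!is.null(nmd_shift))
      write_tsv_table(nmd_shift, file.path(out_dir, "nmd_shift.tsv"))
    yaml::write_yaml(summary(res), file.path(out_dir, "summary.yaml"))
  }
  res
}

#' @export
summary.as_pipeline <- function(object, ...) {
  nf <- object$nf
  list(
    n_events = object$log$n_events,
    n_called_nf = object$log$n_called_nf,
    n_up_nf = sum(nf$direction == "up"),
    n_down_nf = sum(nf$direction == "down"),
    n_called_by_type = as.list(table(nf$event_type[nf$called])),
    n_as_genes = length(unique(object$annotation$events$gene_id[
      match(nf$event_id[nf$called], object$annotation$events$event_id)])),
    percent_response_gun1_median =
      unname(object$percent_response_splicing$median),
    frac_lost_gun1 = object$frac_lost_gun1,
    repressive_pct_called = object$repressive_pct_called,
    enrichment_p = lapply(object$enrichment, function(e) e$p),
    nmd_shift = list(
      repressive_upf1upf3 = if (is.null(object$nmd_shift)) NA_real_
      else object$nmd_shift$median_shift[
        object$nmd_shift$class == "repressive" &
          object$nmd_shift$genotype == "upf1upf3"]),
    n_called_light = object$log$n_called_light,
    attrition_nf = object$log$attrition_nf,
    clip_warnings = object$log$clip_warnings,
    seed = object$log$seed)
}

#' @export
print.as_pipeline <- function(x, ...) {
  s <- summary(x)
  cat("AS pipeline run (seed ", s$seed, "): ", s$n_events, " events; ",
      s$n_called_nf, " NF-regulated (", s$n_up_nf, " up / ", s$n_down_nf,
      " down) in ", s$n_as_genes, " genes\n", sep = "")
  cat("gun1 median percent response: ",
      round(s$percent_response_gun1_median, 1), "%\n", sep = "")
  cat("repressive among called CDS events: ",
      round(s$repressive_pct_called, 1), "%\n", sep = "")
  invisible(x)
}
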