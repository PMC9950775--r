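#!/usr/bin/env Rscript
# Stage 6: convergence statistics. Fisher enrichments (UTR location,
# NF-downregulated expression among repressive-event genes, chloroplast
# localization), the NMD-sensitivity shift of repressive events across
# upf genotypes, and the light-antagonism summary with Kruskal-Wallis
# compact letters.

suppressPackageStartupMessages(library(retrosplice))

cfg <- read_config("results/config.yaml")
ann <- read_annotation("results/data", params = cfg$generator)
nf <- read_tsv_table("results/tables/diff_splicing_nf.tsv")
orf <- read_tsv_table("results/tables/orf_impact.tsv")
expr <- read_tsv_table("results/tables/diff_expression_nf.tsv")
merged <- read_tsv_table("results/tables/merged_psi.tsv")
junc <- read_tsv_table("results/data/junction_counts.tsv")
loc_tab <- read_tsv_table("results/data/gene_localization.tsv")
q <- function(cn) merged[merged$condition == cn, ]

called <- nf$event_id[nf$called]
universe <- nf$event_id[nf$called | nf$control]
gene_of <- stats::setNames(ann$events$gene_id, ann$events$event_id)
region <- stats::setNames(orf$region, orf$event_id)
universe_genes <- unique(gene_of[universe])
repressive_genes <- unique(gene_of[orf$event_id[orf$repressive]])

e_utr <- fisher_enrichment(universe[region[universe] != "CDS"], called,
                           universe)
e_down <- fisher_enrichment(
  repressive_genes, expr$gene_id[expr$called & expr$direction == "down"],
  universe_genes)
loc <- stats::setNames(loc_tab$localization, loc_tab$gene_id)
known <- universe_genes[loc[universe_genes] != "unknown"]
e_chl <- fisher_enrichment(intersect(repressive_genes, known),
                           known[loc[known] == "chloroplast"], known)
enr <- data.frame(
  test = c("UTR_location_in_called", "NF_downregulated_in_repressive",
           "chloroplast_in_repressive"),
  odds_ratio = c(e_utr$odds_ratio, e_down$odds_ratio, e_chl$odds_ratio),
  p = c(e_utr$p, e_down$p, e_chl$p))
write_tsv_table(enr, "results/tables/enrichment.tsv")
cat("Fisher enrichments (two-sided):\n"); print(enr)

# NMD shifts across upf genotypes
nmd_conds <- c("nmd_wt", "upf1", "upf3", "upf1upf3")
psi <- sapply(nmd_conds, function(cn)
  q(cn)$psi[match(universe, q(cn)$event_id)])
rownames(psi) <- universe
cats <- stats::setNames(orf$category, orf$event_id)
classes <- ifelse(universe %in% orf$event_id[orf$repressive],
                  "repressive",
                  ifelse(cats[universe] %in% "protein_isoform" &
                           universe %in% called, "protein_isoform", NA))
shift <- nmd_shift_analysis(psi, classes, wt = "nmd_wt",
                            mutants = c("upf1", "upf3", "upf1upf3"))
write_tsv_table(shift, "results/tables/nmd_shift.tsv")
cat("\nPSI shift vs WT across NMD genotypes:\n"); print(shift)

# light antagonism (dPSI of NF events relative to dark-grown WT, with a
# same-condition replicate-split null)
reps <- sort(unique(junc$replicate))
mer_sub <- function(rs) merge_replicates(
  junc[junc$condition == "wt_dark" & junc$replicate %in% rs, ], cfg$tiers)
dpsi <- list(
  wt_dark_null = project_events(called, mer_sub(reps[reps %% 2 == 1]),
                                mer_sub(reps[reps %% 2 == 0]), cfg),
  wt_light = project_events(called, q("wt_dark"), q("wt_light"), cfg),
  pifq_dark = project_events(called, q("wt_dark"), q("pifq_dark"), cfg),
  pifq_light = project_events(called, q("wt_dark"), q("pifq_light"), cfg))
ant <- antagonism_summary(stats::setNames(nf$direction, nf$event_id)[called],
                          dpsi)
for (dir in names(ant)) {
  cat(sprintf("\nNF-%s events (n=%d): median dPSI vs dark-grown WT\n",
              dir, ant[[dir]]$n))
  print(round(ant[[dir]]$medians, 1))
  cat(sprintf("fraction with light shift opposing the NF sign: %.2f\n",
              ant[[dir]]$frac_opposite))
  if (!is.null(ant[[dir]]$letters)) {
    cat("Kruskal-Wallis letters: ")
    print(ant[[dir]]$letters$letters)
  }
}
yaml::write_yaml(
  list(enrichment = enr,
       antagonism = lapply(ant, function(a)
         list(n = a$n, medians = as.list(round(a$medians, 2)),
              frac_opposite = a$frac_opposite,
              letters = if (!is.null(a$letters))
                as.list(a$letters$letters)))),
  "results/tables/stats_summary.yaml")
cat("\nSummary written to results/tables/stats_summary.yaml\n")
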