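#!/usr/bin/env Rscript
# Stage 3: differential splicing and expression. Calls NF-regulated AS
# events (strict |dPSI| > 15 after the coverage / IR-balance / ALT-use
# cascade), quantifies how much of the WT response the gun1-like genotype
# retains, projects the NF events onto the lincomycin comparison, and
# calls NF-differential gene expression (joint count/cRPKM filter +
# fold change of at least 2 between every replicate pair).

suppressPackageStartupMessages(library(retrosplice))

cfg <- read_config("results/config.yaml")
merged <- read_tsv_table("results/tables/merged_psi.tsv")
q <- function(cn) merged[merged$condition == cn, ]

nf <- call_diff_splicing(q("wt_ctrl"), q("wt_nf"), cfg)
gun1 <- call_diff_splicing(q("wt_ctrl"), q("gun1_nf"), cfg)
write_tsv_table(nf, "results/tables/diff_splicing_nf.tsv")
write_tsv_table(gun1, "results/tables/diff_splicing_gun1.tsv")

called <- nf$event_id[nf$called]
cat("NF-regulated AS events:", length(called),
    sprintf("(%d up / %d down) out of %d events\n",
            sum(nf$direction == "up"), sum(nf$direction == "down"),
            nrow(nf)))
print(table(nf$event_type[nf$called], nf$direction[nf$called]))
cat("Non-regulated control events:", sum(nf$control), "\n\n")

pr <- percent_response(nf$dpsi[match(called, nf$event_id)],
                       gun1$dpsi[match(called, gun1$event_id)])
lost <- mean(abs(gun1$dpsi[match(called, gun1$event_id)]) <=
               cfg$thresholds$min_dpsi, na.rm = TRUE)
write_tsv_table(data.frame(event_id = called, R = pr$R),
                "results/tables/percent_response_gun1.tsv")
cat(sprintf("gun1 percent-of-response: median %.1f%% (mean %.1f%%, n=%d)\n",
            pr$median, pr$mean, pr$n))
cat(sprintf("%.0f%% of NF-regulated events are lost in gun1 (|dPSI| <= %g)\n\n",
            100 * lost, cfg$thresholds$min_dpsi))

linco <- project_events(called, q("wt_ctrl"), q("wt_linco"), cfg)
dirs <- nf$direction[match(names(linco), nf$event_id)]
write_tsv_table(data.frame(event_id = names(linco), dpsi_linco = linco,
                           nf_direction = dirs),
                "results/tables/projection_lincomycin.tsv")
cat("Lincomycin projection of NF events, median dPSI by NF direction:\n")
print(tapply(linco, dirs, median, na.rm = TRUE))

# ---- expression ----
gc <- read_tsv_table("results/data/gene_counts.tsv")
mat <- function(cn) {
  sub <- gc[gc$condition == cn, ]
  m <- do.call(cbind, lapply(split(sub, sub$replicate),
                             function(d) d$count[order(d$gene_id)]))
  rownames(m) <- sort(unique(sub$gene_id))
  m
}
ml <- with(unique(gc[, c("gene_id", "mappable_length")]),
           stats::setNames(mappable_length, gene_id))
ca <- mat("wt_ctrl"); cb <- mat("wt_nf")
crpkm <- quantile_normalize(compute_crpkm(cbind(ca, cb), ml))
expr <- call_diff_expression(ca, cb, crpkm[, 1:ncol(ca)],
                             crpkm[, ncol(ca) + 1:ncol(cb)], cfg)
write_tsv_table(expr, "results/tables/diff_expression_nf.tsv")
cat(sprintf("\nNF-regulated genes (expression): %d of %d kept by the filter\n",
            sum(expr$called), sum(expr$expressed_pass)))
print(table(expr$direction[expr$called]))
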