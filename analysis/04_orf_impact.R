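#!/usr/bin/env Rscript
# Stage 4: ORF impact of the AS events. Classifies gene region
# (5'UTR/CDS/3'UTR), reconstructs both isoforms, applies the 50-nt PTC
# rule, assigns the three-way productivity category and flags repressive
# events (signal-driven accumulation of the NMD-targeted isoform).

suppressPackageStartupMessages(library(retrosplice))

cfg <- read_config("results/config.yaml")
ann <- read_annotation("results/data", params = cfg$generator)
nf <- read_tsv_table("results/tables/diff_splicing_nf.tsv")

orf <- classify_orf_impacts(ann, cfg)
dir_of <- stats::setNames(nf$direction, nf$event_id)
orf$nf_direction <- dir_of[orf$event_id]
orf$repressive <- classify_repressive(
  orf$category, ifelse(is.na(orf$nf_direction), "none", orf$nf_direction))
write_tsv_table(orf, "results/tables/orf_impact.tsv")

universe <- nf$event_id[nf$called | nf$control]
grp <- ifelse(dir_of[universe] == "none", "non_regulated",
              dir_of[universe])
region <- stats::setNames(orf$region, orf$event_id)
cats <- stats::setNames(orf$category, orf$event_id)

cat("Region split (%) per group:\n")
print(do.call(rbind, lapply(split(universe, grp), function(ids)
  round(100 * prop.table(table(factor(region[ids],
                                      c("UTR5", "CDS", "UTR3")))), 1))))

cat("\nProductivity categories of CDS-located events (%):\n")
rows <- lapply(split(universe, grp), function(ids) {
  cp <- category_percentages(cats[ids][region[ids] == "CDS"])
  round(cp$percent, 1)
})
print(do.call(rbind, rows))

cds_called <- universe[dir_of[universe] %in% c("up", "down") &
                         region[universe] == "CDS" &
                         !is.na(cats[universe]) &
                         cats[universe] != "degenerate"]
rep_pct <- 100 * mean(classify_repressive(cats[cds_called],
                                          dir_of[cds_called]))
cat(sprintf("\nRepressive AS events: %.0f%% of the %d called CDS events\n",
            rep_pct, length(cds_called)))
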