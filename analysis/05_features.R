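#!/usr/bin/env Rscript
# Stage 5: genomic regulatory features. Trains donor/acceptor PWMs on the
# annotation's constitutive splice sites, extracts lengths / GC / splice-
# site strengths for every event, and contrasts NF-up- and
# NF-down-regulated introns and exons against the non-regulated controls
# (medians, two-sided Mann-Whitney at P < 0.05).

suppressPackageStartupMessages(library(retrosplice))

cfg <- read_config("results/config.yaml")
ann <- read_annotation("results/data", params = cfg$generator)
nf <- read_tsv_table("results/tables/diff_splicing_nf.tsv")

feats <- extract_features(ann, pwm_cfg = cfg$pwm)
write_tsv_table(feats, "results/tables/features.tsv")

dir_of <- stats::setNames(nf$direction, nf$event_id)
universe <- nf$event_id[nf$called | nf$control]
arrow <- function(d) c(higher = "up", lower = "down", ns = "X",
                       not_assessable = "-")[d]

for (ty in c("IR", "ES")) {
  ids <- universe[nf$event_type[match(universe, nf$event_id)] == ty]
  if (length(ids) < 6) next
  groups <- ifelse(dir_of[ids] == "none", "control", dir_of[ids])
  cmp <- compare_groups(feats[match(ids, feats$event_id), ], groups)
  write_tsv_table(cmp, sprintf("results/tables/feature_comparison_%s.tsv",
                               ty))
  cat("\n", ty, " events vs non-regulated controls:\n", sep = "")
  wide <- do.call(rbind, lapply(split(cmp, cmp$group), function(d)
    stats::setNames(arrow(d$direction), d$feature)))
  print(wide)
}
cat("\n(up/down = significantly higher/lower median than controls,",
    "X = no significant difference)\n")
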