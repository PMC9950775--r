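# PWM splice-site scoring and regulatory-feature extraction/comparison.

test_that("a PWM trained on a single motif ranks that motif highest", {
  donors <- rep("CAGGTAAGT", 30)
  acceptors <- rep(paste0(strrep("CT", 10), "AGG"), 30)
  pwm <- build_pwm(donors, acceptors,
                   background = c(A = .25, C = .25, G = .25, T = .25))
  top <- score_pwm(pwm$donor, "CAGGTAAGT")
  # any single-base perturbation scores strictly lower
  for (pos in 1:9) for (b in c("A", "C", "G", "T")) {
    alt <- "CAGGTAAGT"
    if (substr(alt, pos, pos) == b) next
    substr(alt, pos, pos) <- b
    expect_lt(score_pwm(pwm$donor, alt), top)
  }
})

test_that("a uniform training set scores every sequence near zero", {
  mono <- function(b, w) strrep(b, w)
  donors <- rep(vapply(c("A", "C", "G", "T"), mono, "", w = 9), 5)
  acceptors <- rep(vapply(c("A", "C", "G", "T"), mono, "", w = 23), 5)
  pwm <- build_pwm(donors, acceptors)
  expect_equal(as.numeric(score_pwm(pwm$donor, "CAGGTAAGT")), 0,
               tolerance = 1e-9)
  expect_equal(as.numeric(score_pwm(pwm$acceptor, strrep("G", 23))), 0,
               tolerance = 1e-9)
})

test_that("N positions are skipped and counted, not scored", {
  donors <- rep("CAGGTAAGT", 30)
  acceptors <- rep(paste0(strrep("CT", 10), "AGG"), 30)
  pwm <- build_pwm(donors, acceptors,
                   background = c(A = .25, C = .25, G = .25, T = .25))
  full <- score_pwm(pwm$donor, "CAGGTAAGT")
  with_n <- score_pwm(pwm$donor, "NAGGTAAGT")
  expect_equal(as.numeric(with_n),
               as.numeric(full) - unname(pwm$donor["C", 1]),
               tolerance = 1e-12)
  expect_equal(attr(with_n, "n_skipped"), 1L)
})

test_that("training requires at least 20 sites per class", {
  expect_error(build_pwm(rep("CAGGTAAGT", 5),
                         rep(strrep("C", 23), 30)), "20")
})

test_that("feature lengths and GC match direct computation from the
          annotation", {
  ann <- small_annotation(n = 40, seed = 31)
  feats <- extract_features(ann)
  ev <- ann$events
  expect_equal(feats$L_alt, as.numeric(ev$alt_len))
  # GC of the alternative interval, computed independently from the
  # genome (strand-independent quantity)
  gc_direct <- vapply(seq_len(nrow(ev)), function(i) {
    s <- substring(as.character(ann$genome[[ev$chrom[i]]]),
                   ev$alt_start[i], ev$alt_end[i])
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1))
  expect_equal(feats$GC_alt, gc_direct)
  # minus-strand IR: the upstream exon is the genomically downstream one
  mi <- which(ev$strand == "-" & ev$event_type == "IR" &
                ev$region == "CDS")[1]
  exons <- ann$exons[ann$exons$gene_id == ev$gene_id[mi], ]
  up <- exons[exons$rank == ev$anchor_rank[mi], ]
  expect_gt(up$gstart, ev$alt_end[mi])
  expect_equal(feats$L_up_exon[mi], as.numeric(up$gend - up$gstart + 1))
  # a 5'UTR intron in the first intron has no upstream intron
  ui <- which(ev$region == "UTR5" & ev$anchor_rank == 1)
  expect_true(all(is.na(feats$L_up_intron[ui])))
})

test_that("every feature is invariant under genome reverse-complement
          with strand flip", {
  ann <- small_annotation(n = 24, seed = 37)
  flipped <- flip_annotation(ann)
  sites <- collect_splice_sites(ann)
  sites_f <- collect_splice_sites(flipped)
  expect_setequal(sites$donors, sites_f$donors)
  pwm <- build_pwm(sites$donors, sites$acceptors)
  f1 <- extract_features(ann, pwms = pwm)
  f2 <- extract_features(flipped, pwms = pwm)
  num <- vapply(f1, is.numeric, logical(1))
  expect_equal(f1[, num], f2[, num], tolerance = 1e-12)
})

test_that("group comparison flags shifted features and respects rank
          invariance", {
  set.seed(5)
  base <- data.frame(event_id = sprintf("e%02d", 1:40),
                     event_type = "IR",
                     L_alt = c(1000 + 1:20, 100 + 1:20),
                     L_up_exon = 100, L_down_exon = 100,
                     L_up_intron = 100, L_down_intron = 100,
                     GC_alt = 0.5, GC_up = 0.5, GC_down = 0.5,
                     S5 = rnorm(40), S3 = rnorm(40))
  groups <- c(rep("up", 20), rep("control", 20))
  cmp <- compare_groups(base, groups)
  row <- cmp[cmp$feature == "L_alt", ]
  expect_equal(row$direction, "higher")
  # complete separation: exact two-sided Mann-Whitney extreme
  expect_equal(row$p, 2 / choose(40, 20), tolerance = 1e-6)
  # identical distributions are ns; a single shared constant is ns
  expect_equal(cmp$direction[cmp$feature == "GC_alt"], "ns")
  # adding a constant to both groups leaves the p-value unchanged
  shifted <- base; shifted$S5 <- shifted$S5 + 100
  cmp_sh <- compare_groups(shifted, groups)
  expect_equal(cmp_sh$p[cmp_sh$feature == "S5"],
               cmp$p[cmp$feature == "S5"])
  # tiny groups are not assessable
  cmp_small <- compare_groups(base[c(1, 2, 21:40), ],
                              groups[c(1, 2, 21:40)])
  expect_equal(unique(cmp_small$direction[cmp_small$group == "up"]),
               "not_assessable")
})

test_that("splice-site windows have the documented geometry", {
  ann <- manual_annotation()
  g <- retrosplice:::.gene_premrna(ann, "GP")
  # donor of intron 1: last 3 exonic + first 6 intronic nt
  expect_equal(retrosplice:::.donor_window(g, 1), "GCCGTAAGT")
  # acceptor of intron 1: last 20 intronic + first 3 exonic nt
  expect_equal(retrosplice:::.acceptor_window(g, 1),
               paste0(strrep("C", 18), "AG", "GGC"))
  # identical windows on the mirrored minus-strand copy
  gm <- retrosplice:::.gene_premrna(ann, "GM")
  expect_equal(retrosplice:::.donor_window(gm, 1), "GCCGTAAGT")
})
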