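# Region classification, isoform reconstruction, PTC detection under the
# 50-nt rule, productivity categories (against an independent oracle) and
# the repressive-event flag.

test_that("PTC detection is inclusive at the 50-nt boundary", {
  # ORF: ATG + 9 codons + TAA, then downstream sequence; a single
  # junction placed at varying distance from the stop's last nucleotide
  orf <- paste0("ATG", strrep("GCC", 9), "TAA")
  seq <- paste0(orf, strrep("C", 300))
  stop_end <- nchar(orf)
  for (d in c(10, 49)) {
    r <- detect_ptc(seq, 1, junctions = stop_end + d)
    expect_false(r$is_ptc)
  }
  for (d in c(50, 51, 120)) {
    r <- detect_ptc(seq, 1, junctions = stop_end + d)
    expect_true(r$is_ptc)
    expect_equal(r$d_ptc, d)
  }
  # stop in the last exon: no downstream junction, rule vacuous
  expect_false(detect_ptc(seq, 1, junctions = 5)$is_ptc)
  expect_false(detect_ptc(seq, 1, junctions = integer(0))$is_ptc)
  # no in-frame stop at all: flagged nonstop, not PTC
  ns <- detect_ptc(paste0("ATG", strrep("GGC", 20)), 1, junctions = 30)
  expect_true(ns$nonstop); expect_false(ns$is_ptc)
  # monotone rule: is_ptc never reappears as the junction moves closer
  flags <- vapply(seq(120, 1), function(d)
    detect_ptc(seq, 1, junctions = stop_end + d)$is_ptc, logical(1))
  expect_true(all(diff(as.integer(flags)) <= 0))
  # the nearest qualifying junction defines d_PTC under the any rule,
  # the final one under the last-junction rule
  r2 <- detect_ptc(seq, 1, junctions = stop_end + c(60, 200))
  expect_equal(r2$d_ptc, 60)
  r3 <- detect_ptc(seq, 1, junctions = stop_end + c(60, 200),
                   rule = "last_junction")
  expect_equal(r3$d_ptc, 200)
})

test_that("region classification respects strand and assigns straddles
          to CDS", {
  ann <- manual_annotation()
  for (i in 1:2) {
    ev <- ann$events[i, ]
    gene <- ann$genes[ann$genes$gene_id == ev$gene_id, ]
    expect_equal(classify_region(ev, gene), "CDS")
    # same genomic span relabelled upstream of the CDS -> UTR5 on the
    # correct side of each strand
    up <- ev
    if (gene$strand == "+") {
      up$alt_start <- gene$gstart; up$alt_end <- gene$cds_glo - 1
    } else {
      up$alt_start <- gene$cds_ghi + 1; up$alt_end <- gene$gend
    }
    expect_equal(classify_region(up, gene), "UTR5")
    # straddling the CDS start is assigned to CDS
    str_ev <- ev
    str_ev$alt_start <- gene$cds_glo - 5
    str_ev$alt_end <- gene$cds_glo + 5
    expect_equal(classify_region(str_ev, gene), "CDS")
  }
  out <- ann$events[1, ]; out$alt_start <- 1; out$alt_end <- 10
  expect_error(classify_region(out, ann$genes[1, ]), "outside")
})

test_that("isoform reconstruction has the expected lengths and junction
          counts", {
  ann <- manual_annotation()
  for (i in 1:2) {                      # plus and minus strand
    iso <- reconstruct_isoforms(ann, ann$events[i, ])
    expect_equal(nchar(iso$inclusion$seq), 270 + 60)
    expect_equal(nchar(iso$exclusion$seq), 270)
    # retention removes the exon-exon junction at the splice point
    expect_length(iso$exclusion$junctions, 2)
    expect_length(iso$inclusion$junctions, 1)
    expect_equal(substr(iso$inclusion$seq, iso$inclusion$cds_start,
                        iso$inclusion$cds_start + 2), "ATG")
    # retained intron is frame-preserving and stop-free here: both
    # isoforms are productive
    r <- classify_orf_impact(ann, ann$events[i, ])
    expect_equal(r$category, "protein_isoform")
    expect_true(r$frame_preserved)
  }
})

test_that("generated events reconstruct consistently across types", {
  ann <- small_annotation(n = 50, seed = 21)
  for (i in seq_len(nrow(ann$events))) {
    ev <- ann$events[i, ]
    iso <- reconstruct_isoforms(ann, ev)
    expect_equal(nchar(iso$inclusion$seq) - nchar(iso$exclusion$seq),
                 ev$alt_len)
    dj <- length(iso$inclusion$junctions) -
      length(iso$exclusion$junctions)
    expected_dj <- switch(ev$event_type, IR = -1L, ES = 1L, 0L)
    expect_equal(dj, expected_dj)
  }
})

test_that("classifier categories match the planted flags and the
          independent codon-walking oracle", {
  ann <- small_annotation(n = 80, seed = 23)
  orf <- classify_orf_impacts(ann)
  ev <- ann$events
  # generator round trip: planted NMD flags recovered exactly
  expect_equal(orf$ptc_on_inclusion, ev$nmd_on_inclusion)
  expect_equal(orf$ptc_on_exclusion, ev$nmd_on_exclusion)
  cds <- which(!is.na(ev$category))
  expect_equal(orf$category[cds], ev$category[cds])
  # oracle equivalence, all events including UTR regions
  oracle <- vapply(seq_len(nrow(ev)), function(i)
    oracle_category(ann, ev[i, ]), character(1))
  got <- ifelse(is.na(orf$category), orf$region, orf$category)
  expect_equal(got, oracle)
})

test_that("frame preservation equals the CDS length difference mod 3", {
  ann <- small_annotation(n = 40, seed = 29)
  orf <- classify_orf_impacts(ann)
  ev <- ann$events
  expect_equal(orf$frame_preserved, (ev$alt_len %% 3) == 0)
})

test_that("repressive events increase the unproductive isoform under the
          signal", {
  expect_true(classify_repressive("unproductive_on_inclusion", "up"))
  expect_false(classify_repressive("unproductive_on_inclusion", "down"))
  expect_true(classify_repressive("unproductive_on_exclusion", "down"))
  expect_false(classify_repressive("protein_isoform", "up"))
  expect_equal(
    classify_repressive(
      c("unproductive_on_inclusion", "protein_isoform", NA),
      c("up", "up", "down")),
    c(TRUE, FALSE, FALSE))
})
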