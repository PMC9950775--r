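# Generator: determinism, planted-structure guarantees, truth-model
# formulas, and the sampling model of junction and gene counts.

test_that("identical seeds give byte-identical artifacts", {
  a1 <- small_annotation(n = 15, seed = 42)
  a2 <- small_annotation(n = 15, seed = 42)
  expect_identical(a1$events, a2$events)
  expect_identical(a1$genes, a2$genes)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fasta(a1$genome, file.path(d1, "g.fa"))
  write_fasta(a2$genome, file.path(d2, "g.fa"))
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  tr1 <- build_truth(a1, condition_profiles(a1$params), a1$params, seed = 5)
  tr2 <- build_truth(a2, condition_profiles(a2$params), a2$params, seed = 5)
  expect_identical(tr1$psi, tr2$psi)
  j1 <- simulate_junction_reads(tr1, seed = 5)
  j2 <- simulate_junction_reads(tr2, seed = 5)
  expect_identical(j1, j2)
  a3 <- small_annotation(n = 15, seed = 43)
  expect_false(identical(as.character(a3$genome), as.character(a1$genome)))
})

test_that("planted events carry the intended frame and NMD structure", {
  ann <- small_annotation(n = 60, seed = 7)
  ev <- ann$events
  expect_true(all(ev$frame_preserved == (ev$alt_len %% 3 == 0)))
  # NMD flags only arise from planted unproductive categories
  expect_true(all(ev$nmd_on_inclusion ==
                    (ev$category %in% "unproductive_on_inclusion")))
  expect_true(all(ev$nmd_on_exclusion ==
                    (ev$category %in% "unproductive_on_exclusion")))
  # UTR events never get a productivity category
  expect_true(all(is.na(ev$category[ev$region != "CDS"])))
  # both strands and all four types are represented
  expect_setequal(unique(ev$strand), c("+", "-"))
  expect_setequal(unique(ev$event_type), c("IR", "ES", "ALT5", "ALT3"))
  # alt interval is nested within the gene span
  g <- ann$genes[match(ev$gene_id, ann$genes$gene_id), ]
  expect_true(all(ev$alt_start >= g$gstart & ev$alt_end <= g$gend))
})

test_that("generator rejects infeasible structural constraints", {
  p <- sim_params(n_genes = 2L)
  # corrupt a built gene: planting a stop into a frame-preserving intron
  # must be caught by the reference-ORF validation when it leaks into the
  # reference (simulate by requesting an impossible stop offset)
  expect_error(
    retrosplice:::.intron_translatable(90, p, "strong", stop_at = 85),
    "stop_at")
})

test_that("truth model applies the retrograde, gun1 and light terms", {
  p <- sim_params(n_genes = 60L, psi0_range = c(40, 40),
                  antagonistic_frac = 1)
  ann <- generate_annotation(p$n_genes, p, seed = 3)
  tr <- build_truth(ann, condition_profiles(p), p, seed = 3)
  s <- tr$events$s
  expect_equal(unname(tr$psi[, "wt_ctrl"]), rep(40, length(s)))
  expect_equal(unname(tr$psi[, "wt_nf"]), 40 + s * 30)
  expect_equal(unname(tr$psi[, "gun1_nf"]), 40 + s * 15)
  expect_equal(unname(tr$psi[, "wt_linco"]), 40 + s * 30)
  # light antagonism: sign-flipped shift in light, and in dark when PIFs
  # are inactive (pifq mimics light); plain dark is baseline
  expect_equal(unname(tr$psi[, "wt_dark"]), rep(40, length(s)))
  expect_equal(unname(tr$psi[, "wt_light"]), 40 - s * 30)
  expect_equal(unname(tr$psi[, "pifq_dark"]), 40 - s * 30)
  # null events share psi0 across every condition
  nulls <- s == 0
  expect_true(all(tr$psi[nulls, ] == 40))
})

test_that("NMD decay produces the closed-form effective PSI", {
  # steady state: inclusion mass 0.5*0.2 against exclusion 0.5
  expect_equal(retrosplice:::.effective_psi(50, TRUE, FALSE, 0.8, 1),
               100 * 0.1 / 0.6, tolerance = 1e-12)
  # NMD off (upf-like eta = 0): effective PSI equals true PSI
  psis <- c(0, 12.5, 50, 99)
  expect_equal(retrosplice:::.effective_psi(psis, TRUE, FALSE, 0.8, 0),
               psis)
  # symmetric decay of the exclusion isoform
  expect_equal(retrosplice:::.effective_psi(50, FALSE, TRUE, 0.8, 1),
               100 * 0.5 / 0.6, tolerance = 1e-12)
})

test_that("empirical PSI is consistent at high depth with NMD off", {
  p <- sim_params(n_genes = 60L, depth = 1e4)
  ann <- generate_annotation(p$n_genes, p, seed = 11)
  prof <- condition_profiles(p)
  prof <- prof[prof$condition_id == "upf1upf3", ]   # eta = 0: no decay
  tr <- build_truth(ann, prof, p, seed = 11)
  junc <- simulate_junction_reads(tr, prof, p, seed = 11)
  merged <- merge_replicates(junc)
  err <- abs(merged$psi - tr$psi[merged$event_id, "upf1upf3"])
  expect_gte(mean(err <= 2), 0.95)
  # IR record invariant: inclusion support equals the junction mean
  ir <- junc[junc$event_type == "IR", ]
  expect_equal((ir$inc_j1 + ir$inc_j2) / 2, as.numeric(ir$inc))
})

test_that("gene counts follow the NMD survival and library-size model", {
  p <- sim_params(n_genes = 80L, n_replicates = 10L)
  ann <- generate_annotation(p$n_genes, p, seed = 13)
  prof <- condition_profiles(p)
  prof <- prof[prof$condition_id %in% c("wt_ctrl", "wt_nf",
                                        "nmd_wt", "upf1upf3"), ]
  tr <- build_truth(ann, prof, p, seed = 13)
  gc <- simulate_gene_counts(tr, prof, p, seed = 13)
  mean_count <- function(cond) {
    sub <- gc[gc$condition == cond, ]
    tapply(sub$count, sub$gene_id, mean)
  }
  # genes without an NMD-sensitive isoform are invariant across eta
  ev <- tr$events
  no_nmd <- ev$gene_id[!ev$nmd_on_inclusion & !ev$nmd_on_exclusion]
  m_wt <- mean_count("nmd_wt"); m_upf <- mean_count("upf1upf3")
  rel <- (m_upf[no_nmd] - m_wt[no_nmd]) / pmax(m_wt[no_nmd], 1)
  expect_lt(median(abs(rel)), 0.1)
  # a repressive-event gene (PSI driven up into the degraded isoform)
  # loses expression under NF
  rep_genes <- ev$gene_id[ev$repressive & ev$s == 1]
  rep_genes <- intersect(
    rep_genes, tr$genes$gene_id[tr$genes$expr_s == 0])
  expect_gte(length(rep_genes), 3)
  m_nf <- mean_count("wt_nf")[rep_genes]
  m_ctrl <- mean_count("wt_ctrl")[rep_genes]
  expect_lt(sum(m_nf), sum(m_ctrl))
  expect_gt(median((m_ctrl - m_nf) / pmax(m_ctrl, 1)), 0.1)
  # doubling the library size doubles expected counts
  p2 <- p; p2$library_size <- 2 * p$library_size
  gc2 <- simulate_gene_counts(tr, prof, p2, seed = 13)
  ratio <- sum(gc2$count[gc2$condition == "wt_ctrl"]) /
    sum(gc$count[gc$condition == "wt_ctrl"])
  expect_equal(ratio, 2, tolerance = 0.02)
})
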