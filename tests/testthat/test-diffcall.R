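# Differential splicing/expression calling: the IR balance test, the
# host-exon use filter, the strict magnitude threshold, the joint
# expression filter with the per-replicate-pair fold-change rule, the
# percent-of-response, and event projection.

test_that("IR junction balance uses the exact two-sided binomial test", {
  expect_equal(ir_balance_test(10, 10), 1)
  # independent oracle: enumerate the Binomial(22, 0.5) tail mass
  oracle <- 2 * sum(dbinom(0:2, 22, 0.5))
  expect_equal(ir_balance_test(20, 2), oracle, tolerance = 1e-12)
  expect_lt(ir_balance_test(20, 2), 0.05)
  expect_true(is.na(ir_balance_test(0, 0)))
  expect_error(ir_balance_test(-1, 3), "non-negative")
})

test_that("host-exon use filter is inclusive at the threshold", {
  expect_true(alt_use_filter(80, 40))
  expect_false(alt_use_filter(24.9, 90))
  expect_true(alt_use_filter(25, 25))
  expect_false(alt_use_filter(NA, 80))
})

test_that("the caller applies the filter cascade with a strict
          magnitude threshold", {
  qa <- make_quant(c("e1", "e2", "e3", "e4", "e5"),
                   c("ES", "ES", "ES", "IR", "ALT3"),
                   inc = c(800, 500, 500, 450, 600),
                   exc = c(200, 500, 500, 550, 400),
                   inc_j1 = c(NA, NA, NA, 450, NA),
                   inc_j2 = c(NA, NA, NA, 450, NA),
                   host_inc = c(NA, NA, NA, NA, 100),
                   host_exc = c(NA, NA, NA, NA, 900))
  qb <- make_quant(c("e1", "e2", "e3", "e4", "e5"),
                   c("ES", "ES", "ES", "IR", "ALT3"),
                   inc = c(600, 650, 3, 900, 900),
                   exc = c(400, 350, 4, 100, 100),
                   inc_j1 = c(NA, NA, NA, 880, NA),
                   inc_j2 = c(NA, NA, NA, 920, NA),
                   host_inc = c(NA, NA, NA, NA, 950),
                   host_exc = c(NA, NA, NA, NA, 50))
  res <- call_diff_splicing(qa, qb)
  # e1: 80 -> 60, called down
  expect_equal(res$dpsi[res$event_id == "e1"], -20)
  expect_equal(res$direction[res$event_id == "e1"], "down")
  # e2: 50 -> 65, dPSI exactly 15: strict threshold, a control event
  expect_equal(res$dpsi[res$event_id == "e2"], 15)
  expect_false(res$called[res$event_id == "e2"])
  expect_true(res$control[res$event_id == "e2"])
  # e3: VLOW in sample B only: neither called nor control
  expect_false(res$called[res$event_id == "e3"])
  expect_false(res$control[res$event_id == "e3"])
  # e4: balanced IR junctions pass the balance filter and get called
  expect_true(res$ir_balance_pass[res$event_id == "e4"])
  expect_true(res$called[res$event_id == "e4"])
  # e5: host-exon PSI 10 in sample A fails the use filter despite dPSI 30
  expect_false(res$alt_use_pass[res$event_id == "e5"])
  expect_false(res$called[res$event_id == "e5"])
})

test_that("an imbalanced IR event is dropped by the balance filter", {
  qa <- make_quant("ir", "IR", inc = 110, exc = 500,
                   inc_j1 = 200, inc_j2 = 20)
  qb <- make_quant("ir", "IR", inc = 500, exc = 100,
                   inc_j1 = 500, inc_j2 = 500)
  res <- call_diff_splicing(qa, qb)
  expect_false(res$ir_balance_pass)
  expect_false(res$called)
})

test_that("swapping the compared samples negates every dPSI", {
  set.seed(4)
  n <- 40
  qa <- make_quant(sprintf("e%02d", 1:n), "ES",
                   inc = rpois(n, 300), exc = rpois(n, 300))
  qb <- make_quant(sprintf("e%02d", 1:n), "ES",
                   inc = rpois(n, 300), exc = rpois(n, 300))
  ab <- call_diff_splicing(qa, qb)
  ba <- call_diff_splicing(qb, qa)
  expect_equal(ab$dpsi, -ba$dpsi)
  expect_equal(sum(ab$direction == "up"), sum(ba$direction == "down"))
  expect_equal(sum(ab$direction == "down"), sum(ba$direction == "up"))
  expect_equal(ab$called, ba$called)
})

test_that("event universe mismatch is a hard error", {
  qa <- make_quant(c("e1", "e2"), "ES", inc = c(10, 10), exc = c(10, 10))
  qb <- make_quant(c("e1", "e9"), "ES", inc = c(10, 10), exc = c(10, 10))
  expect_error(call_diff_splicing(qa, qb), "e9")
})

test_that("expression calling uses the joint filter and the
          per-replicate-pair fold-change rule", {
  mk <- function(v) matrix(v, nrow = 1, byrow = TRUE,
                           dimnames = list("g1", NULL))
  cfg <- default_config()
  hi <- mk(c(500, 500))
  # A (10, 12) vs B (40, 50): minimum pairwise fold change with the
  # pseudocount is (40+1)/(12+1) = 3.15 >= 2, consistent direction: called
  r <- call_diff_expression(hi, hi, mk(c(10, 12)), mk(c(40, 50)), cfg)
  expect_true(r$called); expect_equal(r$direction, "up")
  # A (10, 30) vs B (25, 25): the (30, 25) pair breaks the direction
  r2 <- call_diff_expression(hi, hi, mk(c(10, 30)), mk(c(25, 25)), cfg)
  expect_false(r2$called)
  # count 49 and cRPKM 4 in every replicate of both samples: filtered out
  r3 <- call_diff_expression(mk(c(49, 49)), mk(c(49, 49)),
                             mk(c(4, 4)), mk(c(4, 4)), cfg)
  expect_false(r3$expressed_pass)
  # count exactly 50 in all replicates of one sample rescues the gene
  r4 <- call_diff_expression(mk(c(50, 50)), mk(c(10, 10)),
                             mk(c(4, 4)), mk(c(4, 4)), cfg)
  expect_true(r4$expressed_pass)
  # cRPKM strictly greater than 5 rescues a low-count gene
  r5 <- call_diff_expression(mk(c(10, 10)), mk(c(10, 10)),
                             mk(c(5, 5)), mk(c(5, 5)), cfg)
  expect_false(r5$expressed_pass)
  r6 <- call_diff_expression(mk(c(10, 10)), mk(c(10, 10)),
                             mk(c(5.01, 5.01)), mk(c(5.01, 5.01)), cfg)
  expect_true(r6$expressed_pass)
})

test_that("the alternate parse of the expression filter is selectable", {
  mk <- function(v) matrix(v, nrow = 1, byrow = TRUE,
                           dimnames = list("g1", NULL))
  # one replicate fails in each sample: default parse (kept iff some
  # sample has ALL replicates passing) removes the gene; alternate parse
  # (removed iff some sample has ALL replicates failing) keeps it
  ca <- mk(c(100, 10)); cb <- mk(c(100, 10)); cr <- mk(c(1, 1))
  d <- call_diff_expression(ca, cb, cr, cr, default_config())
  expect_false(d$expressed_pass)
  alt_cfg <- default_config(
    thresholds = list(expr_filter_parse = "any_sample_all_fail"))
  a <- call_diff_expression(ca, cb, cr, cr, alt_cfg)
  expect_true(a$expressed_pass)
})

test_that("percent response keeps sign semantics and skips zero
          denominators", {
  expect_equal(percent_response(30, 15)$R, 50)
  expect_equal(percent_response(-20, -20)$R, 100)
  expect_equal(percent_response(10, -5)$R, -50)
  pr <- percent_response(c(30, 0, 10), c(15, 5, 5))
  expect_true(is.na(pr$R[2]))
  expect_equal(pr$n, 2)
  expect_equal(pr$median, 50)
})

test_that("projection reports dPSI without magnitude re-filtering", {
  qa <- make_quant(c("e1", "e2"), "ES", inc = c(500, 4), exc = c(500, 3))
  qb <- make_quant(c("e1", "e2"), "ES", inc = c(720, 3), exc = c(280, 4))
  d <- project_events(c("e1", "e2"), qa, qb)
  expect_equal(unname(d["e1"]), 22)
  expect_true(is.na(d["e2"]))          # under-covered in both samples
  expect_length(project_events(character(0), qa, qb), 0)
})
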