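# Fisher enrichment, Kruskal-Wallis letters, NMD shifts, antagonism
# summaries and category percentages.

test_that("Fisher enrichment matches the exact hypergeometric sum", {
  u <- sprintf("g%02d", 1:40)
  # balanced independence: OR 1, p 1
  r <- fisher_enrichment(u[1:20], u[c(1:10, 21:30)], u)
  expect_equal(unname(r$contingency[1, 1]), 10)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)
  # perfect association: enumerate the two-sided hypergeometric mass
  r2 <- fisher_enrichment(u[1:20], u[1:20], u)
  probs <- dhyper(0:20, 20, 20, 20)
  oracle <- sum(probs[probs <= dhyper(20, 20, 20, 20) * (1 + 1e-7)])
  expect_equal(r2$p, oracle, tolerance = 1e-9)
  expect_equal(r2$odds_ratio, Inf)
  # degenerate memberships: OR undefined, p 1
  r3 <- fisher_enrichment(character(0), u[1:5], u)
  expect_true(is.na(r3$odds_ratio))
  expect_equal(r3$p, 1)
  expect_error(fisher_enrichment(u[1], u[2], character(0)), "universe")
})

test_that("Fisher table symmetry: transposition preserves p, row swap
          inverts the odds ratio", {
  u <- sprintf("g%02d", 1:60)
  a <- u[1:25]; b <- u[c(3:20, 40:50)]
  r_ab <- fisher_enrichment(a, b, u)
  r_ba <- fisher_enrichment(b, a, u)
  expect_equal(r_ab$p, r_ba$p, tolerance = 1e-12)
  expect_equal(r_ab$odds_ratio, r_ba$odds_ratio)
  r_not <- fisher_enrichment(setdiff(u, a), b, u)
  expect_equal(r_not$odds_ratio, 1 / r_ab$odds_ratio, tolerance = 1e-12)
  expect_equal(r_not$p, r_ab$p, tolerance = 1e-12)
})

test_that("Kruskal-Wallis letters separate shifted groups and merge
          identical ones", {
  set.seed(6)
  g <- list(a1 = rnorm(50), a2 = rnorm(50), b = rnorm(50) + 30)
  kl <- kruskal_letters(g)
  expect_lt(kl$p, 0.05)
  expect_equal(kl$letters[["a1"]], kl$letters[["a2"]])
  expect_false(kl$letters[["b"]] == kl$letters[["a1"]])
  # identical groups share one letter
  same <- kruskal_letters(list(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4)))
  expect_true(all(same$letters == "a"))
  # all values identical: H 0, p 1, one letter
  const <- kruskal_letters(list(x = rep(2, 5), y = rep(2, 5)))
  expect_equal(const$H, 0)
  expect_equal(const$p, 1)
})

test_that("three constant groups reach the maximal H for the design and
          Dunn separates the extremes", {
  g <- list(lo = rep(1, 3), mid = rep(2, 3), hi = rep(3, 3))
  kl <- kruskal_letters(g, posthoc = "dunn")
  # exact rank computation: tie-averaged ranks 2/5/8 give uncorrected
  # H = 7.2; the tie correction 1 - 72/720 = 0.9 scales it to 8
  expect_equal(kl$H, 7.2 / 0.9, tolerance = 1e-9)
  expect_false(kl$letters[["lo"]] == kl$letters[["hi"]])
})

test_that("letter partition is invariant under group order", {
  set.seed(7)
  g <- list(a = rnorm(30), b = rnorm(30) + 5, c = rnorm(30) + 5.2)
  k1 <- kruskal_letters(g)
  k2 <- kruskal_letters(g[c("c", "a", "b")])
  shared <- function(k, x, y) {
    any(strsplit(k$letters[[x]], "")[[1]] %in%
          strsplit(k$letters[[y]], "")[[1]])
  }
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c")))
    expect_equal(shared(k1, pair[1], pair[2]),
                 shared(k2, pair[1], pair[2]))
})

test_that("NMD shift analysis detects decay release and stays silent on
          nulls", {
  set.seed(8)
  n <- 40
  wt <- runif(n, 10, 40)
  psi <- cbind(nmd_wt = wt, upf1 = wt + 10, upf3 = wt + 8,
               upf1upf3 = wt + 25 + rnorm(n))
  classes <- rep(c("repressive", "protein_isoform"), each = n / 2)
  # protein events: identical distributions in mutants
  psi[classes == "protein_isoform", -1] <-
    psi[classes == "protein_isoform", 1] + rnorm(3 * n / 2, 0, 0.5)
  res <- nmd_shift_analysis(psi, classes)
  rep_row <- res[res$class == "repressive" & res$genotype == "upf1upf3", ]
  expect_gt(rep_row$median_shift, 0)
  expect_lt(rep_row$p, 0.01)
  prot <- res[res$class == "protein_isoform", ]
  expect_true(all(prot$p > 0.05))
  # fewer than 3 shared events: not assessable
  tiny <- nmd_shift_analysis(psi[1:2, ], classes[1:2])
  expect_false(any(tiny$assessable))
})

test_that("antagonism summary reports opposed medians and letter
          grouping; a null generator yields flat medians", {
  set.seed(9)
  ids <- sprintf("e%02d", 1:40)
  dir <- setNames(rep(c("up", "down"), each = 20), ids)
  anti <- function(sgn) setNames(sgn * runif(40, 20, 40) *
                                   ifelse(dir == "up", 1, -1), ids)
  dpsi <- list(wt_dark_null = setNames(rnorm(40, 0, 1), ids),
               wt_light = anti(-1), pifq_dark = anti(-1))
  s <- antagonism_summary(dir, dpsi)
  expect_lt(s$up$medians[["wt_light"]], 0)
  expect_gt(s$down$medians[["wt_light"]], 0)
  expect_gt(s$up$frac_opposite, 0.9)
  lt <- s$up$letters$letters
  expect_equal(lt[["wt_light"]], lt[["pifq_dark"]])
  expect_false(lt[["wt_dark_null"]] == lt[["wt_light"]])
  # no planted antagonism: medians near zero, omnibus ns
  null_dpsi <- list(wt_dark_null = setNames(rnorm(40), ids),
                    wt_light = setNames(rnorm(40), ids),
                    pifq_dark = setNames(rnorm(40), ids))
  s0 <- antagonism_summary(dir, null_dpsi)
  expect_lt(abs(s0$up$medians[["wt_light"]]), 2)
  expect_true(all(s0$up$letters$letters == "a"))
})

test_that("category percentages sum to 100 with degenerates excluded", {
  cats <- c(rep("unproductive_on_inclusion", 6), rep("protein_isoform", 3),
            "unproductive_on_exclusion", "degenerate", NA)
  cp <- category_percentages(cats)
  expect_equal(sum(cp$percent), 100)
  expect_equal(cp$n, 10)
  expect_equal(cp$n_degenerate, 1)
  expect_equal(unname(cp$percent["protein_isoform"]), 30)
})
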