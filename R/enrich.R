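# Convergence statistics: Fisher enrichment over explicit universes,
# Kruskal-Wallis multi-group comparisons with compact letter displays,
# NMD-sensitivity shifts across genotypes, and light-antagonism summaries.

#' Fisher enrichment of one gene set within another
#'
#' Exact two-sided Fisher test on the 2x2 table formed by membership in
#' `set_a` and `set_b` within an explicit `universe` (never implicit).
#' The odds ratio is the sample ratio `(a*d)/(b*c)`; a zero margin makes
#' it undefined (NA) with p = 1.
#'
#' @param set_a,set_b character vectors of ids, subsets of `universe`.
#' @param universe character vector of all eligible ids.
#' @return list: contingency (2x2 matrix), odds_ratio, p.
#' @export
fisher_enrichment <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe")
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c_ <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(c("in_A", "not_A"), c("in_B", "not_B")))
  zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- if (zero_margin) NA_real_
        else if (b * c_ == 0) Inf
        else (a * d) / (b * c_)
  p <- if (zero_margin) 1 else stats::fisher.test(tab)$p.value
  list(contingency = tab, odds_ratio = or, p = p)
}

# pairwise p-value matrix -> compact letter display (insert-and-absorb).
# Groups sharing a letter are not significantly different pairwise.
.cld_from_pairs <- function(group_names, sig_pairs) {
  k <- length(group_names)
  sets <- list(seq_len(k))
  for (pr in sig_pairs) {
    i <- pr[1]; j <- pr[2]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (x in seq_along(new_sets)) for (y in seq_along(new_sets)) {
      if (x != y && keep[x] && keep[y] &&
          all(new_sets[[x]] %in% new_sets[[y]])) keep[x] <- FALSE
    }
    sets <- new_sets[keep]
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letters_out <- stats::setNames(rep("", k), group_names)
  for (s_i in seq_along(sets)) {
    for (g in sets[[s_i]])
      letters_out[g] <- paste0(letters_out[g], letters[s_i])
  }
  letters_out
}

# Dunn's post-hoc z-test p-values from joint ranks (tie-corrected)
.dunn_pairs <- function(values, labels) {
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  groups <- split(r, labels)
  mean_r <- vapply(groups, mean, numeric(1))
  n_g <- vapply(groups, length, numeric(1))
  nm <- names(groups)
  out <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i < j) {
      se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                   (1 / n_g[i] + 1 / n_g[j]))
      z <- (mean_r[i] - mean_r[j]) / se
      out[[paste(nm[i], nm[j], sep = "|")]] <-
        unname(2 * stats::pnorm(-abs(z)))
    }
  }
  out
}

#' Kruskal-Wallis comparison with compact letter display
#'
#' Tie-corrected Kruskal-Wallis test across the groups; if significant at
#' `alpha`, pairwise two-sided post-hoc tests (Mann-Whitney by default,
#' Dunn optionally) with Holm adjustment drive a compact letter display.
#' Groups sharing a letter are not significantly different pairwise. A
#' non-significant omnibus test (or all-identical values) yields one
#' shared letter.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 3).
#' @param alpha significance threshold.
#' @param posthoc "wilcox" (pairwise Mann-Whitney) or "dunn".
#' @return list: H statistic, p, letters (named), pairwise_p (named,
#'   Holm-adjusted).
#' @export
kruskal_letters <- function(groups, alpha = 0.05,
                            posthoc = c("wilcox", "dunn")) {
  posthoc <- match.arg(posthoc)
  stopifnot(length(groups) >= 2, !is.null(names(groups)),
            all(vapply(groups, length, integer(1)) >= 3))
  ord <- order(names(groups))
  groups <- groups[ord]
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  if (length(unique(values)) == 1) {
    return(list(H = 0, p = 1,
                letters = stats::setNames(rep("a", length(groups)),
                                          names(groups)),
                pairwise_p = NULL))
  }
  kw <- stats::kruskal.test(values, labels)
  if (kw$p.value >= alpha) {
    return(list(H = unname(kw$statistic), p = kw$p.value,
                letters = stats::setNames(rep("a", length(groups)),
                                          names(groups)),
                pairwise_p = NULL))
  }
  if (posthoc == "wilcox") {
    nm <- names(groups)
    raw <- list()
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i < j) {
        raw[[paste(nm[i], nm[j], sep = "|")]] <- suppressWarnings(
          stats::wilcox.test(groups[[i]], groups[[j]])$p.value)
      }
    }
  } else {
    raw <- .dunn_pairs(values, labels)
  }
  adj <- stats::p.adjust(unlist(raw), method = "holm")
  sig <- which(adj < alpha)
  sig_pairs <- lapply(names(adj)[sig], function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    match(parts, names(groups))
  })
  list(H = unname(kw$statistic), p = kw$p.value,
       letters = .cld_from_pairs(names(groups), sig_pairs),
       pairwise_p = adj)
}

#' NMD-sensitivity shift of event classes across genotypes
#'
#' For each mutant genotype: the median per-event PSI shift against the
#' wild type and a two-sided Mann-Whitney p-value on the inclusion
#' distributions, computed separately for each event class (repressive
#' events are expected to shift up in NMD-deficient genotypes;
#' protein-isoform events are the negative control). Classes with fewer
#' than 3 shared events are reported as not assessable.
#'
#' @param psi event x genotype matrix of (merged-sample) PSI values.
#' @param classes character vector aligned to rows (e.g. "repressive",
#'   "protein_isoform", NA to skip).
#' @param wt column name of the wild-type genotype.
#' @param mutants column names of the mutant genotypes.
#' @return data.frame: class, genotype, n, median_shift, p, assessable.
#' @export
nmd_shift_analysis <- function(psi, classes, wt = "nmd_wt",
                               mutants = c("upf1", "upf3", "upf1upf3")) {
  stopifnot(wt %in% colnames(psi), all(mutants %in% colnames(psi)))
  out <- list()
  for (cl in stats::na.omit(unique(classes))) {
    idx <- which(classes %in% cl)
    for (m in mutants) {
      ok <- idx[!is.na(psi[idx, wt]) & !is.na(psi[idx, m])]
      if (length(ok) < 3) {
        out[[length(out) + 1]] <- data.frame(
          class = cl, genotype = m, n = length(ok),
          median_shift = NA_real_, p = NA_real_, assessable = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      shift <- psi[ok, m] - psi[ok, wt]
      p <- suppressWarnings(
        stats::wilcox.test(psi[ok, m], psi[ok, wt])$p.value)
      out[[length(out) + 1]] <- data.frame(
        class = cl, genotype = m, n = length(ok),
        median_shift = stats::median(shift), p = p, assessable = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Direction-concordance summary of light regulation of NF events
#'
#' For each NF-direction class (up/down): the median light-vs-dark dPSI
#' of the class's events in every provided condition, the fraction of
#' events whose light shift opposes the NF sign, and a Kruskal-Wallis
#' compact letter display across the conditions' dPSI distributions
#' (e.g. WT-light, pifq-dark, and a WT-dark null).
#'
#' @param nf_direction named character vector (event id -> "up"/"down").
#' @param dpsi_by_condition named list of named numeric vectors: per
#'   condition, the projected dPSI relative to the dark-grown wild type,
#'   names being event ids.
#' @param light_condition the condition whose shift defines the
#'   opposition fraction (default "wt_light").
#' @return list per class: medians (per condition), frac_opposite,
#'   letters object from [kruskal_letters()] (NULL if groups too small).
#' @export
antagonism_summary <- function(nf_direction, dpsi_by_condition,
                               light_condition = "wt_light") {
  out <- list()
  for (dir in c("up", "down")) {
    ids <- names(nf_direction)[nf_direction == dir]
    if (length(ids) == 0) {
      message("no NF-", dir, " events; class skipped")
      next
    }
    vecs <- lapply(dpsi_by_condition, function(v) {
      x <- v[intersect(ids, names(v))]
      x[!is.na(x)]
    })
    medians <- vapply(vecs, function(x)
      if (length(x)) stats::median(x) else NA_real_, numeric(1))
    nf_sign <- if (dir == "up") 1 else -1
    lv <- vecs[[light_condition]]
    frac_opp <- if (length(lv)) mean(sign(lv) == -nf_sign) else NA_real_
    lets <- if (all(vapply(vecs, length, integer(1)) >= 3))
      kruskal_letters(vecs) else NULL
    out[[dir]] <- list(n = length(ids), medians = medians,
                       frac_opposite = frac_opp, letters = lets)
  }
  out
}

#' Three-way productivity category percentages
#'
#' Percentages of the three productivity categories over an event set;
#' degenerate (both-PTC) events are excluded from the denominator and
#' reported separately. The three percentages sum to 100.
#'
#' @param categories character vector of categories.
#' @return list: percent (named, three categories), n, n_degenerate.
#' @export
category_percentages <- function(categories) {
  cats <- c("unproductive_on_inclusion", "protein_isoform",
            "unproductive_on_exclusion")
  x <- categories[!is.na(categories)]
  n_deg <- sum(x == "degenerate")
  x <- x[x != "degenerate"]
  pct <- if (length(x))
    100 * vapply(cats, function(ct) mean(x == ct), numeric(1))
  else stats::setNames(rep(NA_real_, 3), cats)
  list(percent = pct, n = length(x), n_degenerate = n_deg)
}
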