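# Regulatory-feature extraction for regulated vs control introns/exons:
# lengths of the alternative sequence and its flanking exons/introns, GC
# content, and splice-site strength scored on log-odds position weight
# matrices trained on the annotation's constitutive sites.

# transcript-oriented pre-mRNA of a gene plus exon/intron tx intervals
.gene_premrna <- function(annotation, gene_id) {
  gene <- .gene_row(annotation, gene_id)
  exons <- .gene_exons(annotation, gene_id)
  seq <- substring(as.character(annotation$genome[[gene$chrom]]),
                   gene$gstart, gene$gend)
  if (gene$strand == "-") seq <- .revcomp(seq)
  if (gene$strand == "+") {
    t0 <- exons$gstart - gene$gstart + 1L
    t1 <- exons$gend - gene$gstart + 1L
  } else {
    t0 <- gene$gend - exons$gend + 1L
    t1 <- gene$gend - exons$gstart + 1L
  }
  n <- length(t0)
  introns <- if (n > 1) data.frame(t0 = t1[-n] + 1L, t1 = t0[-1] - 1L)
             else data.frame(t0 = integer(), t1 = integer())
  list(seq = seq, gene = gene,
       ex = data.frame(t0 = t0, t1 = t1),
       intr = introns)
}

.donor_window <- function(g, k, exonic = 3L, intronic = 6L) {
  # last `exonic` nt of exon k + first `intronic` nt of intron k
  if (k < 1 || k > nrow(g$intr)) return(NA_character_)
  paste0(substring(g$seq, g$ex$t1[k] - exonic + 1L, g$ex$t1[k]),
         substring(g$seq, g$intr$t0[k], g$intr$t0[k] + intronic - 1L))
}

.acceptor_window <- function(g, k, intronic = 20L, exonic = 3L) {
  # last `intronic` nt of intron k + first `exonic` nt of exon k+1
  if (k < 1 || k > nrow(g$intr)) return(NA_character_)
  paste0(substring(g$seq, g$intr$t1[k] - intronic + 1L, g$intr$t1[k]),
         substring(g$seq, g$ex$t0[k + 1], g$ex$t0[k + 1] + exonic - 1L))
}

#' Collect constitutive donor and acceptor site sequences
#'
#' Walks every gene and extracts the donor (3 exonic + 6 intronic nt) and
#' acceptor (20 intronic + 3 exonic nt) windows of introns not involved in
#' the gene's AS event (the AS intron itself, the intron carrying an ALT
#' extension, and both introns flanking a skipped exon are excluded).
#' Windows extending beyond contig bounds are skipped and counted.
#'
#' @param annotation an `as_annotation`.
#' @param pwm_cfg window sizes, see `default_config()$pwm`.
#' @return list with character vectors `donors` and `acceptors` and the
#'   count of skipped windows.
#' @export
collect_splice_sites <- function(annotation,
                                 pwm_cfg = default_config()$pwm) {
  donors <- character(); acceptors <- character(); skipped <- 0L
  ev_by_gene <- split(annotation$events, annotation$events$gene_id)
  for (gid in annotation$genes$gene_id) {
    g <- .gene_premrna(annotation, gid)
    n_intr <- nrow(g$intr)
    if (n_intr == 0) next
    excl <- integer()
    evs <- ev_by_gene[[gid]]
    if (!is.null(evs)) for (i in seq_len(nrow(evs))) {
      ev <- evs[i, ]
      excl <- c(excl, switch(ev$event_type,
                             IR = ev$anchor_rank,
                             ALT5 = ev$anchor_rank,
                             ALT3 = ev$anchor_rank,
                             ES = c(ev$anchor_rank - 1L, ev$anchor_rank)))
    }
    for (k in setdiff(seq_len(n_intr), excl)) {
      d <- .donor_window(g, k, pwm_cfg$donor_exonic, pwm_cfg$donor_intronic)
      a <- .acceptor_window(g, k, pwm_cfg$acceptor_intronic,
                            pwm_cfg$acceptor_exonic)
      dn <- pwm_cfg$donor_exonic + pwm_cfg$donor_intronic
      an <- pwm_cfg$acceptor_intronic + pwm_cfg$acceptor_exonic
      if (!is.na(d) && nchar(d) == dn) donors <- c(donors, d)
      else skipped <- skipped + 1L
      if (!is.na(a) && nchar(a) == an) acceptors <- c(acceptors, a)
      else skipped <- skipped + 1L
    }
  }
  list(donors = donors, acceptors = acceptors, skipped = skipped)
}

#' Build donor/acceptor position weight matrices
#'
#' Per-position log2 odds of each base against the background base
#' composition, with a pseudocount (default 0.5) added to every cell.
#' Background defaults to the base composition of the annotation genome.
#'
#' @param donors,acceptors training site sequences (equal lengths within
#'   each class; at least 20 sites per class).
#' @param background named frequency vector over A/C/G/T; if NULL,
#'   computed from the training sequences.
#' @param pseudocount added to each base count.
#' @return list of class `splice_pwm` with matrices `donor`, `acceptor`
#'   and the `background` used.
#' @export
build_pwm <- function(donors, acceptors, background = NULL,
                      pseudocount = 0.5) {
  if (length(donors) < 20 || length(acceptors) < 20)
    stop("need at least 20 constitutive sites per class")
  one <- function(seqs) {
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    counts <- apply(mat, 2, function(col)
      table(factor(col, levels = c("A", "C", "G", "T"))))
    counts <- matrix(as.numeric(counts), nrow = 4,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    probs <- sweep(counts + pseudocount, 2,
                   colSums(counts + pseudocount), "/")
    probs
  }
  if (is.null(background)) {
    all_b <- unlist(strsplit(toupper(c(donors, acceptors)), ""))
    all_b <- all_b[all_b %in% c("A", "C", "G", "T")]
    background <- table(factor(all_b, levels = c("A", "C", "G", "T")))
    background <- as.numeric(background) / sum(background)
    names(background) <- c("A", "C", "G", "T")
  }
  pd <- log2(one(donors) / background)
  pa <- log2(one(acceptors) / background)
  structure(list(donor = pd, acceptor = pa, background = background),
            class = "splice_pwm")
}

#' Score sequences against a position weight matrix
#'
#' Sum of per-position log2-odds. Positions holding a base outside
#' A/C/G/T (e.g. N) are skipped and counted in the `n_skipped` attribute.
#'
#' @param pwm_matrix one of the matrices of [build_pwm()] (4 x width).
#' @param seqs character vector of sequences of the matrix width.
#' @return numeric scores; attribute `n_skipped` holds the number of
#'   skipped positions per sequence.
#' @export
score_pwm <- function(pwm_matrix, seqs) {
  width <- ncol(pwm_matrix)
  skipped <- integer(length(seqs))
  scores <- vapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    if (is.na(s) || nchar(s) != width) { skipped[i] <<- width; return(NA_real_) }
    b <- strsplit(toupper(s), "")[[1]]
    ri <- match(b, rownames(pwm_matrix))
    ok <- !is.na(ri)
    skipped[i] <<- sum(!ok)
    sum(pwm_matrix[cbind(ri[ok], which(ok))])
  }, numeric(1))
  attr(scores, "n_skipped") <- skipped
  scores
}

# background base composition of a genome
.genome_background <- function(genome) {
  f <- Biostrings::alphabetFrequency(genome, baseOnly = TRUE, collapse = TRUE)
  f <- f[c("A", "C", "G", "T")]
  f / sum(f)
}

#' Extract the regulatory feature vector of every AS event
#'
#' Lengths (nt) of the alternative sequence and its upstream/downstream
#' exons and introns (transcript orientation), GC fractions of the
#' alternative sequence and flanking exons, and the splice-site strengths
#' S5/S3 of the alternative sequence's own 5' and 3' splice sites, scored
#' on PWMs trained on the annotation's constitutive sites. Missing flanks
#' (first/last exon situations) yield NA, never 0.
#'
#' For IR the scored sites are the retained intron's own donor and
#' acceptor; for ES the skipped exon's downstream donor and upstream
#' acceptor; for ALT5 the distal (inclusion) donor plus the shared
#' acceptor; for ALT3 the shared donor plus the proximal (inclusion)
#' acceptor.
#'
#' @param annotation an `as_annotation`.
#' @param pwms a `splice_pwm`; if NULL, trained on the annotation itself
#'   with the genome base composition as background.
#' @param pwm_cfg window sizes and pseudocount.
#' @return data.frame: event_id, group columns pass through from the
#'   events table, then L_alt, L_up_exon, L_down_exon, L_up_intron,
#'   L_down_intron, GC_alt, GC_up, GC_down, S5, S3.
#' @export
extract_features <- function(annotation, pwms = NULL,
                             pwm_cfg = default_config()$pwm) {
  if (is.null(pwms)) {
    sites <- collect_splice_sites(annotation, pwm_cfg)
    pwms <- build_pwm(sites$donors, sites$acceptors,
                      background = .genome_background(annotation$genome),
                      pseudocount = pwm_cfg$pseudocount)
  }
  ev <- annotation$events
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    g <- .gene_premrna(annotation, e$gene_id)
    n_intr <- nrow(g$intr)
    ex_len <- g$ex$t1 - g$ex$t0 + 1L
    in_len <- if (n_intr) g$intr$t1 - g$intr$t0 + 1L else integer()
    ex_seq <- substring(g$seq, g$ex$t0, g$ex$t1)
    in_seq <- if (n_intr) substring(g$seq, g$intr$t0, g$intr$t1)
              else character()
    k <- e$anchor_rank
    gv <- function(x, j) if (j >= 1 && j <= length(x)) x[j] else NA
    if (e$event_type == "IR") {
      alt_seq <- in_seq[k]
      f <- list(L_alt = in_len[k], L_up_exon = ex_len[k],
                L_down_exon = ex_len[k + 1],
                L_up_intron = gv(in_len, k - 1L),
                L_down_intron = gv(in_len, k + 1L),
                GC_up = .gc_frac(ex_seq[k]), GC_down = .gc_frac(ex_seq[k + 1]),
                S5 = score_pwm(pwms$donor, .donor_window(
                  g, k, pwm_cfg$donor_exonic, pwm_cfg$donor_intronic)),
                S3 = score_pwm(pwms$acceptor, .acceptor_window(
                  g, k, pwm_cfg$acceptor_intronic, pwm_cfg$acceptor_exonic)))
    } else if (e$event_type == "ES") {
      alt_seq <- ex_seq[k]
      f <- list(L_alt = ex_len[k], L_up_exon = gv(ex_len, k - 1L),
                L_down_exon = gv(ex_len, k + 1L),
                L_up_intron = gv(in_len, k - 1L),
                L_down_intron = gv(in_len, k),
                GC_up = if (k > 1) .gc_frac(ex_seq[k - 1]) else NA_real_,
                GC_down = if (k < length(ex_seq)) .gc_frac(ex_seq[k + 1])
                          else NA_real_,
                S5 = score_pwm(pwms$donor, .donor_window(
                  g, k, pwm_cfg$donor_exonic, pwm_cfg$donor_intronic)),
                S3 = score_pwm(pwms$acceptor, .acceptor_window(
                  g, k - 1L, pwm_cfg$acceptor_intronic,
                  pwm_cfg$acceptor_exonic)))
    } else if (e$event_type == "ALT5") {
      a <- e$alt_len
      alt_seq <- substring(g$seq, g$intr$t0[k], g$intr$t0[k] + a - 1L)
      # distal donor: last 3 nt of the extension + next 6 intronic nt
      distal <- paste0(
        substring(g$seq, g$intr$t0[k] + a - pwm_cfg$donor_exonic,
                  g$intr$t0[k] + a - 1L),
        substring(g$seq, g$intr$t0[k] + a,
                  g$intr$t0[k] + a + pwm_cfg$donor_intronic - 1L))
      f <- list(L_alt = a, L_up_exon = ex_len[k], L_down_exon = ex_len[k + 1],
                L_up_intron = gv(in_len, k - 1L),
                L_down_intron = in_len[k] - a,
                GC_up = .gc_frac(ex_seq[k]), GC_down = .gc_frac(ex_seq[k + 1]),
                S5 = score_pwm(pwms$donor, distal),
                S3 = score_pwm(pwms$acceptor, .acceptor_window(
                  g, k, pwm_cfg$acceptor_intronic, pwm_cfg$acceptor_exonic)))
    } else {                                        # ALT3
      a <- e$alt_len
      alt_seq <- substring(g$seq, g$intr$t1[k] - a + 1L, g$intr$t1[k])
      # proximal acceptor: 20 intronic nt upstream of the extension + its
      # first 3 nt
      proximal <- paste0(
        substring(g$seq, g$intr$t1[k] - a - pwm_cfg$acceptor_intronic + 1L,
                  g$intr$t1[k] - a),
        substring(g$seq, g$intr$t1[k] - a + 1L,
                  g$intr$t1[k] - a + pwm_cfg$acceptor_exonic))
      f <- list(L_alt = a, L_up_exon = ex_len[k], L_down_exon = ex_len[k + 1],
                L_up_intron = in_len[k] - a,
                L_down_intron = gv(in_len, k + 1L),
                GC_up = .gc_frac(ex_seq[k]), GC_down = .gc_frac(ex_seq[k + 1]),
                S5 = score_pwm(pwms$donor, .donor_window(
                  g, k, pwm_cfg$donor_exonic, pwm_cfg$donor_intronic)),
                S3 = score_pwm(pwms$acceptor, proximal))
    }
    data.frame(event_id = e$event_id, event_type = e$event_type,
               L_alt = as.numeric(f$L_alt),
               L_up_exon = as.numeric(f$L_up_exon),
               L_down_exon = as.numeric(f$L_down_exon),
               L_up_intron = as.numeric(f$L_up_intron),
               L_down_intron = as.numeric(f$L_down_intron),
               GC_alt = .gc_frac(alt_seq),
               GC_up = as.numeric(f$GC_up), GC_down = as.numeric(f$GC_down),
               S5 = as.numeric(f$S5), S3 = as.numeric(f$S3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare feature distributions of regulated groups against a control
#'
#' Per feature and group: group and control medians, two-sided
#' Mann-Whitney U p-value against the control group, and a direction call
#' ("higher"/"lower" at p < alpha, otherwise "ns"). Groups with fewer
#' than 3 values are reported as not assessable. No correction is applied
#' across features (per-test threshold semantics).
#'
#' @param features data.frame from [extract_features()].
#' @param groups character vector of group labels aligned to
#'   `features` rows; one label must be `control`.
#' @param control the control label.
#' @param alpha significance threshold.
#' @return data.frame: feature, group, n, median, control_median, p,
#'   direction.
#' @export
compare_groups <- function(features, groups, control = "control",
                           alpha = 0.05) {
  stopifnot(nrow(features) == length(groups), control %in% groups)
  feat_cols <- c("L_alt", "L_up_exon", "L_down_exon", "L_up_intron",
                 "L_down_intron", "GC_alt", "GC_up", "GC_down", "S5", "S3")
  out <- list()
  for (gl in setdiff(unique(groups), control)) {
    for (fc in feat_cols) {
      x <- features[[fc]][groups == gl]
      y <- features[[fc]][groups == control]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 3 || length(y) < 3) {
        out[[length(out) + 1]] <- data.frame(
          feature = fc, group = gl, n = length(x),
          median = if (length(x)) stats::median(x) else NA_real_,
          control_median = if (length(y)) stats::median(y) else NA_real_,
          p = NA_real_, direction = "not_assessable",
          stringsAsFactors = FALSE)
        next
      }
      p <- tryCatch(
        suppressWarnings(stats::wilcox.test(x, y)$p.value),
        error = function(e) NA_real_)
      dir <- if (is.na(p) || p >= alpha) "ns"
        else if (stats::median(x) > stats::median(y)) "higher" else "lower"
      out[[length(out) + 1]] <- data.frame(
        feature = fc, group = gl, n = length(x),
        median = stats::median(x), control_median = stats::median(y),
        p = p, direction = dir, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
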