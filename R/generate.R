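# Synthetic annotation generator: multi-exon gene models carrying one
# planted AS event each (IR/ES/ALT5/ALT3, located in 5'UTR/CDS/3'UTR), with
# sequences constructed so that the intended ORF impact of each isoform is
# guaranteed (planted premature stops, codon-aligned exon/intron chunks,
# T-free filler elsewhere).

# ---- intron / exon sequence builders ---------------------------------------

# constitutive intron (never present in any mRNA isoform): full consensus
# donor GTAAGT and a pyrimidine-rich acceptor ...YYYY CAG
.intron_constitutive <- function(len, params, ss_strength = "strong") {
  stopifnot(len >= 30)
  p <- if (ss_strength == "strong") params$donor_consensus_p else 0.15
  donor <- paste0("GT", .consensusish(c("A", "A", "G", "T"), p))
  tract <- .rand_bases(17L, c("C", "T", "A", "G"),
                       if (ss_strength == "strong") c(0.45, 0.35, 0.1, 0.1)
                       else c(0.25, 0.25, 0.25, 0.25))
  acceptor <- paste0(tract, "CAG")
  paste0(donor, .dna(len - 26L), acceptor)
}

# intron whose sequence can end up inside an mRNA (retained intron, or
# intron carrying an ALT extension): T-free outside the GT dinucleotide,
# optional planted in-frame stop at `stop_at` (1-based, codon-aligned by
# the caller), donor strength selectable
.intron_translatable <- function(len, params, donor_class = "strong",
                                 stop_at = NULL) {
  stopifnot(len >= 30)
  donor4 <- if (donor_class == "strong") {
    .consensusish(c("A", "A", "G", "A"), params$donor_consensus_p,
                  alphabet = c("A", "C", "G"))
  } else {
    .rand_bases(4L, c("C", "G"))
  }
  tract <- .rand_bases(17L, c("C", "A", "G"), c(0.7, 0.15, 0.15))
  seq <- paste0("GT", donor4, .tfree(len - 26L), tract, "CAG")
  if (!is.null(stop_at)) {
    stopifnot(stop_at >= 7L, stop_at + 2L <= len - 20L)
    seq <- .substr_set(seq, stop_at, "TAA")
  }
  seq
}

# codon-aligned planted stop offset near the middle of a window of length
# `len`, offsets congruent to 1 mod 3, kept clear of both ends
.mid_stop_offset <- function(len, lo = 10L, hi_margin = 25L) {
  o <- 3L * (len %/% 6L) + 1L
  o <- min(max(o, lo), len - hi_margin)
  o <- o - ((o - 1L) %% 3L)          # force o == 1 (mod 3)
  if (o < 7L) o <- 7L
  o
}

# CDS chunk: T-free, last 3 nt biased to the exonic donor consensus CAG
.cds_chunk <- function(len, params, donor_end = TRUE) {
  seq <- .tfree(len)
  if (donor_end && len >= 3 && stats::runif(1) < params$donor_consensus_p)
    seq <- .substr_set(seq, len - 2L, "CAG")
  seq
}

.draw_chunk <- function(params) {
  .r3(round(stats::runif(1, params$cds_chunk_range[1],
                         params$cds_chunk_range[2])))
}

.draw_intron_len <- function(params) {
  .r3(round(stats::runif(1, params$intron_len_range[1],
                         params$intron_len_range[2])))
}

# ---- per-gene builders (transcript coordinates) ----------------------------
# Each builder returns list(segs = data.frame(kind, seq, len), cds = c(start,
# end) in mature-transcript coordinates, event = list(...local geometry...)).

.build_ir_cds <- function(category, regulation, params) {
  cc <- replicate(4, .draw_chunk(params))
  i_len <- .draw_intron_len(params)
  if (identical(regulation, "up"))
    i_len <- .r3(i_len * params$up_ir_length_factor)
  donor_class <- if (identical(regulation, "up")) "weak" else "strong"
  stop_at <- if (category == "unproductive_on_inclusion")
    .mid_stop_offset(i_len) else NULL
  u5 <- params$utr5_len; u3 <- params$utr3_len
  segs <- data.frame(
    kind = c("exon", "intron", "exon", "intron", "exon", "intron", "exon"),
    seq = c(
      paste0(.tfree(u5), "ATG", .cds_chunk(cc[1] - 3L, params)),
      .intron_constitutive(.draw_intron_len(params), params),
      .cds_chunk(cc[2], params),
      .intron_translatable(i_len, params, donor_class, stop_at),
      .cds_chunk(cc[3], params),
      .intron_constitutive(.draw_intron_len(params), params),
      paste0(.cds_chunk(cc[4], params, donor_end = FALSE), "TAA", .tfree(u3))
    ), stringsAsFactors = FALSE)
  list(segs = segs,
       cds = c(u5 + 1L, u5 + sum(cc) + 3L),
       event = list(type = "IR", region = "CDS", category = category,
                    regulation = regulation, intron_rank = 2L,
                    host_rank = NA_integer_, ext_len = NA_integer_,
                    nmd_on_inclusion = category == "unproductive_on_inclusion",
                    nmd_on_exclusion = FALSE,
                    alt_len = i_len, donor_class = donor_class))
}

.build_ir_utr5 <- function(regulation, params) {
  cc <- replicate(2, .draw_chunk(params))
  i_len <- .draw_intron_len(params)
  if (identical(regulation, "up"))
    i_len <- .r3(i_len * params$up_ir_length_factor)
  donor_class <- if (identical(regulation, "up")) "weak" else "strong"
  segs <- data.frame(
    kind = c("exon", "intron", "exon", "intron", "exon"),
    seq = c(
      .tfree(60L),
      .intron_translatable(i_len, params, donor_class),
      paste0(.tfree(30L), "ATG", .cds_chunk(cc[1] - 3L, params)),
      .intron_constitutive(.draw_intron_len(params), params),
      paste0(.cds_chunk(cc[2], params, donor_end = FALSE), "TAA",
             .tfree(params$utr3_len))
    ), stringsAsFactors = FALSE)
  list(segs = segs,
       cds = c(91L, 90L + sum(cc) + 3L),
       event = list(type = "IR", region = "UTR5", category = NA_character_,
                    regulation = regulation, intron_rank = 1L,
                    host_rank = NA_integer_, ext_len = NA_integer_,
                    nmd_on_inclusion = FALSE, nmd_on_exclusion = FALSE,
                    alt_len = i_len, donor_class = donor_class))
}

.build_ir_utr3 <- function(regulation, params) {
  cc <- replicate(3, .draw_chunk(params))
  i_len <- .draw_intron_len(params)
  if (identical(regulation, "up"))
    i_len <- .r3(i_len * params$up_ir_length_factor)
  donor_class <- if (identical(regulation, "up")) "weak" else "strong"
  u5 <- params$utr5_len
  # stop sits 30 nt (< 50) upstream of the UTR3 junction, so the reference
  # isoform is not itself an NMD target
  segs <- data.frame(
    kind = c("exon", "intron", "exon", "intron", "exon", "intron", "exon"),
    seq = c(
      paste0(.tfree(u5), "ATG", .cds_chunk(cc[1] - 3L, params)),
      .intron_constitutive(.draw_intron_len(params), params),
      .cds_chunk(cc[2], params),
      .intron_constitutive(.draw_intron_len(params), params),
      paste0(.cds_chunk(cc[3], params, donor_end = FALSE), "TAA", .tfree(30L)),
      .intron_translatable(i_len, params, donor_class),
      .tfree(60L)
    ), stringsAsFactors = FALSE)
  list(segs = segs,
       cds = c(u5 + 1L, u5 + sum(cc) + 3L),
       event = list(type = "IR", region = "UTR3", category = NA_character_,
                    regulation = regulation, intron_rank = 3L,
                    host_rank = NA_integer_, ext_len = NA_integer_,
                    nmd_on_inclusion = FALSE, nmd_on_exclusion = FALSE,
                    alt_len = i_len, donor_class = donor_class))
}

.build_es_cds <- function(category, regulation, params) {
  cc <- replicate(4, .draw_chunk(params))          # c1, c2, c4, c5
  flank_factor <- if (identical(regulation, "down"))
    params$down_es_intron_factor else 1
  flank_ss <- if (regulation %in% c("up", "down")) "weak" else "strong"
  alt_len <- if (category == "unproductive_on_exclusion") 50L
             else .r3(round(stats::runif(1, 60, 120)))
  alt_seq <- .cds_chunk(alt_len, params)
  if (category == "unproductive_on_inclusion")
    alt_seq <- .substr_set(alt_seq, .mid_stop_offset(alt_len, lo = 4L,
                                                     hi_margin = 5L), "TAA")
  # for a planted PTC-on-exclusion, the 50-nt alt exon shifts the frame
  # when skipped; the downstream exon is 151 nt so that the inclusion
  # (reference) CDS remains a codon multiple (50 + 151 == 0 mod 3)
  c4 <- if (category == "unproductive_on_exclusion") 151L else cc[3]
  e4 <- .cds_chunk(c4, params)
  if (category == "unproductive_on_exclusion") {
    # codon-aligned in the exclusion (frame-shifted) isoform only:
    # e4 starts at CDS offset c1+c2 there, a multiple of 3, so local
    # offsets == 1 (mod 3) are in frame after the skip
    e4 <- .substr_set(e4, 31L, "TAA")
  }
  segs <- data.frame(
    kind = c("exon", "intron", "exon", "intron", "exon", "intron", "exon",
             "intron", "exon"),
    seq = c(
      paste0(.tfree(params$utr5_len), "ATG", .cds_chunk(cc[1] - 3L, params)),
      .intron_constitutive(.draw_intron_len(params), params),
      .cds_chunk(cc[2], params),
      .intron_constitutive(.r3(.draw_intron_len(params) * flank_factor),
                           params, ss_strength = flank_ss),
      alt_seq,
      .intron_constitutive(.r3(.draw_intron_len(params) * flank_factor),
                           params, ss_strength = flank_ss),
      e4,
      .intron_constitutive(.draw_intron_len(params), params),
      paste0(.cds_chunk(cc[4], params, donor_end = FALSE), "TAA",
             .tfree(params$utr3_len))
    ), stringsAsFactors = FALSE)
  u5 <- params$utr5_len
  list(segs = segs,
       cds = c(u5 + 1L, u5 + cc[1] + cc[2] + alt_len + c4 + cc[4] + 3L),
       event = list(type = "ES", region = "CDS", category = category,
                    regulation = regulation, intron_rank = NA_integer_,
                    host_rank = NA_integer_, ext_len = NA_integer_,
                    nmd_on_inclusion = category == "unproductive_on_inclusion",
                    nmd_on_exclusion = category == "unproductive_on_exclusion",
                    alt_len = alt_len, donor_class = flank_ss,
                    exon_rank = 3L))
}

.build_alt5_cds <- function(category, regulation, params) {
  cc <- replicate(4, .draw_chunk(params))
  a <- .r3(round(stats::runif(1, 24, 60)))
  donor_class <- if (regulation %in% c("up", "down")) "weak" else "strong"
  # extension = first `a` nt of intron 2; its own first two bases are the
  # proximal (exclusion) donor GT, retained in frame when included
  ext <- paste0("GT", .tfree(a - 2L))
  if (category == "unproductive_on_inclusion")
    ext <- .substr_set(ext, .mid_stop_offset(a, lo = 4L, hi_margin = 5L),
                       "TAA")
  core <- .intron_constitutive(.draw_intron_len(params), params,
                               ss_strength = donor_class)
  segs <- data.frame(
    kind = c("exon", "intron", "exon", "intron", "exon", "intron", "exon"),
    seq = c(
      paste0(.tfree(params$utr5_len), "ATG", .cds_chunk(cc[1] - 3L, params)),
      .intron_constitutive(.draw_intron_len(params), params),
      .cds_chunk(cc[2], params),
      paste0(ext, core),
      .cds_chunk(cc[3], params),
      .intron_constitutive(.draw_intron_len(params), params),
      paste0(.cds_chunk(cc[4], params, donor_end = FALSE), "TAA",
             .tfree(params$utr3_len))
    ), stringsAsFactors = FALSE)
  u5 <- params$utr5_len
  list(segs = segs,
       cds = c(u5 + 1L, u5 + sum(cc) + 3L),
       event = list(type = "ALT5", region = "CDS", category = category,
                    regulation = regulation, intron_rank = 2L,
                    host_rank = 2L, ext_len = a,
                    nmd_on_inclusion = category == "unproductive_on_inclusion",
                    nmd_on_exclusion = FALSE,
                    alt_len = a, donor_class = donor_class))
}

.build_alt3_cds <- function(category, regulation, params) {
  cc <- replicate(4, .draw_chunk(params))
  a <- .r3(round(stats::runif(1, 33, 63)))
  donor_class <- if (regulation %in% c("up", "down")) "weak" else "strong"
  # extension = last `a` nt of intron 2, ending with the distal (exclusion)
  # acceptor AG; the proximal (inclusion) acceptor terminates the core
  tract <- .rand_bases(17L, c("C", "A", "G"), c(0.7, 0.15, 0.15))
  ext <- paste0(.tfree(a - 20L), tract, "CAG")
  if (category == "unproductive_on_inclusion")
    ext <- .substr_set(ext, 4L, "TAA")
  core <- .intron_constitutive(.draw_intron_len(params), params,
                               ss_strength = donor_class)
  segs <- data.frame(
    kind = c("exon", "intron", "exon", "intron", "exon", "intron", "exon"),
    seq = c(
      paste0(.tfree(params$utr5_len), "ATG", .cds_chunk(cc[1] - 3L, params)),
      .intron_constitutive(.draw_intron_len(params), params),
      .cds_chunk(cc[2], params),
      paste0(core, ext),
      .cds_chunk(cc[3], params),
      .intron_constitutive(.draw_intron_len(params), params),
      paste0(.cds_chunk(cc[4], params, donor_end = FALSE), "TAA",
             .tfree(params$utr3_len))
    ), stringsAsFactors = FALSE)
  u5 <- params$utr5_len
  list(segs = segs,
       cds = c(u5 + 1L, u5 + sum(cc) + 3L),
       event = list(type = "ALT3", region = "CDS", category = category,
                    regulation = regulation, intron_rank = 2L,
                    host_rank = 3L, ext_len = a,
                    nmd_on_inclusion = category == "unproductive_on_inclusion",
                    nmd_on_exclusion = FALSE,
                    alt_len = a, donor_class = donor_class))
}

.build_gene_local <- function(type, region, category, regulation, params) {
  if (type == "IR") {
    switch(region,
           CDS  = .build_ir_cds(category, regulation, params),
           UTR5 = .build_ir_utr5(regulation, params),
           UTR3 = .build_ir_utr3(regulation, params))
  } else if (type == "ES") {
    .build_es_cds(category, regulation, params)
  } else if (type == "ALT5") {
    .build_alt5_cds(category, regulation, params)
  } else {
    .build_alt3_cds(category, regulation, params)
  }
}

# ---- assembly onto a genome ------------------------------------------------

# map a pre-mRNA (transcript-orientation, 1-based) interval to genomic
# coordinates for a gene occupying offset+1 .. offset+L
.tx_to_genomic <- function(t0, t1, offset, L, strand) {
  if (strand == "+") c(offset + t0, offset + t1)
  else c(offset + L - t1 + 1L, offset + L - t0 + 1L)
}

.assemble_gene <- function(local, gene_id, chrom, strand, offset) {
  segs <- local$segs
  segs$len <- nchar(segs$seq)
  L <- sum(segs$len)
  t1 <- cumsum(segs$len)
  t0 <- t1 - segs$len + 1L
  pre <- paste(segs$seq, collapse = "")
  gseq <- if (strand == "+") pre else .revcomp(pre)

  is_exon <- segs$kind == "exon"
  ex_idx <- which(is_exon)
  exons <- do.call(rbind, lapply(seq_along(ex_idx), function(r) {
    g <- .tx_to_genomic(t0[ex_idx[r]], t1[ex_idx[r]], offset, L, strand)
    data.frame(gene_id = gene_id, rank = r, gstart = g[1], gend = g[2],
               stringsAsFactors = FALSE)
  }))

  # mature-transcript position -> genomic
  mat_len <- cumsum(segs$len[ex_idx])
  mat_before <- c(0L, mat_len[-length(mat_len)])
  mature_to_genomic <- function(m) {
    k <- which(m > mat_before & m <= mat_len)[1]
    tp <- t0[ex_idx[k]] + (m - mat_before[k]) - 1L
    .tx_to_genomic(tp, tp, offset, L, strand)[1]
  }
  cds_g <- sort(c(mature_to_genomic(local$cds[1]),
                  mature_to_genomic(local$cds[2])))

  ev <- local$event
  # genomic interval of the alternative sequence
  if (ev$type == "IR") {
    in_idx <- which(!is_exon)[ev$intron_rank]
    ag <- .tx_to_genomic(t0[in_idx], t1[in_idx], offset, L, strand)
  } else if (ev$type == "ES") {
    k <- ex_idx[ev$exon_rank]
    ag <- .tx_to_genomic(t0[k], t1[k], offset, L, strand)
  } else if (ev$type == "ALT5") {
    in_idx <- which(!is_exon)[ev$intron_rank]
    ag <- .tx_to_genomic(t0[in_idx], t0[in_idx] + ev$ext_len - 1L,
                         offset, L, strand)
  } else {                                          # ALT3
    in_idx <- which(!is_exon)[ev$intron_rank]
    ag <- .tx_to_genomic(t1[in_idx] - ev$ext_len + 1L, t1[in_idx],
                         offset, L, strand)
  }
  ag <- sort(ag)

  gene <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    gstart = offset + 1L, gend = offset + L,
    tx_len = sum(segs$len[is_exon]),
    cds_tx_start = local$cds[1], cds_tx_end = local$cds[2],
    cds_glo = cds_g[1], cds_ghi = cds_g[2],
    mappable_length = sum(segs$len[is_exon]),
    n_exons = length(ex_idx), stringsAsFactors = FALSE)

  event <- data.frame(
    event_id = NA_character_, gene_id = gene_id,
    event_type = ev$type, region = ev$region,
    chrom = chrom, strand = strand,
    alt_start = ag[1], alt_end = ag[2], alt_len = ev$alt_len,
    anchor_rank = if (ev$type == "ES") ev$exon_rank else ev$intron_rank,
    host_rank = ev$host_rank,
    regulation = ev$regulation, category = ev$category,
    nmd_on_inclusion = ev$nmd_on_inclusion,
    nmd_on_exclusion = ev$nmd_on_exclusion,
    frame_preserved = ev$alt_len %% 3L == 0L,
    donor_class = ev$donor_class, stringsAsFactors = FALSE)

  list(gene = gene, exons = exons, event = event, gseq = gseq, len = L)
}

# Validate the productive isoform: the all-constitutive reference, except
# for ES events planting a PTC on inclusion (poison exons), whose productive
# isoform is the exon-skipped one.
.check_reference_orf <- function(gene_row, exons, genome, event_row) {
  expected_stop <- gene_row$cds_tx_end - 2L
  if (event_row$event_type == "ES" && isTRUE(event_row$nmd_on_inclusion)) {
    exons <- exons[exons$rank != event_row$anchor_rank, ]
    expected_stop <- expected_stop - event_row$alt_len
  }
  mat <- .mature_sequence(exons, genome[[gene_row$chrom]], gene_row$strand)
  cs <- gene_row$cds_tx_start
  if (substr(mat, cs, cs + 2L) != "ATG")
    stop("constraint violation in ", event_row$event_id,
         ": productive CDS of ", gene_row$gene_id,
         " does not begin with ATG")
  fs <- .first_stop(mat, cs)
  if (is.na(fs) || fs != expected_stop)
    stop("constraint violation in ", event_row$event_id,
         ": productive ORF of ", gene_row$gene_id,
         " has a premature or missing stop")
  invisible(TRUE)
}

# mature (all-constitutive reference) transcript sequence; exon rows are in
# transcript order (for minus-strand genes rank 1 is genomically last), so
# each genomic piece is reverse-complemented individually
.mature_sequence <- function(exons, chrom_seq, strand) {
  exons <- exons[order(exons$rank), ]
  pieces <- substring(as.character(chrom_seq), exons$gstart, exons$gend)
  if (strand == "-") pieces <- vapply(pieces, .revcomp, character(1))
  paste(pieces, collapse = "")
}

#' Generate a synthetic annotation with planted AS events
#'
#' Builds `n_genes` multi-exon gene models (one planted alternative-splicing
#' event per gene), a toy genome holding them on both strands of
#' `params$n_chroms` chromosomes, and the event table. Constructed
#' sequences guarantee the intended ORF impact: planted
#' unproductive-on-inclusion events carry an in-frame stop at least 50 nt
#' upstream of a downstream exon-exon junction of the inclusion isoform,
#' and protein-isoform events are frame-preserving with no internal stop.
#'
#' @param n_genes number of genes (one AS event each).
#' @param params generator parameters, see [sim_params()].
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param validate check the reference ORF of every gene (ATG start, single
#'   terminal stop, length a codon multiple) and fail with the offending
#'   event named.
#' @return An object of class `as_annotation`: list with elements `genes`,
#'   `exons`, `events` (data.frames), `genome`
#'   ([Biostrings::DNAStringSet]), and `params`.
#' @export
generate_annotation <- function(n_genes = 300L, params = sim_params(),
                                seed = 1L, validate = TRUE) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  types <- sample(names(params$type_mix), n_genes, TRUE, params$type_mix)
  regions <- ifelse(
    types == "IR",
    sample(names(params$region_mix), n_genes, TRUE, params$region_mix),
    "CDS")
  # direction coupled to type (retained introns are mostly up-regulated)
  regulated <- stats::runif(n_genes) < params$p_regulated
  p_up <- ifelse(types == "IR", params$p_up_ir, params$p_up_other)
  regulation <- ifelse(!regulated, "null",
                       ifelse(stats::runif(n_genes) < p_up, "up", "down"))
  # category coupled to direction for regulated events (most regulated
  # events increase the unproductive isoform under the signal); nulls get
  # the unconditional mix. Exclusion-unproductive events require a
  # skippable exon; infeasible combinations fall back to protein_isoform.
  categories <- vapply(seq_len(n_genes), function(i) {
    if (regions[i] != "CDS") return(NA_character_)
    if (regulation[i] == "null") {
      mix <- params$category_mix
      if (types[i] != "ES")
        mix <- mix[names(mix) != "unproductive_on_exclusion"]
      return(sample(names(mix), 1L, prob = mix))
    }
    role <- sample(names(params$cat_regulated), 1L,
                   prob = params$cat_regulated)
    wanted <- if (role == "protein") "protein_isoform"
      else if ((role == "aligned") == (regulation[i] == "up"))
        "unproductive_on_inclusion"
      else "unproductive_on_exclusion"
    if (wanted == "unproductive_on_exclusion" && types[i] != "ES")
      wanted <- "protein_isoform"
    wanted
  }, character(1))

  chroms <- paste0("chr", seq_len(params$n_chroms))
  offsets <- stats::setNames(rep(0L, length(chroms)), chroms)
  chrom_parts <- stats::setNames(
    lapply(chroms, function(x) list(.dna(params$spacer_len))), chroms)
  offsets[] <- params$spacer_len

  genes <- vector("list", n_genes)
  exons <- vector("list", n_genes)
  events <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    gene_id <- sprintf("GENE%04d", i)
    chrom <- chroms[((i - 1L) %% length(chroms)) + 1L]
    strand <- if (i %% 2L == 0L) "-" else "+"
    local <- .build_gene_local(types[i], regions[i], categories[i],
                               regulation[i], params)
    asm <- .assemble_gene(local, gene_id, chrom, strand, offsets[[chrom]])
    asm$event$event_id <- sprintf("EV%04d_%s", i, types[i])
    genes[[i]] <- asm$gene
    exons[[i]] <- asm$exons
    events[[i]] <- asm$event
    chrom_parts[[chrom]] <- c(chrom_parts[[chrom]],
                              list(asm$gseq, .dna(params$spacer_len)))
    offsets[[chrom]] <- offsets[[chrom]] + asm$len + params$spacer_len
  }

  genome <- Biostrings::DNAStringSet(vapply(
    chrom_parts, function(p) paste(unlist(p), collapse = ""), character(1)))
  names(genome) <- chroms

  ann <- structure(list(genes = do.call(rbind, genes),
                        exons = do.call(rbind, exons),
                        events = do.call(rbind, events),
                        genome = genome,
                        params = params),
                   class = "as_annotation")
  if (validate) {
    for (i in seq_len(n_genes)) {
      g <- ann$genes[i, ]
      .check_reference_orf(g, ann$exons[ann$exons$gene_id == g$gene_id, ],
                           genome, ann$events[i, ])
    }
  }
  ann
}

#' @export
print.as_annotation <- function(x, ...) {
  cat("Synthetic AS annotation:", nrow(x$genes), "genes,",
      nrow(x$events), "events on", length(x$genome), "chromosomes\n")
  cat("Event types:", paste(names(table(x$events$event_type)),
                            table(x$events$event_type), collapse = ", "),
      "\n")
  invisible(x)
}
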