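# Shared fixtures: small generated annotations, a hand-built two-gene
# annotation with known coordinates, quantification-record builders, and an
# independent codon-walking ORF oracle that shares no code with the
# package's isoform-reconstruction path.

small_annotation <- function(n = 40L, seed = 101L, ...) {
  p <- sim_params(n_genes = as.integer(n), ...)
  generate_annotation(p$n_genes, p, seed = seed)
}

# hand-built annotation: one plus-strand and one minus-strand gene with a
# CDS spanning exons 1-3 and a single intron-retention event each.
# Gene layout (transcript orientation): exon1 60 nt (30 UTR5 + 30 CDS),
# intron1 60 nt, exon2 90 nt CDS, intron2 60 nt, exon3 120 nt (60 CDS incl
# stop + 60 UTR3).
manual_annotation <- function() {
  u5 <- strrep("CAG", 10)                                     # 30 nt
  cds1 <- strrep("GCC", 9)                                    # 27 nt
  i1 <- paste0("GTAAGT", strrep("C", 52), "AG")               # 60 nt
  e2 <- strrep("GGC", 30)                                     # 90 nt
  i2 <- paste0("GT", strrep("G", 38), strrep("C", 17), "CAG") # 60 nt
  cds3 <- strrep("GCA", 19)                                   # 57 nt
  u3 <- strrep("CAA", 20)                                     # 60 nt
  pre <- paste0(u5, "ATG", cds1, i1, e2, i2, cds3, "TAA", u3)
  stopifnot(nchar(pre) == 390)
  genome_plus <- pre
  genome_minus <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(pre)))
  genome <- Biostrings::DNAStringSet(c(
    chrP = paste0(strrep("A", 50), genome_plus, strrep("A", 50)),
    chrM = paste0(strrep("A", 50), genome_minus, strrep("A", 50))))
  # transcript-orientation segment spans within the 390-nt gene body
  ex_t <- rbind(c(1, 60), c(121, 210), c(271, 390))
  cds_t <- c(31, 210)       # mature-transcript coordinates
  off <- 50L; L <- 390L
  plus_ex <- data.frame(gene_id = "GP", rank = 1:3,
                        gstart = off + ex_t[, 1], gend = off + ex_t[, 2])
  minus_ex <- data.frame(gene_id = "GM", rank = 1:3,
                         gstart = off + L - ex_t[, 2] + 1L,
                         gend = off + L - ex_t[, 1] + 1L)
  # genomic CDS bounds: mature 31 -> premrna 31 (exon1), mature 330 ->
  # premrna 390 - 60 = 330th mature = exon3 position 60 -> premrna 330
  cds_pre <- c(31L, 330L)
  genes <- data.frame(
    gene_id = c("GP", "GM"), chrom = c("chrP", "chrM"),
    strand = c("+", "-"),
    gstart = off + 1L, gend = off + L, tx_len = 270L,
    cds_tx_start = cds_t[1], cds_tx_end = cds_t[2],
    cds_glo = c(off + cds_pre[1], off + L - cds_pre[2] + 1L),
    cds_ghi = c(off + cds_pre[2], off + L - cds_pre[1] + 1L),
    mappable_length = 270L, n_exons = 3L, stringsAsFactors = FALSE)
  events <- data.frame(
    event_id = c("IRP", "IRM"), gene_id = c("GP", "GM"),
    event_type = "IR", region = "CDS", chrom = c("chrP", "chrM"),
    strand = c("+", "-"),
    alt_start = c(off + 211L, off + L - 270L + 1L),
    alt_end = c(off + 270L, off + L - 211L + 1L),
    alt_len = 60L, anchor_rank = 2L, host_rank = NA_integer_,
    regulation = "null", category = "protein_isoform",
    nmd_on_inclusion = FALSE, nmd_on_exclusion = FALSE,
    frame_preserved = TRUE, donor_class = "strong",
    stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = rbind(plus_ex, minus_ex),
                 events = events, genome = genome, params = sim_params()),
            class = "as_annotation")
}

# quantification rows of the shape produced by merge_replicates()
make_quant <- function(event_id, event_type, inc, exc,
                       inc_j1 = NA_real_, inc_j2 = NA_real_,
                       host_inc = NA_real_, host_exc = NA_real_,
                       condition = "x") {
  event_type <- rep_len(event_type, length(event_id))
  inc_eff <- ifelse(event_type == "IR", (inc_j1 + inc_j2) / 2, inc)
  data.frame(event_id = event_id, event_type = event_type,
             condition = condition, inc = inc, exc = exc,
             inc_j1 = inc_j1, inc_j2 = inc_j2,
             host_inc = host_inc, host_exc = host_exc,
             psi = compute_psi(inc_eff, exc),
             tier = score_coverage(inc_eff, exc),
             host_psi = compute_psi(host_inc, host_exc),
             stringsAsFactors = FALSE)
}

# ---- independent ORF oracle ------------------------------------------------
# Builds each isoform as an explicit set of genomic positions, derives the
# transcript sequence, junctions and CDS start from that set, walks codons
# with Biostrings::translate, and applies the 50-nt rule. No shared code
# with .isoform_blocks()/reconstruct_isoforms()/detect_ptc().

oracle_isoform <- function(ann, event, which_iso) {
  gene <- ann$genes[ann$genes$gene_id == event$gene_id, ]
  exons <- ann$exons[ann$exons$gene_id == event$gene_id, ]
  ref_pos <- sort(unique(unlist(mapply(seq, exons$gstart, exons$gend,
                                       SIMPLIFY = FALSE))))
  alt_pos <- seq(event$alt_start, event$alt_end)
  pos <- if (event$event_type == "ES") {
    if (which_iso == "inclusion") ref_pos else setdiff(ref_pos, alt_pos)
  } else {
    if (which_iso == "inclusion") sort(union(ref_pos, alt_pos)) else ref_pos
  }
  chrom <- as.character(ann$genome[[gene$chrom]])
  bases <- substring(chrom, pos, pos)
  seq_plus <- paste(bases, collapse = "")
  runs <- rle(cumsum(c(1L, diff(pos) != 1L)))$lengths
  if (gene$strand == "+") {
    seq <- seq_plus
    junctions <- cumsum(runs)
    atg_idx <- which(pos == gene$cds_glo)
  } else {
    seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq_plus)))
    junctions <- cumsum(rev(runs))
    atg_idx <- length(pos) - which(pos == gene$cds_ghi) + 1L
  }
  junctions <- junctions[-length(junctions)]
  list(seq = seq, junctions = junctions, cds_start = atg_idx)
}

oracle_first_stop <- function(seq, cds_start) {
  sub <- substring(seq, cds_start, nchar(seq))
  sub <- substring(sub, 1, 3 * (nchar(sub) %/% 3))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(sub),
                          if.fuzzy.codon = "X")))
  hit <- regexpr("*", aa, fixed = TRUE)
  if (hit < 0) NA_integer_ else cds_start + (as.integer(hit) - 1L) * 3L
}

oracle_is_ptc <- function(iso, min_dist = 50) {
  fs <- oracle_first_stop(iso$seq, iso$cds_start)
  if (is.na(fs)) return(FALSE)
  any(iso$junctions - (fs + 2L) >= min_dist)
}

oracle_category <- function(ann, event, min_dist = 50) {
  gene <- ann$genes[ann$genes$gene_id == event$gene_id, ]
  # region by genomic comparison, written independently
  upstream <- if (gene$strand == "+") event$alt_end < gene$cds_glo
              else event$alt_start > gene$cds_ghi
  downstream <- if (gene$strand == "+") event$alt_start > gene$cds_ghi
                else event$alt_end < gene$cds_glo
  if (upstream) return("UTR5")
  if (downstream) return("UTR3")
  inc <- oracle_is_ptc(oracle_isoform(ann, event, "inclusion"), min_dist)
  exc <- oracle_is_ptc(oracle_isoform(ann, event, "exclusion"), min_dist)
  if (inc && !exc) "unproductive_on_inclusion"
  else if (!inc && exc) "unproductive_on_exclusion"
  else if (!inc && !exc) "protein_isoform"
  else "degenerate"
}

# mirror an annotation: reverse-complement every chromosome, flip strands
# and mirror all coordinates (strand-invariance checks)
flip_annotation <- function(ann) {
  lens <- stats::setNames(Biostrings::width(ann$genome),
                          names(ann$genome))
  mirror <- function(chrom, s, e) {
    L <- lens[[chrom]]
    cbind(L - e + 1L, L - s + 1L)
  }
  out <- ann
  out$genome <- Biostrings::reverseComplement(ann$genome)
  names(out$genome) <- names(ann$genome)
  g <- ann$genes
  m <- t(mapply(function(ch, s, e) mirror(ch, s, e)[1, ],
                g$chrom, g$gstart, g$gend))
  g$gstart <- as.integer(m[, 1]); g$gend <- as.integer(m[, 2])
  mc <- t(mapply(function(ch, s, e) mirror(ch, s, e)[1, ],
                 ann$genes$chrom, ann$genes$cds_glo, ann$genes$cds_ghi))
  g$cds_glo <- as.integer(mc[, 1]); g$cds_ghi <- as.integer(mc[, 2])
  g$strand <- ifelse(ann$genes$strand == "+", "-", "+")
  out$genes <- g
  ex <- ann$exons
  chrom_of <- stats::setNames(ann$genes$chrom, ann$genes$gene_id)
  me <- t(mapply(function(ch, s, e) mirror(ch, s, e)[1, ],
                 chrom_of[ex$gene_id], ex$gstart, ex$gend))
  ex$gstart <- as.integer(me[, 1]); ex$gend <- as.integer(me[, 2])
  out$exons <- ex
  ev <- ann$events
  mv <- t(mapply(function(ch, s, e) mirror(ch, s, e)[1, ],
                 ev$chrom, ev$alt_start, ev$alt_end))
  ev$alt_start <- as.integer(mv[, 1]); ev$alt_end <- as.integer(mv[, 2])
  ev$strand <- ifelse(ann$events$strand == "+", "-", "+")
  out$events <- ev
  out
}
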