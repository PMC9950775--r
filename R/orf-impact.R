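# ORF impact of AS events: gene-region classification, inclusion/exclusion
# isoform reconstruction, premature-stop detection under the 50-nt rule,
# the three-way productivity category and the repressive-event flag.

.gene_row <- function(annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown gene: ", gene_id)
  g
}

.gene_exons <- function(annotation, gene_id) {
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, ]
  ex[order(ex$rank), ]
}

# genomic exon blocks (transcript order) of one isoform of an event
.isoform_blocks <- function(exons, event, isoform) {
  type <- event$event_type
  if (type == "IR") {
    if (isoform == "exclusion") return(exons[, c("gstart", "gend")])
    r <- event$anchor_rank
    merged <- exons[, c("gstart", "gend")]
    merged$gstart[r] <- min(exons$gstart[r], exons$gstart[r + 1])
    merged$gend[r] <- max(exons$gend[r], exons$gend[r + 1])
    return(merged[-(r + 1), ])
  }
  if (type == "ES") {
    if (isoform == "inclusion") return(exons[, c("gstart", "gend")])
    return(exons[-event$anchor_rank, c("gstart", "gend")])
  }
  # ALT5 / ALT3: inclusion extends the host exon across the alt interval
  if (isoform == "exclusion") return(exons[, c("gstart", "gend")])
  h <- event$host_rank
  blocks <- exons[, c("gstart", "gend")]
  blocks$gstart[h] <- min(blocks$gstart[h], event$alt_start)
  blocks$gend[h] <- max(blocks$gend[h], event$alt_end)
  blocks
}

.blocks_sequence <- function(blocks, chrom_seq, strand) {
  pieces <- substring(as.character(chrom_seq), blocks$gstart, blocks$gend)
  if (strand == "-") pieces <- vapply(pieces, .revcomp, character(1))
  paste(pieces, collapse = "")
}

# transcript coordinate of a genomic position within transcript-ordered
# blocks (NA if not contained)
.map_genomic_to_tx <- function(blocks, strand, gpos) {
  widths <- blocks$gend - blocks$gstart + 1L
  before <- cumsum(c(0L, widths[-length(widths)]))
  for (k in seq_len(nrow(blocks))) {
    if (gpos >= blocks$gstart[k] && gpos <= blocks$gend[k]) {
      off <- if (strand == "+") gpos - blocks$gstart[k] + 1L
             else blocks$gend[k] - gpos + 1L
      return(before[k] + off)
    }
  }
  NA_integer_
}

#' Classify the gene region of an AS event
#'
#' Determines whether the alternative sequence lies in the 5'UTR, CDS or
#' 3'UTR of its host gene, in transcript orientation. Spans straddling a
#' CDS boundary are assigned to CDS.
#'
#' @param event one row of the events data.frame.
#' @param gene matching row of the genes data.frame.
#' @return one of "UTR5", "CDS", "UTR3".
#' @export
classify_region <- function(event, gene) {
  if (event$alt_start < gene$gstart || event$alt_end > gene$gend)
    stop("event ", event$event_id, " lies outside the span of gene ",
         gene$gene_id)
  if (gene$strand == "+") {
    if (event$alt_end < gene$cds_glo) return("UTR5")
    if (event$alt_start > gene$cds_ghi) return("UTR3")
  } else {
    if (event$alt_start > gene$cds_ghi) return("UTR5")
    if (event$alt_end < gene$cds_glo) return("UTR3")
  }
  "CDS"
}

#' Reconstruct the inclusion and exclusion mRNA isoforms of an event
#'
#' The inclusion mRNA contains the alternative sequence spliced in (IR:
#' intron retained, so its two flanking junctions vanish; ES: exon
#' present with both junctions; ALT5/ALT3: host exon extended across the
#' alternative interval); the exclusion mRNA is the complement.
#' Minus-strand genes are reverse-complemented into transcript
#' orientation.
#'
#' @param annotation an `as_annotation`.
#' @param event one row of `annotation$events`.
#' @return list with `inclusion` and `exclusion`, each holding `seq`
#'   (mRNA sequence), `junctions` (transcript positions of the last
#'   nucleotide of each exon except the final one) and `cds_start`
#'   (transcript coordinate of the annotated start codon).
#' @export
reconstruct_isoforms <- function(annotation, event) {
  gene <- .gene_row(annotation, event$gene_id)
  exons <- .gene_exons(annotation, event$gene_id)
  chrom_seq <- annotation$genome[[gene$chrom]]
  atg_g <- if (gene$strand == "+") gene$cds_glo else gene$cds_ghi
  out <- lapply(c(inclusion = "inclusion", exclusion = "exclusion"),
                function(iso) {
    blocks <- .isoform_blocks(exons, event, iso)
    widths <- blocks$gend - blocks$gstart + 1L
    list(seq = .blocks_sequence(blocks, chrom_seq, gene$strand),
         junctions = cumsum(widths)[-length(widths)],
         cds_start = .map_genomic_to_tx(blocks, gene$strand, atg_g))
  })
  # sanity: the alternative interval must be consistent with the exon chain
  if (nchar(out$inclusion$seq) - nchar(out$exclusion$seq) !=
      (event$alt_end - event$alt_start + 1L))
    stop("alternative interval of ", event$event_id,
         " is inconsistent with the exon structure")
  out
}

#' Detect a premature termination codon under the 50-nt junction rule
#'
#' Translates from `cds_start` to the first in-frame stop codon. The stop
#' is premature (NMD-eliciting) iff an exon-exon junction lies at least
#' `min_dist` nucleotides downstream of the stop codon's last nucleotide
#' (default 50, inclusive: exactly 50 triggers). Under
#' `rule = "last_junction"` only the final junction is considered
#' (equivalent for a single stop). Absence of any in-frame stop is flagged
#' as nonstop, not PTC.
#'
#' @param seq mRNA sequence (character).
#' @param cds_start transcript coordinate of the start codon.
#' @param junctions transcript positions of exon-exon junctions (last
#'   nucleotide of each non-final exon).
#' @param min_dist minimum stop-to-junction distance, nt.
#' @param rule "any_downstream" (default) or "last_junction".
#' @return list: `stop_pos` (first nucleotide of the stop codon, NA if
#'   nonstop), `d_ptc` (distance to the nearest qualifying downstream
#'   junction, NA if none), `is_ptc`, `nonstop`.
#' @export
detect_ptc <- function(seq, cds_start, junctions, min_dist = 50,
                       rule = c("any_downstream", "last_junction")) {
  rule <- match.arg(rule)
  if (is.na(cds_start) || cds_start < 1 || cds_start + 2 > nchar(seq))
    stop("cds_start out of range")
  if (substr(seq, cds_start, cds_start + 2) != "ATG")
    warning("CDS does not begin with ATG at position ", cds_start)
  fs <- .first_stop(seq, cds_start)
  if (is.na(fs))
    return(list(stop_pos = NA_integer_, d_ptc = NA_real_, is_ptc = FALSE,
                nonstop = TRUE))
  stop_end <- fs + 2L
  d <- junctions - stop_end
  d <- d[d >= min_dist]
  if (rule == "last_junction") {
    last_d <- if (length(junctions)) max(junctions) - stop_end else -Inf
    is_ptc <- is.finite(last_d) && last_d >= min_dist
    d_ptc <- if (is_ptc) last_d else NA_real_
  } else {
    is_ptc <- length(d) > 0
    d_ptc <- if (is_ptc) min(d) else NA_real_
  }
  list(stop_pos = fs, d_ptc = d_ptc, is_ptc = is_ptc, nonstop = FALSE)
}

#' Classify the ORF impact of one AS event
#'
#' Runs PTC detection on both reconstructed isoforms and assigns the
#' three-way productivity category: `unproductive_on_inclusion` iff only
#' the inclusion isoform carries a PTC, `unproductive_on_exclusion` iff
#' only the exclusion isoform does, `protein_isoform` iff neither.
#' Both-PTC events are recorded as `degenerate` and excluded from
#' three-way percentages downstream. UTR-located events receive no
#' productivity category; 3'UTR events whose exclusion isoform would put
#' the reference stop >= `min_dist` nt upstream of a junction are flagged
#' (`utr3_ptc_flag`).
#'
#' @param annotation an `as_annotation`.
#' @param event one row of `annotation$events`.
#' @param config pipeline configuration (uses `thresholds$ptc_distance`
#'   and `thresholds$ptc_rule`).
#' @return one-row data.frame: region, frame_preserved, PTC flags and
#'   distances per isoform, category, repressive_if_up, repressive_if_down.
#' @export
classify_orf_impact <- function(annotation, event,
                                config = default_config()) {
  th <- config$thresholds
  gene <- .gene_row(annotation, event$gene_id)
  region <- classify_region(event, gene)
  iso <- reconstruct_isoforms(annotation, event)
  frame_preserved <- (event$alt_end - event$alt_start + 1L) %% 3L == 0L

  inc <- detect_ptc(iso$inclusion$seq, iso$inclusion$cds_start,
                    iso$inclusion$junctions, th$ptc_distance, th$ptc_rule)
  exc <- detect_ptc(iso$exclusion$seq, iso$exclusion$cds_start,
                    iso$exclusion$junctions, th$ptc_distance, th$ptc_rule)

  utr3_flag <- FALSE
  if (region == "UTR3") utr3_flag <- exc$is_ptc || inc$is_ptc
  category <- NA_character_
  if (region == "CDS") {
    category <- if (inc$is_ptc && !exc$is_ptc) "unproductive_on_inclusion"
      else if (!inc$is_ptc && exc$is_ptc) "unproductive_on_exclusion"
      else if (!inc$is_ptc && !exc$is_ptc) "protein_isoform"
      else "degenerate"
  }
  data.frame(
    event_id = event$event_id, gene_id = event$gene_id,
    event_type = event$event_type, region = region,
    frame_preserved = frame_preserved,
    ptc_on_inclusion = inc$is_ptc, ptc_on_exclusion = exc$is_ptc,
    stop_pos_inclusion = inc$stop_pos, stop_pos_exclusion = exc$stop_pos,
    d_ptc_inclusion = inc$d_ptc, d_ptc_exclusion = exc$d_ptc,
    nonstop_inclusion = inc$nonstop, nonstop_exclusion = exc$nonstop,
    category = category, utr3_ptc_flag = utr3_flag,
    repressive_if_up = identical(category, "unproductive_on_inclusion"),
    repressive_if_down = identical(category, "unproductive_on_exclusion"),
    stringsAsFactors = FALSE)
}

#' Classify the ORF impact of every event in an annotation
#'
#' @inheritParams classify_orf_impact
#' @return data.frame with one row per event, see [classify_orf_impact()].
#' @export
classify_orf_impacts <- function(annotation, config = default_config()) {
  rows <- lapply(seq_len(nrow(annotation$events)), function(i)
    classify_orf_impact(annotation, annotation$events[i, ], config))
  do.call(rbind, rows)
}

#' Repressive AS event flag
#'
#' An event is repressive when its splicing change under the signal
#' increases the unproductive (NMD-targeted) isoform: inclusion
#' upregulated for unproductive-on-inclusion events, or downregulated for
#' unproductive-on-exclusion events.
#'
#' @param category productivity category (vectorised).
#' @param direction "up" or "down" (vectorised).
#' @return logical.
#' @export
classify_repressive <- function(category, direction) {
  (direction == "up" & category %in% "unproductive_on_inclusion") |
    (direction == "down" & category %in% "unproductive_on_exclusion")
}
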