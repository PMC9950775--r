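#' Generator parameters
#'
#' Returns the full parameter set of the synthetic-data generator, with the
#' study-condition defaults. Any parameter can be overridden by name.
#'
#' The defaults encode the experimental structure the generator emulates:
#' a retrograde effect of `delta` PSI points attenuated by `r_gun1 = 0.5` in
#' the gun1-like genotype, NMD steady-state decay removing a fraction
#' `d_decay = 0.8` of the unproductive isoform at full NMD efficiency, and a
#' sign-flipped light response of strength `lambda_light` on antagonistic
#' events.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list of generator parameters:
#' \describe{
#'   \item{n_genes}{number of genes; one AS event is planted per gene.}
#'   \item{type_mix}{sampling proportions of IR/ALT3/ALT5/ES events.}
#'   \item{region_mix}{region proportions (CDS/UTR5/UTR3) for IR events;
#'     non-IR events are always CDS-located.}
#'   \item{category_mix}{target ORF-impact category proportions for
#'     CDS-located events (unproductive_on_exclusion is only realisable for
#'     ES events; for other types it is re-normalised away).}
#'   \item{cat_regulated}{three-way split of regulated CDS events into
#'     direction-aligned unproductive (repressive), protein-isoform and
#'     direction-opposed unproductive categories; where a combination is
#'     not constructible for a type (exclusion-unproductive requires a
#'     skippable exon) the mass falls back to protein_isoform.}
#'   \item{p_regulated}{fraction of events planted as retrograde-regulated
#'     (split into up/down per type); the rest are nulls.}
#'   \item{p_up_ir, p_up_other}{probability that a regulated IR (resp.
#'     non-IR) event is up-regulated — retained introns are predominantly
#'     up-regulated by retrograde signals.}
#'   \item{delta}{planted effect size, PSI points.}
#'   \item{r_gun1}{retrograde attenuation factor of the gun1-like genotype.}
#'   \item{lambda_light}{strength of the antagonistic light effect.}
#'   \item{antagonistic_frac}{fraction of regulated events that are
#'     light-antagonistic.}
#'   \item{d_decay}{NMD decay fraction applied to PTC-bearing isoforms at
#'     full NMD efficiency.}
#'   \item{depth}{mean junction reads per event and replicate.}
#'   \item{n_replicates}{replicates per condition.}
#'   \item{library_size}{mean mapped reads per gene-count library.}
#'   \item{expr_fold}{planted transcriptional fold change of NF-regulated
#'     genes.}
#'   \item{p_expr_down_repressive, p_expr_down_other}{probability that a
#'     gene is transcriptionally NF-downregulated, for repressive-event
#'     genes and all other genes.}
#'   \item{p_chloro_repressive, p_chloro_other}{probability of chloroplast
#'     subcellular localization for repressive-event genes and others.}
#'   \item{utr5_len, utr3_len}{UTR lengths, nt.}
#'   \item{cds_chunk_range}{range of per-exon CDS chunk lengths, nt
#'     (rounded to codon multiples).}
#'   \item{intron_len_range}{constitutive/AS intron length range, nt.}
#'   \item{up_ir_length_factor}{length multiplier of up-regulated retained
#'     introns (planted regulatory feature).}
#'   \item{down_es_intron_factor}{flanking-intron length multiplier of
#'     down-regulated skipped exons.}
#'   \item{host_low_frac}{fraction of ALT events with a lowly included host
#'     exon (exercises the alt-use filter).}
#'   \item{host_psi_range, host_psi_low_range}{host-exon PSI draws.}
#'   \item{psi0_range}{baseline PSI draw range.}
#'   \item{expr_lnorm}{meanlog/sdlog of baseline expression (cRPKM scale).}
#'   \item{overdispersion}{Gamma-mixing overdispersion of read depth;
#'     0 keeps pure Poisson sampling.}
#'   \item{n_chroms, spacer_len}{genome layout.}
#'   \item{donor_consensus_p}{per-position consensus probability of
#'     constitutive donor/acceptor sites.}
#' }
#' @export
sim_params <- function(...) {
  p <- list(
    n_genes              = 300L,
    type_mix             = c(IR = 0.45, ALT3 = 0.25, ALT5 = 0.15, ES = 0.15),
    region_mix           = c(CDS = 0.70, UTR5 = 0.15, UTR3 = 0.15),
    category_mix         = c(unproductive_on_inclusion = 0.45,
                             protein_isoform           = 0.40,
                             unproductive_on_exclusion = 0.15),
    cat_regulated        = c(aligned = 0.67, protein = 0.25,
                             opposed = 0.08),
    p_regulated          = 0.5,
    p_up_ir              = 0.8,
    p_up_other           = 0.5,
    delta                = 30,
    r_gun1               = 0.5,
    lambda_light         = 1,
    antagonistic_frac    = 1,
    d_decay              = 0.8,
    depth                = 500,
    n_replicates         = 3L,
    library_size         = 2e6,
    expr_fold            = 4,
    p_expr_down_repressive = 0.5,
    p_expr_down_other    = 0.1,
    p_chloro_repressive  = 0.55,
    p_chloro_other       = 0.20,
    utr5_len             = 60L,
    utr3_len             = 60L,
    cds_chunk_range      = c(60L, 150L),
    intron_len_range     = c(87L, 180L),
    up_ir_length_factor  = 3,
    down_es_intron_factor = 2,
    host_low_frac        = 0.1,
    host_psi_range       = c(60, 95),
    host_psi_low_range   = c(5, 20),
    psi0_range           = c(35, 65),
    expr_lnorm           = c(meanlog = log(20), sdlog = 1),
    overdispersion       = 0,
    n_chroms             = 2L,
    spacer_len           = 200L,
    donor_consensus_p    = 0.85
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown generator parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  stopifnot(p$n_genes >= 1,
            abs(sum(p$region_mix) - 1) < 1e-8,
            abs(sum(p$type_mix) - 1) < 1e-8,
            p$depth > 0, p$n_replicates >= 2)
  p
}

#' Default condition grid
#'
#' The condition profiles the generator emulates: a norflurazon (NF)
#' treatment series in WT and a gun1-like genotype, a lincomycin series,
#' a dark/light series in WT and a pifq-like genotype (PIFs inactive, so
#' dark-grown seedlings mimic light responses), and an untreated NMD series
#' (WT and upf-like mutants). `light_state` is `NA` for conditions outside
#' the light experiment; the light term of the truth model only applies
#' within the dark/light grid.
#'
#' @param params generator parameters from [sim_params()].
#' @return data.frame with one row per condition: condition_id, treatment,
#'   retrograde_factor, nmd_efficiency, light_state, pif_active,
#'   n_replicates, depth.
#' @export
condition_profiles <- function(params = sim_params()) {
  prof <- data.frame(
    condition_id     = c("wt_ctrl", "wt_nf", "gun1_nf", "wt_linco",
                         "wt_dark", "wt_light", "pifq_dark", "pifq_light",
                         "nmd_wt", "upf1", "upf3", "upf1upf3"),
    treatment        = c("control", "NF", "NF", "lincomycin",
                         "control", "control", "control", "control",
                         "control", "control", "control", "control"),
    retrograde_factor = c(1, 1, params$r_gun1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    nmd_efficiency   = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0.3, 0.5, 0),
    light_state      = c(NA, NA, NA, NA,
                         "dark", "light", "dark", "light",
                         NA, NA, NA, NA),
    pif_active       = c(NA, NA, NA, NA, TRUE, TRUE, FALSE, FALSE,
                         NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  prof$n_replicates <- params$n_replicates
  prof$depth <- params$depth
  stopifnot(all(prof$retrograde_factor >= 0 & prof$retrograde_factor <= 1),
            all(prof$nmd_efficiency >= 0 & prof$nmd_efficiency <= 1),
            all(prof$depth > 0))
  prof
}
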