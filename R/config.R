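# Pipeline configuration: every threshold of the filter cascade in one
# structured object, serializable to YAML.

#' Default pipeline configuration
#'
#' All thresholds of the analysis with their standard values: strict
#' |dPSI| > 15 for differential splicing, host-exon minimum PSI 25 for
#' ALT events, IR junction-balance p threshold 0.05, PTC distance 50 nt,
#' expression filter at count 50 / cRPKM 5, per-replicate-pair fold
#' change 2 with pseudocount 1, coverage tiers discarded below LOW, PWM
#' windows (donor 3+6, acceptor 20+3) and pseudocount 0.5.
#'
#' @param ... named overrides applied with [utils::modifyList()] (nested
#'   lists merge by name).
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    generator = sim_params(),
    thresholds = list(
      min_dpsi = 15,
      min_alt_use = 25,
      p_ir = 0.05,
      ptc_distance = 50,
      ptc_rule = "any_downstream",
      min_count = 50,
      min_crpkm = 5,
      min_fc = 2,
      pseudocount = 1,
      discard_tiers = c("N", "VLOW"),
      expr_filter_parse = "all_pass_one_sample"
    ),
    tiers = c(VLOW = 5, LOW = 10, OK = 15, SOK = 100),
    pwm = list(pseudocount = 0.5, donor_exonic = 3L, donor_intronic = 6L,
               acceptor_intronic = 20L, acceptor_exonic = 3L),
    posthoc = "wilcox"
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  th <- cfg$thresholds
  num <- c("min_dpsi", "min_alt_use", "p_ir", "ptc_distance", "min_count",
           "min_crpkm", "min_fc", "pseudocount")
  for (nm in num) {
    if (!is.numeric(th[[nm]]) || length(th[[nm]]) != 1 || th[[nm]] <= 0)
      stop("configuration threshold '", nm, "' must be a positive number")
  }
  if (!all(th$discard_tiers %in% c("N", "VLOW", "LOW", "OK", "SOK")))
    stop("unknown coverage tier in discard_tiers")
  invisible(cfg)
}

# coerce YAML-roundtripped structures back to their canonical R types
.normalize_config <- function(cfg) {
  cfg$tiers <- unlist(cfg$tiers)
  cfg$thresholds$discard_tiers <-
    as.character(unlist(cfg$thresholds$discard_tiers))
  for (nm in c("type_mix", "region_mix", "category_mix", "cat_regulated",
               "psi0_range",
               "cds_chunk_range", "intron_len_range", "host_psi_range",
               "host_psi_low_range", "expr_lnorm"))
    if (!is.null(cfg$generator[[nm]]))
      cfg$generator[[nm]] <- unlist(cfg$generator[[nm]])
  cfg$generator$n_genes <- as.integer(cfg$generator$n_genes)
  cfg$generator$n_replicates <- as.integer(cfg$generator$n_replicates)
  cfg$generator$n_chroms <- as.integer(cfg$generator$n_chroms)
  cfg$generator$spacer_len <- as.integer(cfg$generator$spacer_len)
  cfg$generator$utr5_len <- as.integer(cfg$generator$utr5_len)
  cfg$generator$utr3_len <- as.integer(cfg$generator$utr3_len)
  cfg$seed <- as.integer(cfg$seed)
  for (nm in c("donor_exonic", "donor_intronic", "acceptor_intronic",
               "acceptor_exonic"))
    cfg$pwm[[nm]] <- as.integer(cfg$pwm[[nm]])
  .validate_config(cfg)
  cfg
}

#' Write / read a pipeline configuration
#'
#' YAML serialization; `read_config()` restores canonical types so that a
#' written-then-read configuration is identical to the original.
#'
#' @param cfg configuration list from [default_config()].
#' @param path file path.
#' @return `read_config()` returns the configuration list.
#' @export
write_config <- function(cfg, path) {
  # YAML drops the names of atomic vectors; serialize them as maps
  yamlify <- function(x) {
    if (is.list(x)) lapply(x, yamlify)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(yamlify(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  .normalize_config(yaml::read_yaml(path))
}
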