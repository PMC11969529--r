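#' Default run configuration
#'
#' Central parameter set for the whole pipeline. All values are plain
#' numbers in umol/g tissue/min unless noted:
#' \itemize{
#'   \item `cutoff`: expression evidence threshold (mean TPM) above which a
#'     reaction counts as expressed during extraction (default 1).
#'   \item `exchange_lb`/`exchange_ub`: default exchange bounds, -0.01
#'     (bounded uptake, avoiding free metabolite influx) and 1000
#'     (unbounded release).
#'   \item `protocol`: perturbation parameters - ketone-body uptake raised
#'     to 0.050 and glucose to 0.210 under the ketogenic protocol, oxygen
#'     uptake reduced by 0.100 under hypoxia, and the myelin-formation
#'     flux stepped from 0.010 to 0 at 10% intervals (11 levels) for the
#'     demyelination sweep; GABA intercellular flux coupled to 25% of the
#'     glutamine astrocyte-to-neuron cycle flux.
#'   \item `ppp_ratio`: pentose phosphate pathway flux coupled to 5%
#'     (neuron) and 6% (astrocyte) of glucose uptake.
#'   \item `zero_flux_tol`: reactions with |v| > 1e-6 count as active.
#'   \item `reporter`: reporter-metabolite p-value filters (0.05 and the
#'     stricter 0.025) and the background sample size (10000).
#' }
#'
#' @param seed Integer seed recorded in the config and used by stages with
#'   randomness.
#' @return A nested named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cutoff = 1,
    exchange_lb = -0.01,
    exchange_ub = 1000,
    zero_flux_tol = 1e-6,
    ppp_ratio = c(neuron = 0.05, astrocyte = 0.06),
    biomass_fraction = 0.8,
    resting = list(
      glucose_uptake = 0.180,
      oxygen_uptake = 0.205,
      ketone_uptake = 0.001,
      fatty_acid_uptake = 0.005,
      choline_uptake = 0.050,
      ethanolamine_uptake = 0.050,
      ammonia_uptake_oligodendrocyte = 0.030,
      atp_maintenance = c(neuron = 0.62, astrocyte = 0.58)
    ),
    protocol = list(
      cell_suffixes = c("N", "A", "M", "O"),
      glucose_exchange = "EX_glc",
      ketone_exchanges = c("EX_acac", "EX_bhb"),
      oxygen_exchange = "EX_o2",
      myelin_reaction = "MYELIN_O",
      supplemented_glucose = 0.210,
      ketone_uptake = 0.050,
      hypoxia_o2_decrement = 0.100,
      myelin_levels = seq(0.010, 0, by = -0.001),
      myelin_resting_flux = 0.010,
      cycle_reaction = "ICT_gln_A_to_N",
      gaba_reaction = "ICT_gaba_N_to_A",
      gaba_ratio = 0.25
    ),
    reporter = list(
      n_background = 10000L,
      p_threshold = 0.05,
      p_strict = 0.025
    )
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' @param config A `run_config` (e.g. edited copy of
#'   [default_run_config()]).
#' @return The config, invisibly; errors on invalid entries.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  if (is.null(config$cutoff) || config$cutoff <= 0) {
    stop("config error: cutoff must be > 0")
  }
  if (config$exchange_lb > 0) stop("config error: exchange_lb must be <= 0")
  if (config$protocol$gaba_ratio < 0) stop("config error: gaba_ratio must be >= 0")
  if (any(config$protocol$myelin_levels < 0)) {
    stop("config error: myelin levels must be >= 0")
  }
  invisible(config)
}

#' Read/write a run configuration as YAML
#'
#' The YAML round trip is used to echo the effective configuration into
#' every pipeline output directory, so a run can be reproduced from its
#' outputs alone.
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  cfg <- utils::modifyList(cfg, raw)
  cfg$ppp_ratio <- unlist(cfg$ppp_ratio)
  cfg$resting$atp_maintenance <- unlist(cfg$resting$atp_maintenance)
  cfg$protocol$cell_suffixes <- as.character(cfg$protocol$cell_suffixes)
  cfg$protocol$ketone_exchanges <- as.character(cfg$protocol$ketone_exchanges)
  cfg$protocol$myelin_levels <- as.numeric(cfg$protocol$myelin_levels)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$ppp_ratio <- as.list(cfg$ppp_ratio)        # keep names through YAML
  cfg$resting$atp_maintenance <- as.list(cfg$resting$atp_maintenance)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
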