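#' Pipeline run configuration
#'
#' Collects the tunable constants of the pipeline with their defaults:
#' 150-nt precursor flanks, 210-nt scan windows of ten 21-nt phases, at least
#' 18 paired nucleotides and folding energy below -40 kcal/mol for putative
#' precursors, a 10-RPTM abundance floor, mean +/- 0.5 sd biomass grouping,
#' at most 2 mismatches for mature-miRNA homologs and 4 for target sites,
#' and a 0.05 FDR level.
#'
#' @param flank_len nt of flank extracted on each side of a matched locus.
#' @param window_len phasing scan window length in nt.
#' @param phase_len phase (siRNA) length in nt.
#' @param n_phases number of phases per window (`m` of the register test).
#' @param min_paired minimum paired nucleotides in the mature region.
#' @param max_energy precursors must fold with energy strictly below this
#'   (kcal/mol, internal energy model).
#' @param rptm_floor minimum group-mean RPTM to enter differential testing.
#' @param group_sd_factor `f` in the mean +/- f*sd biomass thresholds.
#' @param max_homolog_mm max substitutions for a mature-miRNA homolog hit.
#' @param max_target_mm max (wobble-discounted) mismatches for a target site.
#' @param fdr_alpha BH-adjusted significance level.
#' @param p_max max window P-value to call a phased locus.
#' @param score_min min phase score to call a phased locus.
#' @param min_k minimum phased unique sRNAs for a nonzero phase score.
#' @param seed integer seed driving all randomness of a run.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(flank_len = 150L, window_len = 210L, phase_len = 21L,
                       n_phases = 10L, min_paired = 18L, max_energy = -40,
                       rptm_floor = 10, group_sd_factor = 0.5,
                       max_homolog_mm = 2L, max_target_mm = 4L,
                       fdr_alpha = 0.05, p_max = 0.001, score_min = 5,
                       min_k = 3L, seed = 1L) {
  cfg <- list(flank_len = as.integer(flank_len),
              window_len = as.integer(window_len),
              phase_len = as.integer(phase_len),
              n_phases = as.integer(n_phases),
              min_paired = as.integer(min_paired),
              max_energy = max_energy,
              rptm_floor = rptm_floor,
              group_sd_factor = group_sd_factor,
              max_homolog_mm = as.integer(max_homolog_mm),
              max_target_mm = as.integer(max_target_mm),
              fdr_alpha = fdr_alpha,
              p_max = p_max, score_min = score_min, min_k = as.integer(min_k),
              seed = as.integer(seed))
  counts <- c("flank_len", "window_len", "phase_len", "n_phases",
              "min_paired", "max_homolog_mm", "max_target_mm", "min_k")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) stop(f, " must be a non-negative count")
  }
  if (cfg$window_len != cfg$phase_len * cfg$n_phases) {
    stop("window_len must equal phase_len * n_phases (got ",
         cfg$window_len, " != ", cfg$phase_len, " * ", cfg$n_phases, ")")
  }
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) stop("fdr_alpha must be in (0, 1)")
  class(cfg) <- "run_config"
  cfg
}
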