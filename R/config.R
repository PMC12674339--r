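#' Run configuration for a WssGWAS analysis
#'
#' Bundles every tunable threshold of the pipeline in one validated object.
#' Defaults mirror a conventional single-step workflow: MAF < 0.05, SNP call
#' rate < 90% and HWE p < 1e-6 filters, G blended with A22 at alpha = 0.95,
#' non-overlapping 30-SNP windows, a 0.5% window-variance threshold for
#' candidate regions, and two weighting iterations.
#'
#' @param maf_min minimum minor allele frequency; SNPs below are removed.
#' @param call_rate_min minimum per-SNP call rate (fraction non-missing).
#' @param hwe_alpha Hardy-Weinberg exact-fit chi-square p-value cutoff.
#' @param mendel_conflict_max maximum tolerated fraction of opposing-homozygote
#'   parent-progeny conflicts before an animal is removed.
#' @param ld_r2_max squared-correlation threshold for LD pruning; 1.0 removes
#'   only perfect duplicates (effectively off).
#' @param ld_window,ld_step LD pruning window size and step, in SNPs.
#' @param alpha_blend weight on G in G* = alpha G + (1 - alpha) A22.
#' @param window_size SNPs per non-overlapping window.
#' @param region_threshold_pct percent of additive genetic variance a window
#'   must strictly exceed to be called a candidate region.
#' @param n_weight_iterations number of SNP re-weighting iterations.
#' @param outlier_sd phenotypes outside mean +/- outlier_sd * SD are dropped.
#' @param seed integer seed; all randomness flows from this one value.
#' @return A list of class `wss_config`.
#' @export
#' @examples
#' cfg <- run_config(seed = 42)
#' cfg$alpha_blend
run_config <- function(maf_min = 0.05,
                       call_rate_min = 0.90,
                       hwe_alpha = 1e-6,
                       mendel_conflict_max = 0.01,
                       ld_r2_max = 1.0,
                       ld_window = 50,
                       ld_step = 5,
                       alpha_blend = 0.95,
                       window_size = 30,
                       region_threshold_pct = 0.5,
                       n_weight_iterations = 2,
                       outlier_sd = 3.0,
                       seed = 1L) {
  frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a single number in [0, 1]", nm), call. = FALSE)
    as.numeric(x)
  }
  cfg <- list(
    maf_min = frac(maf_min, "maf_min"),
    call_rate_min = frac(call_rate_min, "call_rate_min"),
    hwe_alpha = frac(hwe_alpha, "hwe_alpha"),
    mendel_conflict_max = frac(mendel_conflict_max, "mendel_conflict_max"),
    ld_r2_max = frac(ld_r2_max, "ld_r2_max"),
    ld_window = as.integer(ld_window),
    ld_step = as.integer(ld_step),
    alpha_blend = frac(alpha_blend, "alpha_blend"),
    window_size = as.integer(window_size),
    region_threshold_pct = as.numeric(region_threshold_pct),
    n_weight_iterations = as.integer(n_weight_iterations),
    outlier_sd = as.numeric(outlier_sd),
    seed = as.integer(seed)
  )
  if (cfg$window_size < 1L) stop("'window_size' must be >= 1", call. = FALSE)
  if (cfg$n_weight_iterations < 1L)
    stop("'n_weight_iterations' must be >= 1", call. = FALSE)
  if (cfg$ld_window < 2L) stop("'ld_window' must be >= 2", call. = FALSE)
  if (cfg$ld_step < 1L) stop("'ld_step' must be >= 1", call. = FALSE)
  if (cfg$outlier_sd <= 0) stop("'outlier_sd' must be positive", call. = FALSE)
  class(cfg) <- "wss_config"
  cfg
}

#' Read a run configuration from a JSON file
#'
#' The file holds a flat JSON object whose keys mirror [run_config()]
#' arguments; absent keys keep their defaults, unknown keys are an error.
#'
#' @param path path to a JSON configuration file.
#' @return A `wss_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

#' @export
print.wss_config <- function(x, ...) {
  cat("WssGWAS run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
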