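#' Pipeline configuration
#'
#' Returns the list of tunable thresholds used throughout the pipeline.
#' Values follow the validation rules: coverage windows of 50 bp with
#' anomaly thresholds at 1.5x / 0.5x of the scaffold mean (or mean +/- 1.5
#' sd of window coverages in single-cell mode), disagreement majority
#' threshold 0.8, discordant pairs at >3 sd insert deviation or wrong
#' orientation, discordant/multi-align ratio thresholds 0.1, insert-size
#' closeness <2 sd, and >1 disagreement per kbp for large indels.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list with components:
#' \describe{
#'   \item{max_adjacency}{maximum overlap or gap (bp) between adjacent
#'     chained segments on the scaffold (default 1000).}
#'   \item{misjoin_distance}{reference distance (bp) beyond which adjacent
#'     segments are called a misjoin (default 10000).}
#'   \item{indel_min}{minimum scaffold/reference gap discrepancy (bp)
#'     treated as an insertion or deletion rather than alignment jitter
#'     (default 5).}
#'   \item{end_min}{minimum unaligned scaffold end (bp) reported as an end
#'     insertion (default 10).}
#'   \item{gap_run_min}{N-run length (bp) that demotes an overlapping
#'     difference to a gap report (default 10).}
#'   \item{window_cov}{coverage window size in bp (default 50).}
#'   \item{anomaly_windows}{number of anomalous coverage windows required
#'     to flag a region ("more than one", default 2).}
#'   \item{majority_frac}{pileup majority fraction below which a position
#'     is a disagreement (default 0.8, strict).}
#'   \item{min_depth}{minimum depth for disagreement calling (default 5).}
#'   \item{sd_mult_discordant}{insert-size deviation (in sd units) beyond
#'     which a pair is discordant (default 3, strict).}
#'   \item{sd_mult_indel}{insert-size closeness (in sd units) for the
#'     fragment-size test of indel validation (default 2, strict).}
#'   \item{multi_ratio_thresh}{multi-align ratio above which a misjoin is
#'     validated (default 0.1, strict).}
#'   \item{disc_ratio_thresh}{discordant ratio threshold (default 0.1).}
#'   \item{disag_per_kbp}{disagreements per kbp above which a large indel
#'     is validated (default 1, strict).}
#'   \item{window_disc}{sub-region size for discordant/multi ratios over
#'     long regions (default 500).}
#'   \item{min_span_pairs}{minimum spanning pairs for the fragment-size
#'     test (default 3).}
#'   \item{min_region_reads}{below this read count (with no spanning
#'     pairs) a non-error difference is a low-evidence warning
#'     (default 5).}
#'   \item{trim_cap}{maximum misjoin margin trimming per side in bp
#'     (default 200).}
#'   \item{match_slop}{breakpoint tolerance (bp) when matching calls to a
#'     truth table (default 100).}
#'   \item{min_out_len}{minimum corrected fragment length emitted
#'     (default 200).}
#'   \item{mode}{"standard" or "single_cell" coverage thresholds.}
#'   \item{anchor_k}{anchor length for the naive long-sequence aligner
#'     (default 31).}
#'   \item{read_seed_k}{seed length for the naive read aligner
#'     (default 20).}
#'   \item{max_mismatch}{mismatch cap for the naive read aligner
#'     (default 3).}
#'   \item{read_len}{read length used to extend regions for coverage
#'     windows; NULL means estimate from the alignments.}
#'   \item{min_lib_pairs}{minimum proper pairs required to estimate the
#'     insert-size distribution (default 1000).}
#' }
#' @export
misasm_config <- function(...) {
  cfg <- list(
    max_adjacency = 1000L,
    misjoin_distance = 10000L,
    indel_min = 5L,
    end_min = 10L,
    gap_run_min = 10L,
    window_cov = 50L,
    anomaly_windows = 2L,
    majority_frac = 0.8,
    min_depth = 5L,
    sd_mult_discordant = 3,
    sd_mult_indel = 2,
    multi_ratio_thresh = 0.1,
    disc_ratio_thresh = 0.1,
    disag_per_kbp = 1,
    window_disc = 500L,
    min_span_pairs = 3L,
    min_region_reads = 5L,
    trim_cap = 200L,
    match_slop = 100L,
    min_out_len = 200L,
    mode = "standard",
    anchor_k = 31L,
    read_seed_k = 20L,
    max_mismatch = 3L,
    read_len = NULL,
    min_lib_pairs = 1000L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  cfg
}

#' Read pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path path to a YAML file whose top-level keys match
#'   [misasm_config()] components.
#' @return A config list as from [misasm_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(misasm_config, vals)
}
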