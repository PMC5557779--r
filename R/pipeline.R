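#' Pipeline configuration
#'
#' Bundles the stage settings of [run_pipeline()]. At least one of the
#' two association statistics must be enabled.
#'
#' @param filter a [filter_config()].
#' @param window_n,window_step sliding-window size/step (SNPs) for the
#'   delta(SNP-index) profile.
#' @param span_grid candidate loess spans for the ED^5 fit.
#' @param delta_rule,ed_rule [threshold_rule()]s for the two statistics;
#'   defaults are the explicit thresholds 0.26 (windowed delta) and 0.15
#'   (loess ED^5).
#' @param use_snp_index,use_euclidean enable/disable each method.
#' @param ed_mode passed to [euclidean_distance()].
#' @return list with class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_config(),
                            window_n = 200L, window_step = 1L,
                            span_grid = seq(0.05, 0.95, by = 0.05),
                            delta_rule = threshold_rule("explicit", 0.26),
                            ed_rule = threshold_rule("explicit", 0.15),
                            use_snp_index = TRUE, use_euclidean = TRUE,
                            ed_mode = "frequency") {
  if (!use_snp_index && !use_euclidean) {
    stop("pipeline_config: at least one statistic must be enabled",
         call. = FALSE)
  }
  structure(list(filter = filter, window_n = as.integer(window_n),
                 window_step = as.integer(window_step),
                 span_grid = span_grid, delta_rule = delta_rule,
                 ed_rule = ed_rule, use_snp_index = use_snp_index,
                 use_euclidean = use_euclidean, ed_mode = ed_mode),
            class = "pipeline_config")
}

#' Run the association-mapping pipeline
#'
#' Executes the fixed stage order filter -> per-SNP statistics ->
#' smoothing -> thresholds -> region calling -> intersection, optionally
#' writing the association table, per-method BED files and a plain-text
#' run log to `out_dir`.
#'
#' @param sites a [snp_sites()] table (or a path to a canonical depth
#'   TSV).
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or NULL to skip writing files.
#' @return list: `filter_stats`, `assoc` (per-SNP table with smoothed
#'   columns), `delta_windows`, `thresholds`, `regions` (per-method list
#'   of [candidate_regions()] plus `intersection`), `files`.
#' @export
run_pipeline <- function(sites, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(sites)) sites <- read_depth_table(sites)

  flt <- filter_snps(sites, config$filter)
  if (nrow(flt$sites) == 0) {
    stop("run_pipeline: no SNP sites survive filtering", call. = FALSE)
  }
  message(sprintf("filter: %d in, %d passed (depth %d, parent %d, multi %d, pool %d removed)",
                  flt$stats$n_input, flt$stats$n_passed,
                  flt$stats$n_removed_depth,
                  flt$stats$n_removed_parent_monomorphic,
                  flt$stats$n_removed_multiallelic,
                  flt$stats$n_removed_pool_monomorphic))

  ss <- flt$sites[order(flt$sites$chrom, flt$sites$pos), , drop = FALSE]
  class(ss) <- c("snp_sites", "data.frame")
  assoc <- associate(ss, config$ed_mode)
  sm <- smooth_association(assoc, config$window_n, config$window_step,
                           config$span_grid)
  assoc <- sm$assoc

  regions <- list()
  thresholds <- list()
  if (config$use_snp_index) {
    thresholds$snp_index <- compute_threshold(sm$delta_windows$stat,
                                              config$delta_rule)
    regions$snp_index <- call_regions(sm$delta_windows$chrom,
                                      sm$delta_windows$pos,
                                      sm$delta_windows$stat,
                                      thresholds$snp_index, "snp_index")
    message(sprintf("snp_index: threshold %.4f, %d region(s)",
                    thresholds$snp_index, nrow(regions$snp_index)))
  }
  if (config$use_euclidean) {
    keep <- !is_unknown_chrom(assoc$chrom)
    thresholds$euclidean <- compute_threshold(assoc$loess_ed5[keep],
                                              config$ed_rule)
    regions$euclidean <- call_regions(assoc$chrom[keep], assoc$pos[keep],
                                      assoc$loess_ed5[keep],
                                      thresholds$euclidean, "euclidean")
    message(sprintf("euclidean: threshold %.4f, %d region(s)",
                    thresholds$euclidean, nrow(regions$euclidean)))
  }
  if (config$use_snp_index && config$use_euclidean) {
    regions$intersection <- intersect_regions(regions$snp_index,
                                              regions$euclidean)
    if (nrow(regions$intersection) == 0) {
      warning("run_pipeline: the two methods' regions do not overlap",
              call. = FALSE)
    }
  }

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f_assoc <- file.path(out_dir, "association.tsv")
    write_association_table(assoc, f_assoc)
    files <- f_assoc
    for (mth in names(regions)) {
      f <- file.path(out_dir, paste0("regions_", mth, ".bed"))
      write_regions_bed(regions[[mth]], f)
      files <- c(files, f)
    }
    f_log <- file.path(out_dir, "run_log.txt")
    log_lines <- c(
      sprintf("n_input\t%d", flt$stats$n_input),
      sprintf("n_passed\t%d", flt$stats$n_passed),
      sprintf("n_removed_depth\t%d", flt$stats$n_removed_depth),
      sprintf("n_removed_parent_monomorphic\t%d",
              flt$stats$n_removed_parent_monomorphic),
      sprintf("n_removed_multiallelic\t%d", flt$stats$n_removed_multiallelic),
      sprintf("n_removed_pool_monomorphic\t%d",
              flt$stats$n_removed_pool_monomorphic),
      vapply(names(thresholds), function(m)
        sprintf("threshold_%s\t%.6f", m, thresholds[[m]]), character(1)),
      vapply(names(regions), function(m)
        sprintf("n_regions_%s\t%d", m, nrow(regions[[m]])), character(1)))
    writeLines(log_lines, f_log)
    files <- c(files, f_log)
  }

  list(filter_stats = flt$stats, assoc = assoc,
       delta_windows = sm$delta_windows, thresholds = thresholds,
       regions = regions, files = files)
}
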