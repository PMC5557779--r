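#' Threshold rule for candidate-region calling
#'
#' Either an explicit statistic value (e.g. 0.26 for the smoothed
#' delta(SNP-index), 0.15 for the loess-fitted ED^5) or a data-driven
#' rule: genome-wide `median + k_sd * sample SD` of the smoothed values.
#'
#' @param mode `"explicit"` or `"median_plus_k_sd"`.
#' @param explicit_value statistic value (required for explicit mode).
#' @param k_sd SD multiplier for the median rule (default 3).
#' @return list with class `threshold_rule`.
#' @export
threshold_rule <- function(mode = c("explicit", "median_plus_k_sd"),
                           explicit_value = NULL, k_sd = 3) {
  mode <- match.arg(mode)
  if (mode == "explicit" && (is.null(explicit_value) ||
                             !is.finite(explicit_value))) {
    stop("threshold_rule: explicit mode requires explicit_value",
         call. = FALSE)
  }
  if (k_sd <= 0) stop("threshold_rule: k_sd must be > 0", call. = FALSE)
  structure(list(mode = mode, explicit_value = explicit_value, k_sd = k_sd),
            class = "threshold_rule")
}

#' Compute the region-calling threshold
#'
#' @param fitted_values smoothed statistic values (windows or loess fit);
#'   only finite values enter the median/SD.
#' @param rule a [threshold_rule()].
#' @return the threshold, in statistic units.
#' @export
compute_threshold <- function(fitted_values, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (rule$mode == "explicit") return(rule$explicit_value)
  v <- fitted_values[is.finite(fitted_values)]
  if (length(v) < 2) {
    stop("compute_threshold: need at least 2 finite values for the SD rule",
         call. = FALSE)
  }
  stats::median(v) + rule$k_sd * stats::sd(v)
}

#' Call candidate regions from a smoothed profile
#'
#' Maximal runs of consecutive profile points with `fitted > threshold`
#' become one region each; a run's bounds are the first and last profile
#' positions of the run (no extrapolation beyond observed points), and
#' runs never span chromosomes.
#'
#' @param chrom,pos,fitted the profile, sorted by (chrom, pos); NA fitted
#'   values break runs.
#' @param threshold statistic threshold.
#' @param method label stored on the regions.
#' @return a [candidate_regions()] table (possibly empty).
#' @export
call_regions <- function(chrom, pos, fitted, threshold,
                         method = "snp_index") {
  stopifnot(length(chrom) == length(pos), length(chrom) == length(fitted))
  out <- list()
  for (ch in unique(chrom)) {
    ii <- which(chrom == ch)
    ii <- ii[order(pos[ii])]
    above <- !is.na(fitted[ii]) & fitted[ii] > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = pos[ii[starts[k]]], end_bp = pos[ii[ends[k]]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(candidate_regions(method = character()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start_bp), , drop = FALSE]
  candidate_regions(df$chrom, df$start_bp, df$end_bp, method)
}

#' Intersect two sets of candidate regions
#'
#' Pairwise same-chromosome intersections `[max(starts), min(ends)]`,
#' kept when of positive length, labelled `"intersection"`.
#'
#' @param a,b [candidate_regions()] tables.
#' @return a [candidate_regions()] table.
#' @export
intersect_regions <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      s <- max(a$start_bp[i], b$start_bp[j])
      e <- min(a$end_bp[i], b$end_bp[j])
      if (e > s) {
        out[[length(out) + 1L]] <- data.frame(chrom = a$chrom[i],
                                              start_bp = s, end_bp = e,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(candidate_regions(method = character()))
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start_bp), , drop = FALSE]
  candidate_regions(df$chrom, df$start_bp, df$end_bp, "intersection")
}

#' Region size in megabases
#'
#' `(end_bp - start_bp) / 1e6`, rounded half-up to two decimals — the
#' convention that reproduces printed interval sizes and matches the
#' half-open arithmetic used at the BED boundary.
#'
#' @param start_bp,end_bp interval bounds (1-based inclusive), or a
#'   single `candidate_regions` table as first argument.
#' @return numeric Mb value(s) with two decimals.
#' @export
region_size_mb <- function(start_bp, end_bp = NULL) {
  if (is.data.frame(start_bp)) {
    end_bp <- start_bp$end_bp
    start_bp <- start_bp$start_bp
  }
  x <- (as.numeric(end_bp) - as.numeric(start_bp)) / 1e6
  floor(x * 100 + 0.5) / 100
}
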