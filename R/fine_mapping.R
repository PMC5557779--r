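#' Count recombinants per marker
#'
#' In the homozygous-recessive F2 class, a plant's code at a marker
#' counts its recombinant gametes: `0/1` one (single recombinant), `1/1`
#' two (double recombinant), `0/0` none. Plants not listed in the matrix
#' (when `n_population` exceeds the listed columns) are non-recombinant
#' by construction of such tables.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with one row per marker: `marker_id`, `n_single`,
#'   `n_double`, `n_missing`, `n_plants`.
#' @export
count_recombinants <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  data.frame(
    marker_id = gm$marker_ids,
    n_single = rowSums(gm$calls == "0/1", na.rm = TRUE),
    n_double = rowSums(gm$calls == "1/1", na.rm = TRUE),
    n_missing = rowSums(is.na(gm$calls)),
    n_plants = gm$n_population,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Delimit the trait interval from recombinant counts
#'
#' The trait-containing block is the maximal run of markers with zero
#' recombinants (the co-segregating set); the interval bounds are the
#' nearest flanking markers carrying at least one recombinant. Marker
#' row order is taken as the physical order. A side with no recombinant
#' marker beyond the run is reported open (`NA`). Two zero-recombinant
#' runs of equal maximal length cannot be ordered by the data and abort
#' with a genotyping-conflict error.
#'
#' @param gm a [genotype_matrix()] ordered by physical position.
#' @return list: `left_marker`, `right_marker` (NA when open),
#'   `co_segregating` (character vector of marker ids).
#' @export
delimit_interval <- function(gm) {
  counts <- count_recombinants(gm)
  rec <- counts$n_single + counts$n_double
  if (all(rec > 0)) stop("delimit_interval: no co-segregating block",
                         call. = FALSE)
  r <- rle(rec == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zero_runs <- which(r$values)
  lens <- r$lengths[zero_runs]
  best <- zero_runs[lens == max(lens)]
  if (length(best) > 1L) {
    stop("delimit_interval: two equally long zero-recombinant blocks; ",
         "likely genotyping conflict", call. = FALSE)
  }
  s <- starts[best]; e <- ends[best]
  list(
    left_marker = if (s > 1L) counts$marker_id[s - 1L] else NA_character_,
    right_marker = if (e < nrow(counts)) counts$marker_id[e + 1L]
                   else NA_character_,
    co_segregating = counts$marker_id[s:e])
}

#' Recombination fraction in the recessive class
#'
#' Gamete counting over the homozygous-recessive plants: each plant
#' carries two gametes scored against the trait locus, so
#' `r = (n_single + 2 n_double) / (2 (n_plants - n_missing))`.
#'
#' @param n_single,n_double recombinant counts for a marker.
#' @param n_plants class size; `n_missing` plants are excluded from the
#'   denominator.
#' @param n_missing missing calls at this marker.
#' @return estimated recombination fraction in `[0, 0.5)`.
#' @export
recomb_fraction_recessive_class <- function(n_single, n_double, n_plants,
                                            n_missing = 0) {
  stopifnot(n_plants > 0, n_plants > n_missing)
  r <- (n_single + 2 * n_double) / (2 * (n_plants - n_missing))
  if (any(r >= 0.5)) {
    stop("recomb_fraction_recessive_class: r >= 0.5 (marker unlinked)",
         call. = FALSE)
  }
  r
}

#' Kosambi map function
#'
#' Converts a recombination fraction to map distance allowing partial
#' crossover interference: `d = 25 ln((1 + 2r) / (1 - 2r))` centimorgans.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return map distance(s) in cM.
#' @seealso [kosambi_r()] for the inverse.
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("kosambi_cm: r must lie in [0, 0.5)", call. = FALSE)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' `r = tanh(2 d / 100) / 2` for a distance `d` in cM.
#'
#' @param d map distance(s) in cM, `d >= 0`.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
kosambi_r <- function(d) {
  if (any(d < 0)) stop("kosambi_r: d must be >= 0", call. = FALSE)
  tanh(2 * d / 100) / 2
}

#' Goodness-of-fit test for a segregation ratio
#'
#' One-degree-of-freedom chi-square test of observed dominant:recessive
#' counts against an expected ratio (default 3:1, the monogenic dominant
#' model), without continuity correction.
#'
#' @param n_dominant,n_recessive observed counts.
#' @param ratio expected dominant:recessive ratio as a length-2 vector.
#' @return list: `chi2`, `p`, `df`.
#' @export
segregation_chi_square <- function(n_dominant, n_recessive,
                                   ratio = c(3, 1)) {
  stopifnot(n_dominant >= 0, n_recessive >= 0, length(ratio) == 2)
  total <- n_dominant + n_recessive
  if (total == 0) stop("segregation_chi_square: zero total", call. = FALSE)
  expected <- total * ratio / sum(ratio)
  chi2 <- sum((c(n_dominant, n_recessive) - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L)
}
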