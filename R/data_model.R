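#' @keywords internal
BASES <- c("A", "C", "G", "T")

#' Canonical per-site allele-depth columns
#'
#' Column order of the canonical depth table: one row per SNP site with
#' coordinates, parental alleles and per-base read depths in the
#' dominant-phenotype (black) and recessive-phenotype (yellow) bulks.
#'
#' @keywords internal
SNP_SITE_COLUMNS <- c(
  "chrom", "pos", "ref", "alt", "p1_allele", "p2_allele",
  "dom_A", "dom_C", "dom_G", "dom_T",
  "rec_A", "rec_C", "rec_G", "rec_T",
  "p1_depth", "p2_depth"
)

DEPTH_COLUMNS <- c(
  "dom_A", "dom_C", "dom_G", "dom_T",
  "rec_A", "rec_C", "rec_G", "rec_T",
  "p1_depth", "p2_depth"
)

#' Construct a table of SNP sites
#'
#' A `snp_sites` object is a data.frame with one row per biallelic (or
#' not-yet-filtered multiallelic) SNP site. `p1_allele` is the allele of
#' the dominant-phenotype parent (the "M" allele), `p2_allele` that of the
#' recessive-phenotype parent ("P"). `dom_*` columns hold per-base read
#' depths in the dominant (black) bulk, `rec_*` in the recessive (yellow)
#' bulk.
#'
#' @param df data.frame carrying the canonical columns (see
#'   [read_depth_table()] for the file schema).
#' @return the validated data.frame with class `snp_sites`.
#' @export
snp_sites <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(SNP_SITE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("snp_sites: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[SNP_SITE_COLUMNS]
  df$pos <- as.integer(df$pos)
  if (any(is.na(df$pos)) || any(df$pos < 1L)) {
    stop("snp_sites: pos must be an integer >= 1", call. = FALSE)
  }
  if (!all(df$ref %in% BASES)) {
    stop("snp_sites: ref base must be one of A,C,G,T", call. = FALSE)
  }
  for (col in DEPTH_COLUMNS) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      stop("snp_sites: column '", col, "' must hold non-negative integers",
           call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  class(df) <- c("snp_sites", "data.frame")
  df
}

#' Per-bulk total read depth
#'
#' @param sites a `snp_sites` table.
#' @param bulk `"dom"` or `"rec"`.
#' @return integer vector of total depth per site in that bulk.
#' @export
bulk_total_depth <- function(sites, bulk = c("dom", "rec")) {
  bulk <- match.arg(bulk)
  cols <- paste0(bulk, "_", BASES)
  as.integer(rowSums(as.matrix(sites[cols])))
}

#' Candidate-region table
#'
#' Intervals use 1-based inclusive physical coordinates, matching printed
#' genome coordinates; conversion to BED happens only in
#' [write_regions_bed()].
#'
#' @param chrom chromosome labels.
#' @param start_bp,end_bp 1-based inclusive interval bounds (bp).
#' @param method label: `"snp_index"`, `"euclidean"` or `"intersection"`.
#' @return data.frame with class `candidate_regions` and a derived
#'   `size_mb` column, `(end_bp - start_bp)/1e6` rounded half-up to two
#'   decimals.
#' @export
candidate_regions <- function(chrom = character(), start_bp = integer(),
                              end_bp = integer(), method = character()) {
  if (length(method) == 1L && length(chrom) > 1L) {
    method <- rep(method, length(chrom))
  }
  stopifnot(length(chrom) == length(start_bp),
            length(chrom) == length(end_bp),
            length(chrom) == length(method))
  start_bp <- as.numeric(start_bp)
  end_bp <- as.numeric(end_bp)
  if (any(start_bp > end_bp)) {
    stop("candidate_regions: start_bp must be <= end_bp", call. = FALSE)
  }
  ok <- method %in% c("snp_index", "euclidean", "intersection")
  if (!all(ok)) {
    stop("candidate_regions: unknown method label: ",
         paste(unique(method[!ok]), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(chrom = as.character(chrom), start_bp = start_bp,
                   end_bp = end_bp, method = as.character(method),
                   stringsAsFactors = FALSE)
  df$size_mb <- region_size_mb(df$start_bp, df$end_bp)
  class(df) <- c("candidate_regions", "data.frame")
  df
}

GENOTYPE_CODES <- c("0/0", "0/1", "1/1")

#' Marker-by-plant genotype matrix for the recessive F2 class
#'
#' Markers are rows in physical order along the chromosome; plants are
#' columns. Codes count recombinant gametes relative to the trait locus:
#' `"0/0"` non-recombinant, `"0/1"` single recombinant, `"1/1"` double
#' recombinant; `NA` is a missing call. Published recombinant tables often
#' list only the informative plants; pass the full class size as
#' `n_population` and unlisted plants are treated as `"0/0"`.
#'
#' @param calls character matrix of codes with marker ids as rownames and
#'   plant ids as colnames.
#' @param marker_positions optional bp coordinate per marker.
#' @param n_population declared total number of plants in the recessive
#'   class (default: number of columns).
#' @return list with class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, marker_positions = NULL,
                            n_population = NULL) {
  stopifnot(is.matrix(calls), is.character(calls))
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("genotype_matrix: calls must have marker rownames and plant colnames",
         call. = FALSE)
  }
  bad <- which(!(calls %in% GENOTYPE_CODES | is.na(calls)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "genotype_matrix: invalid code '%s' at marker %s, plant %s",
      calls[bad[1, 1], bad[1, 2]],
      rownames(calls)[bad[1, 1]], colnames(calls)[bad[1, 2]]),
      call. = FALSE)
  }
  if (!is.null(marker_positions)) {
    stopifnot(length(marker_positions) == nrow(calls))
  }
  if (is.null(n_population)) n_population <- ncol(calls)
  if (n_population < ncol(calls)) {
    stop("genotype_matrix: n_population smaller than number of listed plants",
         call. = FALSE)
  }
  structure(
    list(marker_ids = rownames(calls), plant_ids = colnames(calls),
         calls = calls, marker_positions = marker_positions,
         n_population = as.integer(n_population)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d listed plants (population %d)\n",
              length(x$marker_ids), length(x$plant_ids), x$n_population))
  print(x$calls, quote = FALSE)
  invisible(x)
}

is_unknown_chrom <- function(chrom) {
  grepl("un(known)?$|unknown", tolower(chrom))
}
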