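#' Read the canonical per-site allele-depth table
#'
#' The canonical format is a tab-separated file with a header row naming
#' exactly these columns: `chrom, pos, ref, alt, p1_allele, p2_allele,
#' dom_A, dom_C, dom_G, dom_T, rec_A, rec_C, rec_G, rec_T, p1_depth,
#' p2_depth`. `alt` may hold a comma-separated list of alternate bases
#' (multiallelic sites are kept here and dropped later by
#' [filter_snps()]).
#'
#' @param path path to the TSV file.
#' @return a [snp_sites()] table, one row per data line, in file order.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop("read_depth_table: no such file: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(SNP_SITE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("read_depth_table: schema error, missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[SNP_SITE_COLUMNS]
  if (nrow(df) == 0) {
    df$pos <- integer()
    for (col in DEPTH_COLUMNS) df[[col]] <- integer()
    return(snp_sites(df))
  }
  for (col in c("pos", DEPTH_COLUMNS)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      # +1 for the header line
      stop(sprintf(
        "read_depth_table: invalid value '%s' in column '%s' at line %d",
        df[[col]][bad[1]], col, bad[1] + 1L), call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  snp_sites(df)
}

#' Write the canonical per-site allele-depth table
#'
#' @param sites a [snp_sites()] table.
#' @param path output path.
#' @export
write_depth_table <- function(sites, path) {
  utils::write.table(as.data.frame(sites)[SNP_SITE_COLUMNS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read bulk allele depths from a multi-sample VCF
#'
#' Reconstructs per-base depths from the per-sample `AD` (allele depth)
#' field of a VCF holding the two parents and the two phenotype bulks.
#' Each REF/ALT allele's depth is assigned to its base; multiallelic
#' records are retained (they are removed later by [filter_snps()]).
#' Records whose REF or any ALT allele is longer than one base (indels)
#' are skipped and counted. A bulk sample without a usable `AD` entry
#' yields zero depths for that bulk and the site is flagged.
#'
#' Parental alleles are taken as the deepest base in each parent's `AD`;
#' ties fall back to the REF base.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param sample_map named character vector mapping the roles
#'   `parent_dom`, `parent_rec`, `bulk_dom`, `bulk_rec` to sample names
#'   present in the VCF.
#' @return a [snp_sites()] table with attributes `n_skipped_indels`
#'   (integer) and `flagged` (logical vector marking sites where a bulk
#'   lacked depth information).
#' @export
read_vcf_bulks <- function(path, sample_map) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf_bulks requires the VariantAnnotation package",
         call. = FALSE)
  }
  roles <- c("parent_dom", "parent_rec", "bulk_dom", "bulk_rec")
  if (!all(roles %in% names(sample_map))) {
    stop("read_vcf_bulks: sample_map must name roles: ",
         paste(roles, collapse = ", "), call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  absent <- setdiff(unname(sample_map[roles]), samples)
  if (length(absent) > 0) {
    stop("read_vcf_bulks: sample(s) not in VCF: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!"AD" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))) {
    stop("read_vcf_bulks: VCF lacks the per-sample AD (allele depth) field",
         call. = FALSE)
  }
  rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- lapply(seq_along(alt_list), function(i) {
    as.character(alt_list[[i]])
  })
  snv <- vapply(seq_along(ref), function(i) {
    nchar(ref[i]) == 1L && ref[i] %in% BASES &&
      all(nchar(alt_chr[[i]]) == 1L) && all(alt_chr[[i]] %in% BASES)
  }, logical(1))
  n_skipped <- sum(!snv)
  ad <- VariantAnnotation::geno(vcf)$AD

  depth_for <- function(i, sample) {
    d <- ad[i, sample][[1]]
    out <- stats::setNames(rep(0L, 4), BASES)
    alleles <- c(ref[i], alt_chr[[i]])
    if (is.null(d) || all(is.na(d)) || length(d) != length(alleles)) {
      return(list(depths = out, ok = FALSE))
    }
    d[is.na(d)] <- 0L
    for (k in seq_along(alleles)) {
      out[alleles[k]] <- out[alleles[k]] + as.integer(d[k])
    }
    list(depths = out, ok = TRUE)
  }

  idx <- which(snv)
  rows <- vector("list", length(idx))
  flagged <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    dom <- depth_for(i, sample_map[["bulk_dom"]])
    rec <- depth_for(i, sample_map[["bulk_rec"]])
    p1 <- depth_for(i, sample_map[["parent_dom"]])
    p2 <- depth_for(i, sample_map[["parent_rec"]])
    flagged[j] <- !(dom$ok && rec$ok)
    call_parent <- function(p) {
      if (!p$ok || sum(p$depths) == 0) return(ref[i])
      top <- BASES[p$depths == max(p$depths)]
      if (length(top) > 1L && ref[i] %in% top) ref[i] else top[1]
    }
    rows[[j]] <- data.frame(
      chrom = as.character(rr$seqnames)[i],
      pos = rr$start[i],
      ref = ref[i], alt = paste(alt_chr[[i]], collapse = ","),
      p1_allele = call_parent(p1), p2_allele = call_parent(p2),
      dom_A = dom$depths[["A"]], dom_C = dom$depths[["C"]],
      dom_G = dom$depths[["G"]], dom_T = dom$depths[["T"]],
      rec_A = rec$depths[["A"]], rec_C = rec$depths[["C"]],
      rec_G = rec$depths[["G"]], rec_T = rec$depths[["T"]],
      p1_depth = sum(p1$depths), p2_depth = sum(p2$depths),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(SNP_SITE_COLUMNS)), SNP_SITE_COLUMNS))
    df$pos <- integer(0)
    for (col in DEPTH_COLUMNS) df[[col]] <- integer(0)
    df
  }
  out <- snp_sites(out)
  attr(out, "n_skipped_indels") <- as.integer(n_skipped)
  attr(out, "flagged") <- flagged
  if (n_skipped > 0) {
    message("read_vcf_bulks: skipped ", n_skipped, " non-SNV record(s)")
  }
  out
}

#' Write candidate regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so each line is `chrom, start_bp - 1, end_bp, method`.
#'
#' @param regions a [candidate_regions()] table.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- if (nrow(regions) == 0) character(0) else {
    sprintf("%s\t%d\t%d\t%s", regions$chrom,
            as.integer(regions$start_bp) - 1L, as.integer(regions$end_bp),
            regions$method)
  }
  writeLines(lines, path)
  invisible(path)
}

ASSOC_STAT_COLUMNS <- c("snp_index_dom", "snp_index_rec", "delta",
                        "ed", "ed5", "window_delta", "loess_ed5")

#' Write the per-SNP association table
#'
#' TSV with one row per SNP: `chrom`, `pos`, then the statistics
#' `snp_index_dom, snp_index_rec, delta, ed, ed5, window_delta,
#' loess_ed5`, formatted to six decimals; undefined statistics are
#' written as `NA`.
#'
#' @param results data.frame as returned by [associate()] /
#'   [run_pipeline()]; statistic columns that are absent are written as
#'   `NA`.
#' @param path output path.
#' @export
write_association_table <- function(results, path) {
  out <- data.frame(chrom = results$chrom, pos = as.integer(results$pos),
                    stringsAsFactors = FALSE)
  for (col in ASSOC_STAT_COLUMNS) {
    v <- if (col %in% names(results)) results[[col]] else rep(NA_real_, nrow(out))
    out[[col]] <- ifelse(is.na(v), "NA", sprintf("%.6f", v))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association table written by [write_association_table()]
#'
#' @param path path to the TSV.
#' @return data.frame with numeric statistic columns (NA where undefined).
#' @export
read_association_table <- function(path) {
  df <- utils::read.delim(path, na.strings = "NA", check.names = FALSE)
  need <- c("chrom", "pos", ASSOC_STAT_COLUMNS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("read_association_table: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df
}

#' Read a marker-by-plant genotype table
#'
#' Tab-separated with the marker id in the first column and one column
#' per plant; cells in `{0/0, 0/1, 1/1, NA}`. Row order is taken as the
#' physical marker order.
#'
#' @param path path to the TSV.
#' @param n_population declared recessive-class population size; listed
#'   columns are the informative plants, the remainder are treated as
#'   non-recombinant (`0/0`).
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, n_population = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", "-"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  genotype_matrix(m, n_population = n_population)
}
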