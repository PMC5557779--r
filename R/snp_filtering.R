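#' Marker-screening configuration
#'
#' Defaults follow the screening used for pooled SLAF-seq BSA data: drop
#' sites with bulk depth below 5x, sites without a parental polymorphism,
#' multiallelic sites, and sites where the two bulks are fixed for the
#' same base. The depth rule is conjunctive by default: both bulks must
#' reach the cutoff (`depth_rule = "both"`); `"either"` requires only one.
#'
#' @param min_bulk_depth minimum total read depth per bulk (reads).
#' @param depth_rule `"both"` (each bulk must reach the cutoff) or
#'   `"either"`.
#' @param require_parent_polymorphism drop sites whose parents carry the
#'   same (or an unknown) allele.
#' @param drop_multiallelic drop sites with more than one alternate base.
#' @param drop_pool_monomorphic drop sites where both bulks are fixed for
#'   one and the same base.
#' @return list with class `filter_config`.
#' @export
filter_config <- function(min_bulk_depth = 5L,
                          depth_rule = c("both", "either"),
                          require_parent_polymorphism = TRUE,
                          drop_multiallelic = TRUE,
                          drop_pool_monomorphic = TRUE) {
  depth_rule <- match.arg(depth_rule)
  stopifnot(is.numeric(min_bulk_depth), min_bulk_depth >= 0)
  structure(list(min_bulk_depth = as.integer(min_bulk_depth),
                 depth_rule = depth_rule,
                 require_parent_polymorphism = require_parent_polymorphism,
                 drop_multiallelic = drop_multiallelic,
                 drop_pool_monomorphic = drop_pool_monomorphic),
            class = "filter_config")
}

#' Screen SNP sites for association analysis
#'
#' Applies the marker-screening rules in a fixed order — depth, parental
#' polymorphism, multiallelic, pool monomorphism — so that each removed
#' site is counted once, under the first rule it fails, and the counter
#' breakdown is deterministic. Surviving sites are biallelic, adequately
#' covered in the bulks, polymorphic between the parents (one allele from
#' each parent), and not fixed for the same base in both bulks. Sites
#' with an unknown parental allele count as parent-monomorphic removals.
#'
#' @param sites a [snp_sites()] table.
#' @param config a [filter_config()].
#' @return list with elements `sites` (the surviving [snp_sites()] table)
#'   and `stats`, a named list: `n_input`, `n_removed_depth`,
#'   `n_removed_parent_monomorphic`, `n_removed_multiallelic`,
#'   `n_removed_pool_monomorphic`, `n_passed`.
#' @export
filter_snps <- function(sites, config = filter_config()) {
  stopifnot(inherits(sites, "snp_sites"), inherits(config, "filter_config"))
  n <- nrow(sites)
  alive <- rep(TRUE, n)

  dom_tot <- bulk_total_depth(sites, "dom")
  rec_tot <- bulk_total_depth(sites, "rec")
  fail_depth <- if (config$depth_rule == "both") {
    dom_tot < config$min_bulk_depth | rec_tot < config$min_bulk_depth
  } else {
    dom_tot < config$min_bulk_depth & rec_tot < config$min_bulk_depth
  }
  rm_depth <- alive & fail_depth
  alive <- alive & !rm_depth

  p1 <- toupper(sites$p1_allele)
  p2 <- toupper(sites$p2_allele)
  parent_mono <- !(p1 %in% BASES) | !(p2 %in% BASES) | p1 == p2
  rm_parent <- if (config$require_parent_polymorphism) alive & parent_mono
               else rep(FALSE, n)
  alive <- alive & !rm_parent

  alt_split <- strsplit(sites$alt, ",", fixed = TRUE)
  multi <- vapply(alt_split, function(a) {
    length(a) != 1L || nchar(a[1]) != 1L || !(a[1] %in% BASES)
  }, logical(1))
  rm_multi <- if (config$drop_multiallelic) alive & multi else rep(FALSE, n)
  alive <- alive & !rm_multi

  dom_mat <- as.matrix(sites[paste0("dom_", BASES)]) > 0
  rec_mat <- as.matrix(sites[paste0("rec_", BASES)]) > 0
  same_fixed <- rowSums(dom_mat) == 1L & rowSums(rec_mat) == 1L &
    rowSums(dom_mat & rec_mat) == 1L
  rm_pool <- if (config$drop_pool_monomorphic) alive & same_fixed
             else rep(FALSE, n)
  alive <- alive & !rm_pool

  stats <- list(
    n_input = n,
    n_removed_depth = sum(rm_depth),
    n_removed_parent_monomorphic = sum(rm_parent),
    n_removed_multiallelic = sum(rm_multi),
    n_removed_pool_monomorphic = sum(rm_pool),
    n_passed = sum(alive))
  out <- sites[alive, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_sites", "data.frame")
  list(sites = out, stats = stats)
}
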