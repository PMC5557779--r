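#' Configuration of a synthetic F2 bulk-sequencing experiment
#'
#' The defaults emulate the mapping design the analysis assumes: a large
#' F2 from two fully homozygous parents segregating a single dominant
#' trait locus, 723 plants (3:1 dominant:recessive in expectation),
#' bulks of 50 plants per phenotype, bulk sequencing depths around
#' 45x/41x and parental depths around 16x/27x. Genome defaults (3
#' chromosomes of 500 Mb / 150 cM, 200 uniformly spaced SNPs each,
#' causal locus mid-chromosome 1) keep a full run cheap while leaving
#' two unlinked chromosomes as negative controls.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp physical length per chromosome (bp).
#' @param n_snps_per_chrom SNPs per chromosome (uniformly spaced).
#' @param genetic_length_cm genetic length per chromosome (cM); map
#'   positions are linear in bp.
#' @param causal_chrom index of the chromosome carrying the trait locus.
#' @param causal_pos_bp physical position of the trait locus; it is also
#'   emitted as a SNP site.
#' @param n_f2 F2 population size.
#' @param bulk_size plants per phenotype bulk.
#' @param mean_depth_dom,mean_depth_rec mean sequencing depth of the
#'   dominant (black) and recessive (yellow) bulks (reads/site).
#' @param mean_depth_parents length-2 means for parent 1 (dominant) and
#'   parent 2 (recessive).
#' @param sequencing_error_rate per-read probability of reporting a
#'   wrong base (spread uniformly over the other three).
#' @param pos_jitter_bp uniform jitter applied to SNP spacing (0 = exactly
#'   uniform).
#' @param seed default seed used by the simulation entry points.
#' @return list with class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 3L, chrom_length_bp = 5e8,
                       n_snps_per_chrom = 200L, genetic_length_cm = 150,
                       causal_chrom = 1L, causal_pos_bp = 2.5e8,
                       n_f2 = 723L, bulk_size = 50L,
                       mean_depth_dom = 45, mean_depth_rec = 41,
                       mean_depth_parents = c(16, 27),
                       sequencing_error_rate = 0.001,
                       pos_jitter_bp = 0, seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp,
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              genetic_length_cm = genetic_length_cm,
              causal_chrom = as.integer(causal_chrom),
              causal_pos_bp = causal_pos_bp,
              n_f2 = as.integer(n_f2), bulk_size = as.integer(bulk_size),
              mean_depth_dom = mean_depth_dom,
              mean_depth_rec = mean_depth_rec,
              mean_depth_parents = mean_depth_parents,
              sequencing_error_rate = sequencing_error_rate,
              pos_jitter_bp = pos_jitter_bp, seed = seed)
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length_bp > 0,
            cfg$n_snps_per_chrom >= 1, cfg$genetic_length_cm >= 0,
            cfg$causal_chrom >= 1, cfg$causal_chrom <= cfg$n_chromosomes,
            cfg$causal_pos_bp >= 1, cfg$causal_pos_bp <= cfg$chrom_length_bp,
            cfg$n_f2 >= 2, cfg$bulk_size >= 1,
            cfg$mean_depth_dom > 0, cfg$mean_depth_rec > 0,
            length(cfg$mean_depth_parents) == 2,
            all(cfg$mean_depth_parents > 0),
            cfg$sequencing_error_rate >= 0, cfg$sequencing_error_rate <= 1)
  structure(cfg, class = "sim_config")
}

# gametes from a crossover process with no interference: crossover count
# Poisson(L Morgans), positions uniform; returns n_gam x n_loci 0/1 matrix
# (1 = allele of the dominant parent), start phase Bernoulli(1/2)
sim_gametes <- function(n_gam, loci_morgan, L_morgan) {
  n_loci <- length(loci_morgan)
  phase0 <- sample(0:1, n_gam, replace = TRUE)
  out <- matrix(0L, n_gam, n_loci)
  if (L_morgan <= 0) {
    out[] <- rep(phase0, n_loci)
    return(out)
  }
  k <- stats::rpois(n_gam, L_morgan)
  xo_all <- stats::runif(sum(k), 0, L_morgan)
  idx <- rep.int(seq_len(n_gam), k)
  xo_by_gam <- split(xo_all, factor(idx, levels = seq_len(n_gam)))
  for (g in seq_len(n_gam)) {
    xo <- xo_by_gam[[g]]
    if (length(xo) == 0L) {
      out[g, ] <- phase0[g]
    } else {
      ncross <- findInterval(loci_morgan, sort(xo))
      out[g, ] <- (phase0[g] + ncross) %% 2L
    }
  }
  out
}

#' Simulate an F2 population at all SNP and trait loci
#'
#' Each plant is the union of two gametes; each gamete is a mosaic of
#' the two fully homozygous parental haplotypes produced by a crossover
#' process without interference along the genetic map (map positions
#' linear in bp). The phenotype is dominant unless the plant is
#' homozygous for the recessive allele at the causal locus, which is
#' included among the emitted loci.
#'
#' @param config a [sim_config()].
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return list with class `f2_population`: `config`, `chromosomes` (per
#'   chromosome: `chrom` label, `pos`, `geno` — an `n_f2 x n_loci` count
#'   of dominant-parent alleles — and `causal_index`), `phenotype`
#'   (character, "dominant"/"recessive"), `causal` (chrom label + bp).
#' @export
simulate_f2 <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  chroms <- vector("list", config$n_chromosomes)
  labels <- paste0(seq_len(config$n_chromosomes), "H")
  for (c_i in seq_len(config$n_chromosomes)) {
    spacing <- config$chrom_length_bp / (config$n_snps_per_chrom + 1)
    pos <- round(spacing * seq_len(config$n_snps_per_chrom))
    if (config$pos_jitter_bp > 0) {
      pos <- pos + round(stats::runif(length(pos), -config$pos_jitter_bp,
                                      config$pos_jitter_bp))
      pos <- sort(pmin(pmax(pos, 1), config$chrom_length_bp))
    }
    causal_index <- NA_integer_
    if (c_i == config$causal_chrom) {
      cp <- round(config$causal_pos_bp)
      if (!cp %in% pos) pos <- sort(c(pos, cp))
      causal_index <- match(cp, pos)
    }
    m <- pos / config$chrom_length_bp * config$genetic_length_cm / 100
    L <- config$genetic_length_cm / 100
    g1 <- sim_gametes(config$n_f2, m, L)
    g2 <- sim_gametes(config$n_f2, m, L)
    chroms[[c_i]] <- list(chrom = labels[c_i], pos = pos,
                          geno = g1 + g2, causal_index = causal_index)
  }
  cc <- chroms[[config$causal_chrom]]
  causal_geno <- cc$geno[, cc$causal_index]
  phenotype <- ifelse(causal_geno >= 1L, "dominant", "recessive")
  structure(list(config = config, chromosomes = chroms,
                 phenotype = phenotype,
                 causal = list(chrom = cc$chrom,
                               pos = cc$pos[cc$causal_index])),
            class = "f2_population")
}

#' Select the two phenotype bulks
#'
#' Simple random sample without replacement within each phenotype class.
#'
#' @param population an [simulate_f2()] result.
#' @param bulk_size plants per bulk.
#' @param seed integer seed, or NULL.
#' @return list: `dom` and `rec`, integer plant indices.
#' @export
make_bulks <- function(population, bulk_size = population$config$bulk_size,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dom_ids <- which(population$phenotype == "dominant")
  rec_ids <- which(population$phenotype == "recessive")
  if (length(dom_ids) < bulk_size || length(rec_ids) < bulk_size) {
    stop(sprintf(
      "make_bulks: need %d plants per class, have %d dominant / %d recessive",
      bulk_size, length(dom_ids), length(rec_ids)), call. = FALSE)
  }
  list(dom = sort(sample(dom_ids, bulk_size)),
       rec = sort(sample(rec_ids, bulk_size)))
}

# observed-base probability vector for a bulk with dominant-allele
# frequency f at a site with alleles (m_base, p_base) and error rate e
base_probs <- function(f, m_base, p_base, e) {
  p <- stats::setNames(rep(e / 3, 4), BASES)
  p[m_base] <- f * (1 - e) + (1 - f) * e / 3
  p[p_base] <- (1 - f) * (1 - e) + f * e / 3
  p
}

#' Simulate pooled sequencing depths
#'
#' Per site and sample: total depth is Poisson with the configured mean;
#' base counts are multinomial with success probabilities given by the
#' sample's dominant-parent allele frequency (over the bulk's
#' `2 * bulk_size` chromosomes) perturbed by the sequencing error rate,
#' which redistributes reads uniformly over the other three bases.
#' Parents are sequenced at their fixed homozygous genotypes. Each
#' site's two alleles are drawn as a random pair of distinct bases, the
#' recessive parent's allele serving as the reference base.
#'
#' @param population an [simulate_f2()] result.
#' @param bulks a [make_bulks()] result.
#' @param seed integer seed, or NULL.
#' @return a [snp_sites()] table with attribute `truth` (causal chrom and
#'   bp position).
#' @export
simulate_depths <- function(population, bulks, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- population$config
  e <- cfg$sequencing_error_rate
  rows <- vector("list", length(population$chromosomes))
  for (c_i in seq_along(population$chromosomes)) {
    ch <- population$chromosomes[[c_i]]
    n_loci <- length(ch$pos)
    f_dom <- colSums(ch$geno[bulks$dom, , drop = FALSE]) /
      (2 * length(bulks$dom))
    f_rec <- colSums(ch$geno[bulks$rec, , drop = FALSE]) /
      (2 * length(bulks$rec))
    pair <- replicate(n_loci, sample(BASES, 2))
    m_base <- pair[1, ]; p_base <- pair[2, ]
    dom_d <- matrix(0L, n_loci, 4, dimnames = list(NULL, BASES))
    rec_d <- matrix(0L, n_loci, 4, dimnames = list(NULL, BASES))
    tot_dom <- stats::rpois(n_loci, cfg$mean_depth_dom)
    tot_rec <- stats::rpois(n_loci, cfg$mean_depth_rec)
    for (l in seq_len(n_loci)) {
      dom_d[l, ] <- stats::rmultinom(1, tot_dom[l],
                                     base_probs(f_dom[l], m_base[l],
                                                p_base[l], e))
      rec_d[l, ] <- stats::rmultinom(1, tot_rec[l],
                                     base_probs(f_rec[l], m_base[l],
                                                p_base[l], e))
    }
    rows[[c_i]] <- data.frame(
      chrom = ch$chrom, pos = ch$pos, ref = p_base, alt = m_base,
      p1_allele = m_base, p2_allele = p_base,
      dom_A = dom_d[, "A"], dom_C = dom_d[, "C"],
      dom_G = dom_d[, "G"], dom_T = dom_d[, "T"],
      rec_A = rec_d[, "A"], rec_C = rec_d[, "C"],
      rec_G = rec_d[, "G"], rec_T = rec_d[, "T"],
      p1_depth = stats::rpois(n_loci, cfg$mean_depth_parents[1]),
      p2_depth = stats::rpois(n_loci, cfg$mean_depth_parents[2]),
      stringsAsFactors = FALSE)
  }
  out <- snp_sites(do.call(rbind, rows))
  attr(out, "truth") <- population$causal
  out
}

#' Simulate a complete bulk-sequencing experiment
#'
#' Runs [simulate_f2()], [make_bulks()] and [simulate_depths()] under a
#' single seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default `config$seed`).
#' @return list: `sites` (a [snp_sites()] table), `truth` (causal locus),
#'   `population`, `bulks`.
#' @export
simulate_bsa <- function(config = sim_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  population <- simulate_f2(config, seed = NULL)
  bulks <- make_bulks(population, config$bulk_size, seed = NULL)
  sites <- simulate_depths(population, bulks, seed = NULL)
  list(sites = sites, truth = population$causal,
       population = population, bulks = bulks)
}
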