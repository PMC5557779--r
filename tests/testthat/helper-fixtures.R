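# shared fixtures and independent oracles

# build a snp_sites table from compact per-site specs:
# list(chrom, pos, ref, alt, p1, p2, dom = c(A,C,G,T), rec = c(A,C,G,T))
make_sites <- function(...) {
  specs <- list(...)
  rows <- lapply(specs, function(s) {
    data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
               p1_allele = s$p1, p2_allele = s$p2,
               dom_A = s$dom[1], dom_C = s$dom[2], dom_G = s$dom[3],
               dom_T = s$dom[4],
               rec_A = s$rec[1], rec_C = s$rec[2], rec_G = s$rec[3],
               rec_T = s$rec[4],
               p1_depth = if (is.null(s$p1_depth)) 20L else s$p1_depth,
               p2_depth = if (is.null(s$p2_depth)) 20L else s$p2_depth,
               stringsAsFactors = FALSE)
  })
  snp_sites(do.call(rbind, rows))
}

# one clean biallelic site with given M/P depths per bulk (M = A, P = T)
site_md <- function(pos, Maa, Paa, Mab, Pab, chrom = "1H") {
  list(chrom = chrom, pos = pos, ref = "T", alt = "A", p1 = "A", p2 = "T",
       dom = c(Maa, 0L, 0L, Paa), rec = c(Mab, 0L, 0L, Pab))
}

# random valid biallelic sites for property tests
random_sites <- function(n, seed) {
  set.seed(seed)
  specs <- lapply(seq_len(n), function(i) {
    pair <- sample(c("A", "C", "G", "T"), 2)
    dom <- rec <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    dom[pair] <- as.integer(rpois(2, 20) + 1)
    rec[pair] <- as.integer(rpois(2, 20) + 1)
    list(chrom = "1H", pos = i * 1000L, ref = pair[2], alt = pair[1],
         p1 = pair[1], p2 = pair[2], dom = unname(dom), rec = unname(rec))
  })
  do.call(make_sites, specs)
}

# brute-force local linear regression oracle: an independent route via
# stats::lm with per-point tricube weights over the span*n nearest
# neighbours
loess_oracle <- function(x, y, span) {
  n <- length(x)
  q <- floor(span * n)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    w <- pmax(0, (1 - (d / h)^3))^3
    use <- w > 0
    fit <- stats::lm(y ~ x, weights = w, subset = use)
    unname(stats::predict(fit, newdata = data.frame(x = x[i])))
  }, numeric(1))
}

table3_gm <- function() {
  read_genotype_table(
    system.file("extdata", "f2_recessive_genotypes.tsv", package = "bsamap"),
    n_population = 172)
}

write_vcf_fixture <- function(path, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1H>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", "P2", "BLACK", "YELLOW", sep = "\t"))
  writeLines(c(header, records), path)
  path
}
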