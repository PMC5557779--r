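test_that("depth-table reader and writer round-trip", {
  sites <- make_sites(
    site_md(100, 30, 15, 0, 40),
    list(chrom = "2H", pos = 5000, ref = "C", alt = "G,T", p1 = "G",
         p2 = "C", dom = c(0L, 10L, 9L, 3L), rec = c(0L, 12L, 0L, 8L)),
    site_md(250, 7, 7, 7, 7, chrom = "chrUn"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_table(sites, path)
  back <- read_depth_table(path)
  expect_s3_class(back, "snp_sites")
  expect_equal(as.data.frame(back), as.data.frame(sites))

  # header-only file -> empty table
  writeLines(readLines(path)[1], path)
  empty <- read_depth_table(path)
  expect_equal(nrow(empty), 0L)
  expect_s3_class(empty, "snp_sites")
})

test_that("depth-table reader reports schema and row errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  sites <- make_sites(site_md(100, 30, 15, 0, 40))
  write_depth_table(sites, path)
  lines <- readLines(path)

  # missing column named in the error
  writeLines(gsub("\tdom_C", "", lines), path)
  expect_error(read_depth_table(path), "dom_C")

  # negative depth named with its line number
  bad <- sub("\t30\t", "\t-1\t", lines[2])
  writeLines(c(lines[1], bad), path)
  expect_error(read_depth_table(path), "line 2")

  expect_error(read_depth_table(tempfile()), "no such file")
})

test_that("snp_sites validates coordinates and depths", {
  df <- as.data.frame(make_sites(site_md(100, 30, 15, 0, 40)))
  df$pos <- 0L
  expect_error(snp_sites(df), "pos")
  df <- as.data.frame(make_sites(site_md(100, 30, 15, 0, 40)))
  df$rec_T <- -3L
  expect_error(snp_sites(df), "rec_T")
  df$rec_T <- NULL
  expect_error(snp_sites(df), "rec_T")
})

test_that("BED writer converts 1-based inclusive to 0-based half-open", {
  regions <- candidate_regions("1H", 427749941, 460155270, "euclidean")
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(regions, path)
  expect_equal(readLines(path), "1H\t427749940\t460155270\teuclidean")

  write_regions_bed(candidate_regions(method = character()), path)
  expect_equal(readLines(path), character(0))

  two <- candidate_regions(c("2H", "1H"), c(10, 5), c(20, 9),
                           c("snp_index", "snp_index"))
  write_regions_bed(two, path)
  got <- readLines(path)
  expect_equal(length(got), 2L)
  expect_equal(got[1], "2H\t9\t20\tsnp_index")  # input order preserved
  # BED invariant: start = start_bp - 1 < end
  starts <- as.numeric(sapply(strsplit(got, "\t"), `[[`, 2))
  ends <- as.numeric(sapply(strsplit(got, "\t"), `[[`, 3))
  expect_true(all(starts < ends))
  expect_equal(starts, two$start_bp - 1)
})

test_that("association table round-trips at 6-decimal precision", {
  set.seed(31)
  n <- 10
  assoc <- data.frame(
    chrom = "1H", pos = seq_len(n) * 100L,
    snp_index_dom = round(runif(n), 6), snp_index_rec = round(runif(n), 6),
    delta = round(runif(n, -1, 1), 6), ed = round(runif(n, 0, sqrt(2)), 6),
    ed5 = round(runif(n), 6), window_delta = round(runif(n), 6),
    loess_ed5 = round(runif(n), 6))
  assoc$delta[3] <- NA  # undefined statistic -> "NA" cell
  path <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(assoc, path)
  raw <- readLines(path)
  expect_equal(length(raw), n + 1L)
  expect_true(grepl("\tNA\t", raw[4]))
  back <- read_association_table(path)
  expect_equal(back$delta, assoc$delta, tolerance = 1e-9)
  expect_equal(back$loess_ed5, assoc$loess_ed5, tolerance = 1e-9)
  expect_true(is.na(back$delta[3]))

  # columns absent from the input are emitted as NA
  write_association_table(assoc[c("chrom", "pos", "delta")], path)
  back <- read_association_table(path)
  expect_true(all(is.na(back$ed)))
})

test_that("VCF bulk reader reconstructs per-base depths", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path, c(
    paste("1H", 100, ".", "A", "T", ".", "PASS", ".", "GT:AD",
          "0/0:10,0", "1/1:0,12", "0/1:30,15", "0/1:5,40", sep = "\t"),
    paste("1H", 200, ".", "C", "G", ".", "PASS", ".", "GT:AD",
          "1/1:0,8", "0/0:9,0", "0/1:12,13", "0/0:20,0", sep = "\t")))
  sm <- c(parent_dom = "P1", parent_rec = "P2",
          bulk_dom = "BLACK", bulk_rec = "YELLOW")
  sites <- read_vcf_bulks(path, sm)
  expect_equal(nrow(sites), 2L)
  expect_equal(attr(sites, "n_skipped_indels"), 0L)
  expect_equal(sites$pos, c(100L, 200L))
  expect_equal(unlist(sites[1, c("dom_A", "dom_C", "dom_G", "dom_T")],
                      use.names = FALSE), c(30L, 0L, 0L, 15L))
  expect_equal(unlist(sites[1, c("rec_A", "rec_C", "rec_G", "rec_T")],
                      use.names = FALSE), c(5L, 0L, 0L, 40L))
  expect_equal(sites$p1_allele, c("A", "G"))
  expect_equal(sites$p2_allele, c("T", "C"))
  expect_equal(sites$p1_depth, c(10L, 8L))

  # indel record skipped with counter
  write_vcf_fixture(path, c(
    paste("1H", 100, ".", "A", "T", ".", "PASS", ".", "GT:AD",
          "0/0:10,0", "1/1:0,12", "0/1:30,15", "0/1:5,40", sep = "\t"),
    paste("1H", 300, ".", "C", "CT", ".", "PASS", ".", "GT:AD",
          "0/0:10,0", "1/1:0,12", "0/1:30,15", "0/1:5,40", sep = "\t")))
  expect_message(sites <- read_vcf_bulks(path, sm), "skipped 1")
  expect_equal(nrow(sites), 1L)
  expect_equal(attr(sites, "n_skipped_indels"), 1L)

  # missing sample -> configuration error
  expect_error(read_vcf_bulks(path, c(sm[-4], bulk_rec = "NOPE")), "NOPE")
  expect_error(read_vcf_bulks(path, sm[-1]), "parent_dom")
})

test_that("VCF bulk reader flags bulks without usable depths", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path, paste(
    "1H", 100, ".", "A", "T", ".", "PASS", ".", "GT:AD",
    "0/0:10,0", "1/1:0,12", "./.:.", "0/1:5,40", sep = "\t"))
  sites <- read_vcf_bulks(path, c(parent_dom = "P1", parent_rec = "P2",
                                  bulk_dom = "BLACK", bulk_rec = "YELLOW"))
  expect_true(attr(sites, "flagged")[1])
  expect_equal(bulk_total_depth(sites, "dom"), 0L)
})

test_that("genotype matrix reader enforces the code set", {
  gm <- table3_gm()
  expect_equal(gm$marker_ids,
               c("HZSNP63", "HZSNP34", "HZSNP36", "HZSNP32",
                 "HZSNP59", "HZSNP61"))
  expect_equal(gm$n_population, 172L)
  expect_equal(length(gm$plant_ids), 15L)

  bad <- matrix("2/2", 1, 1, dimnames = list("m1", "p1"))
  expect_error(genotype_matrix(bad), "m1")
  expect_error(genotype_matrix(matrix("0/0", 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("x", "y"))),
                               n_population = 1), "n_population")
})
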