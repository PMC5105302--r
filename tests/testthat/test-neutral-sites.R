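make_gff3 <- function(records, chrom_len) {
  f <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  write_annotation_gff3(records, f, chrom_len = chrom_len)
  f
}

three_gene_records <- tibble::tibble(
  locus_tag = c("L1", "L2", "L3"), chrom = "testchr",
  start = c(100, 600, 1200), end = c(400, 900, 1500),
  strand = c("+", "-", "+"), feature_type = "gene",
  product = "hypothetical protein"
)

test_that("GFF3 and GenBank reads agree on the same features", {
  gff <- make_gff3(three_gene_records, 5000)
  from_gff <- read_annotation(gff, dialect = "gff3")
  expect_equal(nrow(from_gff), 3)
  expect_equal(from_gff$start, three_gene_records$start)
  expect_equal(from_gff$end, three_gene_records$end)

  gbk <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       testchr                 5000 bp    DNA     linear   BCT",
    "DEFINITION  synthetic three-gene fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..5000",
    "     gene            100..400",
    "                     /locus_tag=\"L1\"",
    "                     /product=\"hypothetical protein\"",
    "     gene            complement(600..900)",
    "                     /locus_tag=\"L2\"",
    "                     /product=\"hypothetical protein\"",
    "     gene            1200..1500",
    "                     /locus_tag=\"L3\"",
    "                     /product=\"hypothetical protein\"",
    "ORIGIN",
    "//"
  ), gbk)
  from_gbk <- read_annotation(gbk, dialect = "genbank")
  expect_equal(
    from_gbk[c("locus_tag", "start", "end", "strand", "feature_type")],
    from_gff[c("locus_tag", "start", "end", "strand", "feature_type")]
  )

  # empty feature table reads as an empty record set
  empty <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       testchr                 5000 bp    DNA     linear   BCT",
    "FEATURES             Location/Qualifiers",
    "ORIGIN",
    "//"
  ), empty)
  expect_equal(nrow(read_annotation(empty, dialect = "genbank")), 0)
  expect_error(read_annotation(gff, dialect = "embl"))
  expect_error(read_annotation("/nonexistent/file.gff3"), "not found")
})

test_that("the three neutral-site ranges are recovered exactly from a planted genome", {
  ns <- pcc7002_neutral_sites()
  ann <- generate_annotation(
    2800, purrr::map2(ns$start, ns$end, c), chrom_len = 3008047, seed = 2
  )
  gaps <- find_intergenic_gaps(ann, chrom_len = 3008047, min_len = 1000)
  expect_equal(nrow(gaps), 3)
  expect_equal(gaps$start, ns$start)
  expect_equal(gaps$end, ns$end)
  expect_equal(gaps$length, ns$end - ns$start + 1)
  # flanking loci are the features abutting each gap
  for (i in 1:3) {
    left <- dplyr::filter(ann, end == ns$start[i] - 1)
    right <- dplyr::filter(ann, start == ns$end[i] + 1)
    expect_equal(gaps$left_locus[i], left$locus_tag)
    expect_equal(gaps$right_locus[i], right$locus_tag)
  }
})

test_that("abutting features leave no gap and thresholding is strict and anti-monotone", {
  abutting <- tibble::tibble(
    locus_tag = c("a", "b"), chrom = "c",
    start = c(1, 501), end = c(500, 1000),
    strand = "+", feature_type = "gene", product = NA_character_
  )
  expect_equal(nrow(find_intergenic_gaps(abutting, 1000, min_len = 0)), 0)
  # a gap of exactly min_len is excluded ("greater than", strict)
  two <- tibble::tibble(
    locus_tag = c("a", "b"), chrom = "c",
    start = c(1, 1501), end = c(500, 2500),
    strand = "+", feature_type = "gene", product = NA_character_
  )
  expect_equal(nrow(find_intergenic_gaps(two, 2500, min_len = 1000)), 0)
  expect_equal(nrow(find_intergenic_gaps(two, 2500, min_len = 999)), 1)
  # raising the threshold never adds gaps
  withr::with_seed(31, {
    rec <- random_records(25, 30000)
    sizes <- vapply(c(0, 200, 500, 1000, 2000), function(ml) {
      nrow(find_intergenic_gaps(rec, 30000, min_len = ml))
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0))
  })
  expect_error(find_intergenic_gaps(two, chrom_len = 2000), "exceeds")
})

test_that("gap finder equals the per-base coverage-mask oracle and ignores record order", {
  withr::with_seed(32, {
    for (i in 1:25) {
      chrom_len <- sample(5000:30000, 1)
      rec <- random_records(sample(3:40, 1), chrom_len)
      circular <- i %% 2 == 0
      got <- find_intergenic_gaps(rec, chrom_len, min_len = 500,
                                  circular = circular)
      want <- oracle_gaps(rec, chrom_len, min_len = 500, circular = circular)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$length, want$length)
      shuffled <- rec[sample(nrow(rec)), ]
      again <- find_intergenic_gaps(shuffled, chrom_len, min_len = 500,
                                    circular = circular)
      expect_equal(again, got)
    }
  })
})

test_that("circular mode joins the terminal and origin gaps across the origin", {
  rec <- tibble::tibble(
    locus_tag = c("a", "b"), chrom = "c",
    start = c(2001, 6001), end = c(4000, 8000),
    strand = "+", feature_type = "gene", product = NA_character_
  )
  linear <- find_intergenic_gaps(rec, 10000, min_len = 0)
  expect_equal(nrow(linear), 3)
  circ <- find_intergenic_gaps(rec, 10000, min_len = 0, circular = TRUE)
  expect_equal(nrow(circ), 2)
  wrap <- dplyr::filter(circ, start > end)
  expect_equal(wrap$start, 8001)
  expect_equal(wrap$end, 2000)
  expect_equal(wrap$length, 4000)
  expect_equal(wrap$left_locus, "b")
  expect_equal(wrap$right_locus, "a")
})

test_that("homology arms sit inside the gap and tiers follow the arm length", {
  gap <- tibble::tibble(chrom = "c", start = 10001, end = 14000,
                        length = 4000, left_locus = "a", right_locus = "b")
  tiers <- vapply(c(100, 250, 499, 500, 749, 750, 1250), function(len) {
    design_homology_arms(gap, len)$predicted_tier
  }, character(1))
  expect_equal(tiers, c("below_minimum", "low", "low", "moderate",
                        "moderate", "high", "high"))
  arms <- design_homology_arms(gap, 500)
  expect_equal(arms$five_prime_start, 10001)
  expect_equal(arms$five_prime_end, 10500)
  expect_equal(arms$three_prime_start, 13501)
  expect_equal(arms$three_prime_end, 14000)
  expect_error(design_homology_arms(gap, 2500), "exceeds")
  expect_error(design_homology_arms(gap, 0), "positive")
})

test_that("gap exports preserve coordinates in each convention", {
  rec <- three_gene_records
  gaps <- find_intergenic_gaps(rec, 5000, min_len = 100)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_gaps_tsv(gaps, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$start, gaps$start)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gaps_bed(gaps, bed)
  bed_cols <- readr::read_tsv(bed, col_names = FALSE, show_col_types = FALSE)
  expect_equal(bed_cols$X2, gaps$start - 1) # BED is 0-based half-open
  expect_equal(bed_cols$X3, gaps$end)
})
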