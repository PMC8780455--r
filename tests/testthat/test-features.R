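test_that("exactly 96 trinucleotide classes exist and match a brute-force oracle", {
  classes <- trinucleotide_classes()
  expect_length(classes, 96L)
  expect_length(unique(classes), 96L)
  # enumerate all 192 stranded (context, alt) combinations and canonicalize
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(f5 = bases, ref = bases, f3 = bases, alt = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  ctx <- paste0(grid$f5, grid$ref, grid$f3)
  got <- canonical_trinucleotide(ctx, grid$alt)
  expect_identical(got, oracle_canonical(ctx, grid$alt))
  expect_setequal(unique(got), classes)
  # the motif example: ACA with C>G is already on the pyrimidine strand
  expect_equal(canonical_trinucleotide("ACA", "G"), "ACA>AGA")
  # purine ref G>A in context TGC reverse-complements to GCA with C>T
  expect_equal(canonical_trinucleotide("TGC", "A"), "GCA>GTA")
})

test_that("trinucleotide counts conserve context-resolvable variants", {
  fx <- tiny_fixture()
  s <- fx$cohort$samples[[3]]
  tc <- trinucleotide_counts(s, fx$reference$genome)
  expect_equal(sum(tc) + attr(tc, "n_skipped"), n_variants(s))
  expect_true(all(tc >= 0))
})

test_that("ref-mismatching or flankless variants are skipped, not fatal", {
  genome <- structure(list(seq = c(Z = "ACGTACGT"),
                           lengths = c(Z = 8L)), class = "genome_ref")
  s <- sample_variants("s", variants = data.frame(
    chrom = "Z",
    pos = c(2L, 1L, 8L, 3L),
    ref = c("C", "A", "T", "T"), # pos 3 is G in the genome: mismatch
    alt = c("G", "T", "A", "A")))
  expect_message(tc <- trinucleotide_counts(s, genome), "skipped 3")
  expect_equal(sum(tc), 1L)
  expect_equal(unname(tc["ACG>AGG"]), 1L)
})

test_that("bin counting honors 1-based inclusive boundaries", {
  bins <- bin_index(data.frame(chrom = c("1", "1"),
                               start = c(1L, 1000001L),
                               end = c(1000000L, 2000000L)))
  s <- sample_variants("s", variants = data.frame(
    chrom = c("1", "1"), pos = c(1000000L, 1000001L),
    ref = "A", alt = "T"))
  bc <- bin_counts(s, bins)
  expect_equal(as.integer(bc), c(1L, 1L))
  # outside all bins / unknown chromosome -> unbinned tally
  s2 <- sample_variants("s2", variants = data.frame(
    chrom = c("1", "9"), pos = c(2000001L, 5L), ref = "A", alt = "T"))
  bc2 <- bin_counts(s2, bins)
  expect_equal(sum(bc2), 0L)
  expect_equal(attr(bc2, "n_unbinned"), 2L)
})

test_that("driver counting is inclusive and double-counts overlapping genes", {
  genes <- gene_regions(data.frame(gene = c("G1", "G2"),
                                   chrom = "1", start = c(100L, 150L),
                                   end = c(200L, 250L)))
  s <- sample_variants("s", variants = data.frame(
    chrom = "1", pos = c(200L, 201L, 160L), ref = "A", alt = "T"))
  dc <- driver_counts(s, genes)
  # G1 gets 160 and 200 (201 is 1 bp past its end); G2 gets all three
  expect_equal(unname(dc), c(2L, 3L))
  expect_gt(sum(dc), n_variants(s)) # overlap can exceed the variant count
})

test_that("interval counters agree with a GenomicRanges oracle", {
  skip_if_not_installed("GenomicRanges")
  fx <- tiny_fixture()
  s <- fx$cohort$samples[[7]]
  bins <- fx$reference$bins
  genes <- fx$reference$genes
  gr_var <- GenomicRanges::GRanges(s$variants$chrom,
                                   IRanges::IRanges(s$variants$pos, s$variants$pos))
  gr_bins <- GenomicRanges::GRanges(bins$chrom,
                                    IRanges::IRanges(bins$start, bins$end))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start, genes$end))
  expect_equal(as.integer(bin_counts(s, bins)),
               GenomicRanges::countOverlaps(gr_bins, gr_var))
  expect_equal(as.integer(driver_counts(s, genes)),
               GenomicRanges::countOverlaps(gr_genes, gr_var))
})

test_that("features are linear under disjoint union and monotone under downsampling", {
  fx <- tiny_fixture()
  ref <- fx$reference
  s <- fx$cohort$samples[[1]]
  n <- n_variants(s)
  half1 <- sample_variants("h1", variants = s$variants[1:(n %/% 2), ])
  half2 <- sample_variants("h2", variants = s$variants[(n %/% 2 + 1):n, ])
  for (fun in list(function(x) bin_counts(x, ref$bins),
                   function(x) trinucleotide_counts(x, ref$genome),
                   function(x) driver_counts(x, ref$genes))) {
    expect_equal(as.integer(fun(s)),
                 as.integer(fun(half1)) + as.integer(fun(half2)))
  }
  d <- downsample(s, 0.1, seed = 3)
  expect_true(all(bin_counts(d, ref$bins) <= bin_counts(s, ref$bins)))
  expect_true(all(trinucleotide_counts(d, ref$genome) <=
                    trinucleotide_counts(s, ref$genome)))
  expect_true(all(driver_counts(d, ref$genes) <= driver_counts(s, ref$genes)))
})

test_that("cohort feature matrices have aligned shapes and names", {
  fx <- tiny_fixture()
  cohort <- fx$cohort$samples[1:6]
  fm <- suppressMessages(build_feature_matrix(cohort, fx$reference$bins,
                                              fx$reference$genes,
                                              fx$reference$genome))
  expect_equal(dim(fm$bins), c(6L, nrow(fx$reference$bins)))
  expect_equal(dim(fm$tri), c(6L, 96L))
  expect_equal(dim(fm$drivers), c(6L, nrow(fx$reference$genes)))
  expect_equal(fm$sample_ids,
               unname(vapply(cohort, `[[`, character(1), "sample_id")))
  empty <- build_feature_matrix(list(), fx$reference$bins, fx$reference$genes,
                                fx$reference$genome)
  expect_equal(nrow(empty$bins), 0L)
  expect_equal(colnames(empty$tri), trinucleotide_classes())

  prep <- prepare_features(fm, "log1p")
  expect_equal(prep$bins, log1p(matrix(as.numeric(fm$bins), nrow(fm$bins),
                                       ncol(fm$bins),
                                       dimnames = dimnames(fm$bins))))
  tot <- prepare_features(fm, "total")
  expect_true(all(abs(rowSums(tot$tri) - 1) < 1e-9))
})
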