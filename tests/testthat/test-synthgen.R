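small_config <- function(...) {
  synthetic_config(n_classes = 3L, samples_per_class = 5L, n_chromosomes = 2L,
                   chromosome_length = 1e6, bin_size = 2.5e5,
                   n_driver_genes = 6L, gene_length = 1e4,
                   burden_median = 300, seed = 11L, ...)
}

test_that("reference generation tiles bins and places non-overlapping genes", {
  ref <- generate_reference(synthetic_config(n_chromosomes = 2L,
                                             chromosome_length = 3e6))
  expect_equal(nrow(ref$bins), 6L)
  expect_equal(unname(ref$genome$lengths), c(3e6, 3e6))
  g <- ref$genes[order(ref$genes$chrom, ref$genes$start), ]
  for (chr in unique(g$chrom)) {
    rows <- g[g$chrom == chr, ]
    if (nrow(rows) > 1)
      expect_true(all(rows$start[-1] > rows$end[-nrow(rows)]))
  }
  expect_error(generate_reference(synthetic_config(
    n_chromosomes = 1L, chromosome_length = 1e5, n_driver_genes = 10L,
    gene_length = 2e4)), "do not fit")
})

test_that("the genome's base composition is near-uniform across seeds", {
  for (seed in 1:3) {
    cfg <- synthetic_config(n_chromosomes = 2L, chromosome_length = 3e6,
                            seed = seed)
    ref <- generate_reference(cfg)
    gc <- sum(vapply(ref$genome$seq, function(s)
      sum(strsplit(s, "")[[1]] %in% c("G", "C")), numeric(1))) /
      sum(ref$genome$lengths)
    expect_lt(abs(gc - 0.5), 0.01)
  }
})

test_that("generation is a pure function of config and seed", {
  cfg <- small_config()
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$genome$seq, r2$genome$seq)
  c1 <- generate_cohort(cfg, r1)
  c2 <- generate_cohort(cfg, r2)
  expect_identical(lapply(c1$samples, `[[`, "variants"),
                   lapply(c2$samples, `[[`, "variants"))
  expect_identical(c1$truth, c2$truth)
})

test_that("cohorts have the configured shape and genome-consistent variants", {
  cfg <- small_config()
  ref <- generate_reference(cfg)
  cohort <- generate_cohort(cfg, ref)
  expect_length(cohort$samples, 15L)
  expect_equal(nrow(cohort$labels), 15L)
  expect_true(all(table(cohort$labels$label) == 5L))
  for (s in cohort$samples[c(1, 8, 15)]) {
    v <- s$variants
    expect_false(any(duplicated(paste(v$chrom, v$pos))))
    expect_identical(mutorigin:::genome_base(ref$genome, v$chrom, v$pos), v$ref)
    expect_true(all(v$pos >= 2 &
                      v$pos <= ref$genome$lengths[v$chrom] - 1))
  }
})

test_that("empirical bin frequencies approach the class truth as cohorts grow", {
  tv_dist <- function(spc) {
    # driver enrichment is a fixed bias on the bin profile, so it is
    # disabled here to isolate multinomial convergence
    cfg <- synthetic_config(n_classes = 3L, samples_per_class = spc,
                            n_chromosomes = 2L, chromosome_length = 1e6,
                            bin_size = 2.5e5, n_driver_genes = 6L,
                            gene_length = 1e4, burden_median = 300,
                            driver_multiplier = 0, bin_alpha = 1,
                            seed = 11L)
    ref <- generate_reference(cfg)
    cohort <- generate_cohort(cfg, ref)
    cls <- cohort$truth$classes[1]
    ids <- cohort$labels$sample_id[cohort$labels$label == cls]
    counts <- Reduce(`+`, lapply(cohort$samples[ids], bin_counts,
                                 bins = ref$bins))
    emp <- counts / sum(counts)
    # driver enrichment perturbs the profile slightly; TV still shrinks
    sum(abs(emp - cohort$truth$bin_profile[[cls]])) / 2
  }
  expect_lt(tv_dist(60L), tv_dist(5L))
})

test_that("enriched driver genes are hotter than background genes in-class", {
  fx <- tiny_fixture()
  ref <- fx$reference
  truth <- fx$cohort$truth
  cls <- truth$classes[1]
  ids <- fx$cohort$labels$sample_id[fx$cohort$labels$label == cls]
  dmat <- do.call(rbind, lapply(fx$cohort$samples[ids], driver_counts,
                                genes = ref$genes))
  enriched <- colnames(dmat) %in% truth$enriched_genes[[cls]]
  expect_true(any(enriched))
  w <- stats::wilcox.test(as.numeric(dmat[, enriched]),
                          as.numeric(dmat[, !enriched]),
                          alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 0.01)
})

test_that("fixtures rebuild byte-identically from the same seed", {
  d1 <- file.path(tempdir(), "fixrep1")
  d2 <- file.path(tempdir(), "fixrep2")
  cfg <- small_config()
  f1 <- suppressMessages(make_fixture("tiny", dir = d1, seed = 5, config = cfg))
  f2 <- suppressMessages(make_fixture("tiny", dir = d2, seed = 5, config = cfg))
  md5_1 <- tools::md5sum(list.files(d1, recursive = TRUE, full.names = TRUE))
  md5_2 <- tools::md5sum(list.files(d2, recursive = TRUE, full.names = TRUE))
  expect_equal(unname(md5_1[!grepl("manifest", names(md5_1))]),
               unname(md5_2[!grepl("manifest", names(md5_2))]))
  expect_length(f1$vcfs, 15L)
})
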