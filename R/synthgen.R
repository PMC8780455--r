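## -------------------------------------------------------------------------
## Synthetic cohort generator. Emits the statistical structure the
## classifier exploits — classes differing in 1 Mb bin-density profile,
## trinucleotide substitution spectrum and driver-gene mutation rates —
## as ordinary VCF / FASTA / TSV files, so the whole pipeline runs without
## controlled-access patient data.
## -------------------------------------------------------------------------

#' Configuration of a synthetic cohort
#'
#' @param n_classes number of cancer-type classes.
#' @param samples_per_class samples (one donor each) per class.
#' @param n_chromosomes,chromosome_length synthetic genome shape (bp).
#' @param bin_size density-bin width in bp.
#' @param n_driver_genes,gene_length driver-gene regions placed
#'   non-overlapping on the genome.
#' @param burden_median,burden_sdlog per-sample mutation burden is drawn
#'   log-normal with this median and log-sd.
#' @param bin_alpha Dirichlet concentration of the per-class bin profiles.
#'   Smaller values give more distinct (more separable) classes; the default
#'   (40) yields diffuse profiles whose subtle differences are detectable
#'   from full mutation profiles but noisy under strong downsampling, the
#'   regime sparse liquid-biopsy profiles occupy.
#' @param subst_alpha Dirichlet concentration of the per-class preference
#'   over the 6 pyrimidine substitution types.
#' @param n_enriched_per_class driver genes enriched in each class.
#' @param driver_multiplier rate multiplier of enriched genes over the
#'   baseline expectation `burden * gene_length / genome_length`.
#' @param seed master seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 4L, samples_per_class = 20L,
                             n_chromosomes = 2L, chromosome_length = 3e6,
                             bin_size = 1e6, n_driver_genes = 12L,
                             gene_length = 2e4, burden_median = 2000,
                             burden_sdlog = 0.3, bin_alpha = 40,
                             subst_alpha = 40, n_enriched_per_class = 2L,
                             driver_multiplier = 10, seed = 1L) {
  stopifnot(n_classes >= 2, samples_per_class >= 1, n_chromosomes >= 1,
            chromosome_length >= 3, bin_size >= 1, burden_median >= 1,
            bin_alpha > 0, subst_alpha > 0, driver_multiplier >= 0)
  if (n_driver_genes * 2 * gene_length > n_chromosomes * chromosome_length)
    stop_mo("driver genes do not fit: %d genes of %g bp on a %g bp genome",
            n_driver_genes, gene_length, n_chromosomes * chromosome_length)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic reference genome and its manifests
#'
#' The genome is i.i.d. uniform A/C/G/T per chromosome; bins tile each
#' chromosome at `bin_size` (final bin partial); driver genes are placed
#' non-overlapping, at a random offset inside equal-width slots.
#'
#' @param config a [synthetic_config()].
#' @param seed seed (defaults to the config's).
#' @return list with `genome` (a `genome_ref`), `bins` (a [bin_index()]) and
#'   `genes` (a [gene_regions()]).
#' @export
generate_reference <- function(config, seed = config$seed) {
  with_seed(derive_seed(seed, "reference"), {
    chroms <- paste0("S", seq_len(config$n_chromosomes))
    seqs <- vapply(chroms, function(chr)
      paste(sample(DNA_BASES, config$chromosome_length, replace = TRUE),
            collapse = ""), character(1))
    genome <- structure(list(seq = seqs,
                             lengths = stats::setNames(nchar(seqs), chroms)),
                        class = "genome_ref")
    bins <- tile_bins(genome$lengths, config$bin_size)
    # genes: distribute over chromosomes, one per slot, random offset
    per_chr <- largest_remainder(config$n_driver_genes,
                                 rep(1 / config$n_chromosomes,
                                     config$n_chromosomes))
    rows <- list()
    g <- 0L
    for (ci in seq_len(config$n_chromosomes)) {
      k <- per_chr[ci]
      if (k == 0) next
      slot <- floor(config$chromosome_length / k)
      if (slot <= config$gene_length)
        stop_mo("driver genes do not fit on chromosome %s", chroms[ci])
      for (s in seq_len(k)) {
        g <- g + 1L
        start <- (s - 1L) * slot +
          sample.int(slot - config$gene_length, 1L)
        rows[[g]] <- data.frame(gene = sprintf("GENE%03d", g),
                                chrom = chroms[ci], start = start,
                                end = start + config$gene_length - 1L,
                                stringsAsFactors = FALSE)
      }
    }
    list(genome = genome, bins = bins,
         genes = gene_regions(do.call(rbind, rows)))
  })
}

SUBST_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, length(alpha))
  g / sum(g)
}

## Choose alt alleles for given ref bases under a class's preference over
## the 6 pyrimidine substitution types (purine refs use the complementary
## strand's type, so the emitted alt is complemented back).
draw_alts <- function(ref, pref) {
  n <- length(ref)
  alt <- character(n)
  pyr_ref <- ifelse(ref %in% c("C", "T"), ref, COMP[ref])
  for (pr in c("C", "T")) {
    idx <- which(pyr_ref == pr)
    if (!length(idx)) next
    types <- SUBST_TYPES[substr(SUBST_TYPES, 1, 1) == pr]
    w <- pref[types]
    if (sum(w) <= 0) w <- rep(1, 3)
    pick <- sample(3L, length(idx), replace = TRUE, prob = w / sum(w))
    pyr_alt <- substr(types, 3, 3)[pick]
    flip <- !(ref[idx] %in% c("C", "T"))
    alt[idx] <- ifelse(flip, COMP[pyr_alt], pyr_alt)
  }
  alt
}

#' Generate a synthetic multi-class cohort
#'
#' For each class, draws a bin-density profile (Dirichlet), a substitution
#' preference over the 6 pyrimidine substitution types (Dirichlet) and a set
#' of enriched driver genes. For each sample, draws a log-normal mutation
#' burden, allocates mutations to bins multinomially, places each uniformly
#' inside its bin (never on a chromosome edge, so every variant has a full
#' trinucleotide context), reads the reference base from the genome and
#' draws the alternate allele from the class's substitution preference.
#' Enriched genes then receive extra mutations at
#' `driver_multiplier x baseline` Poisson rate. Positions are deduplicated
#' within a sample.
#'
#' @param config a [synthetic_config()].
#' @param reference a [generate_reference()] result (regenerated from the
#'   config if missing).
#' @return list with `samples` (list of [sample_variants()]), `labels` (a
#'   [label_table()]) and `truth` (the class-level profiles, preferences,
#'   enriched gene sets and per-sample burdens actually drawn).
#' @export
generate_cohort <- function(config, reference = generate_reference(config)) {
  genome <- reference$genome
  bins <- reference$bins
  genes <- reference$genes
  genome_len <- sum(genome$lengths)
  class_names <- sprintf("CLASS%02d", seq_len(config$n_classes))
  truth <- list(classes = class_names, bin_profile = list(),
                subst_pref = list(), enriched_genes = list(), burden = list())
  samples <- list()
  label_rows <- list()
  for (k in seq_len(config$n_classes)) {
    cls <- class_names[k]
    cseed <- derive_seed(config$seed, "class", cls)
    class_truth <- with_seed(cseed, {
      list(profile = rdirichlet1(rep(config$bin_alpha, nrow(bins))),
           pref = stats::setNames(rdirichlet1(rep(config$subst_alpha, 6)),
                                  SUBST_TYPES),
           enriched = if (config$n_enriched_per_class > 0 && nrow(genes) > 0)
             sort(sample(genes$gene, min(config$n_enriched_per_class,
                                         nrow(genes))))
           else character(0))
    })
    truth$bin_profile[[cls]] <- class_truth$profile
    truth$subst_pref[[cls]] <- class_truth$pref
    truth$enriched_genes[[cls]] <- class_truth$enriched
    burdens <- integer(config$samples_per_class)
    for (i in seq_len(config$samples_per_class)) {
      sid <- sprintf("%s_S%03d", cls, i)
      sv <- with_seed(derive_seed(config$seed, "sample", sid), {
        burden <- max(1L, as.integer(round(stats::rlnorm(
          1, meanlog = log(config$burden_median), sdlog = config$burden_sdlog))))
        burdens[i] <- burden
        n_per_bin <- as.integer(stats::rmultinom(1, burden, class_truth$profile))
        chrom <- rep(bins$chrom, n_per_bin)
        lo <- rep(pmax(bins$start, 2L), n_per_bin)
        hi <- rep(pmin(bins$end, genome$lengths[bins$chrom] - 1L), n_per_bin)
        pos <- lo + floor(stats::runif(length(lo)) * (hi - lo + 1))
        # driver enrichment: extra mutations in the class's enriched genes
        if (length(class_truth$enriched)) {
          for (gn in class_truth$enriched) {
            row <- genes[genes$gene == gn, ]
            rate <- config$driver_multiplier * burden *
              config$gene_length / genome_len
            extra <- stats::rpois(1, rate)
            if (extra > 0) {
              chrom <- c(chrom, rep(row$chrom, extra))
              pos <- c(pos, row$start +
                         floor(stats::runif(extra) * (row$end - row$start + 1)))
            }
          }
        }
        keep <- !duplicated(paste(chrom, pos))
        chrom <- chrom[keep]; pos <- as.integer(pos[keep])
        ref <- genome_base(genome, chrom, pos)
        alt <- draw_alts(ref, class_truth$pref)
        sample_variants(sid, donor_id = paste0("D_", sid), label = cls,
                        variants = data.frame(chrom = chrom, pos = pos,
                                              ref = ref, alt = alt,
                                              stringsAsFactors = FALSE))
      })
      samples[[sid]] <- sv
      label_rows[[sid]] <- data.frame(sample_id = sid,
                                      donor_id = sv$donor_id, label = cls,
                                      stringsAsFactors = FALSE)
    }
    truth$burden[[cls]] <- burdens
  }
  list(samples = samples,
       labels = label_table(do.call(rbind, label_rows)),
       truth = truth)
}

#' Write a ready-to-use synthetic cohort to disk
#'
#' Generates a named cohort profile and writes every file the pipeline
#' reads: `genome.fa`, `bins.tsv`, `genes.tsv`, `labels.tsv`, one VCF per
#' sample under `vcf/`, and a `manifest.json` with md5 checksums of all
#' files. Rebuilding with the same profile and seed reproduces identical
#' files.
#'
#' @param profile `"tiny"` (4 classes x 20 samples on a 6 Mb genome) or
#'   `"standard"` (6 classes x 40 samples on a 20 Mb genome).
#' @param dir output directory (created).
#' @param seed master seed.
#' @param config optional [synthetic_config()] overriding the profile.
#' @return list of file paths plus the in-memory `cohort` and `reference`.
#' @export
make_fixture <- function(profile = c("tiny", "standard"), dir = tempfile(),
                         seed = 1L, config = NULL) {
  profile <- match.arg(profile)
  if (is.null(config)) {
    config <- switch(profile,
      tiny = synthetic_config(n_classes = 4L, samples_per_class = 20L,
                              n_chromosomes = 2L, chromosome_length = 3e6,
                              n_driver_genes = 12L, seed = seed),
      standard = synthetic_config(n_classes = 6L, samples_per_class = 40L,
                                  n_chromosomes = 4L, chromosome_length = 5e6,
                                  n_driver_genes = 24L, seed = seed))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  reference <- generate_reference(config)
  cohort <- generate_cohort(config, reference)
  paths <- list(genome = file.path(dir, "genome.fa"),
                bins = file.path(dir, "bins.tsv"),
                genes = file.path(dir, "genes.tsv"),
                labels = file.path(dir, "labels.tsv"))
  write_genome(reference$genome, paths$genome)
  write_manifest(reference$bins, paths$bins)
  write_manifest(reference$genes, paths$genes)
  utils::write.table(as.data.frame(cohort$labels), paths$labels, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vcfs <- character(0)
  for (s in cohort$samples) {
    p <- file.path(dir, "vcf", paste0(s$sample_id, ".vcf"))
    write_vcf(s, p, contigs = reference$genome$lengths)
    vcfs[s$sample_id] <- p
  }
  files <- c(unlist(paths), vcfs)
  manifest <- list(profile = profile, seed = seed,
                   md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(dir = dir, paths = paths, vcfs = vcfs, config = config,
       reference = reference, cohort = cohort,
       manifest = file.path(dir, "manifest.json"))
}
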