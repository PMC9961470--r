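test_that("parameter validation catches impossible settings", {
  expect_error(synth_params(substitution_rate = 1.2), "rates")
  expect_error(synth_params(contig_len_range = c(2e3, 300e3)),
               "contig length")
})

test_that("generation is byte-identical for a fixed seed", {
  p <- synth_params(n_chromosomes = 2L, chrom_len_range = c(30e3, 40e3),
                    contig_len_range = c(2e3, 15e3), gene_count = 40L,
                    n_markers = 12L, n_dart = 20L, n_stc = 6L, seed = 99L)
  d1 <- file.path(tempdir(), "synth-det-1")
  d2 <- file.path(tempdir(), "synth-det-2")
  t1 <- synth_generate(p, d1)
  t2 <- synth_generate(p, d2)
  for (f in names(t1$files)) {
    expect_identical(readLines(t1$files[[f]]), readLines(t2$files[[f]]),
                     info = f)
  }
  expect_identical(t1$contigs, t2$contigs)
  expect_identical(t1$corruptions, t2$corruptions)
})

test_that("every generated file is accepted by the package readers", {
  truth <- synth_fixture()
  f <- truth$files
  expect_no_warning({
    ref <- read_fasta(f$reference)
    ctg <- read_fasta(f$contigs)
    genes <- read_gff_genes(f$genes)
    reps <- read_repeatmasker_out(f$repeats)
    pa <- read_blast_tab(f$proteins_refA)
    pb <- read_blast_tab(f$proteins_refB)
  })
  expect_equal(length(ref), truth$params$n_chromosomes)
  expect_setequal(names(ctg), truth$contigs$contig_id)
  expect_equal(nrow(genes), truth$params$gene_count)
  expect_gt(nrow(reps), 0L)
  expect_gt(nrow(pa), 0L)
  # planted gene biotypes are recovered exactly from the GFF
  expect_equal(sum(genes$subclass == "lncRNA"),
               sum(truth$genes$biotype == "lncRNA"))
  expect_equal(sum(genes$subclass == "protein_coding"),
               sum(truth$genes$biotype == "protein_coding"))
})

test_that("noiseless whole-chromosome contigs place back onto themselves", {
  p <- synth_params(n_chromosomes = 3L, chrom_len_range = c(25e3, 30e3),
                    substitution_rate = 0, indel_rate = 0,
                    contig_len_range = c(20e3, 25e3),
                    repeat_mass_fraction = 0, dispersed_repeat_prob = 0,
                    gene_count = 10L, n_markers = 5L, n_dart = 5L,
                    n_stc = 3L, evidence_error_rate = 0, seed = 7L)
  d <- file.path(tempdir(), "synth-noiseless")
  truth <- synth_generate(p, d)
  ref <- read_fasta(truth$files$reference)
  ctg <- read_fasta(truth$files$contigs)
  idx <- build_anchor_index(ref, 21L)
  pl <- place_contigs(ctg, idx)
  expect_true(all(pl$status == "placed"))
  expect_true(all(pl$confidence == 1.0))
  want <- truth$contigs$chromosome[match(pl$contig_id,
                                         truth$contigs$contig_id)]
  expect_identical(pl$chromosome, want)
})

test_that("injected corruption counts follow the configured error rate", {
  p <- synth_params(n_chromosomes = 2L, chrom_len_range = c(20e3, 24e3),
                    contig_len_range = c(2e3, 8e3), gene_count = 30L,
                    n_markers = 30L, n_dart = 0L, n_stc = 30L,
                    evidence_error_rate = 0.1, seed = 1L)
  n_seeds <- 60L
  counts <- integer(n_seeds)
  claims <- integer(n_seeds)
  for (i in seq_len(n_seeds)) {
    p$seed <- i
    tr <- synth_generate(p, file.path(tempdir(), "synth-binom"))
    counts[i] <- sum(tr$corruptions$source %in% c("markers", "bac_fish"))
    claims[i] <- sum(tr$loci$source %in% c("markers", "bac_fish"))
  }
  # total corruptions ~ Binomial(total claims, 0.1); check a 99.9% CI
  ci <- qbinom(c(5e-4, 1 - 5e-4), sum(claims), 0.1)
  expect_gte(sum(counts), ci[1L])
  expect_lte(sum(counts), ci[2L])
})

test_that("truth_compare measures accuracy and detects universe mismatch", {
  truth <- synth_fixture()
  ids <- truth$contigs$contig_id
  perfect <- data.frame(contig_id = ids,
                        chromosome = truth$contigs$chromosome,
                        stringsAsFactors = FALSE)
  tc <- truth_compare(perfect, truth)
  expect_equal(tc$chromosome_accuracy, 1.0)
  expect_equal(tc$assignment_rate, 1.0)

  one_wrong <- perfect
  wrong_chrom <- setdiff(unique(truth$contigs$chromosome),
                         one_wrong$chromosome[1L])[1L]
  one_wrong$chromosome[1L] <- wrong_chrom
  tc2 <- truth_compare(one_wrong, truth)
  expect_equal(tc2$chromosome_accuracy, (nrow(perfect) - 1) / nrow(perfect))

  expect_error(truth_compare(perfect[-1, ], truth), "universe")
})
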