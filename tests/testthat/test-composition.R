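iv <- function(seq_id, start, end) {
  data.frame(seq_id = seq_id, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("merge_intervals unions overlaps and counts covered bases", {
  m <- merge_intervals(iv("c1", c(1, 41), c(50, 60)))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1, 60))
  expect_equal(attr(m, "total_bp"), 60)

  m <- merge_intervals(iv("c1", c(1, 20), c(10, 30)))
  expect_equal(nrow(m), 2L)
  expect_equal(attr(m, "total_bp"), 21)  # 1-based inclusive arithmetic

  m <- merge_intervals(iv(character(0), integer(0), integer(0)))
  expect_equal(attr(m, "total_bp"), 0)

  expect_error(merge_intervals(iv("c1", 5, 50), c(c1 = 40L)), "beyond")
  expect_error(merge_intervals(iv("zz", 1, 5), c(c1 = 40L)), "unknown")
})

test_that("merge_intervals is idempotent and permutation-invariant", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    d <- iv(sample(c("a", "b"), n, TRUE),
            sample.int(500, n, TRUE), 0)
    d$end <- d$start + sample.int(80, n, TRUE) - 1L
    m1 <- merge_intervals(d)
    m2 <- merge_intervals(d[sample(n), , drop = FALSE])
    expect_identical(m1, m2)
    expect_identical(merge_intervals(m1), m1)
  }
})

test_that("merged coverage equals the per-base bitmap oracle", {
  set.seed(22)
  lens <- c(c1 = 8000L, c2 = 10000L, c3 = 3000L)
  for (rep in 1:25) {
    n <- sample(1:50, 1)
    id <- sample(names(lens), n, TRUE)
    start <- vapply(id, function(x) sample.int(lens[[x]] - 100L, 1),
                    integer(1))
    d <- iv(id, start, pmin(start + sample.int(400, n, TRUE), lens[id]))
    expect_equal(interval_coverage(d, lens), coverage_bitmap(d, lens))
  }
})

test_that("composition splits totals, repeats and genes by partition", {
  pl <- data.frame(contig_id = c("c1", "c2"),
                   status = c("placed", "placed"),
                   stringsAsFactors = FALSE)
  contigs <- c(c1 = strrep("A", 1000), c2 = strrep("C", 500),
               c3 = strrep("G", 300))
  genes <- data.frame(seq_id = c("c1", "c1", "c3"),
                      start = c(1, 101, 1), end = c(50, 150, 30),
                      subclass = c("protein_coding", "lncRNA",
                                   "protein_coding"),
                      stringsAsFactors = FALSE)
  reps <- iv("c3", c(1, 41), c(50, 60))
  comp <- compute_composition(pl, contigs, reps, genes)

  placed <- comp[comp$partition == "placed", ]
  unplaced <- comp[comp$partition == "unplaced", ]
  expect_equal(placed$total_bp, 1500)
  expect_equal(unplaced$total_bp, 300)     # unlisted contig -> unplaced
  expect_equal(placed$repeat_bp, 0)
  expect_equal(unplaced$repeat_bp, 60)
  expect_equal(placed$n_genes, 2L)
  expect_equal(placed$n_lncRNA, 1L)
  expect_equal(unplaced$n_protein_coding, 1L)
  # conservation: partitions add up to the whole assembly
  expect_equal(sum(comp$total_bp), sum(nchar(contigs)))
  expect_equal(protein_coding_placement_rate(comp), 1 / 2)
})

test_that("ambiguous contigs count as unplaced and accounting never leaks", {
  contigs <- c(a = strrep("A", 100), b = strrep("C", 200))
  genes <- data.frame(seq_id = c("a", "b"), start = 1, end = 10,
                      subclass = "protein_coding", stringsAsFactors = FALSE)
  reps <- iv(c("a", "b"), 1, c(20, 30))
  mk <- function(status_a) {
    data.frame(contig_id = c("a", "b"), status = c(status_a, "placed"),
               stringsAsFactors = FALSE)
  }
  c1 <- compute_composition(mk("placed"), contigs, reps, genes)
  c2 <- compute_composition(mk("ambiguous"), contigs, reps, genes)
  # moving contig a out of the placed partition moves exactly its mass
  expect_equal(c1$total_bp[1] - c2$total_bp[1], 100)
  expect_equal(c1$repeat_bp[1] - c2$repeat_bp[1], 20)
  expect_equal(c1$n_genes[1] - c2$n_genes[1], 1L)
  expect_equal(sum(c1$total_bp), sum(c2$total_bp))
  expect_equal(sum(c1$repeat_bp), sum(c2$repeat_bp))
  expect_equal(sum(c1$n_genes), sum(c2$n_genes))
})

test_that("protein-coding placement rate follows its definition", {
  comp <- data.frame(partition = c("placed", "unplaced"),
                     n_protein_coding = c(98L, 2L))
  expect_equal(protein_coding_placement_rate(comp), 0.98)
  comp$n_protein_coding <- c(0L, 0L)
  expect_error(protein_coding_placement_rate(comp), "no protein-coding")
})

test_that("synthetic planted repeat mass is recovered exactly", {
  truth <- synth_fixture()
  rm <- read_repeatmasker_out(truth$files$repeats)
  contigs <- read_fasta(truth$files$contigs)
  # truth bookkeeping: array contigs are repeat-covered end to end, plus
  # one dispersed unit copy per annotated non-array contig
  rep_only <- truth$contigs[truth$contigs$repeat_only, ]
  n_dispersed <- sum(!truth$repeats$contig_id %in% rep_only$contig_id)
  expected_bp <- sum(rep_only$length) +
    n_dispersed * truth$params$repeat_unit_len
  got_bp <- interval_coverage(rm[c("seq_id", "start", "end")],
                              nchar(contigs))
  expect_equal(got_bp, expected_bp, tolerance = 1e-9)
  # and each array contig individually is fully covered after merging
  for (id in rep_only$contig_id) {
    d <- rm[rm$seq_id == id, c("seq_id", "start", "end")]
    expect_equal(interval_coverage(d), nchar(contigs[[id]]))
  }

  genes <- read_gff_genes(truth$files$genes)
  pl <- placement_fixture()
  comp <- compute_composition(pl, contigs, rm, genes)
  expect_equal(sum(comp$total_bp), sum(nchar(contigs)))
  expect_equal(sum(comp$n_genes), nrow(truth$genes))
  # repeat-only contigs are unplaced, so the unplaced partition is
  # repeat-dominated while the placed partition is mostly unique sequence
  expect_gt(comp$repeat_fraction[comp$partition == "unplaced"], 0.9)
  expect_lt(comp$repeat_fraction[comp$partition == "placed"], 0.1)
})
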