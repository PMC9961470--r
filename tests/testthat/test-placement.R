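# independent canonical-kmer dictionary used as the oracle for index content
oracle_unique_kmers <- function(reference, k) {
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  all <- character(0)
  for (seq in reference) {
    n <- nchar(seq) - k + 1
    for (i in seq_len(max(n, 0))) {
      f <- substr(seq, i, i + k - 1)
      r <- rc1(f)
      all <- c(all, if (f <= r) f else r)
    }
  }
  all <- all[!grepl("N", all, fixed = TRUE)]
  names(which(table(all) == 1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("anchor index keeps exactly the k-mers unique across strands", {
  # "ACGTT": forward 3-mers ACG, CGT, GTT; ACG and CGT fold to the same
  # canonical form (each is the other's reverse complement), GTT folds to
  # AAC -> only AAC is unique
  idx <- build_anchor_index(c(chr1 = "ACGTT"), k = 3L)
  expect_identical(idx$kmer, "AAC")
  expect_identical(idx$pos, 3L)

  # every canonical 3-mer of ACGTACGT repeats -> empty index
  idx <- build_anchor_index(c(chr1 = "ACGTACGT"), k = 3L)
  expect_length(idx$kmer, 0L)

  # two identical chromosomes share all k-mers -> nothing unique
  s <- random_dna(300)
  idx <- build_anchor_index(c(chr1 = s, chr2 = s), k = 21L)
  expect_length(idx$kmer, 0L)

  set.seed(31)
  ref <- c(chr1 = random_dna(400), chr2 = random_dna(400),
           chr3 = paste0(random_dna(100), "NNNNN", random_dna(100)))
  for (k in c(5L, 11L)) {
    idx <- build_anchor_index(ref, k)
    expect_setequal(idx$kmer, oracle_unique_kmers(ref, k))
  }
})

test_that("anchor index rejects invalid k", {
  expect_error(build_anchor_index(c(c1 = "ACGT"), k = 4L), "odd")
  expect_error(build_anchor_index(c(c1 = "ACGT"), k = 21L), "exceeds")
})

test_that("exact substrings place with full confidence and correct strand", {
  set.seed(91)
  ref <- setNames(vapply(1:3, function(i) random_dna(3000), character(1)),
                  paste0("Chr", 1:3))
  idx <- build_anchor_index(ref, 21L)

  slice <- c(ctgA = substr(ref[["Chr3"]], 1001, 2000))
  p <- place_contig(slice, idx)
  expect_identical(p$status, "placed")
  expect_identical(p$chromosome, "Chr3")
  expect_identical(p$orientation, "+")
  expect_equal(p$confidence, 1.0)
  expect_true(p$position >= 1001 && p$position <= 2000)

  rc <- c(ctgB = revcomp(slice)[[1]])
  p2 <- place_contig(rc, idx)
  expect_identical(p2$chromosome, "Chr3")
  expect_identical(p2$orientation, "-")

  # vote tallies are invariant to reverse-complementation
  expect_identical(p$votes_total, p2$votes_total)
  expect_identical(attr(p, "votes")[[1]], attr(p2, "votes")[[1]])
})

test_that("foreign sequence is unplaced and chimeras are ambiguous", {
  set.seed(92)
  ref <- setNames(vapply(1:2, function(i) random_dna(3000), character(1)),
                  c("Chr1", "Chr2"))
  idx <- build_anchor_index(ref, 21L)

  p <- place_contig(c(ctgX = random_dna(500)), idx)
  expect_identical(p$status, "unplaced")
  expect_equal(p$votes_total, 0L)

  # equal-length halves from two chromosomes cast equal votes
  half1 <- substr(ref[["Chr1"]], 101, 400)
  half2 <- substr(ref[["Chr2"]], 101, 400)
  p <- place_contig(c(chim = paste0(half1, half2)), idx)
  expect_identical(p$status, "ambiguous")
})

test_that("placement is deterministic across repeated runs", {
  set.seed(93)
  ref <- c(Chr1 = random_dna(2000), Chr2 = random_dna(2000))
  ctg <- c(a = substr(ref[["Chr1"]], 301, 900),
           b = substr(ref[["Chr2"]], 51, 700))
  idx <- build_anchor_index(ref, 21L)
  p1 <- place_contigs(ctg, idx)
  p2 <- place_contigs(ctg, idx)
  expect_identical(p1, p2)
})

test_that("order_and_export sorts by position and joins with gaps", {
  pl <- data.frame(
    contig_id = c("c2", "c1", "c3"), status = "placed",
    chromosome = "Chr1", orientation = c("+", "+", "-"),
    position = c(500, 10, 900), stringsAsFactors = FALSE)
  lens <- c(c1 = 100L, c2 = 200L, c3 = 150L)
  agp <- order_and_export(pl, lens, gap_len = 100L, reference_tag = "ref9")
  w <- agp[agp$component_type == "W", ]
  expect_identical(w$component_id, c("c1", "c2", "c3"))
  expect_equal(nrow(agp), 5L)  # 3 W + 2 U = 2n-1 parts
  expect_identical(unique(agp$object_id), "Chr1_ref9")
  expect_equal(max(agp$object_end), 100L + 100L + 200L + 100L + 150L)

  # no placed contigs: singleton unplaced objects only
  pl$status <- "unplaced"
  agp <- order_and_export(pl, lens)
  expect_identical(agp$object_id, agp$component_id)
  expect_true(all(agp$part_number == 1L))

  pl2 <- rbind(pl, pl[1, ])
  expect_error(order_and_export(pl2, lens), "duplicate")
})

test_that("agp_to_evidence claims chromosomes for W parts on chromosome objects", {
  agp <- read_agp(tsv_file(c(
    "Chr2_9930\t1\t250\t1\tW\tctg105\t1\t250\t+",
    "Chr2_9930\t251\t350\t2\tU\t100\tscaffold\tyes\talign_genus",
    "Chr2_9930\t351\t430\t3\tW\tctg22\t1\t80\t-",
    "ctg999\t1\t60\t1\tW\tctg999\t1\t60\t+")))
  ev <- agp_to_evidence(agp, "9930")
  expect_equal(nrow(ev), 2L)  # one record per W line on a chromosome object
  expect_identical(ev$contig_id[1], "ctg105")
  expect_identical(ev$chromosome[1], "Chr2")
  expect_identical(unique(ev$source), "scaffold:9930")
})
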