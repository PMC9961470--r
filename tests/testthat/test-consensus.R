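test_that("locus hits convert to evidence via threshold, best hit and map", {
  hits <- data.frame(
    locus_id = c("L1", "L1", "L2", "L3"),
    contig_id = c("ctgA", "ctgB", "ctgC", "ctgD"),
    pct_identity = c(95, 91, 89.9, 99),
    evalue = c(1e-30, 1e-20, 1e-40, 1e-10),
    stringsAsFactors = FALSE)
  map <- c(L1 = "Chr2", L2 = "Chr5", L3 = "Chr1")
  ev <- loci_to_evidence(hits, map, source = "dart", min_identity = 90)
  # L1 keeps only its best hit; L2 is below the identity floor
  expect_equal(nrow(ev), 2L)
  expect_identical(ev$contig_id[ev$locus_id == "L1"], "ctgA")
  expect_identical(ev$chromosome[ev$locus_id == "L1"], "Chr2")
  # loci absent from the map yield nothing
  ev2 <- loci_to_evidence(hits, map[c("L1")], source = "dart")
  expect_identical(ev2$locus_id, "L1")
})

test_that("majority vote assigns, ties abstain, empty evidence is flagged", {
  one <- ev_of("c1", markers = "Chr5")
  r <- consensus_assign(one)
  expect_identical(r$consensus, "Chr5")
  expect_equal(r$support, 1.0)
  expect_equal(nrow(r$conflicts), 0L)

  tie <- rbind(ev_of("c1", markers = "Chr1", dart = "Chr1"),
               ev_of("c1", bac_fish = "Chr2", `scaffold:ref` = "Chr2"))
  expect_identical(consensus_assign(tie)$status, "ambiguous")

  none <- evidence_records(character(0), character(0), character(0))
  none$contig_id <- character(0)
  r <- consensus_table(none, contig_universe = "c9")
  expect_identical(r$status, "no_evidence")
})

test_that("dissenting sources are enumerated as conflicts", {
  ev <- rbind(
    ev_of("ctg2607", markers = "Chr3", `scaffold:9930` = "Chr3_9930",
          `scaffold:Gy14` = "Chr3_Gy14", `blastp:9930` = "Chr3",
          `blastp:gy14` = "Chr3", dart = "Chr3", bac_fish = "Chr1"))
  r <- consensus_assign(ev)
  expect_identical(r$consensus, "Chr3")
  expect_equal(r$support, 6 / 7)
  expect_identical(r$conflicts$source, "bac_fish")
  expect_identical(r$conflicts$chromosome, "Chr1")
})

test_that("consensus is invariant to record order and duplication", {
  set.seed(51)
  base <- rbind(
    ev_of("c1", markers = "Chr1", dart = "Chr1", bac_fish = "Chr4"),
    ev_of("c2", markers = "Chr2"),
    ev_of("c3", dart = "Chr3", bac_fish = "Chr3"))
  r0 <- consensus_table(base)
  for (i in 1:10) {
    shuf <- base[sample(nrow(base)), , drop = FALSE]
    rownames(shuf) <- NULL
    expect_equal(consensus_table(shuf), r0, ignore_attr = TRUE)
  }
  dup <- rbind(base, base[c(1, 1, 4), , drop = FALSE])
  expect_equal(consensus_table(dup), r0, ignore_attr = TRUE)
})

test_that("a source outweighing all others dictates the consensus", {
  ev <- rbind(
    ev_of("c1", markers = "Chr1", dart = "Chr1", `scaffold:ref` = "Chr1"),
    ev_of("c1", bac_fish = "Chr6"))
  expect_identical(consensus_assign(ev)$consensus, "Chr1")
  ev$weight[ev$source == "bac_fish"] <- 3.5  # above the sum of the rest
  r <- consensus_assign(ev)
  expect_identical(r$consensus, "Chr6")
  expect_setequal(r$conflicts$source,
                  c("markers", "dart", "scaffold:ref"))
})

test_that("a source claiming two chromosomes keeps its internal majority", {
  ev <- evidence_records(
    contig_id = "c1",
    chromosome = c("Chr1", "Chr1", "Chr2", "Chr9"),
    source = c("dart", "dart", "dart", "markers"),
    locus_id = c("d1", "d2", "d3", "m1"))
  r <- consensus_assign(ev)
  # dart resolves internally to Chr1, then ties 1-1 against markers' Chr9
  expect_identical(r$status, "ambiguous")

  # an internal tie makes the source abstain entirely
  ev2 <- evidence_records(
    contig_id = "c1",
    chromosome = c("Chr1", "Chr2", "Chr3"),
    source = c("dart", "dart", "markers"),
    locus_id = c("d1", "d2", "m1"))
  r2 <- consensus_assign(ev2)
  expect_identical(r2$consensus, "Chr3")
  expect_equal(r2$support, 1.0)
})

test_that("integrated table lays out one column per source plus consensi", {
  ev <- rbind(
    ev_of("c1", markers = "Chr1", dart = "Chr1", bac_fish = "Chr2"),
    ev_of("c2", dart = "Chr7"))
  tab <- build_integrated_table(c("c1", "c2", "c3"), ev)
  expect_identical(tab$contig_id, c("c1", "c2", "c3"))
  expect_true(all(c("markers", "dart", "bac_fish") %in% names(tab)))
  expect_identical(names(tab)[ncol(tab) - 5L], "bac_fish")  # bac_fish last
  expect_identical(tab$consensus_all, c("Chr1", "Chr7", NA))
  expect_identical(tab$status[3L], "no_evidence")
  expect_identical(tab$markers, c("Chr1", "", ""))
  expect_match(tab$conflict_sources[1L], "bac_fish:Chr2")

  # evidence outside the universe warns but is still reported
  expect_warning(tab2 <- build_integrated_table("c1", ev), "outside")
  expect_true("c2" %in% tab2$contig_id)
})
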