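test_that("FASTA families are read with the header organism rule", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp1|orgA", "MKLV", ">sp2|orgB", "MKIV", ">sp3|orgC", "MRLV"),
             path)
  fam <- read_family(path)
  expect_s3_class(fam, "protein_family")
  expect_true(fam$aligned)
  expect_equal(nrow(fam$records), 3L)
  expect_equal(fam$records$organism, c("orgA", "orgB", "orgC"))
  expect_equal(fam$records$sequence[1], "MKLV")

  # unequal lengths -> unaligned, not an error
  writeLines(c(">a|x", "MKLV", ">b|y", "MK"), path)
  expect_false(read_family(path)$aligned)
})

test_that("malformed, empty and duplicated FASTA inputs raise input errors", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), path)
  expect_error(read_family(path), "no records", class = "mirrortree_input_error")

  writeLines(c("MKLV", ">a", "MKLV"), path)
  expect_error(read_family(path), "line 1", class = "mirrortree_input_error")

  writeLines(c(">a|x", "MKLV", ">a|x", "MKIV"), path)
  expect_error(read_family(path), "duplicate", class = "mirrortree_input_error")

  expect_error(read_family(file.path(tempdir(), "nope.fasta")),
               "not found", class = "mirrortree_input_error")
})

test_that("clustal alignments and organism mapping files are supported", {
  path <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (2.1) multiple sequence alignment", "", "",
               "sp1             MKLVA",
               "sp2             MKIVA",
               "                ** **", ""), path)
  map <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sp1\torganismA", "sp2\torganismB"), map)
  fam <- read_family(path, format = "clustal", organisms = map)
  expect_equal(fam$records$id, c("sp1", "sp2"))
  expect_equal(fam$records$organism, c("organismA", "organismB"))
  expect_equal(fam$records$sequence, c("MKLVA", "MKIVA"))
  expect_true(fam$aligned)

  expect_error(read_family(path, format = "clustal",
                           organisms = c(sp1 = "a")),
               "no organism mapping", class = "mirrortree_input_error")
})

test_that("read -> write -> read round-trips ids, organisms and sequences", {
  withr::local_seed(402)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    fam <- toy_family(replicate(n, random_aa_string(30)),
                      orgs = sprintf("org%02d", seq_len(n)),
                      ids = sprintf("gi%d|ref%d|org%02d", seq_len(n),
                                    seq_len(n), seq_len(n)))
    p1 <- withr::local_tempfile(fileext = ".fasta")
    write_family(fam, p1)
    back <- read_family(p1)
    p2 <- withr::local_tempfile(fileext = ".fasta")
    write_family(back, p2)
    back2 <- read_family(p2)
    expect_identical(back$records, back2$records)
    expect_identical(back$records$sequence, fam$records$sequence)
    expect_identical(back$records$organism, fam$records$organism)
  }
})

test_that("coverage filter is strict and monotone", {
  hits <- tibble::tibble(
    subject_id = c("s1", "s2", "s3"), organism = c("a", "b", "c"),
    bitscore = c(10, 20, 30), coverage = c(0.55, 0.65, 0.80))
  expect_equal(filter_hits(hits, 0.60)$subject_id, c("s2", "s3"))

  # a hit at exactly the threshold is excluded (strict >)
  at <- tibble::tibble(subject_id = "s", organism = "a", bitscore = 1,
                       coverage = 0.60)
  expect_equal(nrow(filter_hits(at, 0.60)), 0L)

  expect_equal(nrow(filter_hits(hits[0, ], 0.6)), 0L)

  # subset of input, non-increasing in the threshold, order preserved
  withr::local_seed(11)
  big <- tibble::tibble(subject_id = sprintf("s%03d", 1:60),
                        organism = sample(letters, 60, replace = TRUE),
                        bitscore = runif(60, 0, 200),
                        coverage = runif(60))
  prev <- nrow(big)
  for (thr in seq(0, 1, by = 0.1)) {
    kept <- filter_hits(big, thr)
    expect_true(all(kept$subject_id %in% big$subject_id))
    expect_identical(kept$subject_id,
                     big$subject_id[big$subject_id %in% kept$subject_id])
    expect_lte(nrow(kept), prev)
    prev <- nrow(kept)
  }
})

test_that("one representative per organism: bitscore, then coverage, then id", {
  hits <- tibble::tibble(
    subject_id = c("s2", "s1", "s3", "s4", "s5"),
    organism = c("a", "a", "b", "b", "c"),
    bitscore = c(100, 90, 50, 50, 10),
    coverage = c(0.7, 0.9, 0.7, 0.9, 0.8))
  sel <- select_one_per_organism(hits)
  expect_equal(sel$subject_id, c("s2", "s4", "s5"))  # a: top bitscore; b: coverage tie-break
  expect_equal(sel$organism, c("a", "b", "c"))

  # id tie-break and idempotence
  tie <- tibble::tibble(subject_id = c("zz", "aa"), organism = c("x", "x"),
                        bitscore = c(5, 5), coverage = c(0.5, 0.5))
  expect_equal(select_one_per_organism(tie)$subject_id, "aa")
  expect_identical(select_one_per_organism(sel), sel)

  # all-distinct organisms: identity
  dis <- tibble::tibble(subject_id = c("s1", "s2"), organism = c("a", "b"),
                        bitscore = c(1, 2), coverage = c(0.1, 0.2))
  expect_identical(select_one_per_organism(dis), dis)
})

test_that("hit tables read from TSV and validate their ranges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\torganism\tbitscore\tcoverage",
               "s1\ta\t100\t0.8", "s2\tb\t50\t0.61"), path)
  hits <- read_hits(path)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$coverage, c(0.8, 0.61))

  writeLines(c("subject_id\torganism\tbitscore\tcoverage",
               "s1\ta\t100\t1.8"), path)
  expect_error(read_hits(path), "coverage", class = "mirrortree_input_error")
})

test_that("family construction enforces its invariants", {
  expect_error(toy_family(character(0)), "no records",
               class = "mirrortree_input_error")
  expect_error(toy_family(c("MK", "ML"), ids = c("a", "a")), "duplicate",
               class = "mirrortree_input_error")
  expect_error(toy_family(c("MK", "ML"), orgs = c("", "b")), "organism",
               class = "mirrortree_input_error")
  expect_error(toy_family("MK1Z"), "alphabet",
               class = "mirrortree_input_error")
})
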