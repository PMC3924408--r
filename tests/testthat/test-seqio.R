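test_that("read_fasta parses headers, wraps and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 demo protein", "ACDE",
               ">p2", "AC", "DE",
               ">p3 x", "MKLVWY"), f)
  d <- read_fasta(f)
  expect_equal(d$id, c("p1", "p2", "p3"))
  expect_equal(d$residues, c("ACDE", "ACDE", "MKLVWY"))
  expect_equal(d$description[1], "demo protein")
  expect_equal(d$description[2], "")

  # write-then-read oracle: ids and residues survive the round trip
  set.seed(11)
  orig <- pga_dataset(c("a1", "a2", "a3"),
                      c(rand_seq(75), rand_seq(120), rand_seq(33)))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(orig, f2, width = 50)
  back <- read_fasta(f2)
  expect_equal(back$id, orig$id)
  expect_equal(back$residues, orig$residues)

  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "cannot read")
  f3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">empty1", ">p2", "ACDE"), f3)
  expect_error(read_fasta(f3), "empty1")
})

test_that("validate_sequence applies strict/drop/map policies", {
  expect_equal(validate_sequence("acde"), "ACDE")
  expect_equal(validate_sequence("AC DE\n"), "ACDE")
  expect_error(validate_sequence("ACXDE", "strict"), "'X' at position 3")
  expect_equal(validate_sequence("ACXDE", "drop"), "ACDE")
  expect_equal(validate_sequence("ABZ", "map"), "ADE")
  expect_equal(validate_sequence("UXJO", "map"), "CLK")
  expect_error(validate_sequence("X", "drop"), "empty after validation")
  expect_error(validate_sequence(""), "non-empty")
})

test_that("redundancy filter removes >threshold pairs and nothing else", {
  set.seed(42)
  # duplicates collapse
  d <- pga_dataset(c("a", "b"), rep(strrep("ACDE", 10), 2))
  expect_equal(nrow(reduce_redundancy(d)), 1)

  # disjoint homopolymers are both kept
  d2 <- pga_dataset(c("a", "w"), c(strrep("A", 50), strrep("W", 50)))
  expect_equal(nrow(reduce_redundancy(d2, 0.9)), 2)

  # 10 sequences, 3 of which are >=95% copies of one template -> 8 kept,
  # cross-checked against an all-pairs identity matrix from the R oracle
  template <- rand_seq(100)
  copies <- vapply(1:3, function(i) mutate_seq(template, 0.03), "")
  others <- vapply(1:7, function(i) rand_seq(100), "")
  d3 <- pga_dataset(sprintf("s%02d", 1:10), c(copies, others))
  kept <- reduce_redundancy(d3, 0.9)
  expect_equal(nrow(kept), 8)
  idm <- outer(seq_len(nrow(kept)), seq_len(nrow(kept)), Vectorize(function(i, j)
    oracle_identity(kept$residues[i], kept$residues[j])))
  expect_true(all(idm[upper.tri(idm)] <= 0.9))

  # idempotence and exact-duplicate behaviour at threshold 1.0
  expect_equal(reduce_redundancy(kept, 0.9)$id, kept$id)
  d4 <- pga_dataset(c("x", "y", "z"),
                    c(others[1], others[1], mutate_seq(others[1], 0.02)))
  at1 <- reduce_redundancy(d4, 1.0)
  expect_equal(nrow(at1), 2)  # only the byte-identical pair collapses

  empty <- pga_dataset(character(), character(), validate = NULL)
  expect_equal(nrow(reduce_redundancy(empty)), 0)
})

test_that("C++ identity matches the R oracle", {
  set.seed(5)
  for (i in 1:25) {
    a <- rand_seq(sample(5:60, 1))
    b <- rand_seq(sample(5:60, 1))
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b))
  }
  expect_equal(pairwise_identity("ACD", "XXACDXX"), 1)
})

test_that("sequence statistics: masses, counts, percentages", {
  g <- compute_stats("G")
  expect_equal(g$molecular_weight, 75.0672, tolerance = 1e-8)

  a4 <- compute_stats("AAAA")
  expect_equal(unname(a4$composition_percent["A"]), 100)
  expect_equal(sum(a4$composition_percent != 0), 1)

  uni <- compute_stats(paste(aa_alphabet(), collapse = ""))
  expect_true(all(uni$composition_percent == 5))

  set.seed(3)
  for (i in 1:20) {
    s <- rand_seq(sample(2:200, 1))
    st <- compute_stats(s)
    expect_equal(sum(st$composition_percent), 100, tolerance = 1e-6)
    expect_equal(sum(st$residue_counts), nchar(s))
    # appending any residue strictly increases the molecular weight
    heavier <- compute_stats(paste0(s, sample(aa_alphabet(), 1)))
    expect_gt(heavier$molecular_weight, st$molecular_weight)
  }
})

test_that("label manifests round-trip and attach to datasets", {
  d <- pga_dataset(c("u1", "u2", "u3"), c("ACDE", "MKLV", "WYWY"),
                   label = c("SK", "NEG", "tPA"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_labels(d, f)
  lab <- read_labels(f)
  expect_equal(unname(lab[d$id]), d$label)

  bare <- pga_dataset(d$id, d$residues)
  expect_equal(attach_labels(bare, lab)$label, d$label)
  expect_error(attach_labels(bare, lab[1:2]), "no label for")
  writeLines("u9\tBOGUS", f)
  expect_error(read_labels(f), "unknown labels")
})

test_that("dataset constructor enforces invariants", {
  expect_error(pga_dataset(c("a", "a"), c("AC", "AC")), "duplicate")
  expect_error(pga_dataset("a", "AC", label = "POS"), "unknown labels")
  expect_error(pga_dataset(c("", "b"), c("AC", "AC")), "non-empty")
})
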