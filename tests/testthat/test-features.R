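test_that("amino-acid composition counts residue fractions", {
  expect_equal(unname(amino_acid_composition("AAAA")["A"]), 1)
  expect_true(all(amino_acid_composition(paste(AA, collapse = "")) == 0.05))
  v <- amino_acid_composition("AAC")
  expect_equal(unname(v[c("A", "C")]), c(2 / 3, 1 / 3))
  expect_equal(sum(v), 1)
  expect_error(amino_acid_composition(""), "empty")
})

test_that("dipeptide composition tallies overlapping pairs", {
  v <- dipeptide_composition("AA")
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v != 0), 1)
  v2 <- dipeptide_composition("ACA")
  expect_equal(unname(v2[c("AC", "CA")]), c(0.5, 0.5))
  expect_error(dipeptide_composition("A"), "at least 2")

  set.seed(21)
  s <- rand_seq(50)
  expect_equal(dipeptide_composition(s), oracle_dc(s),
               ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("encoders satisfy dimension, sum and symmetry properties", {
  set.seed(8)
  for (i in 1:50) {
    s <- rand_seq(sample(2:150, 1))
    ac <- amino_acid_composition(s)
    dc <- dipeptide_composition(s)
    hy <- hybrid_composition(s)
    expect_length(ac, 20)
    expect_length(dc, 400)
    expect_length(hy, 420)
    expect_equal(sum(ac), 1, tolerance = 1e-9)
    expect_equal(sum(dc), 1, tolerance = 1e-9)
    expect_equal(unname(hy[1:20]), unname(ac), ignore_attr = TRUE)
    expect_equal(unname(hy[21:420]), unname(dc), ignore_attr = TRUE)

    # AC is permutation invariant
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(amino_acid_composition(perm), ac)
  }
})

test_that("reversal maps DC entry (a,b) to (b,a) exactly", {
  set.seed(9)
  for (i in 1:20) {
    s <- rand_seq(sample(2:80, 1))
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    m <- matrix(dipeptide_composition(s), 20, 20, byrow = TRUE,
                dimnames = list(AA, AA))
    mr <- matrix(dipeptide_composition(rev_s), 20, 20, byrow = TRUE,
                 dimnames = list(AA, AA))
    expect_equal(mr, t(m))
  }
})

test_that("PSSM files round-trip through write/parse", {
  set.seed(4)
  s <- rand_seq(40)
  prof <- mock_pssm(s, seed = 2)
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(prof, f)
  back <- parse_pssm(f)
  expect_equal(unname(back$scores), unname(prof$scores))
  expect_equal(colnames(back$scores), colnames(prof$scores))
  expect_equal(back$consensus, s)

  # truncated row is rejected with its line number
  lines <- readLines(f)
  lines[6] <- substr(lines[6], 1, 30)
  writeLines(lines, f)
  expect_error(parse_pssm(f), "line 6")
})

test_that("PSSM composition: sigmoid-normalised, length-averaged", {
  zero4 <- structure(list(scores = matrix(0L, 4, 20,
                                          dimnames = list(NULL, AA)),
                          consensus = "AAAA"), class = "pga_pssm")
  v <- pssm_composition(zero4, "AAAA")
  expect_length(v, 400)
  expect_true(all(abs(v[paste0("A", AA)] - 0.5) < 1e-12))
  expect_true(all(v[!grepl("^A", names(v))] == 0))

  zero2 <- structure(list(scores = matrix(0L, 2, 20,
                                          dimnames = list(NULL, AA)),
                          consensus = "AC"), class = "pga_pssm")
  v2 <- pssm_composition(zero2, "AC")
  expect_true(all(abs(v2[paste0("A", AA)] - 0.25) < 1e-12))
  expect_true(all(abs(v2[paste0("C", AA)] - 0.25) < 1e-12))

  # random profile vs brute-force double loop
  set.seed(13)
  s <- rand_seq(30)
  sc <- matrix(sample(-9:9, 30 * 20, replace = TRUE), 30, 20,
               dimnames = list(NULL, AA))
  prof <- structure(list(scores = sc, consensus = s), class = "pga_pssm")
  expect_equal(unname(pssm_composition(prof, s)),
               unname(oracle_pssm_comp(sc, s)), tolerance = 1e-14,
               ignore_attr = TRUE)

  # saturated scores: sigmoid -> 1, entries tend to AC row values
  sat <- structure(list(scores = matrix(20L, 30, 20,
                                        dimnames = list(NULL, AA)),
                        consensus = s), class = "pga_pssm")
  vs <- pssm_composition(sat, s)
  ac <- amino_acid_composition(s)
  for (a in AA)
    expect_equal(unname(vs[paste0(a, "A")]), unname(ac[a]), tolerance = 1e-6)

  expect_error(pssm_composition(zero2, "ACD"), "2 rows")
  expect_true(all(vs >= 0 & vs <= 1))
})

test_that("mock PSSM provider is seeded and residue-biased", {
  p1 <- mock_pssm("AAA", seed = 1)
  p2 <- mock_pssm("AAA", seed = 1)
  expect_identical(p1, p2)
  expect_false(identical(p1$scores, mock_pssm("AAA", seed = 2)$scores))
  expect_true(all(p1$scores >= -5 & p1$scores <= 9))

  # +4 own-residue bias: over many positions the own column dominates
  set.seed(6)
  s <- strrep("ACD", 80)
  prof <- mock_pssm(s, seed = 3)
  ch <- strsplit(s, "")[[1]]
  own <- mean(prof$scores[cbind(seq_along(ch),
                                match(ch, colnames(prof$scores)))])
  other <- mean(prof$scores) # includes own columns, still ~0.2 vs 4
  expect_gt(own, other + 2)
})

test_that("pssm_provider modes: precomputed lookup and configuration errors", {
  dir <- withr::local_tempdir()
  s <- rand_seq(15)
  write_pssm(mock_pssm(s, seed = 9), file.path(dir, "q1.pssm"))
  prof <- pssm_provider("q1", s, "precomputed", dir = dir)
  expect_equal(prof$consensus, s)
  expect_error(pssm_provider("absent", s, "precomputed", dir = dir),
               "no precomputed profile")
  expect_error(pssm_provider("q1", s, "external", exe = "no-such-psiblast"),
               "not found")
})

test_that("feature_matrix assembles encodings with stable ordering", {
  d <- pga_dataset(c("x", "y"), c("ACDEACDE", "MKLVMKLV"))
  for (m in c("AC", "DC", "HYBRID", "PSSM")) {
    fm <- feature_matrix(d, m, seed = 5)
    expect_equal(rownames(fm), d$id)
    expect_equal(ncol(fm), c(AC = 20, DC = 400, HYBRID = 420, PSSM = 400)[[m]])
    expect_identical(fm, feature_matrix(d, m, seed = 5))
  }
  profs <- list(x = mock_pssm("ACDEACDE", 1), y = mock_pssm("MKLVMKLV", 2))
  fm <- feature_matrix(d, "PSSM", pssm = profs)
  expect_equal(nrow(fm), 2)
  expect_error(feature_matrix(d, "PSSM", pssm = list(x = profs$x)),
               "no PSSM profile")
})

test_that("feature matrices export to TSV and SVM-light", {
  d <- pga_dataset(c("x", "y"), c("AACC", "MMKK"))
  fm <- feature_matrix(d, "AC")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(fm, f1)
  back <- utils::read.table(f1, header = TRUE, sep = "\t")
  expect_equal(back$id, d$id)
  expect_equal(unname(as.matrix(back[, -1])), unname(fm), tolerance = 1e-12,
               ignore_attr = TRUE)

  f2 <- withr::local_tempfile(fileext = ".svml")
  write_svmlight(fm, f2, labels = c(1, -1))
  lines <- readLines(f2)
  expect_match(lines[1], "^\\+1 1:0\\.5 2:0\\.5$")
  expect_match(lines[2], "^-1 ")
})
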