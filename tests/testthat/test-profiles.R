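# Proteome reading, probe-set frequency patterns, pattern correlation and
# column standardization.

test_that("FASTA proteomes are read with uppercasing and gene-count defaults", {
  path <- write_fasta_fixture(list(p1 = "MKLV", p2 = "aacd", p3 = "QLHH"))
  p <- read_proteome(path, organism_id = "org1")
  expect_s3_class(p, "proteome")
  expect_length(p$proteins, 3)
  expect_equal(p$gene_count, 3L)
  expect_equal(unname(p$proteins[["p2"]]), "AACD")
  p10 <- read_proteome(path, organism_id = "org1", gene_count = 10)
  expect_equal(p10$gene_count, 10L)
  expect_error(read_proteome(write_fasta_fixture(list())), "empty FASTA")
  dup <- write_fasta_fixture(list(a = "MK", a = "ML"))
  expect_error(read_proteome(dup, strict = TRUE), "duplicate")
})

test_that("probe frequency is total occurrences over gene count", {
  p <- proteome("o", c(a = "QQAAQQ", b = "AAQA"), gene_count = 4)
  probe <- parse_pattern("A-A")
  # occurrences: 1 in a, 1 in b = 2 total; 2 / 4 genes
  expect_equal(probe_frequency(probe, p), 0.5)
  expect_equal(probe_frequency(parse_pattern("W-W"), p), 0)
  one <- proteome("o", c(a = "AAAA"), gene_count = 1)
  expect_equal(probe_frequency(probe, one), 3)  # overlapping starts
})

test_that("frequency patterns align with probe order and matrix rows with proteomes", {
  probes <- list(parse_pattern("A-A", id = "pr1"),
                 parse_pattern("W-W", id = "pr2"))
  p <- proteome("o", c(a = "CAAC"), gene_count = 2)
  fp <- frequency_pattern(probes, p)
  expect_equal(unname(fp), c(0.5, 0))
  expect_equal(names(fp), c("pr1", "pr2"))
  expect_equal(unname(frequency_pattern(rev(probes), p)), c(0, 0.5))
  m <- build_matrix(probes, list(p, proteome("o2", c(a = "AAA"),
                                             gene_count = 3)))
  expect_equal(rownames(m), c("o", "o2"))
  expect_equal(unname(m["o2", ]), c(2 / 3, 0))
})

test_that("frequencies are invariant to protein order and record splits", {
  probes <- list(parse_pattern("A-C-D", id = "p1"))
  seqs <- c(x = "MACDWW", y = "ACDACD")
  p1 <- proteome("o", seqs, gene_count = 2)
  p2 <- proteome("o", rev(seqs), gene_count = 2)
  expect_equal(frequency_pattern(probes, p1), frequency_pattern(probes, p2))
  # splitting a record at a non-match boundary preserves the total
  split <- proteome("o", c(x1 = "MACD", x2 = "WW", y = "ACDACD"),
                    gene_count = 2)
  expect_equal(frequency_pattern(probes, split), frequency_pattern(probes, p1))
})

test_that("planted Poisson rates are recovered by the measured frequencies", {
  probes <- random_probes(6, seed = 31)
  lambda <- c(2, 0.5, 0, 0, 0, 0)
  prof <- group_profile("cal", lambda, 1, 200)
  p <- synthetic_proteome(prof, 1, probes, seed = 77, protein_length = 200)
  f <- frequency_pattern(probes, p)
  for (i in 1:2) {
    se <- sqrt(lambda[i] / 200)  # Poisson total / genes
    expect_lt(abs(f[i] - lambda[i]), 3 * se + 1e-9)
  }
  expect_lt(max(f[3:6]), 0.05)  # only chance background matches
})

test_that("pattern correlation is the Pearson coefficient", {
  a <- c(1, 0, 2, 4)
  b <- c(2, 1, 1, 3)
  # textbook formula computed independently of stats::cor
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pattern_cc(a, b), num / den)
  expect_equal(pattern_cc(a, a), 1)
  expect_equal(pattern_cc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(pattern_cc(c(1, 1, 1), a[1:3]), "zero-variance")
})

test_that("pattern correlation is invariant to positive affine rescaling", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(10)
    b <- rnorm(10)
    alpha <- runif(1, 0.1, 5)
    beta <- rnorm(1)
    expect_equal(pattern_cc(alpha * a + beta, b), pattern_cc(a, b))
  }
})

test_that("standardization yields population z-scores and zeros constant columns", {
  m <- cbind(p1 = c(1, 3), p2 = c(2, 2))
  rownames(m) <- c("a", "b")
  s <- standardize_matrix(m)
  expect_equal(unname(s[, "p1"]), c(-1, 1))  # mu = 2, population sigma = 1
  expect_equal(unname(s[, "p2"]), c(0, 0))
  set.seed(9)
  m2 <- matrix(rpois(60, 4), nrow = 6,
               dimnames = list(paste0("o", 1:6), paste0("p", 1:10)))
  s2 <- standardize_matrix(m2)
  nonconst <- apply(m2, 2, function(col) length(unique(col)) > 1)
  expect_equal(unname(colMeans(s2)), rep(0, 10))
  pop_sd <- sqrt(colMeans(sweep(s2, 2, colMeans(s2))^2))
  expect_equal(unname(pop_sd[nonconst]),
               rep(1, sum(nonconst)))
  expect_error(standardize_matrix(m[1, , drop = FALSE]), "at least 2")
})

test_that("frequency matrices round-trip through TSV", {
  m <- matrix(c(0.5, 0, 1 / 3, 2), nrow = 2,
              dimnames = list(c("org a", "org_b"), c("PS1", "PS2")))
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  expect_equal(read_matrix_tsv(path), m)
})

test_that("identical proteomes produce identical matrix rows", {
  probes <- random_probes(4, seed = 3)
  prof <- group_profile("g", c(0.3, 0.1, 0, 0.2), 1, 30)
  p <- synthetic_proteome(prof, 1, probes, seed = 12)
  copies <- lapply(1:3, function(i) {
    q <- p
    q$organism_id <- paste0("copy", i)
    q
  })
  m <- build_matrix(probes, copies)
  expect_equal(m[2, ], m[1, ], ignore_attr = TRUE)
  expect_equal(m[3, ], m[1, ], ignore_attr = TRUE)
})
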