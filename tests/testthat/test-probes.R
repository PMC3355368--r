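# Pattern descriptor parsing, serialization, and occurrence counting.

test_that("the chloramphenicol acetyltransferase descriptor parses as expected", {
  p <- parse_pattern("Q-[LIV]-H-H-[SA]-x(2)-D-G-[FY]-H", id = "PS00100")
  expect_length(p$elements, 10)
  kinds <- vapply(p$elements, `[[`, character(1), "kind")
  expect_equal(kinds[c(2, 5, 9)], rep("one_of", 3))
  expect_setequal(p$elements[[2]]$residues, c("L", "I", "V"))
  expect_setequal(p$elements[[5]]$residues, c("S", "A"))
  expect_setequal(p$elements[[9]]$residues, c("F", "Y"))
  expect_equal(p$elements[[6]]$kind, "any")
  expect_equal(p$elements[[6]]$min_repeat, 2L)
  expect_equal(p$elements[[6]]$max_repeat, 2L)
  expect_false(p$anchored_start)
  expect_false(p$anchored_end)
})

test_that("anchors, variable repeats and exclusion sets parse", {
  p <- parse_pattern("<M-x(2,4)-{P}-D.")
  expect_true(p$anchored_start)
  expect_false(p$anchored_end)
  expect_length(p$elements, 4)
  expect_equal(p$elements[[2]]$kind, "any")
  expect_equal(p$elements[[2]]$min_repeat, 2L)
  expect_equal(p$elements[[2]]$max_repeat, 4L)
  expect_equal(p$elements[[3]]$kind, "none_of")
  expect_equal(p$elements[[3]]$residues, "P")
  # behavior agrees with the brute-force enumerator on random short strings
  set.seed(41)
  for (i in 1:200) {
    s <- paste(sample(c("M", "A", "P", "D"), sample(0:8, 1), replace = TRUE),
               collapse = "")
    expect_identical(count_occurrences(p, s), bf_count(p, s), label = s)
  }
})

test_that("malformed descriptors raise parse errors naming the token", {
  expect_error(parse_pattern("Q-["), "element 2.*\\[")
  expect_error(parse_pattern("A-[]-C"), "empty residue set")
  expect_error(parse_pattern("A-x(0)-C"), "repeat count of 0")
  expect_error(parse_pattern("A-x(3,2)-C"), "n > m")
  expect_error(parse_pattern("A-J-C"), "unrecognized element")
  expect_error(parse_pattern("A-[BZ]-C"), "non-standard residue")
  expect_error(parse_pattern(""), "empty descriptor")
})

test_that("serialized probes re-parse to identical element lists", {
  set.seed(7)
  texts <- replicate(40, rand_descriptor())
  for (txt in texts) {
    p <- parse_pattern(txt)
    q <- parse_pattern(format(p))
    expect_identical(q$elements, p$elements, label = txt)
    expect_identical(q$anchored_start, p$anchored_start)
    expect_identical(q$anchored_end, p$anchored_end)
  }
})

test_that("occurrences are distinct start positions, overlaps included", {
  ps <- parse_pattern("Q-[LIV]-H-H-[SA]-x(2)-D-G-[FY]-H")
  expect_identical(count_occurrences(ps, "QLHHSGGDGFH"), 1L)
  expect_identical(count_occurrences(ps, "QVHHAGGDGYH"), 1L)
  expect_identical(count_occurrences(parse_pattern("A-A"), "AAAA"), 3L)
  expect_identical(count_occurrences(ps, ""), 0L)
  # a variable-repeat pattern matching one start several ways counts once
  p <- parse_pattern("A-x(1,3)-D")
  expect_identical(count_occurrences(p, "AGGD"), 1L)
  expect_identical(bf_count(p, "AGGD"), 1L)
})

test_that("non-standard sequence letters match only where documented", {
  expect_identical(count_occurrences(parse_pattern("A-x-C"), "ABC"), 1L)
  expect_identical(count_occurrences(parse_pattern("A-x-C"), "ABC",
                                     wildcard_nonstandard = FALSE), 0L)
  expect_identical(count_occurrences(parse_pattern("A-[CD]-A"), "ABA"), 0L)
  expect_identical(count_occurrences(parse_pattern("A-{P}-A"), "ABA"), 0L)
  expect_identical(count_occurrences(parse_pattern("A-A"), "AXA*AUA"), 0L)
})

test_that("anchored probes match only at the sequence boundaries", {
  ps <- parse_pattern("<A-C")
  expect_identical(count_occurrences(ps, "ACAC"), 1L)
  expect_identical(count_occurrences(ps, "GACAC"), 0L)
  pe <- parse_pattern("A-C>")
  expect_identical(count_occurrences(pe, "ACAC"), 1L)
  expect_identical(count_occurrences(pe, "ACACG"), 0L)
})

test_that("appending residues never decreases the occurrence count", {
  set.seed(13)
  for (i in 1:50) {
    p <- parse_pattern(rand_descriptor())
    if (p$anchored_end) next  # anchoring to the end is not monotone
    s <- rand_sequence(20)
    longer <- paste0(s, rand_sequence(8))
    expect_gte(count_occurrences(p, longer), count_occurrences(p, s))
  }
})

test_that("PROSITE flat files parse, concatenate PA lines and honor skip flags", {
  path <- prosite_fixture_file()
  probes <- suppressWarnings(read_probe_file(path, format = "prosite"))
  expect_length(probes, 3)  # the matrix-profile record is skipped
  expect_warning(read_probe_file(path, format = "prosite"), "no PA line")
  expect_equal(vapply(probes, `[[`, character(1), "id"),
               c("PS00100", "PS90001", "PS90003"))
  # multi-line PA concatenation round-trips against the one-line descriptor
  ref <- parse_pattern("Q-[LIV]-H-H-[SA]-x(2)-D-G-[FY]-H")
  expect_identical(probes[[1]]$elements, ref$elements)
  expect_true(probes[[2]]$skip_flagged)
  dropped <- suppressWarnings(
    read_probe_file(path, format = "prosite", drop_frequent = TRUE))
  expect_length(dropped, 2)
  expect_false(any(vapply(dropped, `[[`, logical(1), "skip_flagged")))
})

test_that("plain TSV probe lists are equivalent to parse_pattern", {
  path <- tempfile(fileext = ".tsv")
  writeLines("PS00100\tQ-[LIV]-H-H-[SA]-x(2)-D-G-[FY]-H", path)
  probes <- read_probe_file(path, format = "tsv")
  expect_length(probes, 1)
  expect_identical(probes[[1]]$elements,
                   parse_pattern("Q-[LIV]-H-H-[SA]-x(2)-D-G-[FY]-H")$elements)
  expect_equal(probes[[1]]$id, "PS00100")
})

test_that("unparseable records are skipped with a warning, or raised in strict mode", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("GOOD\tA-C-D", "BAD\tA-[("), path)
  expect_warning(probes <- read_probe_file(path, format = "tsv"),
                 "skipping probe BAD")
  expect_length(probes, 1)
  expect_error(read_probe_file(path, format = "tsv", strict = TRUE))
  expect_error(read_probe_file(tempfile(), format = "tsv"), "cannot read")
})
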