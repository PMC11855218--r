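test_that("continuity test reports seamlessness and first-stop offset", {
  fx <- make_shilan_fixture(seed = 5)
  ct <- continuity_test(fx$insertion)
  expect_true(ct$seamless)
  expect_true(is.na(ct$first_stop_offset_nt))
  expect_equal(nchar(ct$host_frame_translation), 202L)

  # stop in the very first codon
  ct2 <- continuity_test(paste0("TAATAA", strrep("GCA", 10)))
  expect_false(ct2$seamless)
  expect_equal(ct2$first_stop_offset_nt, 3L)
  expect_equal(ct2$first_stop_offset_nt %% 3L, 0L)

  expect_error(continuity_test("ACGTA"), "multiple of 3")
})

test_that("relative_frame follows the 1-based frame convention", {
  expect_equal(relative_frame(18), 3L)
  expect_equal(relative_frame(1), 1L)
  expect_equal(relative_frame(2), 2L)
  expect_equal(relative_frame(c(1, 4, 7)), c(1L, 1L, 1L))
  expect_error(relative_frame(0), "positive")
})

test_that("hidden-ORF scan recovers the canonical planted layout", {
  fx <- make_shilan_fixture(seed = 5)
  orfs <- scan_hidden_orfs(fx$insertion, min_len_aa = 50)
  top <- orfs[[1]]
  expect_equal(top$start_nt, 18L)
  expect_equal(top$frame_index, 3L)
  expect_equal(top$start_codon, "GTG")
  expect_equal(top$product_len_aa, 195L)
  expect_equal(top$stop_nt, 605L)
  expect_true(top$is_primary)
  # lengths are sorted descending
  lens <- vapply(orfs, function(o) o$product_len_aa, 1L)
  expect_true(all(diff(lens) <= 0))
})

test_that("scan returns empty results gracefully", {
  expect_length(scan_hidden_orfs(strrep("AC", 30)), 0L)   # no start codons
  expect_length(scan_hidden_orfs("AC"), 0L)               # sub-codon input
})

test_that("scan matches the exhaustive brute-force oracle", {
  set.seed(71)
  for (rep in 1:150) {
    s <- rand_nuc(sample(9:60, 1))
    got <- orf_key_table(scan_hidden_orfs(s, min_len_aa = 1))
    want <- oracle_orf_scan(s, min_len_aa = 1)
    expect_equal(got, want, info = s)
  }
  for (rep in 1:20) {
    s <- rand_nuc(300)
    got <- orf_key_table(scan_hidden_orfs(s, min_len_aa = 10))
    want <- oracle_orf_scan(s, min_len_aa = 10)
    expect_equal(got, want, info = s)
  }
})

test_that("open-ended mode matches the oracle too", {
  set.seed(72)
  for (rep in 1:50) {
    s <- rand_nuc(sample(9:90, 1))
    got <- orf_key_table(scan_hidden_orfs(s, min_len_aa = 1,
                                          require_stop = FALSE))
    want <- oracle_orf_scan(s, min_len_aa = 1, require_stop = FALSE)
    expect_equal(got, want, info = s)
  }
})

test_that("reported products retranslate from their coordinates", {
  set.seed(73)
  for (rep in 1:20) {
    s <- rand_nuc(sample(60:240, 1))
    orfs <- scan_hidden_orfs(s, min_len_aa = 1)
    rc <- reverse_complement(s)
    for (o in orfs) {
      src <- if (o$strand == "+") s else rc
      span <- substr(src, o$start_nt,
                     if (o$open_ended) o$start_nt + 3 * o$product_len_aa - 1
                     else o$stop_nt - 3)
      expect_equal(as.character(translate_seq(span, 0)),
                   as.character(o$product))
    }
  }
})

test_that("scan is invariant under a partial (<3 nt) appended tail", {
  set.seed(74)
  for (rep in 1:20) {
    s <- rand_nuc(sample(30:120, 1))
    base <- orf_key_table(scan_hidden_orfs(s, min_len_aa = 1,
                                           strands = "forward"))
    for (tail in c("A", "GC")) {
      ext <- orf_key_table(scan_hidden_orfs(paste0(s, tail),
                                            min_len_aa = 1,
                                            strands = "forward"))
      expect_equal(ext, base)
    }
  }
})

test_that("continuity agrees with a frame-1 stop scan", {
  set.seed(75)
  for (rep in 1:30) {
    s <- rand_nuc(3 * sample(5:60, 1))
    ct <- continuity_test(s)
    codons <- cryptorf:::codon_split(s)
    k <- which(codons %in% c("TAA", "TAG", "TGA"))[1]
    expect_equal(ct$seamless, is.na(k))
    if (!is.na(k)) expect_equal(ct$first_stop_offset_nt, 3L * k)
  }
})

test_that("min_len_aa filters and start-codon set is honoured", {
  s <- paste0("ATG", strrep("GCA", 8), "TAA")   # 9-aa product, ATG start
  expect_length(scan_hidden_orfs(s, min_len_aa = 10), 0L)
  expect_length(scan_hidden_orfs(s, min_len_aa = 9,
                                 strands = "forward"), 1L)
  only_gtg <- genetic_code(start_codons = "GTG")
  expect_length(scan_hidden_orfs(s, code = only_gtg, min_len_aa = 1,
                                 strands = "forward"), 0L)
})
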