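test_that("intein +1 and terminal residue tests follow the rules", {
  ins_asn <- prot_seq(paste0("C", strrep("A", 50), "HN"))
  sig <- intein_signature(ins_asn, "TQAAAAAAAAA")
  expect_true(sig$plus1$pass)
  expect_equal(sig$plus1$residue, "T")
  expect_false(sig$plus1$proline_flag)
  expect_equal(sig$terminal$status, "asn")

  sig_p <- intein_signature(ins_asn, "PQAAAAAAAAA")
  expect_false(sig_p$plus1$pass)
  expect_true(sig_p$plus1$proline_flag)

  for (r in c("S", "C")) {
    expect_true(intein_signature(ins_asn, paste0(r, "AAA"))$plus1$pass)
  }

  ins_ser <- prot_seq(paste0(strrep("A", 50), "S"))
  expect_equal(intein_signature(ins_ser, "TAA")$terminal$status,
               "ser_variant")
  ins_other <- prot_seq(paste0(strrep("A", 50), "K"))
  expect_equal(intein_signature(ins_other, "TAA")$terminal$status,
               "fail")

  skipped <- intein_signature(ins_asn, "")
  expect_true(skipped$plus1$skipped)
  expect_true(is.na(skipped$plus1$pass))
  expect_error(intein_signature("", "TAA"), "empty insertion")
})

test_that("splicing-block motif scan reports named hits", {
  ins <- prot_seq(paste0("C", strrep("A", 10), "TKLH",
                         strrep("A", 10), "LHN", strrep("A", 10), "HN"))
  sig <- intein_signature(ins, "TAA")
  expect_setequal(unique(sig$motifs_found$name),
                  c("block_A", "block_B", "block_F", "block_G"))
  none <- intein_signature(prot_seq(strrep("AK", 30)), "AAA")
  expect_equal(nrow(none$motifs_found), 0L)
})

test_that("intron end-motif tests match the stated signatures", {
  expect_false(intron_signature(paste0(strrep("GCA", 20), "TAAC"))$g_3prime)
  expect_true(intron_signature(paste0("GTGCG", strrep("A", 20)))$gtgcg_5prime)
  expect_true(intron_signature(paste0(strrep("A", 20), "G"))$g_3prime)
  expect_false(intron_signature(strrep("A", 20))$gtgcg_5prime)
  expect_error(intron_signature("ACGT"), "shorter")
})

test_that("flank similarity is an exact positional identity", {
  expect_equal(flank_similarity("KLMNPQRSTVW", "KLMNPQRSTVW", 11), 100)
  expect_equal(flank_similarity("AAAAAAAAAAA", "KKKKKKKKKKK", 11), 0)
  set.seed(55)
  aas <- c("A", "C", "D", "E", "F")
  for (rep in 1:30) {
    a <- paste(sample(aas, 11, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 11, replace = TRUE), collapse = "")
    want <- 100 * sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]) / 11
    expect_equal(as.numeric(flank_similarity(a, b, 11)), want)
    expect_equal(as.numeric(flank_similarity(a, b, 11)),
                 as.numeric(flank_similarity(b, a, 11)))  # symmetric
  }
  expect_equal(as.numeric(flank_similarity("abc", "ABC", 3)), 100)
  clipped <- flank_similarity("AAAA", "AAAAAAAAAAA", 11)
  expect_true(attr(clipped, "clipped"))
  expect_error(flank_similarity("", "A", 5), "expected|empty")
})

test_that("group means aggregate per group", {
  comp <- data.frame(
    id = c("i1", "i2", "u1"),
    group = c("invaded", "invaded", "uninvaded"),
    head = c("AAAAAAAAAA", "AAAAAAAAAA", "AAAAAAAAAA"),
    c_flank = c("AAAAAA____", "AAAAAAAA__", "AAAAAAAAAA"),
    stringsAsFactors = FALSE)
  comp$c_flank <- c("AAAAAACCCC", "AAAAAAAACC", "AAAAAAAAAA")
  m <- group_flank_similarity(comp, window = 10)
  expect_equal(unname(m["invaded"]), 70)   # mean of 60 and 80
  expect_equal(unname(m["uninvaded"]), 100)
  single <- group_flank_similarity(comp[3, ], window = 10)
  expect_equal(unname(single), 100)
})

test_that("HNH scan equals brute-force triple enumeration", {
  # planted triad at known spacing
  p <- paste0(strrep("A", 20), "H", strrep("A", 29), "N",
              strrep("A", 29), "H", strrep("A", 20))
  hits <- hnh_motif_scan(p)
  expect_equal(nrow(hits$all_hits), 1L)
  expect_equal(unlist(hits$hits[1, ]), c(h1 = 21L, n = 51L, h2 = 81L))

  expect_equal(nrow(hnh_motif_scan(strrep("ANAN", 30))$all_hits), 0L)

  set.seed(66)
  for (rep in 1:10) {
    p <- paste(sample(c("H", "N", "A"), 120, replace = TRUE,
                      prob = c(.2, .2, .6)), collapse = "")
    got <- hnh_motif_scan(p, spacing = c(5, 20, 5, 20))$all_hits
    ch <- strsplit(p, "")[[1]]
    want <- expand.grid(h1 = which(ch == "H"), n = which(ch == "N"),
                        h2 = which(ch == "H"))
    want <- want[want$n - want$h1 >= 5 & want$n - want$h1 <= 20 &
                   want$h2 - want$n >= 5 & want$h2 - want$n <= 20, ]
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      key <- function(d) sort(paste(d$h1, d$n, d$h2))
      expect_equal(key(got), key(want))
    }
  }
})

test_that("zinc-finger scan finds CXX(X)C motifs and pairs", {
  p <- paste0("CAAC", strrep("A", 10), "CAAAC", strrep("A", 60))
  res <- znf_motif_scan(p, pair_window = 10)
  expect_equal(nrow(res$motifs), 2L)
  expect_equal(res$motifs$type, c("CXXC", "CXXXC"))
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$gap, 10L)
  # window just too small
  expect_equal(nrow(znf_motif_scan(p, pair_window = 9)$pairs), 0L)
  expect_equal(nrow(znf_motif_scan(strrep("AK", 20))$motifs), 0L)

  # brute force on random C-rich strings
  set.seed(77)
  for (rep in 1:10) {
    p <- paste(sample(c("C", "A"), 60, replace = TRUE,
                      prob = c(.3, .7)), collapse = "")
    got <- znf_motif_scan(p, pair_window = 15)$motifs
    ch <- strsplit(p, "")[[1]]
    want <- list()
    for (i in seq_len(max(0, length(ch) - 3))) {
      if (ch[i] == "C" && ch[i + 3] == "C") {
        want[[length(want) + 1]] <- c(i, i + 3)
      }
    }
    for (i in seq_len(max(0, length(ch) - 4))) {
      if (ch[i] == "C" && ch[i + 4] == "C") {
        want[[length(want) + 1]] <- c(i, i + 4)
      }
    }
    expect_equal(nrow(got), length(want))
  }
})

test_that("motif scans on the canonical product recover planted truth", {
  fx <- make_shilan_fixture(seed = 9)
  top <- scan_hidden_orfs(fx$insertion)[[1]]
  hnh <- hnh_motif_scan(top$product)
  expect_equal(nrow(hnh$all_hits), 1L)
  expect_equal(unname(unlist(hnh$hits[1, ])),
               unname(fx$truth$hnh))
  znf <- znf_motif_scan(top$product)
  expect_equal(nrow(znf$motifs), 4L)
  expect_equal(nrow(znf$pairs), 2L)
  expect_equal(znf$motifs$start, fx$truth$znf$start)
  expect_equal(znf$motifs$end, fx$truth$znf$end)
})

test_that("pattern files load and validate", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\talphabet\tpattern",
               "my_block\taa\t^[CST]"), tmp)
  pat <- load_motif_patterns(tmp)
  expect_equal(pat$name, "my_block")
  writeLines(c("name\talphabet\tpattern",
               "bad\taa\t^[CST"), tmp)
  expect_error(load_motif_patterns(tmp), "compile")
  expect_equal(load_motif_patterns(NULL), default_intein_patterns())
})
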