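test_that("generation is seed-deterministic", {
  expect_identical(as.character(make_shilan_fixture(3)$insertion),
                   as.character(make_shilan_fixture(3)$insertion))
  expect_identical(as.character(make_littlee_fixture(4)$insertion),
                   as.character(make_littlee_fixture(4)$insertion))
  f1 <- make_host_family(seed = 5, n_invaded = 1, n_uninvaded = 2,
                         gene_len_aa = 120, element_class = "inert",
                         insertion_len_nt = 150)
  f2 <- make_host_family(seed = 5, n_invaded = 1, n_uninvaded = 2,
                         gene_len_aa = 120, element_class = "inert",
                         insertion_len_nt = 150)
  expect_identical(f1$homologs$cds, f2$homologs$cds)
  expect_identical(f1$homologs$alignment, f2$homologs$alignment)
  # different seeds, different bytes
  f3 <- make_host_family(seed = 6, n_invaded = 1, n_uninvaded = 2,
                         gene_len_aa = 120, element_class = "inert",
                         insertion_len_nt = 150)
  expect_false(identical(f1$homologs$cds, f3$homologs$cds))
})

test_that("zero divergence gives identical uninvaded members", {
  fam <- make_host_family(n_invaded = 1, n_uninvaded = 3,
                          gene_len_aa = 120, divergence = 0, seed = 7,
                          element_class = "inert",
                          insertion_len_nt = 150)
  un <- fam$homologs$cds[fam$homologs$uninvaded_ids]
  expect_equal(length(unique(un)), 1L)
})

test_that("the canonical fixture satisfies every printed constraint", {
  fx <- make_shilan_fixture(seed = 8)
  s <- as.character(fx$insertion)
  expect_equal(nchar(s), 606L)
  expect_equal(substr(s, 18, 20), "GTG")
  expect_equal(substr(s, 603, 606), "TAAC")
  ct <- continuity_test(fx$insertion)
  expect_true(ct$seamless)
  expect_equal(nchar(ct$host_frame_translation), 202L)
  expect_false(grepl("\\*", as.character(ct$host_frame_translation)))
  # in-frame translation ends on asparagine (codon AAC from ...TA AC)
  tr <- as.character(ct$host_frame_translation)
  expect_equal(substr(tr, 202, 202), "N")
  sig <- intron_signature(fx$insertion)
  expect_false(sig$g_3prime)
  expect_false(sig$gtgcg_5prime)
  # frame-3 translation contains the product; frame +1 has no stop
  fr <- six_frames(fx$insertion)
  expect_false(grepl("\\*", as.character(fr[["+1"]])))
  expect_true(grepl(fx$truth$product, as.character(fr[["+3"]]),
                    fixed = TRUE))
})

test_that("planted ORFs are recovered exactly for random valid specs", {
  set.seed(31)
  for (rep in 1:15) {
    P <- sample(110:200, 1)
    a <- sample(c(2L, 3L, 18L, 20L), 1)           # alternate frames
    L <- 3L * (((a - 1L + 3L * (P + 1L)) %/% 3L) + sample(2:6, 1))
    b <- a + 3L * (P + 1L) - 1L
    sc <- sample(c("ATG", "GTG", "TTG"), 1)
    spec <- plant_spec("hidden_orf", insertion_len_nt = L,
                       orf_start_nt = a, orf_stop_nt = b,
                       start_codon = sc, plant_hnh = TRUE,
                       plant_znf_pairs = 2L)
    out <- plant_hidden_orf(spec, seed = sample.int(1e6, 1))
    orfs <- scan_hidden_orfs(out$insertion, min_len_aa = 50)
    hit <- Filter(function(o) o$strand == "+" && o$start_nt == a, orfs)
    expect_length(hit, 1L)
    expect_equal(hit[[1]]$product_len_aa, P)
    expect_equal(hit[[1]]$stop_nt, b)
    expect_equal(hit[[1]]$start_codon, sc)
    expect_true(hit[[1]]$is_primary)
    expect_equal(hit[[1]]$frame_index, relative_frame(a))
    expect_equal(as.character(hit[[1]]$product), out$truth$product)
    expect_true(continuity_test(out$insertion)$seamless)
  }
})

test_that("plant_spec rejects inconsistent layouts", {
  expect_error(plant_spec("hidden_orf", insertion_len_nt = 605),
               "divisible by 3")
  expect_error(plant_spec("hidden_orf", orf_start_nt = 18,
                          orf_stop_nt = 604), "multiple of 3")
  expect_error(plant_spec("hidden_orf", insertion_len_nt = 300,
                          orf_start_nt = 18, orf_stop_nt = 299),
               "too short")
})

test_that("intron-like fixtures are interrupted exactly as specified", {
  fx <- make_littlee_fixture(seed = 9)
  ct <- continuity_test(fx$insertion)
  expect_false(ct$seamless)
  expect_equal(ct$first_stop_offset_nt, 30L)
  expect_true(intron_signature(fx$insertion)$g_3prime)

  fx45 <- make_littlee_fixture(seed = 9, first_stop_offset_nt = 45)
  expect_equal(continuity_test(fx45$insertion)$first_stop_offset_nt, 45L)
})

test_that("family truth records index valid coordinates", {
  fam <- make_host_family(n_invaded = 2, n_uninvaded = 2,
                          gene_len_aa = 150, divergence = 0.05,
                          seed = 10, element_class = "hidden_orf",
                          insertion_len_nt = 606)
  for (tr in fam$truth) {
    cds <- fam$homologs$cds[[tr$host_id]]
    expect_true(tr$nt_end <= nchar(cds))
    ins <- substr(cds, tr$nt_start, tr$nt_end)
    expect_equal(nchar(ins), tr$insertion_len_nt)
    # the planted ORF is where the truth says, in host-CDS terms
    expect_equal(substr(ins, tr$orf_start_nt, tr$orf_start_nt + 2),
                 tr$start_codon)
    expect_true(continuity_test(ins)$seamless)
  }
})

test_that("flank mimicry parameter is recovered from inert families", {
  p <- 0.7
  sims <- c()
  for (seed in 1:12) {
    fam <- make_host_family(n_invaded = 2, n_uninvaded = 2,
                            gene_len_aa = 120, divergence = 0,
                            seed = 100 + seed, element_class = "inert",
                            insertion_len_nt = 150, flank_mimicry = p)
    loci <- find_insertion_blocks(fam$homologs)
    for (loc in loci) {
      tab <- family_flank_table(fam$homologs, loc)
      own <- tab[tab$id == loc$host_id, ]
      sims <- c(sims, as.numeric(flank_similarity(own$head, own$c_flank)))
    }
  }
  n_pos <- length(sims) * 11
  se <- 100 * sqrt(p * (1 - p) / n_pos)
  expect_lt(abs(mean(sims) - 100 * p), 3 * se + 1e-9)
})
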