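# helper: hand-built family with arbitrary planted blocks
# (aa positions given as insert-after sites on the ancestral protein)
build_manual_family <- function(anc_len, blocks, seed = 99) {
  set.seed(seed)
  bg <- cryptorf:::BG_AA
  anc <- sample(bg, anc_len, replace = TRUE)
  ins_aa <- lapply(blocks, function(b) sample(bg, b$len, replace = TRUE))
  inv_aa <- anc
  aln_inv <- character(0)
  aln_un <- character(0)
  pos <- 1L
  inv_full <- c()
  for (k in seq_along(blocks)) {
    site <- blocks[[k]]$after
    prev <- if (k == 1) 1L else blocks[[k - 1]]$after + 1L
    inv_full <- c(inv_full, anc[prev:site], ins_aa[[k]])
    aln_un <- c(aln_un, anc[prev:site], rep("-", blocks[[k]]$len))
  }
  last <- blocks[[length(blocks)]]$after
  inv_full <- c(inv_full, anc[(last + 1L):anc_len])
  aln_un <- c(aln_un, anc[(last + 1L):anc_len])
  cds <- c(
    invaded = cryptorf:::rev_translate(inv_full),
    uninvaded_a = cryptorf:::rev_translate(anc),
    uninvaded_b = cryptorf:::rev_translate(anc))
  alignment <- c(
    invaded = paste(inv_full, collapse = ""),
    uninvaded_a = paste(aln_un, collapse = ""),
    uninvaded_b = paste(aln_un, collapse = ""))
  homolog_set(cds, invaded_ids = "invaded",
              uninvaded_ids = c("uninvaded_a", "uninvaded_b"),
              alignment = alignment)
}

test_that("a single planted 202-aa insertion yields exactly one locus", {
  fam <- make_host_family(n_invaded = 1, n_uninvaded = 3,
                          gene_len_aa = 200, divergence = 0,
                          seed = 303, element_class = "hidden_orf")
  loci <- find_insertion_blocks(fam$homologs)
  expect_length(loci, 1L)
  loc <- loci[[1]]
  tr <- fam$truth[[loc$host_id]]
  expect_equal(loc$aa_end - loc$aa_start + 1L, 202L)
  expect_equal(loc$aa_start, tr$aa_start)
  expect_equal(loc$aa_end, tr$aa_end)
  expect_equal(loc$nt_start, tr$nt_start)
  expect_equal(loc$nt_end, tr$nt_end)
  # coordinate invariants: in-phase, between codons
  expect_equal((loc$nt_start - 1L) %% 3L, 0L)
  expect_equal(loc$nt_end - loc$nt_start + 1L,
               3L * (loc$aa_end - loc$aa_start + 1L))
  expect_false(loc$phase_warning)
})

test_that("identical invaded and uninvaded members give no loci", {
  prot <- strrep("ADEK", 40)
  cds <- cryptorf:::rev_translate(strsplit(prot, "")[[1]])
  hs <- homolog_set(c(a = cds, b = cds), invaded_ids = "a",
                    uninvaded_ids = "b",
                    alignment = c(a = prot, b = prot))
  expect_length(find_insertion_blocks(hs), 0L)
})

test_that("two non-adjacent planted blocks are both recovered exactly", {
  hs <- build_manual_family(
    anc_len = 150,
    blocks = list(list(after = 40, len = 35), list(after = 90, len = 44)))
  loci <- find_insertion_blocks(hs, min_block_aa = 30)
  expect_length(loci, 2L)
  expect_equal(loci[[1]]$aa_start, 41L)
  expect_equal(loci[[1]]$aa_end, 75L)
  expect_equal(loci[[2]]$aa_start, 126L)  # 90 + 35 + 1 in invaded coords
  expect_equal(loci[[2]]$aa_end, 169L)
  expect_equal(unname(vapply(loci, function(l) l$nt_start, 1L)),
               c(121L, 376L))
})

test_that("detection is invariant to member order", {
  fam <- make_host_family(n_invaded = 2, n_uninvaded = 3,
                          gene_len_aa = 150, divergence = 0.05,
                          seed = 11, element_class = "inert",
                          insertion_len_nt = 240)
  hs <- fam$homologs
  perm <- rev(seq_along(hs$cds))
  hs2 <- homolog_set(hs$cds[perm], invaded_ids = hs$invaded_ids,
                     uninvaded_ids = hs$uninvaded_ids,
                     alignment = hs$alignment[perm])
  key <- function(loci) {
    lapply(loci, function(l) list(l$host_id, l$aa_start, l$aa_end))
  }
  expect_equal(key(find_insertion_blocks(hs)),
               key(find_insertion_blocks(hs2)))
})

test_that("blocks separated by fewer than min_gap_aa columns merge", {
  # 30-aa block, 1 ancestral residue, 30-aa block -> one merged locus
  bg <- cryptorf:::BG_AA
  set.seed(17)
  anc <- sample(bg, 120, replace = TRUE)
  insA <- sample(bg, 30, replace = TRUE)
  insB <- sample(bg, 30, replace = TRUE)
  inv <- c(anc[1:60], insA, anc[61], insB, anc[62:120])
  aln_un <- c(anc[1:60], rep("-", 30), anc[61], rep("-", 30),
              anc[62:120])
  hs <- homolog_set(
    c(inv = cryptorf:::rev_translate(inv),
      un = cryptorf:::rev_translate(anc)),
    invaded_ids = "inv", uninvaded_ids = "un",
    alignment = c(inv = paste(inv, collapse = ""),
                  un = paste(aln_un, collapse = "")))
  merged <- find_insertion_blocks(hs, min_block_aa = 30, min_gap_aa = 3)
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$aa_end - merged[[1]]$aa_start + 1L, 61L)
  split <- find_insertion_blocks(hs, min_block_aa = 30, min_gap_aa = 0)
  expect_length(split, 2L)
})

test_that("flank extraction matches direct indexing and clips", {
  fam <- make_host_family(n_invaded = 1, n_uninvaded = 2,
                          gene_len_aa = 150, divergence = 0,
                          seed = 21, element_class = "inert",
                          insertion_len_nt = 150)
  loc <- find_insertion_blocks(fam$homologs)[[1]]
  fl <- extract_flanks(loc, window_aa = 11)
  prot <- loc$host_protein
  expect_equal(nchar(fl$c_flank_aa), 11L)
  expect_equal(fl$c_flank_aa,
               substr(prot, loc$aa_end + 1, loc$aa_end + 11))
  expect_equal(fl$n_flank_aa,
               substr(prot, loc$aa_start - 11, loc$aa_start - 1))
  expect_equal(nchar(fl$c_flank_nt), 33L)
  # +1 residue via window 1 equals direct indexing; the family plants
  # the Thr conversion track there
  fl1 <- extract_flanks(loc, window_aa = 1)
  expect_equal(fl1$c_flank_aa, substr(prot, loc$aa_end + 1,
                                      loc$aa_end + 1))
  expect_equal(fl1$c_flank_aa, "T")
  # clipping at the gene end
  fl_big <- extract_flanks(loc, window_aa = 500)
  expect_true("c_flank_clipped" %in% fl_big$flags)
  expect_lt(nchar(fl_big$c_flank_aa), 500L)
})

test_that("pairwise-alignment fallback finds the planted block", {
  fam <- make_host_family(n_invaded = 1, n_uninvaded = 2,
                          gene_len_aa = 150, divergence = 0,
                          seed = 31, element_class = "inert",
                          insertion_len_nt = 300)
  hs <- fam$homologs
  hs_noaln <- homolog_set(hs$cds, invaded_ids = hs$invaded_ids,
                          uninvaded_ids = hs$uninvaded_ids,
                          alignment = NULL)
  loci <- find_insertion_blocks(hs_noaln)
  expect_length(loci, 1L)
  tr <- fam$truth[[loci[[1]]$host_id]]
  expect_equal(loci[[1]]$aa_end - loci[[1]]$aa_start + 1L, 100L)
  # gap placement can shift by a residue or two where flank and
  # insertion happen to agree; the block itself must match closely
  expect_lt(abs(loci[[1]]$aa_start - tr$aa_start), 3L)
})

test_that("homolog_set validates its inputs", {
  cds <- c(a = "ATGGCTGCT", b = "ATGGCTGCT")
  expect_error(homolog_set(cds, invaded_ids = "a", uninvaded_ids = "a"),
               "overlap")
  expect_error(homolog_set(cds, invaded_ids = "a", uninvaded_ids = "z"),
               "not in cds")
  expect_error(homolog_set(c(a = "ATGGC", b = "ATGGC"),
                           invaded_ids = "a", uninvaded_ids = "b"),
               "multiple of 3")
  expect_error(homolog_set(cds, invaded_ids = "a", uninvaded_ids = "b",
                           alignment = c(a = "MAA", b = "MA")),
               "unequal")
  expect_error(homolog_set(cds, invaded_ids = "a", uninvaded_ids = "b",
                           alignment = c(a = "MAA", b = "MAK")),
               "does not match")
  hs <- homolog_set(cds["a"], invaded_ids = "a",
                    uninvaded_ids = character(0))
  expect_error(find_insertion_blocks(hs), "at least one")
})
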