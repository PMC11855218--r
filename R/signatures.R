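# Sequence-signature tests used to classify an insertion element:
# intein residue/motif tests, self-splicing-intron end motifs, the
# insertion-head vs C-flank similarity statistic, and HNH/zinc-finger
# motif scans on alternate-frame products.

#' Default intein splicing-motif patterns
#'
#' Conservative regular-expression sketches of the conserved intein
#' splicing blocks (A, B, F, G).  The literature describes these blocks
#' by position-specific preferences rather than strict consensus, so
#' these defaults are deliberately loose and fully user-overridable via
#' a pattern file (see [load_motif_patterns]); a hit contributes to an
#' intein call only in conjunction with the +1 and terminal residue
#' tests.
#'
#' @return Data frame with columns `name`, `alphabet`, `pattern`.
#' @export
default_intein_patterns <- function() {
  data.frame(
    name = c("block_A", "block_B", "block_F", "block_G"),
    alphabet = "aa",
    pattern = c(
      "^[CST]",        # N-terminal nucleophile of the intein
      "T..H",          # TxxH box
      "[LIVM]H[NQ]",   # hydrophobic-His-Asn/Gln near the C-terminal region
      "[HN][NS]$"      # penultimate His/Asn + terminal Asn/Ser
    ),
    stringsAsFactors = FALSE
  )
}

#' Load motif patterns from a TSV file
#'
#' The file has a header line `name<TAB>alphabet<TAB>pattern`; lines
#' beginning with `#` are ignored.  `alphabet` is `"aa"` or `"nt"`.
#'
#' @param path Pattern file; `NULL` returns the shipped defaults.
#' @return Data frame with columns `name`, `alphabet`, `pattern`.
#' @export
load_motif_patterns <- function(path = NULL) {
  if (is.null(path)) return(default_intein_patterns())
  pat <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("name", "alphabet", "pattern")
  if (!all(need %in% names(pat))) {
    stop("pattern file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- vapply(pat$pattern,
                function(p) {
                  inherits(suppressWarnings(try(regexpr(p, "A"),
                                                silent = TRUE)),
                           "try-error")
                },
                logical(1))
  if (any(bad)) {
    stop("pattern(s) do not compile: ",
         paste(pat$name[bad], collapse = ", "), call. = FALSE)
  }
  pat
}

#' Intein signature tests on an insertion and its C-terminal flank
#'
#' Three independent pieces of evidence used by intein classification:
#' \itemize{
#'   \item the +1 test: intein splicing requires Thr, Ser or Cys as the
#'     first host residue C-terminal of the insertion site; a proline
#'     there is splicing-inhibiting and flagged explicitly;
#'   \item the terminal-residue test: a canonical intein ends on Asn
#'     (`"asn"`); a terminal Ser is reported as the non-canonical
#'     `"ser_variant"`; anything else is `"fail"`;
#'   \item a scan of the insertion's in-frame translation for the
#'     conserved splicing blocks (A/B/F/G by default).
#' }
#'
#' @param insertion_aa [prot_seq]: in-frame (host-frame) translation of
#'   the insertion.
#' @param c_flank_aa [prot_seq] or `""`: host residues immediately
#'   C-terminal of the insertion site.
#' @param patterns Data frame of splicing-block patterns
#'   (see [load_motif_patterns]).
#' @return List with `plus1` (list: `residue`, `pass`, `proline_flag`,
#'   `skipped`), `terminal` (list: `residue`, `status`), and
#'   `motifs_found` (data frame: `name`, `start`, `end`).
#' @export
intein_signature <- function(insertion_aa, c_flank_aa,
                             patterns = default_intein_patterns()) {
  ins <- as_prot_string(insertion_aa)
  if (!nzchar(ins)) stop("empty insertion translation", call. = FALSE)
  flank <- if (is.null(c_flank_aa)) "" else as_prot_string(c_flank_aa)

  if (nzchar(flank)) {
    r1 <- substr(flank, 1L, 1L)
    plus1 <- list(residue = r1, pass = r1 %in% c("T", "S", "C"),
                  proline_flag = identical(r1, "P"), skipped = FALSE)
  } else {
    plus1 <- list(residue = NA_character_, pass = NA,
                  proline_flag = FALSE, skipped = TRUE)
  }

  last <- substr(ins, nchar(ins), nchar(ins))
  terminal <- list(
    residue = last,
    status = if (last == "N") "asn"
             else if (last == "S") "ser_variant"
             else "fail")

  pat <- patterns[patterns$alphabet == "aa", , drop = FALSE]
  hits <- do.call(rbind, lapply(seq_len(nrow(pat)), function(i) {
    m <- gregexpr(pat$pattern[i], ins, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(name = pat$name[i], start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) {
    hits <- data.frame(name = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  }
  list(plus1 = plus1, terminal = terminal, motifs_found = hits)
}

#' Self-splicing-intron end-motif tests
#'
#' Group I introns commonly end with G at the 3' end; group II introns
#' commonly begin with GTGCG at the 5' end.
#'
#' @param insertion_nt [nuc_seq], length >= 5.
#' @return List with logicals `g_3prime` and `gtgcg_5prime`.
#' @export
intron_signature <- function(insertion_nt) {
  s <- as_nuc_string(insertion_nt)
  if (nchar(s) < 5L) stop("insertion shorter than 5 nt", call. = FALSE)
  list(g_3prime = substr(s, nchar(s), nchar(s)) == "G",
       gtgcg_5prime = substr(s, 1L, 5L) == "GTGCG")
}

#' Ungapped percent identity over a fixed window
#'
#' Position-by-position identity of the first `window` characters of
#' the two sequences, as a percentage.  No realignment is done: the
#' statistic deliberately compares fixed windows, as when the head of
#' an insertion is compared against the flank it may mimic.  If either
#' sequence is shorter than `window` the comparison is clipped to the
#' shorter length and the result carries attribute `clipped = TRUE`.
#' Defined identically for amino-acid and nucleotide inputs;
#' case-insensitive.
#'
#' @param a,b Sequences ([nuc_seq], [prot_seq] or character scalar).
#' @param window Number of leading positions to compare (default 11,
#'   the conventional flank bracket width).
#' @return Numeric percent identity in `[0, 100]`.
#' @export
flank_similarity <- function(a, b, window = 11L) {
  sa <- toupper(if (is.character(a)) a else as.character(a))
  sb <- toupper(if (is.character(b)) b else as.character(b))
  w <- min(window, nchar(sa), nchar(sb))
  if (w < 1L) stop("empty comparison window", call. = FALSE)
  ca <- strsplit(substr(sa, 1L, w), "")[[1]]
  cb <- strsplit(substr(sb, 1L, w), "")[[1]]
  out <- 100 * mean(ca == cb)
  if (w < window) attr(out, "clipped") <- TRUE
  out
}

#' Per-group mean flank similarity across a homolog family
#'
#' For each family member, compares the insertion head (the first
#' `window` residues/bases of the insertion read in the host frame)
#' against that member's own C-terminal flank at the insertion site,
#' then averages within the invaded and uninvaded groups.  This is the
#' group I intron "internal guide sequence mimicry" statistic: a 5'
#' insertion head resembling the 3' exon flank.
#'
#' Aggregation is the arithmetic mean over all (insertion head, member
#' C-flank) comparisons in the group; this interpretation (rather than
#' all-vs-all pairwise averaging) is a documented choice.
#'
#' @param comparisons Data frame with columns `id`, `group`
#'   (`"invaded"`/`"uninvaded"`), `head` and `c_flank` (character
#'   sequences in a common alphabet).  [family_flank_table] builds this
#'   from a `homolog_set` and an `insertion_locus`.
#' @param window Comparison window (positions).
#' @return Named numeric vector of group means (percent identity).
#' @export
group_flank_similarity <- function(comparisons, window = 11L) {
  stopifnot(all(c("id", "group", "head", "c_flank") %in%
                  names(comparisons)))
  groups <- unique(comparisons$group)
  if (!length(groups)) stop("no comparisons supplied", call. = FALSE)
  vapply(stats::setNames(groups, groups), function(g) {
    rows <- comparisons[comparisons$group == g, , drop = FALSE]
    if (!nrow(rows)) stop("empty group: ", g, call. = FALSE)
    mean(mapply(function(h, f) as.numeric(flank_similarity(h, f, window)),
                rows$head, rows$c_flank))
  }, numeric(1))
}

#' Scan a protein for His-Asn-His (HNH) residue triads
#'
#' The HNH endonuclease catalytic core is characterised by a
#' histidine-asparagine-histidine residue arrangement.  This scan
#' enumerates all position triples `(i, j, k)` with `H`, `N`, `H`
#' respectively and inter-residue spacings inside the given brackets.
#' Spacing defaults (10-60, 10-60 residues) bracket the compact HNH
#' cores of solved phage endonuclease structures and are configurable.
#'
#' @param product A [prot_seq] (alternate-frame product, typically).
#' @param spacing Integer vector `(min1, max1, min2, max2)`: allowed
#'   `j - i` and `k - j` ranges.
#' @return List with `all_hits` (data frame `h1, n, h2` of every
#'   admissible triple) and `hits` (greedy non-overlapping selection,
#'   left to right).
#' @export
hnh_motif_scan <- function(product, spacing = c(10L, 60L, 10L, 60L)) {
  s <- as_prot_string(product)
  stopifnot(length(spacing) == 4L, all(spacing >= 0L))
  ch <- strsplit(s, "")[[1]]
  hpos <- which(ch == "H")
  npos <- which(ch == "N")
  all_hits <- data.frame(h1 = integer(0), n = integer(0), h2 = integer(0))
  for (i in hpos) {
    js <- npos[npos - i >= spacing[1] & npos - i <= spacing[2]]
    for (j in js) {
      ks <- hpos[hpos - j >= spacing[3] & hpos - j <= spacing[4]]
      if (length(ks)) {
        all_hits <- rbind(all_hits,
                          data.frame(h1 = i, n = j, h2 = ks))
      }
    }
  }
  # greedy non-overlapping selection ordered by (h1, n, h2)
  sel <- all_hits[order(all_hits$h1, all_hits$n, all_hits$h2), ,
                  drop = FALSE]
  picked <- sel[0, ]
  last_end <- 0L
  while (nrow(sel)) {
    cand <- sel[sel$h1 > last_end, , drop = FALSE]
    if (!nrow(cand)) break
    picked <- rbind(picked, cand[1L, ])
    last_end <- cand$h2[1L]
    sel <- cand[-1L, , drop = FALSE]
  }
  rownames(all_hits) <- rownames(picked) <- NULL
  list(all_hits = all_hits, hits = picked)
}

#' Scan a protein for zinc-finger CXX(X)C motif pairs
#'
#' Finds every `CxxC` and `CxxxC` occurrence (overlaps allowed) and
#' reports pairs of two non-overlapping motifs separated by at most
#' `pair_window` residues as zinc-finger candidates; single motifs are
#' also returned.
#'
#' @param product A [prot_seq].
#' @param pair_window Maximum number of residues between the end of
#'   one motif and the start of the next for the two to pair
#'   (default 40; zinc-finger domains flanking HNH cores are compact).
#' @return List with `motifs` (data frame `start, end, type`) and
#'   `pairs` (data frame `start1, end1, start2, end2, gap`).
#' @export
znf_motif_scan <- function(product, pair_window = 40L) {
  s <- as_prot_string(product)
  find <- function(pat, type, len) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(start = as.integer(m), end = as.integer(m) + len - 1L,
               type = type, stringsAsFactors = FALSE)
  }
  motifs <- rbind(find("(?=C.{2}C)", "CXXC", 4L),
                  find("(?=C.{3}C)", "CXXXC", 5L))
  if (is.null(motifs)) {
    motifs <- data.frame(start = integer(0), end = integer(0),
                         type = character(0), stringsAsFactors = FALSE)
  }
  motifs <- motifs[order(motifs$start, motifs$end), , drop = FALSE]
  rownames(motifs) <- NULL
  pairs <- data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      gap = integer(0))
  if (nrow(motifs) >= 2L) {
    for (i in seq_len(nrow(motifs) - 1L)) {
      for (j in seq.int(i + 1L, nrow(motifs))) {
        gap <- motifs$start[j] - motifs$end[i] - 1L
        if (gap >= 0L && gap <= pair_window) {
          pairs <- rbind(pairs, data.frame(
            start1 = motifs$start[i], end1 = motifs$end[i],
            start2 = motifs$start[j], end2 = motifs$end[j], gap = gap))
        }
      }
    }
  }
  list(motifs = motifs, pairs = pairs)
}

#' Collect the full signature evidence for one insertion element
#'
#' Convenience wrapper running every signature test on one element and
#' returning a single `signature_evidence` object consumed by
#' [classify_element].
#'
#' @param insertion_nt [nuc_seq] of the insertion (host phase).
#' @param c_flank_aa C-terminal flank translation ([prot_seq] or `""`).
#' @param orfs Hidden-ORF list from [scan_hidden_orfs] (motif scans run
#'   on the top primary product); may be empty.
#' @param code A [genetic_code].
#' @param window Flank-similarity window (residues).
#' @param c_flank_nt Optional [nuc_seq]/string of the nucleotide
#'   C-flank; when given, a nucleotide flank identity over `3 * window`
#'   bases is reported alongside the amino-acid one.
#' @param patterns Intein splicing-block patterns.
#' @param hnh_spacing,znf_pair_window Motif-scan parameters.
#' @return Object of class `signature_evidence`.
#' @export
signature_evidence <- function(insertion_nt, c_flank_aa, orfs = list(),
                               code = genetic_code(), window = 11L,
                               c_flank_nt = NULL,
                               patterns = default_intein_patterns(),
                               hnh_spacing = c(10L, 60L, 10L, 60L),
                               znf_pair_window = 40L) {
  ins_aa <- translate_seq(insertion_nt, 0L, code, stop_policy = "mark")
  intein <- intein_signature(ins_aa, c_flank_aa, patterns)
  intron <- intron_signature(insertion_nt)
  flank_aa <- if (nzchar(as_prot_string(c_flank_aa))) {
    as.numeric(flank_similarity(ins_aa, c_flank_aa, window))
  } else NA_real_
  flank_nt <- if (!is.null(c_flank_nt) &&
                  nzchar(as_nuc_string(c_flank_nt))) {
    as.numeric(flank_similarity(insertion_nt, c_flank_nt, 3L * window))
  } else NA_real_
  hnh <- list(all_hits = NULL, hits = NULL)
  znf <- list(motifs = NULL, pairs = NULL)
  top <- NULL
  if (length(orfs)) {
    top <- orfs[[1L]]
    hnh <- hnh_motif_scan(top$product, hnh_spacing)
    znf <- znf_motif_scan(top$product, znf_pair_window)
  }
  structure(list(
    intein_plus1 = intein$plus1,
    intein_terminal = intein$terminal,
    intein_motifs_found = intein$motifs_found,
    intron_g_3prime = intron$g_3prime,
    intron_gtgcg_5prime = intron$gtgcg_5prime,
    flank_identity_aa = flank_aa,
    flank_identity_nt = flank_nt,
    hnh_hits = hnh$hits,
    hnh_all_hits = hnh$all_hits,
    znf_hits = znf$pairs,
    znf_motifs = znf$motifs
  ), class = "signature_evidence")
}
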