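# Locating insertion blocks from invaded/uninvaded homolog comparisons.
#
# An insertion element shows up in a protein alignment as a run of
# columns where every uninvaded homolog has a gap and an invaded
# homolog has residues.  Blocks are mapped back to the invaded
# member's ungapped protein and CDS coordinates (1-based inclusive
# throughout) and carry their flanking windows.

#' Assemble a set of homologous coding sequences
#'
#' @param cds Named character vector (or list of [nuc_seq]) of coding
#'   sequences; each length must be a multiple of 3 and translate
#'   without internal stops.
#' @param invaded_ids,uninvaded_ids Disjoint id sets; both must be
#'   subsets of `names(cds)`.
#' @param alignment Optional named character vector: an aligned protein
#'   FASTA of the same genes (equal-length gapped strings whose
#'   degapped form equals each member's translation).  When absent,
#'   [find_insertion_blocks] falls back to pairwise alignment.
#' @param code A [genetic_code].
#' @return Object of class `homolog_set`.
#' @export
homolog_set <- function(cds, invaded_ids, uninvaded_ids,
                        alignment = NULL, code = genetic_code()) {
  if (is.list(cds)) {
    nm <- vapply(cds, function(s) s$id, character(1))
    cds <- vapply(cds, as.character, character(1))
    names(cds) <- nm
  }
  ids <- names(cds)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("cds must be uniquely named", call. = FALSE)
  }
  if (length(intersect(invaded_ids, uninvaded_ids))) {
    stop("invaded and uninvaded id sets overlap", call. = FALSE)
  }
  missing <- setdiff(c(invaded_ids, uninvaded_ids), ids)
  if (length(missing)) {
    stop("group ids not in cds: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_len <- ids[nchar(cds) %% 3L != 0L]
  if (length(bad_len)) {
    stop("CDS length not a multiple of 3: ",
         paste(bad_len, collapse = ", "), call. = FALSE)
  }
  proteins <- vapply(ids, function(id) {
    as.character(translate_seq(cds[[id]], 0L, code, stop_policy = "mark"))
  }, character(1))
  # internal stops are NOT rejected: a gene invaded by an intron-like
  # element legitimately translates with internal stops, and detecting
  # exactly that is part of the pipeline's job
  if (!is.null(alignment)) {
    if (length(unique(nchar(alignment))) != 1L) {
      stop("aligned strings have unequal lengths", call. = FALSE)
    }
    for (id in intersect(names(alignment), ids)) {
      degapped <- gsub("-", "", alignment[[id]])
      if (degapped != sub("\\*$", "", proteins[[id]])) {
        stop("alignment record '", id,
             "' does not match its translated CDS", call. = FALSE)
      }
    }
    missing_aln <- setdiff(c(invaded_ids, uninvaded_ids), names(alignment))
    if (length(missing_aln)) {
      stop("members missing from alignment: ",
           paste(missing_aln, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(cds = cds, proteins = proteins, alignment = alignment,
                 invaded_ids = invaded_ids, uninvaded_ids = uninvaded_ids,
                 code = code),
            class = "homolog_set")
}

#' @export
print.homolog_set <- function(x, ...) {
  cat(sprintf("<homolog_set: %d members (%d invaded, %d uninvaded), %s>\n",
              length(x$cds), length(x$invaded_ids), length(x$uninvaded_ids),
              if (is.null(x$alignment)) "no alignment (pairwise mode)"
              else "aligned"))
  invisible(x)
}

# runs of TRUE in a logical vector, merging runs separated by fewer
# than `min_gap` FALSE positions; returns matrix [start, end]
true_runs <- function(flag, min_gap = 0L) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) > 1L && min_gap > 0L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in seq.int(2L, nrow(runs))) {
      if (runs[i, 1L] - merged[nrow(merged), 2L] - 1L < min_gap) {
        merged[nrow(merged), 2L] <- runs[i, 2L]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  runs
}

# build one insertion_locus for an invaded member given the gapped
# member string and the [start,end] column run of the block
locus_from_run <- function(hs, host_id, member_aln, run, window_aa) {
  chars <- strsplit(member_aln, "")[[1]]
  nongap <- chars != "-"
  cum <- cumsum(nongap)
  n_res <- sum(nongap[run[1]:run[2]])
  if (n_res == 0L) return(NULL)
  aa_start <- if (run[1] == 1L) 1L else cum[run[1] - 1L] + 1L
  aa_end <- cum[run[2]]
  nt <- aa_to_nt(aa_start, aa_end)
  cds <- hs$cds[[host_id]]
  prot <- sub("\\*$", "", hs$proteins[[host_id]])
  phase_warning <- (nt[2] - nt[1] + 1L) %% 3L != 0L ||
    (nt[1] - 1L) %% 3L != 0L
  insertion <- nuc_seq(substr(cds, nt[1], nt[2]),
                       id = paste0(host_id, "_ins_", aa_start))
  loc <- structure(list(
    host_id = host_id,
    aa_start = aa_start, aa_end = aa_end,
    nt_start = unname(nt[1]), nt_end = unname(nt[2]),
    insertion_nt = insertion,
    insertion_aa = translate_seq(insertion, 0L, hs$code, "mark"),
    host_cds = cds, host_protein = prot,
    aln_cols = c(run[1], run[2]),
    phase_warning = phase_warning,
    flags = character(0)
  ), class = "insertion_locus")
  fl <- extract_flanks(loc, window_aa = window_aa)
  loc$n_flank_aa <- fl$n_flank_aa
  loc$c_flank_aa <- fl$c_flank_aa
  loc$n_flank_nt <- fl$n_flank_nt
  loc$c_flank_nt <- fl$c_flank_nt
  loc$flags <- fl$flags
  loc
}

#' Locate insertion blocks in a homolog family
#'
#' With an alignment: maximal runs of alignment columns in which every
#' uninvaded member is gapped and the invaded member under scrutiny has
#' residues; runs separated by fewer than `min_gap_aa` columns are
#' merged, and merged runs shorter than `min_block_aa` residues are
#' dropped.  Without an alignment: each invaded member is globally
#' aligned (affine gaps, BLOSUM62) against its most similar uninvaded
#' member and blocks are derived from the subject's gap runs.
#'
#' @param hs A [homolog_set].
#' @param min_block_aa Minimum block length in residues (default 30;
#'   the smallest elements of interest encode >150 aa products, and
#'   smaller thresholds flood output with ordinary indels).
#' @param min_gap_aa Merge adjacent blocks separated by fewer than this
#'   many columns (default 3).
#' @param window_aa Flanking-window width in residues (default 11).
#' @return List of `insertion_locus` objects, ordered by host id then
#'   start.  Loci that are not a whole number of codons or do not sit
#'   between codons carry `phase_warning = TRUE` instead of being
#'   dropped.
#' @export
find_insertion_blocks <- function(hs, min_block_aa = 30L,
                                  min_gap_aa = 3L, window_aa = 11L) {
  stopifnot(inherits(hs, "homolog_set"))
  if (!length(hs$invaded_ids) || !length(hs$uninvaded_ids)) {
    stop("need at least one invaded and one uninvaded member",
         call. = FALSE)
  }
  loci <- list()
  for (host_id in sort(hs$invaded_ids)) {
    if (!is.null(hs$alignment)) {
      member <- hs$alignment[[host_id]]
      un <- do.call(rbind, strsplit(
        unname(hs$alignment[sort(hs$uninvaded_ids)]), ""))
      all_un_gap <- apply(un == "-", 2L, all)
      member_res <- strsplit(member, "")[[1]] != "-"
      flag <- all_un_gap & member_res
    } else {
      pw <- pairwise_block_alignment(hs, host_id)
      member <- pw$pattern
      flag <- strsplit(pw$subject, "")[[1]] == "-" &
        strsplit(pw$pattern, "")[[1]] != "-"
    }
    runs <- true_runs(flag, min_gap = min_gap_aa)
    if (!nrow(runs)) next
    for (i in seq_len(nrow(runs))) {
      run <- runs[i, ]
      loc <- locus_from_run(hs, host_id, member, run, window_aa)
      if (is.null(loc)) next
      if (loc$aa_end - loc$aa_start + 1L < min_block_aa) next
      loci[[length(loci) + 1L]] <- loc
    }
  }
  loci
}

# global pairwise protein alignment of one invaded member against its
# most similar uninvaded member (ties broken by id order)
pairwise_block_alignment <- function(hs, host_id) {
  p <- sub("\\*$", "", hs$proteins[[host_id]])
  candidates <- sort(hs$uninvaded_ids)
  best <- NULL
  best_score <- -Inf
  for (uid in candidates) {
    q <- sub("\\*$", "", hs$proteins[[uid]])
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(p), Biostrings::AAString(q),
      substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5, type = "global")
    if (Biostrings::score(pa) > best_score) {
      best_score <- Biostrings::score(pa)
      best <- pa
    }
  }
  list(pattern = as.character(Biostrings::alignedPattern(best)),
       subject = as.character(Biostrings::alignedSubject(best)))
}

#' Extract flanking windows around an insertion locus
#'
#' The C-terminal flank begins at the first host residue after the
#' insertion (its first residue is the "+1" residue of the intein
#' tests); the N-terminal flank ends at the last host residue before
#' it.  Nucleotide windows are `3 * window_aa` bases.  Windows running
#' off the gene are clipped and flagged.
#'
#' @param locus An `insertion_locus`.
#' @param window_aa Window width in residues (>= 1).
#' @return List with `n_flank_aa`, `c_flank_aa`, `n_flank_nt`,
#'   `c_flank_nt` (character, possibly empty) and `flags`.
#' @export
extract_flanks <- function(locus, window_aa = 11L) {
  stopifnot(window_aa >= 1L)
  prot <- locus$host_protein
  cds <- locus$host_cds
  flags <- character(0)
  # protein coordinates of the host *without* the insertion removed:
  # the insertion occupies aa_start..aa_end of the translated CDS
  n_from <- max(1L, locus$aa_start - window_aa)
  n_to <- locus$aa_start - 1L
  c_from <- locus$aa_end + 1L
  c_to <- min(nchar(prot), locus$aa_end + window_aa)
  n_flank <- if (n_to >= n_from) substr(prot, n_from, n_to) else ""
  c_flank <- if (c_to >= c_from) substr(prot, c_from, c_to) else ""
  if (nchar(n_flank) < window_aa) flags <- c(flags, "n_flank_clipped")
  if (nchar(c_flank) < window_aa) flags <- c(flags, "c_flank_clipped")
  if (!nzchar(c_flank)) flags <- c(flags, "c_flank_empty")
  list(
    n_flank_aa = n_flank,
    c_flank_aa = c_flank,
    n_flank_nt = if (nzchar(n_flank))
      substr(cds, 3L * (n_from - 1L) + 1L, 3L * n_to) else "",
    c_flank_nt = if (nzchar(c_flank))
      substr(cds, 3L * (c_from - 1L) + 1L, 3L * c_to) else "",
    flags = flags
  )
}

#' @export
print.insertion_locus <- function(x, ...) {
  cat(sprintf(
    "<insertion_locus %s: aa %d-%d (nt %d-%d), %d aa%s>\n",
    x$host_id, x$aa_start, x$aa_end, x$nt_start, x$nt_end,
    x$aa_end - x$aa_start + 1L,
    if (isTRUE(x$phase_warning)) ", PHASE WARNING" else ""))
  invisible(x)
}

#' Build the per-member flank comparison table for a locus
#'
#' For each family member, pairs the insertion head (first `window`
#' residues of the insertion read in the host frame, or `3 * window`
#' bases) with that member's own C-terminal flank at the homologous
#' insertion site, for use by [group_flank_similarity].  Requires the
#' homolog set to carry an alignment (the site is an alignment column).
#'
#' @param hs A [homolog_set] with alignment.
#' @param locus An `insertion_locus` found in `hs`.
#' @param window Window width (residues).
#' @param alphabet `"aa"` or `"nt"`.
#' @return Data frame with columns `id`, `group`, `head`, `c_flank`.
#' @export
family_flank_table <- function(hs, locus, window = 11L,
                               alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (is.null(hs$alignment)) {
    stop("family_flank_table requires an aligned homolog_set",
         call. = FALSE)
  }
  col_start <- locus$aln_cols[1]
  col_after <- locus$aln_cols[2] + 1L
  rows <- lapply(c(hs$invaded_ids, hs$uninvaded_ids), function(id) {
    aln <- strsplit(hs$alignment[[id]], "")[[1]]
    nongap <- aln != "-"
    # residue index (in the member's own protein) of the first residue
    # at or after col_after
    idx_at <- cumsum(nongap)
    later <- which(nongap & seq_along(aln) >= col_after)
    if (!length(later)) return(NULL)
    first_res <- idx_at[later[1]]
    prot <- sub("\\*$", "", hs$proteins[[id]])
    cf_aa <- substr(prot, first_res,
                    min(nchar(prot), first_res + window - 1L))
    if (id %in% hs$invaded_ids) {
      # that member's own insertion head (block columns in its own
      # residue coordinates)
      in_block <- which(nongap & seq_along(aln) >= col_start &
                          seq_along(aln) < col_after)
      hs_from <- idx_at[in_block[1]]
      head_aa <- substr(prot, hs_from,
                        min(nchar(prot), hs_from + window - 1L))
      head_nt <- substr(hs$cds[[id]], 3L * (hs_from - 1L) + 1L,
                        min(nchar(hs$cds[[id]]),
                            3L * (hs_from + window - 1L)))
      group <- "invaded"
    } else {
      # uninvaded members are compared against the reference
      # insertion's head
      head_aa <- substr(as.character(locus$insertion_aa), 1L, window)
      head_nt <- substr(as.character(locus$insertion_nt), 1L, 3L * window)
      group <- "uninvaded"
    }
    cf_nt <- substr(hs$cds[[id]], 3L * (first_res - 1L) + 1L,
                    min(nchar(hs$cds[[id]]),
                        3L * (first_res + window - 1L)))
    data.frame(id = id, group = group,
               head = if (alphabet == "aa") head_aa else head_nt,
               c_flank = if (alphabet == "aa") cf_aa else cf_nt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no member has residues after the insertion site", call. = FALSE)
  }
  out
}
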