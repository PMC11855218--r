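# In-frame continuity testing and exhaustive hidden-ORF scanning.
#
# The central question for a candidate mobile element inside a coding
# gene: does the insertion read through seamlessly in the host frame
# (intein-like / hidden-ORF-like), or does it interrupt translation
# (intron-like)?  And does any alternate frame conceal a protein-length
# ORF, possibly starting at a non-canonical GTG/TTG?

#' In-frame continuity test of an insertion
#'
#' Translates the insertion in the host reading phase (frame +1) and
#' reports whether the reading is seamless (no internal stop codon) or,
#' if not, how many bp into the insertion the first stop is reached.
#' The offset is the position of the *last* base of the first in-frame
#' stop codon, matching the usual "a stop codon is reached N bp into
#' the insertion" phrasing.
#'
#' @param insertion_nt A [nuc_seq]; length must be a multiple of 3
#'   (the insertion is assumed extracted in host phase).
#' @param code A [genetic_code].
#' @return An object of class `continuity_result`: list with
#'   `seamless` (logical), `first_stop_offset_nt` (integer or `NA`),
#'   and `host_frame_translation` (a [prot_seq], stops marked `*`).
#' @export
continuity_test <- function(insertion_nt, code = genetic_code()) {
  s <- as_nuc_string(insertion_nt)
  if (nchar(s) %% 3L != 0L) {
    stop("insertion length ", nchar(s),
         " is not a multiple of 3: not in host phase", call. = FALSE)
  }
  tr <- translate_seq(s, 0L, code, stop_policy = "mark")
  aa <- strsplit(as.character(tr), "")[[1]]
  k <- match("*", aa)
  structure(list(
    seamless = is.na(k),
    first_stop_offset_nt = if (is.na(k)) NA_integer_ else 3L * k,
    host_frame_translation = tr
  ), class = "continuity_result")
}

#' @export
print.continuity_result <- function(x, ...) {
  if (x$seamless) {
    cat("seamless in-frame reading (no internal stop),",
        nchar(x$host_frame_translation), "aa\n")
  } else {
    cat("first in-frame stop reached", x$first_stop_offset_nt,
        "bp into the insertion\n")
  }
  invisible(x)
}

#' Relative reading frame of a 1-based start position
#'
#' Frame 1 is the host frame; an ORF starting at base 18 of the
#' insertion is in frame `((18 - 1) %% 3) + 1 = 3`.
#'
#' @param start_nt_1based Positive integer position.
#' @return Frame index in `1:3`.
#' @export
relative_frame <- function(start_nt_1based) {
  if (any(start_nt_1based < 1L)) {
    stop("positions are 1-based and must be positive", call. = FALSE)
  }
  ((as.integer(start_nt_1based) - 1L) %% 3L) + 1L
}

# Scan one strand of a sequence for stop-anchored ORFs in all three
# frame offsets.  `s` is the sequence actually walked (for the minus
# strand, its reverse complement); coordinates are relative to `s`.
scan_one_strand <- function(s, strand, code, min_len_aa, require_stop,
                            orig_len) {
  out <- list()
  for (off in 0:2) {
    codons <- codon_split(s, off + 1L)
    nc <- length(codons)
    if (nc == 0L) next
    is_stop <- codons %in% code$stop_codons
    is_start <- codons %in% code$start_codons
    stop_idx <- which(is_stop)
    start_idx <- which(is_start)
    if (!length(start_idx)) next
    # index (into stop_idx) of the first stop strictly after each start
    nxt <- findInterval(start_idx, stop_idx) + 1L
    seen_primary <- integer(0)  # stop codon indices already anchored
    for (k in seq_along(start_idx)) {
      i <- start_idx[k]
      j <- if (nxt[k] <= length(stop_idx)) stop_idx[nxt[k]] else NA_integer_
      open_ended <- is.na(j)
      if (open_ended && !require_stop) {
        prod_codons <- codons[seq.int(i, nc)]
        stop_nt <- NA_integer_
        plen <- nc - i + 1L
      } else if (!open_ended) {
        plen <- j - i
        if (plen < 1L) next
        prod_codons <- codons[seq.int(i, j - 1L)]
        stop_nt <- off + 3L * j
      } else {
        next
      }
      if (plen < min_len_aa) next
      start_nt <- off + 3L * (i - 1L) + 1L
      aa <- translate_codons(prod_codons, code)
      if (code$initiator_to_met) aa[1L] <- "M"
      anchor <- if (open_ended) -off - 1L else j * 3L + off  # unique per (frame, stop)
      is_primary <- !(anchor %in% seen_primary)
      seen_primary <- c(seen_primary, anchor)
      fidx <- relative_frame(start_nt)
      orf <- structure(list(
        start_nt = start_nt,
        stop_nt = stop_nt,
        strand = strand,
        frame_index = if (strand == "+") fidx else -fidx,
        start_codon = codons[i],
        product = prot_seq(paste(aa, collapse = ""),
                           id = sprintf("orf_%s%d_%d", strand, fidx, start_nt)),
        product_len_aa = plen,
        is_primary = is_primary,
        open_ended = open_ended,
        orig_start = if (strand == "+") start_nt else
          orig_len - (if (open_ended) start_nt + 3L * plen - 1L else stop_nt) + 1L,
        orig_end = if (strand == "+")
          (if (open_ended) start_nt + 3L * plen - 1L else stop_nt)
          else orig_len - start_nt + 1L
      ), class = "hidden_orf")
      out[[length(out) + 1L]] <- orf
    }
  }
  out
}

#' Scan an insertion for hidden ORFs in alternate reading frames
#'
#' Enumerates, for every requested frame and strand, every maximal open
#' reading frame that begins at a start codon from the genetic code's
#' start set and runs to the first downstream in-frame stop codon.
#' Within one stop-anchored ORF the most upstream start (longest
#' product) is flagged primary; downstream in-frame starts are listed
#' as alternates.  Results are sorted by product length descending,
#' ties broken by strand (`+` first) then smaller start coordinate.
#'
#' Minus-strand ORFs are scanned on the reverse complement;
#' `start_nt`/`stop_nt` are coordinates on the scanned strand, while
#' `orig_start`/`orig_end` always locate the ORF on the input sequence.
#'
#' @param insertion_nt A [nuc_seq] (typically an insertion element
#'   extracted from a host gene).
#' @param code A [genetic_code] (start-codon set taken from here;
#'   default includes the non-canonical starts GTG and TTG).
#' @param min_len_aa Minimum product length (aa, excluding the stop)
#'   for an ORF to be reported.  Default 50: real hidden-ORF products
#'   run 160-195 aa, and smaller values flood output with micro-ORFs.
#' @param require_stop If `TRUE` (default) an ORF must terminate at a
#'   stop codon inside the sequence; if `FALSE`, ORFs running off the
#'   end are reported with `open_ended = TRUE`.
#' @param strands `"both"` (default: all six frames) or `"forward"`.
#' @return List of `hidden_orf` objects (possibly empty).  Each has
#'   `start_nt`, `stop_nt` (last base of the stop codon; `NA` when
#'   open-ended), `strand`, `frame_index` (1..3 forward, -1..-3
#'   reverse, relative to the host frame), `start_codon`, `product`
#'   (a [prot_seq]), `product_len_aa`, `is_primary`, `open_ended`,
#'   `orig_start`, `orig_end`.
#' @examples
#' fx <- make_shilan_fixture(seed = 1)
#' top <- scan_hidden_orfs(fx$insertion)[[1]]
#' c(top$start_nt, top$frame_index, top$product_len_aa)  # 18 3 195
#' @export
scan_hidden_orfs <- function(insertion_nt, code = genetic_code(),
                             min_len_aa = 50L, require_stop = TRUE,
                             strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (min_len_aa < 1L) stop("min_len_aa must be >= 1", call. = FALSE)
  s <- as_nuc_string(insertion_nt)
  if (nchar(s) < 3L) return(list())
  orfs <- scan_one_strand(s, "+", code, min_len_aa, require_stop, nchar(s))
  if (strands == "both") {
    rc <- reverse_complement(s)
    orfs <- c(orfs,
              scan_one_strand(rc, "-", code, min_len_aa, require_stop,
                              nchar(s)))
  }
  if (!length(orfs)) return(orfs)
  len <- vapply(orfs, function(o) o$product_len_aa, integer(1))
  st <- vapply(orfs, function(o) o$strand == "-", logical(1))
  beg <- vapply(orfs, function(o) o$start_nt, integer(1))
  orfs[order(-len, st, beg)]
}

#' @export
print.hidden_orf <- function(x, ...) {
  cat(sprintf(
    "<hidden_orf %s strand %s frame %+d: start %d (%s), %s, %d aa%s>\n",
    if (x$is_primary) "primary" else "alternate",
    x$strand, x$frame_index, x$start_nt, x$start_codon,
    if (x$open_ended) "open-ended" else sprintf("stop %d", x$stop_nt),
    x$product_len_aa,
    if (x$open_ended) " (no stop)" else ""))
  invisible(x)
}
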