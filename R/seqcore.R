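#' @keywords internal
"_PACKAGE"

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
PROT_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                   "X", "*")

#' Construct a validated nucleotide sequence
#'
#' A `nuc_seq` is a labelled DNA string over `{A,C,G,T,N}`.  Lowercase
#' input is normalised to uppercase; any other character is rejected.
#'
#' @param residues Single character string of nucleotides.
#' @param id Text label for the sequence.
#' @return An object of class `nuc_seq` with fields `id` and `residues`.
#' @examples
#' s <- nuc_seq("gtgaaataa", id = "demo")
#' nchar(s)
#' @export
nuc_seq <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) {
    stop("nucleotide sequence must be non-empty", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), NUC_ALPHABET)
  if (length(bad)) {
    stop("invalid nucleotide character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(id = as.character(id), residues = residues),
            class = "nuc_seq")
}

#' Construct a validated protein sequence
#'
#' A `prot_seq` is a labelled amino-acid string over the 20 standard
#' residues plus `X` (from ambiguous codons) and `*` (translated stop).
#'
#' @param residues Single character string of amino acids.
#' @param id Text label.
#' @return An object of class `prot_seq`.
#' @export
prot_seq <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), PROT_ALPHABET)
  if (length(bad)) {
    stop("invalid amino-acid character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(id = as.character(id), residues = residues),
            class = "prot_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq %s: %d nt>\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' @export
print.prot_seq <- function(x, ...) {
  cat(sprintf("<prot_seq %s: %d aa>\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' @exportS3Method base::nchar
nchar.nuc_seq <- function(x, ...) nchar(x$residues)

#' @exportS3Method base::nchar
nchar.prot_seq <- function(x, ...) nchar(x$residues)

#' @export
as.character.nuc_seq <- function(x, ...) x$residues

#' @export
as.character.prot_seq <- function(x, ...) x$residues

as_nuc_string <- function(x) {
  if (inherits(x, "nuc_seq")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a nuc_seq or a character scalar", call. = FALSE)
}

as_prot_string <- function(x) {
  if (inherits(x, "prot_seq")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a prot_seq or a character scalar", call. = FALSE)
}

#' Genetic code with configurable start codons
#'
#' Builds the codon table used throughout the package.  The amino-acid
#' map is the standard code (identical, for coding sequences, to the
#' bacterial/archaeal table); the default start-codon set is the
#' bacterial `{ATG, GTG, TTG}`, reflecting the prevalence of GTG/TTG
#' initiation in phages and their actinobacterial hosts.  Stops are
#' fixed at `{TAA, TAG, TGA}`.
#'
#' @param start_codons Character vector of start codons.
#' @param initiator_to_met If `TRUE`, translation of an open reading
#'   frame remaps its initiator codon to `M` even for GTG/TTG starts.
#'   Off by default: products report the literal Val/Leu.
#' @return An object of class `genetic_code`: a list with `map` (named
#'   character vector, 64 codons), `start_codons` and `stop_codons`.
#' @examples
#' code <- genetic_code()
#' code$map[["GTG"]]  # "V"
#' @export
genetic_code <- function(start_codons = c("ATG", "GTG", "TTG"),
                         initiator_to_met = FALSE) {
  map <- as.character(Biostrings::GENETIC_CODE)
  names(map) <- names(Biostrings::GENETIC_CODE)
  start_codons <- toupper(start_codons)
  if (!all(start_codons %in% names(map))) {
    stop("unknown start codon(s): ",
         paste(setdiff(start_codons, names(map)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(map = map,
                 start_codons = start_codons,
                 stop_codons = c("TAA", "TAG", "TGA"),
                 initiator_to_met = isTRUE(initiator_to_met)),
            class = "genetic_code")
}

# Split a string into consecutive codons starting at `from` (1-based);
# trailing partial codon dropped.
codon_split <- function(s, from = 1L) {
  n <- nchar(s)
  if (from > n - 2L) return(character(0))
  starts <- seq.int(from, n - 2L, by = 3L)
  substring(s, starts, starts + 2L)
}

translate_codons <- function(codons, code) {
  aa <- unname(code$map[codons])
  aa[is.na(aa)] <- "X"  # codons containing N (or any ambiguity)
  aa
}

#' Translate a nucleotide sequence in a fixed frame
#'
#' Translates consecutive codons of `seq` beginning at a 0-based
#' `offset`, dropping any trailing partial codon.  Codons containing
#' `N` translate to `X` and are never treated as stops.
#'
#' @param seq A [nuc_seq] (or character scalar).
#' @param offset 0-based frame offset (0, 1 or 2 for the three forward
#'   frames, but any in-range value is accepted).
#' @param code A [genetic_code].
#' @param stop_policy One of `"mark"` (emit `*` and continue, the
#'   default), `"truncate"` (end the product at the first stop) or
#'   `"run_through"` (alias of `"mark"`).
#' @return A [prot_seq].
#' @examples
#' as.character(translate_seq(nuc_seq("GTGAAATAA"), 0))  # "VK*"
#' @export
translate_seq <- function(seq, offset = 0L, code = genetic_code(),
                          stop_policy = c("mark", "truncate", "run_through")) {
  stop_policy <- match.arg(stop_policy)
  s <- as_nuc_string(seq)
  offset <- as.integer(offset)
  if (offset < 0L || offset >= nchar(s)) {
    stop("offset out of range [0, ", nchar(s) - 1L, "]", call. = FALSE)
  }
  if (nchar(s) - offset < 3L) {
    stop("no complete codon at offset ", offset, call. = FALSE)
  }
  codons <- codon_split(s, offset + 1L)
  aa <- translate_codons(codons, code)
  if (stop_policy == "truncate") {
    k <- match("*", aa)
    if (!is.na(k)) aa <- aa[seq_len(k - 1L)]
  }
  id <- if (inherits(seq, "nuc_seq")) seq$id else "seq"
  prot_seq(paste(aa, collapse = ""), id = id)
}

#' Reverse complement
#'
#' @param seq A [nuc_seq] or character scalar.
#' @return Same type as the input, reverse-complemented (`N` maps to
#'   `N`); applying it twice is the identity.
#' @export
reverse_complement <- function(seq) {
  s <- as_nuc_string(seq)
  rc <- chartr("ACGTN", "TGCAN", s)
  rc <- paste(rev(strsplit(rc, "")[[1]]), collapse = "")
  if (inherits(seq, "nuc_seq")) nuc_seq(rc, id = seq$id) else rc
}

#' Translate all six reading frames
#'
#' Frames `+1, +2, +3` are forward offsets 0, 1, 2; frames `-1, -2, -3`
#' are offsets 0, 1, 2 on the reverse complement.  Translation uses
#' `stop_policy = "mark"` so internal stops appear as `*`.
#'
#' @param seq A [nuc_seq] or character scalar of length >= 3 nt.
#' @param code A [genetic_code].
#' @return Named list of six [prot_seq] objects, names
#'   `"+1","+2","+3","-1","-2","-3"`.  Frames with no complete codon
#'   yield an empty-string entry.
#' @export
six_frames <- function(seq, code = genetic_code()) {
  s <- as_nuc_string(seq)
  if (nchar(s) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  rc <- reverse_complement(s)
  one <- function(str, off) {
    if (nchar(str) - off < 3L) return(prot_seq("", id = "frame"))
    translate_seq(str, off, code, stop_policy = "mark")
  }
  out <- list(
    `+1` = one(s, 0L), `+2` = one(s, 1L), `+3` = one(s, 2L),
    `-1` = one(rc, 0L), `-2` = one(rc, 1L), `-3` = one(rc, 2L)
  )
  out
}

#' Convert amino-acid coordinates to CDS nucleotide coordinates
#'
#' All coordinates are 1-based inclusive, the R/Bioconductor
#' convention used throughout this package.  Residue `i` occupies CDS
#' bases `3*(i-1)+1 .. 3*i`.
#'
#' @param aa_start,aa_end 1-based inclusive residue span.
#' @return Integer vector `c(nt_start, nt_end)`.
#' @export
aa_to_nt <- function(aa_start, aa_end) {
  stopifnot(aa_start >= 1L, aa_end >= aa_start - 1L)
  if (aa_end < aa_start) {          # empty span
    return(c(nt_start = 3L * (aa_start - 1L) + 1L,
             nt_end = 3L * (aa_start - 1L)))
  }
  c(nt_start = 3L * (as.integer(aa_start) - 1L) + 1L,
    nt_end = 3L * as.integer(aa_end))
}

#' @rdname aa_to_nt
#' @param nt_start,nt_end 1-based inclusive base span; must cover whole
#'   codons.
#' @export
nt_to_aa <- function(nt_start, nt_end) {
  if ((nt_start - 1L) %% 3L != 0L || nt_end %% 3L != 0L) {
    stop("nucleotide span does not cover whole codons", call. = FALSE)
  }
  c(aa_start = (as.integer(nt_start) - 1L) %/% 3L + 1L,
    aa_end = as.integer(nt_end) %/% 3L)
}

#' Read a (multi-)FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet] that returns a named
#' character vector of uppercase sequences.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param type `"nuc"` or `"prot"`; sequences are validated against the
#'   corresponding alphabet (gap `-` is allowed for `"aln"`).
#' @return Named character vector.
#' @export
read_fasta <- function(path, type = c("nuc", "prot", "aln")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  v <- toupper(as.character(set))
  names(v) <- sub("\\s.*$", "", names(set))
  ok_chars <- switch(type,
    nuc = NUC_ALPHABET,
    prot = PROT_ALPHABET,
    aln = c(PROT_ALPHABET, "-"))
  for (i in seq_along(v)) {
    bad <- setdiff(unique(strsplit(v[[i]], "")[[1]]), ok_chars)
    if (length(bad)) {
      stop("record '", names(v)[i], "' in ", path,
           ": invalid character(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  v
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, or a list of `nuc_seq`/`prot_seq`.
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.list(seqs)) {
    nm <- vapply(seqs, function(s) s$id, character(1))
    seqs <- vapply(seqs, as.character, character(1))
    names(seqs) <- nm
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
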