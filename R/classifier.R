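# Rule-cascade classification of an insertion element from its
# continuity, hidden-ORF and signature evidence.  The cascade mirrors
# the elimination order used when characterising cryptic elements:
# first ask whether the element carries the full conjunction of intein
# hallmarks, then the self-splicing-intron end motifs, and only then
# fall back to the hidden-ORF interpretation.  Labels are candidate
# classes only: no rule asserts actual splicing capability.

#' Classify an insertion element
#'
#' Applies a transparent rule cascade; the highest-priority satisfied
#' rule gives the label and any other satisfied rules are recorded as
#' co-labels in the notes.
#'
#' \enumerate{
#'   \item `intein_candidate`: seamless in-frame continuity AND +1
#'     flank residue in \{T, S, C\} AND terminal residue Asn (or the
#'     Ser variant) AND at least one splicing-block motif hit.
#'   \item `group1_intron_candidate`: terminal G, OR non-seamless
#'     continuity with flank identity at or above the threshold
#'     (5'-insertion/3'-flank mimicry).
#'   \item `group2_intron_candidate`: the insertion begins `GTGCG`.
#'   \item `hidden_orf_element`: at least one alternate-frame
#'     (`frame_index != 1`) ORF of at least `min_orf_len_aa`;
#'     sublabel `hnh_endonuclease` when the product carries an H-N-H
#'     triad, else `zinc_finger_bearing` when it carries a CXX(X)C
#'     pair, else `other`.
#'   \item `unclassified` otherwise.
#' }
#'
#' Single signals never suffice for the splicing classes: each rule
#' requires its stated conjunction, because individually these motifs
#' arise easily by chance.
#'
#' @param locus An `insertion_locus` (may be a minimal stand-in with
#'   `host_id`, coordinates and flags for pre-extracted insertions).
#' @param continuity A `continuity_result` for the same insertion.
#' @param orfs Hidden-ORF list from [scan_hidden_orfs].
#' @param evidence A `signature_evidence` object.
#' @param thresholds List: `flank_sim` (percent identity at or above
#'   which a non-seamless element counts as flank-mimicking, default
#'   70) and `min_orf_len_aa` (default 50).
#' @return Object of class `element_call`: list with `label`,
#'   `sublabel`, `locus`, `evidence` (continuity + signatures + orfs),
#'   `notes` (character flags) and `co_labels`.
#' @export
classify_element <- function(locus, continuity, orfs, evidence,
                             thresholds = list(flank_sim = 70,
                                               min_orf_len_aa = 50L)) {
  stopifnot(inherits(continuity, "continuity_result"),
            inherits(evidence, "signature_evidence"))
  if (is.null(thresholds$flank_sim)) thresholds$flank_sim <- 70
  if (is.null(thresholds$min_orf_len_aa)) thresholds$min_orf_len_aa <- 50L

  alt_orfs <- Filter(function(o) o$frame_index != 1L &&
                       o$product_len_aa >= thresholds$min_orf_len_aa,
                     orfs)

  rule_intein <- isTRUE(continuity$seamless) &&
    isTRUE(evidence$intein_plus1$pass) &&
    evidence$intein_terminal$status %in% c("asn", "ser_variant") &&
    nrow(evidence$intein_motifs_found) >= 1L
  rule_g1 <- isTRUE(evidence$intron_g_3prime) ||
    (!continuity$seamless &&
       !is.na(evidence$flank_identity_aa) &&
       evidence$flank_identity_aa >= thresholds$flank_sim)
  rule_g2 <- isTRUE(evidence$intron_gtgcg_5prime)
  rule_orf <- length(alt_orfs) >= 1L

  satisfied <- c(intein_candidate = rule_intein,
                 group1_intron_candidate = rule_g1,
                 group2_intron_candidate = rule_g2,
                 hidden_orf_element = rule_orf)
  label <- if (any(satisfied)) names(satisfied)[which(satisfied)[1L]]
           else "unclassified"
  co_labels <- setdiff(names(satisfied)[satisfied], label)

  sublabel <- NA_character_
  if (label == "hidden_orf_element") {
    has_hnh <- !is.null(evidence$hnh_hits) && nrow(evidence$hnh_hits) >= 1L
    has_znf <- !is.null(evidence$znf_hits) && nrow(evidence$znf_hits) >= 1L
    sublabel <- if (has_hnh) "hnh_endonuclease"
                else if (has_znf) "zinc_finger_bearing"
                else "other"
  }

  notes <- character(0)
  if (isTRUE(evidence$intein_plus1$proline_flag)) {
    notes <- c(notes, "proline_flank")
  }
  if (identical(evidence$intein_terminal$status, "ser_variant")) {
    notes <- c(notes, "ser_variant_terminus")
  }
  if (any(vapply(orfs, function(o) isTRUE(o$open_ended), logical(1)))) {
    notes <- c(notes, "open_ended_orf")
  }
  if (isTRUE(locus$phase_warning)) notes <- c(notes, "phase_warning")
  if (length(co_labels)) {
    notes <- c(notes, paste0("co_label:", co_labels))
  }

  structure(list(
    locus = locus,
    label = label,
    sublabel = sublabel,
    evidence = list(continuity = continuity,
                    signatures = evidence,
                    orfs = orfs),
    notes = notes,
    co_labels = co_labels,
    thresholds = thresholds
  ), class = "element_call")
}

#' @export
print.element_call <- function(x, ...) {
  cat(sprintf("<element_call %s: %s%s%s>\n",
              x$locus$host_id, x$label,
              if (!is.na(x$sublabel)) paste0(" / ", x$sublabel) else "",
              if (length(x$notes))
                paste0(" [", paste(x$notes, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Run the full evidence chain and classify one insertion
#'
#' Convenience wrapper: continuity test, hidden-ORF scan, signature
#' collection, classification.
#'
#' @param locus An `insertion_locus`.
#' @param code A [genetic_code].
#' @param min_len_aa,require_stop,strands Passed to [scan_hidden_orfs].
#' @param window Flank window (residues) for the similarity statistic.
#' @param patterns Intein splicing-block patterns.
#' @param thresholds Classification thresholds (see [classify_element]).
#' @return An `element_call`.
#' @export
characterize_locus <- function(locus, code = genetic_code(),
                               min_len_aa = 50L, require_stop = TRUE,
                               strands = "both", window = 11L,
                               patterns = default_intein_patterns(),
                               thresholds = list(flank_sim = 70,
                                                 min_orf_len_aa = min_len_aa)) {
  continuity <- continuity_test(locus$insertion_nt, code)
  orfs <- scan_hidden_orfs(locus$insertion_nt, code,
                           min_len_aa = min_len_aa,
                           require_stop = require_stop,
                           strands = strands)
  ev <- signature_evidence(locus$insertion_nt,
                           c_flank_aa = locus$c_flank_aa %||% "",
                           orfs = orfs, code = code, window = window,
                           c_flank_nt = locus$c_flank_nt,
                           patterns = patterns)
  classify_element(locus, continuity, orfs, ev, thresholds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
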