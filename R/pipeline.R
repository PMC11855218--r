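# End-to-end orchestration: map insertions, run the evidence chain,
# classify, and write standard-format outputs (GFF3, JSON, TSV,
# protein FASTA queries).  Human-facing coordinates are 1-based
# inclusive throughout.

#' Build a run configuration
#'
#' @param cds_fasta Nucleotide FASTA of homologous coding sequences
#'   (mapping mode), or `NULL`.
#' @param groups_tsv Two-column TSV (`id`, `group`) assigning each CDS
#'   to `invaded` or `uninvaded` (mapping mode).
#' @param alignment_fasta Optional aligned protein FASTA of the same
#'   genes; when absent, pairwise alignment is used.
#' @param insertion_fasta Pre-extracted insertion FASTA
#'   (single-insertion mode; mapping is skipped).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer seed (recorded; the analysis itself is
#'   deterministic).
#' @param start_codons Start-codon set for the hidden-ORF scan.
#' @param min_orf_len_aa,require_stop,strands Hidden-ORF scan options.
#' @param min_block_aa,min_gap_aa,window Insertion-mapping options.
#' @param flank_sim_threshold Classifier flank-similarity threshold.
#' @param pattern_file Optional intein splicing-block pattern TSV.
#' @return A `run_config` list.
#' @export
run_config <- function(cds_fasta = NULL, groups_tsv = NULL,
                       alignment_fasta = NULL, insertion_fasta = NULL,
                       out_dir = "cryptorf_out", seed = NULL,
                       start_codons = c("ATG", "GTG", "TTG"),
                       min_orf_len_aa = 50L, require_stop = TRUE,
                       strands = "both", min_block_aa = 30L,
                       min_gap_aa = 3L, window = 11L,
                       flank_sim_threshold = 70,
                       pattern_file = NULL) {
  for (p in c(cds_fasta, groups_tsv, alignment_fasta, insertion_fasta,
              pattern_file)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  if (is.null(cds_fasta) && is.null(insertion_fasta)) {
    stop("need either cds_fasta (mapping mode) or insertion_fasta ",
         "(single-insertion mode)", call. = FALSE)
  }
  stopifnot(flank_sim_threshold >= 0, flank_sim_threshold <= 100,
            min_orf_len_aa >= 1L)
  structure(list(cds_fasta = cds_fasta, groups_tsv = groups_tsv,
                 alignment_fasta = alignment_fasta,
                 insertion_fasta = insertion_fasta,
                 out_dir = out_dir, seed = seed,
                 start_codons = start_codons,
                 min_orf_len_aa = as.integer(min_orf_len_aa),
                 require_stop = isTRUE(require_stop),
                 strands = strands,
                 min_block_aa = as.integer(min_block_aa),
                 min_gap_aa = as.integer(min_gap_aa),
                 window = as.integer(window),
                 flank_sim_threshold = flank_sim_threshold,
                 pattern_file = pattern_file),
            class = "run_config")
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

write_gff3 <- function(rows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste0("# coordinates are 1-based inclusive on the host ",
                    "CDS"), con)
  for (r in rows) {
    attrs <- paste(vapply(names(r$attributes), function(k) {
      paste0(k, "=", gff3_escape(as.character(r$attributes[[k]])))
    }, character(1)), collapse = ";")
    writeLines(paste(gff3_escape(r$seqid), "cryptorf", r$type,
                     r$start, r$end, ".", r$strand, ".", attrs,
                     sep = "\t"), con)
  }
  invisible(path)
}

# plain-list representation of an element_call for JSON export
report_element <- function(call) {
  loc <- call$locus
  ct <- call$evidence$continuity
  sig <- call$evidence$signatures
  orfs <- lapply(call$evidence$orfs, function(o) {
    list(start_nt = o$start_nt,
         stop_nt = if (is.na(o$stop_nt)) NULL else o$stop_nt,
         strand = o$strand, frame_index = o$frame_index,
         start_codon = o$start_codon,
         product_len_aa = o$product_len_aa,
         is_primary = o$is_primary, open_ended = o$open_ended,
         host_cds_start = if (!is.na(loc$nt_start))
           loc$nt_start - 1L + o$orig_start else o$orig_start,
         host_cds_end = if (!is.na(loc$nt_start))
           loc$nt_start - 1L + o$orig_end else o$orig_end,
         product = as.character(o$product))
  })
  list(
    host_id = loc$host_id,
    label = call$label,
    sublabel = if (is.na(call$sublabel)) NULL else call$sublabel,
    notes = as.list(call$notes),
    coordinates = list(aa_start = loc$aa_start, aa_end = loc$aa_end,
                       nt_start = loc$nt_start, nt_end = loc$nt_end),
    continuity = list(
      seamless = ct$seamless,
      first_stop_offset_nt = if (is.na(ct$first_stop_offset_nt)) NULL
                             else ct$first_stop_offset_nt,
      host_frame_translation = as.character(ct$host_frame_translation)),
    signatures = list(
      intein_plus1 = sig$intein_plus1,
      intein_terminal = sig$intein_terminal,
      intein_motifs_found = sig$intein_motifs_found,
      intron_g_3prime = sig$intron_g_3prime,
      intron_gtgcg_5prime = sig$intron_gtgcg_5prime,
      flank_identity_aa = sig$flank_identity_aa,
      flank_identity_nt = sig$flank_identity_nt,
      hnh_hits = sig$hnh_hits,
      znf_pairs = sig$znf_hits,
      znf_motifs = sig$znf_motifs),
    hidden_orfs = orfs,
    thresholds = call$thresholds
  )
}

#' Run the full pipeline from a configuration
#'
#' Mapping mode (CDS FASTA + group file): locate insertion blocks from
#' the invaded/uninvaded comparison, then run continuity, hidden-ORF
#' and signature analysis on each locus and classify it.
#' Single-insertion mode (insertion FASTA): skip mapping and treat
#' each record as a pre-extracted insertion in host phase.
#'
#' Writes to `config$out_dir`: `elements.gff3` (loci and ORFs),
#' `elements.json` (full evidence per locus), `summary.tsv` (one row
#' per locus), `hidden_orf_products.faa` (primary alternate-frame
#' products) and `run_log.txt`.  An empty finding set is a success.
#'
#' @param config A [run_config].
#' @return Invisibly, the list of `element_call` objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  code <- genetic_code(start_codons = config$start_codons)
  patterns <- load_motif_patterns(config$pattern_file)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$cds_fasta)) {
    cds <- read_fasta(config$cds_fasta, type = "nuc")
    if (is.null(config$groups_tsv)) {
      stop("mapping mode needs a group assignment file", call. = FALSE)
    }
    groups <- utils::read.delim(config$groups_tsv, header = TRUE,
                                stringsAsFactors = FALSE)
    if (!all(c("id", "group") %in% names(groups))) {
      stop("group file must have columns 'id' and 'group'",
           call. = FALSE)
    }
    unknown <- setdiff(groups$id, names(cds))
    if (length(unknown)) {
      stop("group file references unknown ids: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    aln <- if (!is.null(config$alignment_fasta)) {
      read_fasta(config$alignment_fasta, type = "aln")
    } else NULL
    hs <- homolog_set(cds,
                      invaded_ids = groups$id[groups$group == "invaded"],
                      uninvaded_ids = groups$id[groups$group == "uninvaded"],
                      alignment = aln, code = code)
    loci <- find_insertion_blocks(hs, min_block_aa = config$min_block_aa,
                                  min_gap_aa = config$min_gap_aa,
                                  window_aa = config$window)
  } else {
    ins <- read_fasta(config$insertion_fasta, type = "nuc")
    loci <- lapply(names(ins), function(id) {
      standalone_locus(nuc_seq(ins[[id]], id = id))
    })
  }

  calls <- lapply(loci, function(loc) {
    characterize_locus(loc, code = code,
                       min_len_aa = config$min_orf_len_aa,
                       require_stop = config$require_stop,
                       strands = config$strands,
                       window = config$window,
                       patterns = patterns,
                       thresholds = list(
                         flank_sim = config$flank_sim_threshold,
                         min_orf_len_aa = config$min_orf_len_aa))
  })

  write_report_bundle(calls, config)
  invisible(calls)
}

write_report_bundle <- function(calls, config) {
  out <- config$out_dir
  # GFF3
  rows <- list()
  for (i in seq_along(calls)) {
    call <- calls[[i]]
    loc <- call$locus
    lid <- sprintf("locus_%02d", i)
    rows[[length(rows) + 1L]] <- list(
      seqid = loc$host_id, type = "sequence_insertion",
      start = loc$nt_start, end = loc$nt_end, strand = "+",
      attributes = list(ID = lid, label = call$label,
                        sublabel = if (is.na(call$sublabel)) "NA"
                                   else call$sublabel,
                        aa_start = loc$aa_start, aa_end = loc$aa_end))
    for (j in seq_along(call$evidence$orfs)) {
      o <- call$evidence$orfs[[j]]
      rows[[length(rows) + 1L]] <- list(
        seqid = loc$host_id, type = "ORF",
        start = loc$nt_start - 1L + o$orig_start,
        end = loc$nt_start - 1L + o$orig_end,
        strand = o$strand,
        attributes = list(ID = sprintf("%s_orf_%02d", lid, j),
                          Parent = lid,
                          frame_index = o$frame_index,
                          start_codon = o$start_codon,
                          insertion_start_nt = o$start_nt,
                          product_len_aa = o$product_len_aa,
                          primary = tolower(o$is_primary)))
    }
  }
  write_gff3(rows, file.path(out, "elements.gff3"))

  # JSON evidence
  jsonlite::write_json(lapply(calls, report_element),
                       file.path(out, "elements.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  # TSV summary
  summ <- do.call(rbind, lapply(calls, function(call) {
    ct <- call$evidence$continuity
    top <- if (length(call$evidence$orfs)) call$evidence$orfs[[1]] else NULL
    data.frame(
      host_id = call$locus$host_id,
      aa_start = call$locus$aa_start, aa_end = call$locus$aa_end,
      nt_start = call$locus$nt_start, nt_end = call$locus$nt_end,
      label = call$label,
      sublabel = call$sublabel,
      seamless = ct$seamless,
      first_stop_offset_nt = ct$first_stop_offset_nt,
      top_orf_start_nt = if (is.null(top)) NA_integer_ else top$start_nt,
      top_orf_frame = if (is.null(top)) NA_integer_ else top$frame_index,
      top_orf_len_aa = if (is.null(top)) NA_integer_
                       else top$product_len_aa,
      flank_identity_aa = call$evidence$signatures$flank_identity_aa,
      notes = paste(call$notes, collapse = ","),
      stringsAsFactors = FALSE)
  }))
  if (is.null(summ)) {
    summ <- data.frame(host_id = character(0))
  }
  utils::write.table(summ, file.path(out, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # primary alternate-frame products
  prods <- list()
  for (call in calls) {
    for (o in call$evidence$orfs) {
      if (o$is_primary && o$frame_index != 1L) {
        id <- sprintf("%s_frame%+d_start%d", call$locus$host_id,
                      o$frame_index, o$start_nt)
        prods[[id]] <- as.character(o$product)
      }
    }
  }
  if (length(prods)) {
    write_fasta(unlist(prods), file.path(out, "hidden_orf_products.faa"))
  }

  # run log
  log <- c(
    sprintf("cryptorf %s", as.character(utils::packageVersion("cryptorf"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    "config:",
    vapply(names(config), function(k) {
      sprintf("  %s: %s", k,
              paste(as.character(config[[k]] %||% "NULL"),
                    collapse = " "))
    }, character(1)),
    sprintf("loci: %d", length(calls)))
  writeLines(log, file.path(out, "run_log.txt"))
  invisible(out)
}

#' Export original-frame and alternate-frame query FASTA
#'
#' Prepares the translations an external database search would use:
#' for every element call, the in-frame (host-frame) translation of
#' the insertion and the product of its top alternate-frame ORF, as
#' FASTA records named by locus and frame.
#'
#' @param calls Non-empty list of `element_call` objects.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written
#'   (`queries_original_frame.faa`, `queries_alternate_frame.faa`).
#' @export
export_queries <- function(calls, out_dir) {
  if (!length(calls)) stop("no element calls to export", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  orig <- list()
  alt <- list()
  for (call in calls) {
    loc <- call$locus
    tr <- call$evidence$continuity$host_frame_translation
    orig[[sprintf("%s_ins%d_%d_frame+1", loc$host_id, loc$nt_start,
                  loc$nt_end)]] <- as.character(tr)
    alts <- Filter(function(o) o$is_primary && o$frame_index != 1L,
                   call$evidence$orfs)
    if (length(alts)) {
      o <- alts[[1]]
      alt[[sprintf("%s_ins%d_%d_frame%+d", loc$host_id, loc$nt_start,
                   loc$nt_end, o$frame_index)]] <- as.character(o$product)
    }
  }
  paths <- character(0)
  p1 <- file.path(out_dir, "queries_original_frame.faa")
  write_fasta(unlist(orig), p1)
  paths <- p1
  if (length(alt)) {
    p2 <- file.path(out_dir, "queries_alternate_frame.faa")
    write_fasta(unlist(alt), p2)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
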