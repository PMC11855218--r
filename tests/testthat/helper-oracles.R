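# Independent oracles used across the suite.

# random nucleotide string
rand_nuc <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# translation oracle: Biostrings, fuzzy codons to X
oracle_translate <- function(s, offset = 0) {
  sub <- substr(s, offset + 1, nchar(s))
  sub <- substr(sub, 1, (nchar(sub) %/% 3) * 3)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# brute-force ORF enumeration: every position on every requested
# strand, start-codon membership test, codon walk to the first stop.
# Returns a data frame keyed on (strand, start_nt, stop_nt).
oracle_orf_scan <- function(s, min_len_aa = 50, require_stop = TRUE,
                            strands = "both",
                            starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  scan1 <- function(str, strand) {
    L <- nchar(str)
    rows <- list()
    if (L < 3) return(rows)
    for (i in seq_len(L - 2)) {
      if (!substr(str, i, i + 2) %in% starts) next
      j <- i + 3
      stop_nt <- NA_integer_
      while (j + 2 <= L) {
        if (substr(str, j, j + 2) %in% stops) {
          stop_nt <- j + 2
          break
        }
        j <- j + 3
      }
      if (is.na(stop_nt)) {
        if (require_stop) next
        plen <- (L - i + 1) %/% 3
      } else {
        plen <- (stop_nt - i + 1) %/% 3 - 1
      }
      if (plen < min_len_aa) next
      rows[[length(rows) + 1]] <- data.frame(
        strand = strand, start_nt = i, stop_nt = stop_nt,
        product_len_aa = plen)
    }
    rows
  }
  rows <- scan1(s, "+")
  if (strands == "both") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    rows <- c(rows, scan1(rc, "-"))
  }
  if (!length(rows)) {
    return(data.frame(strand = character(0), start_nt = integer(0),
                      stop_nt = integer(0), product_len_aa = integer(0),
                      is_primary = logical(0)))
  }
  df <- do.call(rbind, rows)
  # primary = most upstream start per (strand, stop anchor); open-ended
  # ORFs anchor on (strand, frame)
  anchor <- ifelse(is.na(df$stop_nt),
                   paste(df$strand, "open", (df$start_nt - 1) %% 3),
                   paste(df$strand, df$stop_nt))
  df$is_primary <- df$start_nt == ave(df$start_nt, anchor, FUN = min)
  df <- df[order(df$strand, df$start_nt), ]
  rownames(df) <- NULL
  df
}

# canonical key table from a scan_hidden_orfs result, for set
# comparison against the oracle
orf_key_table <- function(orfs) {
  if (!length(orfs)) {
    return(data.frame(strand = character(0), start_nt = integer(0),
                      stop_nt = integer(0), product_len_aa = integer(0),
                      is_primary = logical(0)))
  }
  df <- do.call(rbind, lapply(orfs, function(o) {
    data.frame(strand = o$strand, start_nt = o$start_nt,
               stop_nt = o$stop_nt, product_len_aa = o$product_len_aa,
               is_primary = o$is_primary)
  }))
  df <- df[order(df$strand, df$start_nt), ]
  rownames(df) <- NULL
  df
}

# minimal locus for a pre-extracted insertion
test_locus <- function(insertion, c_flank_aa = "") {
  cryptorf:::standalone_locus(insertion, c_flank_aa = c_flank_aa)
}

expected_label <- c(hidden_orf = "hidden_orf_element",
                    intein_like = "intein_candidate",
                    group1_intron_like = "group1_intron_candidate",
                    group2_intron_like = "group2_intron_candidate")
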