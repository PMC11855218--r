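# Seed-deterministic synthetic-data generation: host-gene families
# with planted insertion elements of known class and layout, plus
# ground-truth records, so every pipeline stage is testable without
# any download.
#
# Hidden-ORF insertions are built by constrained codon-wise
# construction: the alternate-frame ORF is laid down codon by codon
# (synonymous choices free), and a randomized local-repair loop then
# removes host-frame stop codons, upstream in-frame start codons and
# any other forbidden local pattern.  Whole-sequence rejection
# sampling would be hopeless here: a ~590-nt stop-free shifted frame
# has probability on the order of (61/64)^196 of arising by chance in
# *each* frame simultaneously, and the joint constraint essentially
# never holds.

BASES <- c("A", "C", "G", "T")

# background amino-acid set for generated products: excludes H, N, C
# (so motif-scan ground truth is unambiguous) and the single-codon
# residues M, W (so every background codon has a synonymous
# alternative for the repair loop)
BG_AA <- c("A", "D", "E", "F", "G", "I", "K", "L", "P", "Q", "R",
           "S", "T", "V", "Y")

codons_for <- function(aa, code = genetic_code()) {
  names(code$map)[code$map == aa]
}

# evaluate expr with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# derive a small deterministic sub-seed stream from a master seed
sub_seed <- function(seed, k) {
  ((seed %% 1000003L) * 1009L + k) %% 2147483629L
}

#' Specification for a planted insertion element
#'
#' Validated parameter bundle consumed by [plant_hidden_orf] and the
#' family generator.
#'
#' @param element_class One of `"hidden_orf"`, `"intein_like"`,
#'   `"group1_intron_like"`, `"group2_intron_like"`, `"inert"`.
#' @param insertion_len_nt Insertion length (multiple of 3 for the
#'   seamless classes).
#' @param orf_start_nt,orf_stop_nt 1-based first base of the start
#'   codon and last base of the stop codon of the planted
#'   alternate-frame ORF (hidden_orf class only).
#' @param start_codon Start codon for the planted ORF.
#' @param plant_hnh Plant an H-N-H residue triad in the ORF product.
#' @param plant_znf_pairs Number of CXX(X)C motif pairs to plant.
#' @param flank_mimicry For the `inert` class: probability that each
#'   of the first `window` host-frame residues of the insertion copies
#'   the corresponding C-flank residue.
#' @param terminal_motif Bases forced at the 3' end of the insertion
#'   (e.g. `"TAAC"`... the last base(s)); `NULL` for none.
#' @param first_stop_offset_nt For intron-like classes: bp offset of
#'   the last base of the first host-frame stop codon.
#' @param seed Integer seed recorded with the spec.
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(element_class = c("hidden_orf", "intein_like",
                                         "group1_intron_like",
                                         "group2_intron_like", "inert"),
                       insertion_len_nt = 606L,
                       orf_start_nt = 18L,
                       orf_stop_nt = insertion_len_nt - 1L,
                       start_codon = "GTG",
                       plant_hnh = TRUE,
                       plant_znf_pairs = 2L,
                       flank_mimicry = NA_real_,
                       terminal_motif = NULL,
                       first_stop_offset_nt = 30L,
                       seed = NULL) {
  element_class <- match.arg(element_class)
  L <- as.integer(insertion_len_nt)
  if (element_class %in% c("hidden_orf", "intein_like", "inert") &&
      L %% 3L != 0L) {
    stop("seamless classes need insertion_len_nt divisible by 3",
         call. = FALSE)
  }
  if (element_class == "hidden_orf") {
    a <- as.integer(orf_start_nt); b <- as.integer(orf_stop_nt)
    if ((b - a + 1L) %% 3L != 0L) {
      stop("ORF span (orf_stop_nt - orf_start_nt + 1) must be a ",
           "multiple of 3", call. = FALSE)
    }
    if (a < 1L || b > L) stop("ORF outside the insertion", call. = FALSE)
    P <- (b - a + 1L) %/% 3L - 1L
    if (P < 1L) stop("ORF too short for any product", call. = FALSE)
    if (plant_hnh && P < 90L) {
      stop("product too short to plant an HNH triad (need >= 90 aa)",
           call. = FALSE)
    }
    if (plant_znf_pairs > 0L && P < 106L) {
      stop("product too short to plant zinc-finger pairs alongside ",
           "the HNH triad (need >= 106 aa)", call. = FALSE)
    }
  }
  structure(list(element_class = element_class,
                 insertion_len_nt = L,
                 orf_start_nt = as.integer(orf_start_nt),
                 orf_stop_nt = as.integer(orf_stop_nt),
                 start_codon = toupper(start_codon),
                 plant_hnh = isTRUE(plant_hnh),
                 plant_znf_pairs = as.integer(plant_znf_pairs),
                 flank_mimicry = flank_mimicry,
                 terminal_motif = terminal_motif,
                 first_stop_offset_nt = as.integer(first_stop_offset_nt),
                 seed = seed),
            class = "plant_spec")
}

# ---- constrained construction engine ---------------------------------

# integer base encoding A=0 C=1 G=2 T=3; codon id = 16*b1 + 4*b2 + b3
enc_base <- function(ch) match(ch, BASES) - 1L
dec_base <- function(i) BASES[i + 1L]
enc_codon <- function(codon) enc_base(strsplit(codon, "")[[1]])
codon_ids <- function(codons) {
  vapply(codons, function(cd) {
    b <- enc_codon(cd)
    16L * b[1] + 4L * b[2] + b[3]
  }, integer(1), USE.NAMES = FALSE)
}

# Build an insertion of length L subject to local constraints, by
# codon-wise construction plus randomized sweep repair: every sweep
# recomputes all violations (vectorized over integer-encoded codons)
# and mutates one mutable base (or synonymously resamples one ORF
# codon) inside each violating span.
#   orf: NULL or list(a, product_aa, start_codon, stop_codon)
#   fixed: list of list(pos = int vector, bases = char vector)
#   host_nonstop: host-frame codon indices that must not be stops
#   host_stop_at: host-frame codon index carrying a planted stop
#   host_pattern_free: aa regexes the host-frame translation must avoid
build_constrained <- function(L, orf = NULL, fixed = list(),
                              host_nonstop = integer(0),
                              host_stop_at = NULL,
                              forbid_5p_gtgcg = TRUE,
                              forbid_3p_g = TRUE,
                              host_pattern_free = character(0),
                              code = genetic_code(),
                              max_iter = 3000L) {
  stop_ids <- codon_ids(code$stop_codons)
  start_ids <- codon_ids(code$start_codons)
  aa_by_id <- character(64)
  for (cd in names(code$map)) aa_by_id[codon_ids(cd) + 1L] <- code$map[[cd]]
  syn <- lapply(stats::setNames(nm = unique(c(BG_AA, "H", "N", "C",
                                              "M", "W"))),
                function(r) lapply(codons_for(r, code), enc_codon))

  x <- sample.int(4L, L, replace = TRUE) - 1L
  owner <- integer(L)                    # 0 free, -1 fixed, t>0 ORF codon
  product_aa <- orf$product_aa
  aa_mutable <- orf$aa_mutable %||% rep(FALSE, length(product_aa))
  if (!is.null(orf)) {
    P <- length(orf$product_aa)
    for (t in seq_len(P)) {
      pos <- orf$a + 3L * (t - 1L) + 0:2
      if (t == 1L) {
        x[pos] <- enc_codon(orf$start_codon)
        owner[pos] <- -1L
      } else {
        cands <- syn[[orf$product_aa[t]]]
        x[pos] <- cands[[sample.int(length(cands), 1L)]]
        owner[pos] <- t
      }
    }
    spos <- orf$a + 3L * P + 0:2
    x[spos] <- enc_codon(orf$stop_codon)
    owner[spos] <- -1L
  }
  if (!is.null(host_stop_at)) {
    pos <- 3L * host_stop_at - 2:0
    x[pos] <- enc_codon(sample(code$stop_codons, 1L))
    owner[pos] <- -1L
  }
  for (f in fixed) {
    x[f$pos] <- enc_base(f$bases)
    owner[f$pos] <- -1L
  }

  hp <- seq.int(1L, L - 2L, by = 3L)               # host codon starts
  host_mask <- logical(length(hp))
  host_mask[host_nonstop] <- TRUE
  up_q <- if (!is.null(orf) && orf$a > 3L) {
    seq.int(((orf$a - 1L) %% 3L) + 1L, orf$a - 3L, by = 3L)
  } else integer(0)

  violations <- function() {
    v <- list()
    hc <- 16L * x[hp] + 4L * x[hp + 1L] + x[hp + 2L]
    bad <- which(host_mask & (hc %in% stop_ids))
    for (i in bad) v[[length(v) + 1L]] <- (3L * i - 2L):(3L * i)
    if (length(up_q)) {
      uc <- 16L * x[up_q] + 4L * x[up_q + 1L] + x[up_q + 2L]
      for (q in up_q[uc %in% start_ids]) {
        v[[length(v) + 1L]] <- q:(q + 2L)
      }
    }
    if (forbid_5p_gtgcg &&
        all(x[1:5] == c(2L, 3L, 2L, 1L, 2L))) {
      v[[length(v) + 1L]] <- 1:5
    }
    if (forbid_3p_g && x[L] == 2L) {
      v[[length(v) + 1L]] <- L
    }
    if (length(host_pattern_free)) {
      tr <- paste(aa_by_id[hc + 1L], collapse = "")
      for (p in host_pattern_free) {
        m <- regexpr(p, tr, perl = TRUE)
        if (m[1] != -1L) {
          s <- as.integer(m); e <- s + attr(m, "match.length") - 1L
          v[[length(v) + 1L]] <- (3L * (s - 1L) + 1L):(3L * e)
        }
      }
    }
    v
  }

  for (iter in seq_len(max_iter)) {
    v <- violations()
    if (!length(v)) {
      return(list(seq = paste(dec_base(x), collapse = ""),
                  owner = owner, product_aa = product_aa))
    }
    for (span in v) {
      mutable <- span[owner[span] >= 0L]
      if (!length(mutable)) {
        stop("unsatisfiable constraint: violation at positions ",
             span[1], "-", span[length(span)],
             " overlaps only fixed bases", call. = FALSE)
      }
      for (pos in mutable[sample.int(length(mutable))]) {
        if (owner[pos] == 0L) {
          x[pos] <- sample((0:3)[-(x[pos] + 1L)], 1L)
          break
        }
        t <- owner[pos]
        cpos <- orf$a + 3L * (t - 1L) + 0:2
        # background residues may be swapped outright: synonymous
        # moves alone cannot escape e.g. a fixed GTG start followed by
        # a residue whose codons all begin with A (host codon locked
        # at TGA)
        if (aa_mutable[t] && stats::runif(1) < 0.15) {
          product_aa[t] <- sample(setdiff(BG_AA, product_aa[t]), 1L)
          cands <- syn[[product_aa[t]]]
          x[cpos] <- cands[[sample.int(length(cands), 1L)]]
          break
        }
        cands <- syn[[product_aa[t]]]
        alt <- Filter(function(cd) any(cd != x[cpos]), cands)
        if (length(alt)) {
          x[cpos] <- alt[[sample.int(length(alt), 1L)]]
          break
        }
      }
    }
  }
  stop("generation failed: constraints not satisfied after ",
       max_iter, " repair sweeps (host stop-freedom vs planted ",
       "ORF layout)", call. = FALSE)
}

# positions of planted motifs within a product of length P
motif_layout <- function(P, plant_hnh, plant_znf_pairs) {
  lay <- list(hnh = NULL, znf = NULL)
  if (plant_hnh) {
    h1 <- max(24L, (P - 60L) %/% 2L)
    lay$hnh <- c(h1 = h1, n = h1 + 30L, h2 = h1 + 60L)
    if (lay$hnh[["h2"]] > P - 2L) stop("product too short for HNH triad")
  }
  if (plant_znf_pairs > 0L) {
    # pair 1 upstream of the triad, pair 2 downstream
    znf <- list()
    znf[[1]] <- data.frame(start = c(10L, 18L), end = c(13L, 22L),
                           type = c("CXXC", "CXXXC"))
    if (plant_znf_pairs >= 2L) {
      q <- lay$hnh[["h2"]] + 8L
      znf[[2]] <- data.frame(start = c(q, q + 10L),
                             end = c(q + 3L, q + 14L),
                             type = c("CXXC", "CXXXC"))
      if (q + 14L > P) stop("product too short for second zinc-finger pair")
    }
    lay$znf <- do.call(rbind, znf)
  }
  lay
}

# design the amino-acid product for a planted ORF
design_product <- function(P, start_aa, plant_hnh, plant_znf_pairs) {
  aa <- sample(BG_AA, P, replace = TRUE)
  aa[1L] <- start_aa
  lay <- motif_layout(P, plant_hnh, plant_znf_pairs)
  if (!is.null(lay$hnh)) {
    aa[lay$hnh[["h1"]]] <- "H"
    aa[lay$hnh[["n"]]] <- "N"
    aa[lay$hnh[["h2"]]] <- "H"
  }
  if (!is.null(lay$znf)) {
    for (i in seq_len(nrow(lay$znf))) {
      aa[lay$znf$start[i]] <- "C"
      aa[lay$znf$end[i]] <- "C"
    }
  }
  list(aa = aa, layout = lay)
}

#' Plant a hidden-ORF insertion element
#'
#' Builds an insertion whose host-frame reading is stop-free while an
#' alternate-frame ORF with the requested layout (start codon, stop
#' codon placement, planted HNH/zinc-finger motifs) is embedded in it.
#' The host-frame translation is additionally kept free of the intein
#' splicing-block patterns and of upstream in-frame start codons that
#' would displace the planted start as the primary ORF.
#'
#' @param spec A [plant_spec] with `element_class = "hidden_orf"`.
#' @param seed Integer seed (deterministic output for a given
#'   seed + spec).
#' @return List with `insertion` (a [nuc_seq]) and `truth` (class
#'   `truth_record`: layout, product string, motif coordinates, seed
#'   and parameters).
#' @export
plant_hidden_orf <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "plant_spec"),
            spec$element_class == "hidden_orf")
  code <- genetic_code()
  with_seed(seed, {
    L <- spec$insertion_len_nt
    a <- spec$orf_start_nt; b <- spec$orf_stop_nt
    P <- (b - a + 1L) %/% 3L - 1L
    start_aa <- unname(code$map[[spec$start_codon]])
    des <- design_product(P, start_aa, spec$plant_hnh,
                          spec$plant_znf_pairs)
    fixed <- list()
    if (!is.null(spec$terminal_motif)) {
      tm <- strsplit(toupper(spec$terminal_motif), "")[[1]]
      pos <- (L - length(tm) + 1L):L
      # only fix bases outside the ORF codons (the ORF stop codon may
      # be part of the terminal motif, e.g. TAA of TAAC)
      free_of_orf <- pos < a | pos > b
      fixed <- list(list(pos = pos[free_of_orf],
                         bases = tm[free_of_orf]))
    }
    aa_mutable <- rep(TRUE, P)
    aa_mutable[1L] <- FALSE
    if (!is.null(des$layout$hnh)) aa_mutable[des$layout$hnh] <- FALSE
    if (!is.null(des$layout$znf)) {
      aa_mutable[c(des$layout$znf$start, des$layout$znf$end)] <- FALSE
    }
    built <- build_constrained(
      L,
      orf = list(a = a, product_aa = des$aa,
                 start_codon = spec$start_codon, stop_codon = "TAA",
                 aa_mutable = aa_mutable),
      fixed = fixed,
      host_nonstop = seq_len(L %/% 3L),
      forbid_5p_gtgcg = TRUE,
      forbid_3p_g = TRUE,
      host_pattern_free = default_intein_patterns()$pattern,
      code = code)
    truth <- structure(list(
      element_class = "hidden_orf",
      insertion_len_nt = L,
      orf_start_nt = a,
      orf_stop_nt = b,
      start_codon = spec$start_codon,
      frame_index = relative_frame(a),
      product_len_aa = P,
      product = paste(built$product_aa, collapse = ""),
      hnh = des$layout$hnh,
      znf = des$layout$znf,
      seed = seed
    ), class = "truth_record")
    list(insertion = nuc_seq(built$seq, id = "planted_hidden_orf"),
         truth = truth)
  })
}

# stop-free reverse translation of an amino-acid vector
rev_translate <- function(aa, code = genetic_code()) {
  paste(vapply(aa, function(r) {
    cands <- codons_for(r, code)
    if (!length(cands)) stop("no codon for residue ", r)
    if (length(cands) == 1L) cands else sample(cands, 1L)
  }, character(1)), collapse = "")
}

# anti-matched random flank: differs from `ref` at every position
anti_flank <- function(ref) {
  paste(vapply(strsplit(ref, "")[[1]], function(r) {
    sample(setdiff(BG_AA, r), 1L)
  }, character(1)), collapse = "")
}

# ---- canonical fixtures ----------------------------------------------

# run fn over derived sub-seeds until it succeeds and verifies
retry_seeds <- function(seed, fn, verify = function(res) TRUE,
                        attempts = 50L) {
  last_err <- NULL
  for (k in seq_len(attempts)) {
    s <- if (is.null(seed)) NULL else sub_seed(seed, k - 1L)
    res <- tryCatch(fn(s), error = function(e) e)
    if (!inherits(res, "error")) {
      ok <- tryCatch(verify(res), error = function(e) FALSE)
      if (isTRUE(ok)) return(res)
      last_err <- simpleError("generated fixture failed verification")
    } else last_err <- res
  }
  stop("fixture generation failed after ", attempts, " attempts: ",
       conditionMessage(last_err), call. = FALSE)
}

#' Canonical hidden-ORF fixture (printed layout)
#'
#' A 606-nt insertion with GTG at 1-based positions 18-20, TAA at
#' 603-605 and terminal base C (so the last four bases read TAAC), a
#' stop-free host frame (202 aa in-frame product, ending on Asn by
#' construction of the TAAC terminus) and a stop-free frame-3 ORF from
#' the GTG to the TAA (195 aa product) carrying a planted H-N-H triad
#' and two CXX(X)C zinc-finger pairs.
#'
#' @param seed Integer seed; the same seed gives identical bytes.
#' @return List with `insertion` ([nuc_seq]), `truth`
#'   (`truth_record`), and flank context `c_flank_aa` (beginning with
#'   the splicing-friendly Thr that invaded hosts carry at +1) and
#'   `n_flank_aa`.
#' @export
make_shilan_fixture <- function(seed = NULL) {
  spec <- plant_spec("hidden_orf", insertion_len_nt = 606L,
                     orf_start_nt = 18L, orf_stop_nt = 605L,
                     start_codon = "GTG", plant_hnh = TRUE,
                     plant_znf_pairs = 2L, terminal_motif = "TAAC",
                     seed = seed)
  res <- retry_seeds(seed, function(s) {
    out <- plant_hidden_orf(spec, seed = s)
    with_seed(if (is.null(s)) NULL else s + 1L, {
      out$c_flank_aa <- paste0("T", paste(sample(BG_AA, 10L,
                                                 replace = TRUE),
                                          collapse = ""))
      out$n_flank_aa <- paste(sample(BG_AA, 11L, replace = TRUE),
                              collapse = "")
    })
    out
  }, verify = function(out) {
    top <- scan_hidden_orfs(out$insertion)[[1]]
    ct <- continuity_test(out$insertion)
    isTRUE(ct$seamless) && top$start_nt == 18L &&
      top$frame_index == 3L && top$product_len_aa == 195L
  })
  res
}

#' Intron-interrupted fixture (major-capsid-style group I intron)
#'
#' An insertion whose in-frame reading with the host gene hits its
#' first stop codon a fixed distance in (default 30 bp, the distance
#' at which a group I intron in a phage major capsid gene truncates
#' the host product) and whose final base is G, the classic group I
#' 3' signature.
#'
#' @param seed Integer seed.
#' @param insertion_len_nt Insertion length (default 402 nt, a
#'   realistic compact group I intron size).
#' @param first_stop_offset_nt Offset (bp, last base of the stop
#'   codon) of the first in-frame stop; must be a multiple of 3.
#' @return List with `insertion` and `truth`.
#' @export
make_littlee_fixture <- function(seed = NULL, insertion_len_nt = 402L,
                                 first_stop_offset_nt = 30L) {
  L <- as.integer(insertion_len_nt)
  off <- as.integer(first_stop_offset_nt)
  stopifnot(off %% 3L == 0L, off >= 3L, off <= L)
  k <- off %/% 3L
  res <- retry_seeds(seed, function(s) {
    with_seed(s, {
      built <- build_constrained(
        L,
        host_nonstop = seq_len(k - 1L),
        host_stop_at = k,
        fixed = list(list(pos = L, bases = "G")),
        forbid_5p_gtgcg = TRUE,
        forbid_3p_g = FALSE)
      truth <- structure(list(
        element_class = "group1_intron_like",
        insertion_len_nt = L,
        first_stop_offset_nt = off,
        terminal_base = "G",
        seed = s
      ), class = "truth_record")
      list(insertion = nuc_seq(built$seq, id = "intron_like_fixture"),
           truth = truth)
    })
  }, verify = function(out) {
    ct <- continuity_test(out$insertion)
    !ct$seamless && ct$first_stop_offset_nt == off &&
      intron_signature(out$insertion)$g_3prime
  })
  res
}

#' Second hidden-ORF fixture (divergent methylase layout)
#'
#' An insertion carrying a planted alternate-frame (frame 2) ORF whose
#' coding span including the stop codon is 483 nt, yielding a 160-aa
#' HNH-bearing product, with a seamless host frame -- the layout of
#' the second out-of-frame endonuclease insertion characterised in a
#' divergent phage DNA methylase.
#'
#' @param seed Integer seed.
#' @param insertion_len_nt Total insertion length (default 507 nt).
#' @return List with `insertion`, `truth` and flank context.
#' @export
make_pacc40_fixture <- function(seed = NULL, insertion_len_nt = 507L) {
  L <- as.integer(insertion_len_nt)
  a <- 11L                     # frame 2
  b <- a + 483L - 1L           # 483 coding nt including the stop
  stopifnot(b + 1L <= L, L %% 3L == 0L)
  spec <- plant_spec("hidden_orf", insertion_len_nt = L,
                     orf_start_nt = a, orf_stop_nt = b,
                     start_codon = "GTG", plant_hnh = TRUE,
                     plant_znf_pairs = 2L, seed = seed)
  retry_seeds(seed, function(s) {
    out <- plant_hidden_orf(spec, seed = s)
    out$insertion$id <- "planted_hidden_orf_frame2"
    with_seed(if (is.null(s)) NULL else s + 1L, {
      out$c_flank_aa <- paste0("P", paste(sample(BG_AA, 10L,
                                                 replace = TRUE),
                                          collapse = ""))
    })
    out
  }, verify = function(out) {
    top <- scan_hidden_orfs(out$insertion)[[1]]
    isTRUE(continuity_test(out$insertion)$seamless) &&
      top$start_nt == a && top$product_len_aa == 160L
  })
}

#' Intein-like fixture
#'
#' A seamless insertion whose in-frame translation is designed to
#' carry the intein hallmarks: an N-terminal nucleophile (Cys), a
#' TxxH block, a hydrophobic-His-Asn block, and an His-Asn C-terminal
#' dipeptide ending on the crucial terminal Asn.  Comes with a
#' C-flank starting with the splicing-required Thr at +1.
#'
#' @param seed Integer seed.
#' @param insertion_len_nt Length (multiple of 3; default 405 nt /
#'   135 aa, a compact mini-intein size).
#' @return List with `insertion`, `truth`, `c_flank_aa`.
#' @export
make_intein_fixture <- function(seed = NULL, insertion_len_nt = 405L) {
  L <- as.integer(insertion_len_nt)
  stopifnot(L %% 3L == 0L, L >= 120L)
  n_aa <- L %/% 3L
  retry_seeds(seed, function(s) {
    with_seed(s, {
      aa <- sample(BG_AA, n_aa, replace = TRUE)
      aa[1L] <- "C"                              # block A nucleophile
      aa[5:8] <- c("T", aa[6], aa[7], "H")       # TxxH (block B)
      mid <- n_aa %/% 2L
      aa[mid + 0:2] <- c("L", "H", "N")          # block F sketch
      aa[(n_aa - 1L):n_aa] <- c("H", "N")        # block G + terminal Asn
      cds <- rev_translate(aa)
      truth <- structure(list(
        element_class = "intein_like",
        insertion_len_nt = L,
        terminal_residue = "N",
        seed = s
      ), class = "truth_record")
      list(insertion = nuc_seq(cds, id = "intein_like_fixture"),
           truth = truth,
           c_flank_aa = paste0("T", paste(sample(BG_AA, 10L,
                                                 replace = TRUE),
                                          collapse = "")))
    })
  }, verify = function(out) {
    ct <- continuity_test(out$insertion)
    sig <- intein_signature(
      translate_seq(out$insertion, 0L),
      out$c_flank_aa)
    ct$seamless && sig$terminal$status == "asn" &&
      nrow(sig$motifs_found) >= 1L &&
      !intron_signature(out$insertion)$g_3prime &&
      !intron_signature(out$insertion)$gtgcg_5prime
  })
}

#' Group II intron-like fixture
#'
#' Begins with the group II 5' motif GTGCG, is interrupted (early
#' in-frame stop), does not end in G, and carries a C-flank that the
#' insertion head does not mimic.
#'
#' @param seed Integer seed.
#' @param insertion_len_nt Length (default 420 nt).
#' @return List with `insertion`, `truth`, `c_flank_aa`.
#' @export
make_group2_fixture <- function(seed = NULL, insertion_len_nt = 420L) {
  L <- as.integer(insertion_len_nt)
  retry_seeds(seed, function(s) {
    with_seed(s, {
      built <- build_constrained(
        L,
        host_nonstop = seq_len(9L),
        host_stop_at = 10L,
        fixed = list(list(pos = 1:5,
                          bases = c("G", "T", "G", "C", "G"))),
        forbid_5p_gtgcg = FALSE,
        forbid_3p_g = TRUE)
      head_aa <- as.character(translate_seq(
        substr(built$seq, 1L, 33L), 0L, stop_policy = "mark"))
      head_aa <- gsub("\\*", "A", head_aa)  # only for anti-matching
      truth <- structure(list(
        element_class = "group2_intron_like",
        insertion_len_nt = L,
        first_stop_offset_nt = 30L,
        seed = s
      ), class = "truth_record")
      list(insertion = nuc_seq(built$seq, id = "group2_intron_fixture"),
           truth = truth,
           c_flank_aa = anti_flank(head_aa))
    })
  }, verify = function(out) {
    sig <- intron_signature(out$insertion)
    sig$gtgcg_5prime && !sig$g_3prime &&
      !continuity_test(out$insertion)$seamless
  })
}

#' One synthetic element fixture of a given class
#'
#' Dispatcher used by the benchmark generator: returns an insertion,
#' its truth record and enough flank context to run the full evidence
#' chain.
#'
#' @param element_class Fixture class.
#' @param seed Integer seed.
#' @return List with `insertion`, `truth`, and (class-dependent)
#'   `c_flank_aa`.
#' @export
make_element_fixture <- function(element_class = c("hidden_orf",
                                                   "intein_like",
                                                   "group1_intron_like",
                                                   "group2_intron_like"),
                                 seed = NULL) {
  element_class <- match.arg(element_class)
  switch(element_class,
    hidden_orf = {
      out <- make_shilan_fixture(seed)
      # benchmark hidden-ORF fixtures get the uninvaded-style proline
      # +1 flank, exercising the proline flag
      out$c_flank_aa <- paste0("P", substr(out$c_flank_aa, 2L, 11L))
      out
    },
    intein_like = make_intein_fixture(seed),
    group1_intron_like = {
      out <- make_littlee_fixture(seed)
      out$c_flank_aa <- ""
      out
    },
    group2_intron_like = make_group2_fixture(seed)
  )
}

# minimal insertion_locus stand-in for a pre-extracted insertion
standalone_locus <- function(insertion, c_flank_aa = "",
                             host_id = insertion$id) {
  n <- nchar(insertion)
  structure(list(
    host_id = host_id,
    aa_start = 1L, aa_end = n %/% 3L,
    nt_start = 1L, nt_end = n,
    insertion_nt = insertion,
    insertion_aa = translate_seq(insertion, 0L, stop_policy = "mark"),
    host_cds = as.character(insertion),
    host_protein = as.character(translate_seq(insertion, 0L,
                                              stop_policy = "mark")),
    aln_cols = c(NA_integer_, NA_integer_),
    c_flank_aa = c_flank_aa,
    c_flank_nt = NULL,
    n_flank_aa = "",
    phase_warning = n %% 3L != 0L,
    flags = if (nzchar(c_flank_aa)) character(0) else "c_flank_empty"
  ), class = "insertion_locus")
}

#' Four-class synthetic classification benchmark
#'
#' Generates `n_per_class` fixtures for each of the four element
#' classes under a deterministic seed stream and returns fixtures plus
#' truth labels, for measuring classification accuracy.
#'
#' @param n_per_class Fixtures per class.
#' @param seed Master seed.
#' @return Data-frame-free list: each entry has `fixture`, `truth_label`.
#' @export
make_element_benchmark <- function(n_per_class = 50L, seed = 1L) {
  classes <- c("hidden_orf", "intein_like", "group1_intron_like",
               "group2_intron_like")
  out <- list()
  i <- 0L
  for (cl in classes) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1L
      out[[i]] <- list(
        fixture = make_element_fixture(cl, seed = sub_seed(seed,
                                                           i * 101L)),
        truth_label = cl)
    }
  }
  out
}

# ---- host-gene families ----------------------------------------------

# apply per-codon substitutions: synonymous with prob `rate`,
# nonsynonymous with prob `rate * nonsyn_frac` (never creating stops)
mutate_cds <- function(cds, rate, nonsyn_frac = 0.25,
                       code = genetic_code()) {
  if (rate <= 0) return(cds)
  codons <- codon_split(cds)
  for (i in seq_along(codons)) {
    r <- stats::runif(1)
    if (r < rate * nonsyn_frac) {
      aa_new <- sample(BG_AA, 1L)
      codons[i] <- sample(codons_for(aa_new, code), 1L)
    } else if (r < rate) {
      syn <- setdiff(codons_for(code$map[[codons[i]]], code), codons[i])
      if (length(syn)) codons[i] <- sample(syn, 1L)
    }
  }
  paste(codons, collapse = "")
}

# inert insertion: stop-free host frame, optional flank mimicry over
# the first `window` residues
build_inert_insertion <- function(L, c_flank_aa, mimicry, window = 11L,
                                  code = genetic_code()) {
  n_aa <- L %/% 3L
  aa <- sample(BG_AA, n_aa, replace = TRUE)
  if (!is.na(mimicry) && nzchar(c_flank_aa)) {
    fl <- strsplit(c_flank_aa, "")[[1]]
    w <- min(window, n_aa, length(fl))
    for (i in seq_len(w)) {
      aa[i] <- if (stats::runif(1) < mimicry) fl[i]
               else sample(setdiff(BG_AA, fl[i]), 1L)
    }
  }
  rev_translate(aa, code)
}

#' Generate a host-gene family with planted insertions
#'
#' Emulates a family of homologous phage coding genes, some invaded by
#' an insertion element and some not: a stop-free ancestral CDS,
#' per-member substitution noise (synonymous-biased, site-independent,
#' no indels outside the planted insertions), and an insertion of the
#' requested class planted between two codons at the same position in
#' every invaded member.  A protein alignment and per-member truth
#' records are emitted alongside.
#'
#' @param n_invaded,n_uninvaded Family composition (each >= 1 for the
#'   mapper to work).
#' @param gene_len_aa Host gene length in residues (>= 100).
#' @param divergence Per-codon substitution probability in `[0, 0.5)`.
#' @param seed Master seed: same seed, byte-identical family.
#' @param element_class Insertion class planted in invaded members.
#' @param insertion_len_nt Insertion length (default 606).
#' @param insert_after_aa Host residue after which the insertion sits
#'   (default: mid-gene).
#' @param flank_mimicry For `"inert"` insertions: per-position
#'   probability that the insertion head copies the C-flank residue.
#' @param window Flank window (residues).
#' @return List with `homologs` (a [homolog_set] with alignment),
#'   `truth` (list of `truth_record`, one per invaded member) and
#'   `params`.
#' @export
make_host_family <- function(n_invaded = 3L, n_uninvaded = 5L,
                             gene_len_aa = 250L, divergence = 0.05,
                             seed = NULL,
                             element_class = c("hidden_orf", "inert",
                                               "intein_like",
                                               "group1_intron_like",
                                               "group2_intron_like"),
                             insertion_len_nt = 606L,
                             insert_after_aa = NULL,
                             flank_mimicry = NA_real_,
                             window = 11L) {
  element_class <- match.arg(element_class)
  stopifnot(gene_len_aa >= 100L, divergence >= 0, divergence < 0.5,
            n_invaded >= 1L, n_uninvaded >= 1L)
  code <- genetic_code()
  if (is.null(insert_after_aa)) insert_after_aa <- gene_len_aa %/% 2L
  site <- as.integer(insert_after_aa)
  stopifnot(site >= window, site <= gene_len_aa - window)
  with_seed(seed, {
    anc_aa <- sample(BG_AA, gene_len_aa, replace = TRUE)
    # uninvaded hosts carry a proline at +1 of the insertion site;
    # invaded members get a splicing-friendly Thr there instead (the
    # "conversion track" the element brings along when invading)
    anc_aa[site + 1L] <- "P"
    anc_cds <- rev_translate(anc_aa, code)
    ids <- c(sprintf("invaded_%02d", seq_len(n_invaded)),
             sprintf("uninvaded_%02d", seq_len(n_uninvaded)))
    invaded_ids <- ids[seq_len(n_invaded)]
    uninvaded_ids <- setdiff(ids, invaded_ids)
    cds <- character(0)
    alignment <- character(0)
    truth <- list()
    ins_aa_len <- insertion_len_nt %/% 3L
    for (id in ids) {
      host <- mutate_cds(anc_cds, divergence, code = code)
      if (id %in% invaded_ids) {
        # conversion track: the +1 residue of an invaded host is Thr
        tcod <- sample(codons_for("T", code), 1L)
        substr(host, 3L * site + 1L, 3L * site + 3L) <- tcod
        host_prot <- as.character(translate_seq(host, 0L, code, "mark"))
        cf <- substr(host_prot, site + 1L, site + window)
        ins <- switch(element_class,
          hidden_orf = {
            fx <- retry_seeds(NULL, function(s) plant_hidden_orf(
              plant_spec("hidden_orf",
                         insertion_len_nt = insertion_len_nt,
                         orf_start_nt = 18L,
                         orf_stop_nt = insertion_len_nt - 1L,
                         terminal_motif = "TAAC"),
              seed = s), attempts = 20L)
            truth_rec <- fx$truth
            as.character(fx$insertion)
          },
          inert = {
            truth_rec <- structure(list(element_class = "inert",
                                        insertion_len_nt = insertion_len_nt,
                                        flank_mimicry = flank_mimicry),
                                   class = "truth_record")
            build_inert_insertion(insertion_len_nt, cf, flank_mimicry,
                                  window, code)
          },
          intein_like = {
            fx <- make_intein_fixture(
              seed = sample.int(1000000L, 1L),
              insertion_len_nt = insertion_len_nt)
            truth_rec <- fx$truth
            as.character(fx$insertion)
          },
          group1_intron_like = {
            fx <- make_littlee_fixture(
              seed = sample.int(1000000L, 1L),
              insertion_len_nt = insertion_len_nt)
            truth_rec <- fx$truth
            as.character(fx$insertion)
          },
          group2_intron_like = {
            fx <- make_group2_fixture(
              seed = sample.int(1000000L, 1L),
              insertion_len_nt = insertion_len_nt)
            truth_rec <- fx$truth
            as.character(fx$insertion)
          })
        full <- paste0(substr(host, 1L, 3L * site), ins,
                       substr(host, 3L * site + 1L, nchar(host)))
        cds[[id]] <- full
        prot_full <- as.character(translate_seq(full, 0L, code, "mark"))
        alignment[[id]] <- prot_full
        truth_rec$host_id <- id
        truth_rec$aa_start <- site + 1L
        truth_rec$aa_end <- site + nchar(ins) %/% 3L
        truth_rec$nt_start <- 3L * site + 1L
        truth_rec$nt_end <- 3L * site + nchar(ins)
        truth[[id]] <- truth_rec
      } else {
        cds[[id]] <- host
        prot <- as.character(translate_seq(host, 0L, code, "mark"))
        alignment[[id]] <- paste0(substr(prot, 1L, site),
                                  strrep("-", ins_aa_len),
                                  substr(prot, site + 1L, nchar(prot)))
      }
    }
    # intron-like insertions contain host-frame stops: translations of
    # invaded members then contain '*', which is fine for the aligned
    # protein strings used for block detection
    hs <- homolog_set(cds, invaded_ids, uninvaded_ids,
                      alignment = alignment, code = code)
    list(homologs = hs,
         truth = truth,
         params = list(n_invaded = n_invaded, n_uninvaded = n_uninvaded,
                       gene_len_aa = gene_len_aa, divergence = divergence,
                       element_class = element_class,
                       insertion_len_nt = insertion_len_nt,
                       insert_after_aa = site,
                       flank_mimicry = flank_mimicry, seed = seed))
  })
}
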