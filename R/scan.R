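.homeoscan_env <- new.env(parent = emptyenv())

# BLOSUM62 from Biostrings, plus a char-code lookup into its rows, cached.
.blosum62 <- function() {
  if (is.null(.homeoscan_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    storage.mode(m) <- "integer"
    lookup <- rep(-1L, 256L)
    lookup[utf8ToInt(paste(rownames(m), collapse = "")) + 1L] <-
      seq_len(nrow(m)) - 1L
    .homeoscan_env$blosum62 <- m
    .homeoscan_env$blosum62_lookup <- lookup
  }
  list(matrix = .homeoscan_env$blosum62,
       lookup = .homeoscan_env$blosum62_lookup)
}

#' Six-frame translation with coordinate maps
#'
#' Translates a nucleotide sequence in all six reading frames using the
#' standard genetic code.  Codons containing `N` (or any non-ACGT base)
#' translate to `X`; stop codons to `*`.
#'
#' @param dna a single nucleotide string (alphabet ACGTN, case-insensitive),
#'   length at least 3.
#' @return A list of six elements named `F0`,`F1`,`F2`,`R0`,`R1`,`R2`, each a
#'   list with `aa` (the translation), `strand` (`"+"` or `"-"`), and
#'   `frame` (0-2).  Residue `i` (0-based) of a frame maps back to forward-
#'   strand coordinates via [aa_span_to_genomic()].
#' @export
#' @examples
#' translate_six_frames("ATGGCC")$F0$aa  # "MA"
translate_six_frames <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  if (nchar(dna) < 3L) stop("sequence shorter than one codon")
  if (grepl("[^ACGTN]", dna)) {
    stop("non-IUPAC character in sequence (allowed: A, C, G, T, N)")
  }
  rc <- cpp_revcomp(dna)
  out <- list()
  for (f in 0:2) {
    out[[paste0("F", f)]] <- list(aa = cpp_translate(dna, f),
                                  strand = "+", frame = f)
    out[[paste0("R", f)]] <- list(aa = cpp_translate(rc, f),
                                  strand = "-", frame = f)
  }
  out
}

#' Map an amino-acid span in a reading frame to genomic coordinates
#'
#' @param aa_start,aa_end 0-based half-open residue interval within the
#'   frame translation.
#' @param strand `"+"` or `"-"`.
#' @param frame frame offset 0-2.
#' @param contig_length length of the contig in bp.
#' @return `c(start, end)`: 0-based half-open forward-strand interval.
#' @export
aa_span_to_genomic <- function(aa_start, aa_end, strand, frame,
                               contig_length) {
  if (strand == "+") {
    c(frame + 3 * aa_start, frame + 3 * aa_end)
  } else {
    c(contig_length - frame - 3 * aa_end,
      contig_length - frame - 3 * aa_start)
  }
}

#' Affine-gap local alignment of two peptide sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap penalties
#' (a gap of length L costs `gap_open + L * gap_extend`).  Percent identity
#' is computed over columns where both residues are non-gap.
#'
#' @param query_aa,target_aa peptide strings.
#' @param gap_open,gap_extend gap penalties (BLAST convention; defaults
#'   11/1).
#' @return A list with `score`, `identity_pct`, aligned strings `q_aln` /
#'   `t_aln` (with `-` for gaps), and 0-based half-open residue spans
#'   `q_start`,`q_end`,`t_start`,`t_end`.  A pair with no positive-scoring
#'   cell returns score 0 and empty alignment.
#' @export
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")$score
local_align <- function(query_aa, target_aa, gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(query_aa) > 0L, nchar(target_aa) > 0L)
  b <- .blosum62()
  cpp_local_align(toupper(query_aa), toupper(target_aa), b$matrix, b$lookup,
                  as.integer(gap_open), as.integer(gap_extend))
}

# Karlin-Altschul statistics with fixed gapped BLOSUM62 constants.
.ka_lambda <- 0.267
.ka_logK <- log(0.041)

.bitscore <- function(score) (.ka_lambda * score - .ka_logK) / log(2)

.evalue <- function(score, search_len, query_len) {
  search_len * query_len * 2^(-.bitscore(score))
}

.load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
      file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    g <- toupper(as.character(ss))
    names(g) <- sub("\\s.*$", "", names(ss))
    return(g)
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(toupper(genome))
  }
  stop("genome must be a FASTA path or a named character vector of contigs")
}

.empty_hits <- function() {
  df <- data.frame(contig = character(), start = integer(), end = integer(),
                   strand = character(), frame = integer(),
                   query_id = character(), family = character(),
                   score = integer(), bitscore = numeric(),
                   evalue = numeric(), identity_pct = numeric(),
                   q_start = integer(), q_end = integer(), aa = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("homeobox_hits", "data.frame")
  df
}

# Scan one translated frame of one contig against all queries.
.scan_frame <- function(aa, strand, frame, contig, contig_len, refset,
                        evalue_max, search_len, k, exhaustive) {
  queries <- refset$sequence
  aa_len <- nchar(aa)
  # seed windows per query: qi index, ws/we 0-based aa window bounds
  if (exhaustive) {
    qi <- seq_along(queries)
    ws <- rep(0L, length(queries))
    we <- rep(aa_len, length(queries))
  } else {
    seeds <- cpp_seed_positions(aa, queries, k)
    parts <- lapply(seq_along(queries), function(i) {
      pos <- seeds[[i]]
      if (length(pos) == 0L) return(NULL)
      qlen <- nchar(queries[i])
      brk <- which(diff(pos) > qlen)
      lo <- pos[c(1L, brk + 1L)]
      hi <- pos[c(brk, length(pos))]
      cbind(i, pmax(0L, lo - qlen - 5L),
            pmin(aa_len, hi + k + qlen + 5L))
    })
    parts <- do.call(rbind, parts)
    if (is.null(parts)) return(list())
    qi <- parts[, 1]
    ws <- parts[, 2]
    we <- parts[, 3]
  }
  b <- .blosum62()
  windows <- substring(aa, ws + 1L, we)
  rows <- lapply(seq_along(qi), function(g) {
    if (nchar(windows[g]) == 0L) return(NULL)
    qlen <- nchar(queries[qi[g]])
    al <- cpp_local_align(queries[qi[g]], windows[g], b$matrix, b$lookup,
                          11L, 1L)
    if (al$score <= 0L) return(NULL)
    ev <- .evalue(al$score, search_len, qlen)
    if (ev > evalue_max) return(NULL)
    span <- aa_span_to_genomic(ws[g] + al$t_start, ws[g] + al$t_end,
                               strand, frame, contig_len)
    data.frame(
      contig = contig, start = span[1], end = span[2], strand = strand,
      frame = frame, query_id = refset$id[qi[g]],
      family = refset$family[qi[g]], score = al$score,
      bitscore = .bitscore(al$score), evalue = ev,
      identity_pct = al$identity_pct, q_start = al$q_start,
      q_end = al$q_end, aa = gsub("-", "", al$t_aln, fixed = TRUE),
      stringsAsFactors = FALSE)
  })
  rows[!vapply(rows, is.null, logical(1))]
}

#' Scan a genome for candidate homeobox loci
#'
#' Six-frame translated local alignment of every reference homeodomain
#' against every contig, emulating a TBLASTN search.  Full dynamic
#' programming is gated by an exact 4-mer amino-acid seed prefilter unless
#' `exhaustive = TRUE`.  E-values are computed from the alignment bitscore
#' via Karlin-Altschul statistics with fixed gapped-BLOSUM62 constants
#' (lambda = 0.267, K = 0.041) and search space = total genome length x
#' query length.
#'
#' @param genome FASTA path or named character vector of contig sequences.
#' @param refset a [reference_set()].
#' @param evalue_max E-value threshold (default `1e-5`).
#' @param k seed k-mer length (default 4).
#' @param exhaustive force full DP of every query against every frame
#'   (no seeding); slow, for validation.
#' @return A `homeobox_hits` data.frame: `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `frame`, `query_id`, `family`, `score`,
#'   `bitscore`, `evalue`, `identity_pct`, `q_start`, `q_end`, `aa`
#'   (translated matched sequence).
#' @export
scan_genome <- function(genome, refset, evalue_max = 1e-5, k = 4,
                        exhaustive = FALSE) {
  stopifnot(inherits(refset, "reference_set"))
  g <- .load_genome(genome)
  if (length(g) == 0L || sum(nchar(g)) == 0L) {
    warning("empty genome: no sequence to scan")
    return(.empty_hits())
  }
  search_len <- sum(nchar(g))
  rows <- list()
  for (ctg in names(g)) {
    dna <- g[[ctg]]
    if (nchar(dna) < 3L) next
    frames <- translate_six_frames(dna)
    for (fr in frames) {
      rows <- c(rows, .scan_frame(fr$aa, fr$strand, fr$frame, ctg,
                                  nchar(dna), refset, evalue_max,
                                  search_len, k, exhaustive))
    }
  }
  if (length(rows) == 0L) return(.empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[!duplicated(hits[c("contig", "start", "end", "strand",
                                  "frame", "query_id")]), , drop = FALSE]
  hits <- hits[order(hits$contig, hits$start, hits$end, hits$query_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("homeobox_hits", "data.frame")
  hits
}

#' Merge overlapping hits into loci
#'
#' Hits whose genomic intervals overlap by at least 1 bp (either strand)
#' are grouped by transitive closure into a single locus.  The
#' representative hit is the longest aligned genomic span, ties broken by
#' higher score then lexicographic query id.
#'
#' @param hits a `homeobox_hits` data.frame from [scan_genome()].
#' @return A `homeobox_loci` data.frame, one row per locus, carrying the
#'   representative hit's coordinates, query, family, score and translated
#'   sequence plus `n_hits` (supporting hits) and the merged component
#'   interval `region_start`/`region_end`.  Loci are mutually
#'   non-overlapping.
#' @export
merge_overlapping_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    df <- cbind(.empty_hits()[0, ],
                data.frame(locus_id = character(), n_hits = integer(),
                           region_start = integer(),
                           region_end = integer()))
    class(df) <- c("homeobox_loci", "data.frame")
    return(df)
  }
  hits <- hits[order(hits$contig, hits$start, hits$end), , drop = FALSE]
  loci <- list()
  for (ctg in unique(hits$contig)) {
    h <- hits[hits$contig == ctg, , drop = FALSE]
    run_end <- cummax(h$end)
    # new component where interval starts at/after the running max end
    comp <- cumsum(c(TRUE, h$start[-1] >= run_end[-nrow(h)]))
    for (cid in unique(comp)) {
      hc <- h[comp == cid, , drop = FALSE]
      len <- hc$end - hc$start
      ord <- order(-len, -hc$score, hc$query_id)
      rep_hit <- hc[ord[1], , drop = FALSE]
      rep_hit$locus_id <- sprintf("%s:%d-%d", ctg, rep_hit$start,
                                  rep_hit$end)
      rep_hit$n_hits <- nrow(hc)
      rep_hit$region_start <- min(hc$start)
      rep_hit$region_end <- max(hc$end)
      loci[[length(loci) + 1L]] <- rep_hit
    }
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("homeobox_loci", "data.frame")
  out
}

#' Rescan locus flanks at a permissive threshold
#'
#' Re-aligns the reference set against each locus extended by `flank` bp on
#' either side (clamped at contig ends) with a permissive E-value cutoff,
#' recovering tandem neighbours missed by the primary scan.  Only hits that
#' do not overlap an existing locus region are returned, for a second merge
#' round.
#'
#' @param genome as in [scan_genome()].
#' @param loci `homeobox_loci` from [merge_overlapping_hits()].
#' @param refset a [reference_set()].
#' @param flank flank size in bp (default 1000).
#' @param evalue_max permissive threshold for the rescan (default `1e-3`).
#' @param k seed k-mer length.
#' @return A `homeobox_hits` data.frame of newly found hits (possibly
#'   empty).
#' @export
rescan_flanks <- function(genome, loci, refset, flank = 1000,
                          evalue_max = 1e-3, k = 4) {
  g <- .load_genome(genome)
  search_len <- sum(nchar(g))
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    ctg <- loci$contig[i]
    L <- nchar(g[[ctg]])
    ws <- max(0L, loci$region_start[i] - as.integer(flank))
    we <- min(L, loci$region_end[i] + as.integer(flank))
    sub <- substr(g[[ctg]], ws + 1L, we)
    if (nchar(sub) < 3L) next
    frames <- translate_six_frames(sub)
    for (fr in frames) {
      sub_rows <- .scan_frame(fr$aa, fr$strand, fr$frame, ctg, nchar(sub),
                              refset, evalue_max, search_len, k, FALSE)
      for (r in sub_rows) {
        r$start <- r$start + ws
        r$end <- r$end + ws
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  if (length(rows) == 0L) return(.empty_hits())
  new_hits <- do.call(rbind, rows)
  # drop hits overlapping any existing locus region on the same contig
  keep <- vapply(seq_len(nrow(new_hits)), function(i) {
    l <- loci[loci$contig == new_hits$contig[i], , drop = FALSE]
    !any(new_hits$start[i] < l$region_end & new_hits$end[i] > l$region_start)
  }, logical(1))
  new_hits <- new_hits[keep, , drop = FALSE]
  new_hits <- new_hits[!duplicated(new_hits[c("contig", "start", "end",
                                              "strand", "frame",
                                              "query_id")]), , drop = FALSE]
  rownames(new_hits) <- NULL
  class(new_hits) <- c("homeobox_hits", "data.frame")
  new_hits
}

#' Full two-round homeobox locus discovery
#'
#' Runs [scan_genome()], merges overlapping hits, rescans 1-kb flanks at a
#' permissive threshold, and merges again.
#'
#' @inheritParams rescan_flanks
#' @param evalue_max primary scan threshold (default `1e-5`).
#' @param rescan_evalue flank rescan threshold (default `1e-3`).
#' @return A list with `hits` (all retained raw hits) and `loci`
#'   (`homeobox_loci` after the second merge round).
#' @export
find_homeobox_loci <- function(genome, refset, evalue_max = 1e-5,
                               flank = 1000, rescan_evalue = 1e-3, k = 4) {
  hits <- scan_genome(genome, refset, evalue_max = evalue_max, k = k)
  loci <- merge_overlapping_hits(hits)
  if (nrow(loci) > 0L) {
    extra <- rescan_flanks(genome, loci, refset, flank = flank,
                           evalue_max = rescan_evalue, k = k)
    if (nrow(extra) > 0L) {
      hits <- rbind(hits, extra)
      loci <- merge_overlapping_hits(hits)
    }
  }
  list(hits = hits, loci = loci)
}

#' @export
print.homeobox_loci <- function(x, ...) {
  cat("Candidate homeobox loci:", nrow(x), "on",
      length(unique(x$contig)), "contig(s)\n")
  if (nrow(x) > 0) print(as.data.frame(x[, c("locus_id", "strand", "family",
                                             "identity_pct", "evalue")]))
  invisible(x)
}
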