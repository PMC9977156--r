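#' Simulation configuration
#'
#' Defines a seeded synthetic genome: background base composition, the Hox
#' cluster plan (gene order per the canonical lepidopteran order, lognormal
#' intergenic gaps), Shx tandem-array copy numbers and divergence, the
#' displaced `lab` position, optional NK and hbn-Rx-otp clusters on their
#' own contigs, and an interspersed-repeat plan per TE class with an
#' optional Shx-region density multiplier.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param gc background GC fraction (default 0.37).
#' @param gap_meanlog,gap_sdlog lognormal intergenic-gap parameters for the
#'   Hox/NK/PRD clusters (default median 50 kb, sdlog 1, giving a Hox
#'   cluster span around 1.2 Mb).
#' @param array_gap_meanlog,array_gap_sdlog lognormal gap parameters inside
#'   tandem Shx arrays (default median 5 kb).
#' @param shx_copies named integer vector of copies per Shx family.
#' @param shx_divergence,hox_divergence per-copy amino-acid substitution
#'   fraction applied to planted domains (in `[0, 0.5]`).
#' @param lab_offset distance of `lab` beyond `Abd-B` in bp (default 7e6).
#' @param margin bp of plain background before the first and after the last
#'   planted feature.
#' @param clusters subset of `c("HOX", "NK", "PRD_TRIO")` to plant.
#' @param repeat_coverage named numeric: background coverage fraction per TE
#'   class.
#' @param shx_repeat_multiplier named numeric: density multiplier inside
#'   the Shx region per TE class.
#' @param repeat_len_range element length range in bp (uniform).
#' @param line_period when set, consecutive copies within a Shx tandem
#'   array are spaced by this many bp with a same-orientation LINE/CR1
#'   element planted centrally between them.
#' @param contig_length optional fixed length of the Hox contig; planted
#'   content exceeding it is an error.  `NULL` sizes the contig
#'   automatically.
#' @param refset optional [reference_set()] to draw planted domains from;
#'   by default a synthetic reference is generated.
#' @param n_ref_species species variants per family in the generated
#'   synthetic reference.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, gc = 0.37,
                       gap_meanlog = log(5e4), gap_sdlog = 1,
                       array_gap_meanlog = log(5e3), array_gap_sdlog = 0.3,
                       shx_copies = c(ShxA = 1, ShxB = 1, ShxC = 1,
                                      ShxD = 1),
                       shx_divergence = 0.05, hox_divergence = 0.05,
                       lab_offset = 7e6, margin = 5e4,
                       clusters = "HOX",
                       repeat_coverage = c(LINE = 0.05, SINE = 0.02,
                                           LTR = 0.02, DNA = 0.02),
                       shx_repeat_multiplier = c(LINE = 1, SINE = 1,
                                                 LTR = 1, DNA = 1),
                       repeat_len_range = c(80, 400),
                       line_period = NULL, contig_length = NULL,
                       refset = NULL, n_ref_species = 2) {
  stopifnot(gc > 0, gc < 1,
            shx_divergence >= 0, shx_divergence <= 0.5,
            hox_divergence >= 0, hox_divergence <= 0.5,
            all(shx_copies >= 0), lab_offset >= 0,
            all(clusters %in% c("HOX", "NK", "PRD_TRIO")))
  cfg <- list(seed = as.integer(seed), gc = gc, gap_meanlog = gap_meanlog,
              gap_sdlog = gap_sdlog, array_gap_meanlog = array_gap_meanlog,
              array_gap_sdlog = array_gap_sdlog, shx_copies = shx_copies,
              shx_divergence = shx_divergence,
              hox_divergence = hox_divergence, lab_offset = lab_offset,
              margin = margin, clusters = clusters,
              repeat_coverage = repeat_coverage,
              shx_repeat_multiplier = shx_repeat_multiplier,
              repeat_len_range = repeat_len_range,
              line_period = line_period, contig_length = contig_length,
              refset = refset, n_ref_species = n_ref_species)
  class(cfg) <- "sim_config"
  cfg
}

#' Mutate a homeodomain to a target divergence
#'
#' Substitutes exactly `round(fraction * nchar(aa))` positions, each to a
#' different residue; positions and replacement residues are drawn from the
#' current RNG stream, or from `seed` (restoring the caller's RNG state)
#' when given.
#'
#' @param aa amino-acid string.
#' @param fraction substitution fraction in `[0, 0.5]`.
#' @param seed optional integer seed for a self-contained draw.
#' @return The diverged sequence.
#' @export
mutate_domain <- function(aa, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 0.5)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  chars <- strsplit(aa, "")[[1]]
  n_mut <- round(fraction * length(chars))
  if (n_mut == 0L) return(aa)
  pos <- sample(length(chars), n_mut)
  alpha <- .aa_alphabet()
  for (p in pos) {
    chars[p] <- sample(setdiff(alpha, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Reverse-translate with synonymous codon choice weighted towards the
# target GC (weight proportional to gc^g * (1-gc)^(3-g), g = GC bases).
.reverse_translate <- function(aa, gc) {
  if (is.null(.homeoscan_env$syn_codons)) {
    code <- Biostrings::GENETIC_CODE
    .homeoscan_env$syn_codons <- split(names(code), unname(code))
  }
  syn <- .homeoscan_env$syn_codons
  chars <- strsplit(aa, "")[[1]]
  codons <- vapply(chars, function(r) {
    cands <- syn[[r]]
    g <- vapply(strsplit(cands, ""), function(b) sum(b %in% c("G", "C")),
                numeric(1))
    w <- gc^g * (1 - gc)^(3 - g)
    sample(cands, 1L, prob = w)
  }, character(1))
  paste(codons, collapse = "")
}

#' Generate a synthetic homeodomain reference set
#'
#' Draws an independent random 60-residue consensus per family and
#' `n_species` lightly diverged species variants of each.  Families are
#' therefore far better separated than real homeodomain families; see the
#' methods vignette for what that implies.
#'
#' @param families families to include (catalog names).
#' @param n_species variants per family.
#' @param within_divergence substitution fraction between variants of one
#'   family.
#' @return A [reference_set()].
#' @export
make_reference <- function(families, n_species = 2,
                           within_divergence = 0.03) {
  alpha <- .aa_alphabet()
  rows <- list()
  for (f in families) {
    consensus <- paste(sample(alpha, 60, replace = TRUE), collapse = "")
    for (s in seq_len(n_species)) {
      seqs <- if (s == 1) consensus else
        mutate_domain(consensus, within_divergence)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_sp%d", gsub("[^A-Za-z0-9]", "", f), s),
        family = f, species_tag = sprintf("sp%d", s), sequence = seqs,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  reference_set(df$id, df$family, df$species_tag, df$sequence)
}

.random_bases <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# Plan one cluster's gene placements; returns df(family,start,end,strand,
# divergence) in 0-based half-open coords, plus planted array LINEs.
.plan_cluster <- function(cfg, order_fams, shx_expand = FALSE) {
  gene_len <- 180L
  fams <- order_fams
  if (shx_expand) {
    fams <- unlist(lapply(order_fams, function(f) {
      if (f %in% names(cfg$shx_copies)) {
        rep(f, cfg$shx_copies[[f]])
      } else f
    }))
  }
  genes <- data.frame(family = fams, start = 0L, end = 0L,
                      strand = sample(c("+", "-"), length(fams),
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
  lines <- data.frame(start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  cursor <- cfg$margin
  for (i in seq_len(nrow(genes))) {
    genes$start[i] <- as.integer(cursor)
    genes$end[i] <- as.integer(cursor + gene_len)
    if (i < nrow(genes)) {
      same_array <- genes$family[i + 1] == genes$family[i] &&
        genes$family[i] %in% names(cfg$shx_copies)
      if (same_array && !is.null(cfg$line_period)) {
        gap <- as.integer(cfg$line_period)
        le_len <- 500L
        le_start <- genes$end[i] + (gap - le_len) %/% 2L
        lines <- rbind(lines, data.frame(start = le_start,
                                         end = le_start + le_len,
                                         strand = "+",
                                         stringsAsFactors = FALSE))
      } else if (same_array) {
        gap <- as.integer(round(rlnorm(1, cfg$array_gap_meanlog,
                                       cfg$array_gap_sdlog)))
      } else {
        gap <- as.integer(round(rlnorm(1, cfg$gap_meanlog, cfg$gap_sdlog)))
      }
      gap <- max(gap, 2000L)
      cursor <- genes$end[i] + gap
    }
  }
  list(genes = genes, lines = lines)
}

.sample_repeats <- function(cfg, contig, L, shx_region = NULL) {
  len_range <- cfg$repeat_len_range
  mean_len <- mean(len_range)
  fam_name <- c(LINE = "LINE/CR1", SINE = "SINE/tRNA", LTR = "LTR/Gypsy",
                DNA = "DNA/hAT")
  rows <- list()
  draw <- function(n, lo, hi, cls) {
    if (n <= 0L) return(NULL)
    lens <- as.integer(round(runif(n, len_range[1], len_range[2])))
    starts <- as.integer(floor(runif(n, lo, hi - lens)))
    data.frame(contig = contig, start = starts, end = starts + lens,
               te_class = cls, name = fam_name[[cls]],
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  for (cls in names(cfg$repeat_coverage)) {
    cov <- cfg$repeat_coverage[[cls]]
    rate <- cov / mean_len
    rows[[length(rows) + 1L]] <- draw(rpois(1, rate * L), 0, L, cls)
    mult <- cfg$shx_repeat_multiplier[[cls]]
    if (!is.null(shx_region) && !is.null(mult) && mult > 1) {
      extra_n <- rpois(1, rate * (mult - 1) * diff(shx_region))
      rows[[length(rows) + 1L]] <- draw(extra_n, shx_region[1],
                                        shx_region[2], cls)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(contig = character(), start = integer(),
                      end = integer(), te_class = character(),
                      name = character(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Generate a seeded synthetic genome with ground truth
#'
#' Builds contigs of i.i.d. background bases at the configured GC, plants
#' reverse-translated homeodomains (divergence applied at the amino-acid
#' level before reverse translation) following the canonical lepidopteran
#' Hox order with `lab` displaced beyond `Abd-B`, tandem Shx arrays with
#' optional interleaved same-orientation LINE elements, optional NK and
#' hbn-Rx-otp clusters on separate contigs, and a per-class Poisson
#' interspersed-repeat annotation with a Shx-region density multiplier.
#'
#' @param config a [sim_config()].
#' @return A `synthetic_genome`: list with `genome` (named character
#'   vector), `truth_genes` (family, contig, start, end, strand,
#'   divergence), `truth_repeats` (contig, start, end, te_class, name,
#'   strand), `refset`, `config`.  Identical configs give byte-identical
#'   output.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  co <- canonical_orders()
  need_fams <- character(0)
  if ("HOX" %in% config$clusters) need_fams <- c(need_fams, co$LEP_HOX,
                                                 "lab")
  if ("NK" %in% config$clusters) need_fams <- c(need_fams, unique(co$NK))
  if ("PRD_TRIO" %in% config$clusters) need_fams <- c(need_fams,
                                                      co$PRD_TRIO)
  refset <- config$refset
  if (is.null(refset)) {
    refset <- make_reference(unique(need_fams),
                             n_species = config$n_ref_species)
  }
  ref_seq <- function(f) refset$sequence[refset$family == f][1]

  genome <- character(0)
  truth_genes <- list()
  truth_repeats <- list()

  plant <- function(contig_name, genes, L) {
    bases <- .random_bases(L, config$gc)
    for (i in seq_len(nrow(genes))) {
      f <- genes$family[i]
      div <- if (f %in% c("ShxA", "ShxB", "ShxC", "ShxD")) {
        config$shx_divergence
      } else config$hox_divergence
      aa <- mutate_domain(ref_seq(f), div)
      dna <- .reverse_translate(aa, config$gc)
      if (genes$strand[i] == "-") dna <- cpp_revcomp(dna)
      bases[(genes$start[i] + 1L):genes$end[i]] <-
        strsplit(dna, "")[[1]]
      genes$divergence[i] <- div
    }
    genes$contig <- contig_name
    list(seq = paste(bases, collapse = ""), genes = genes)
  }

  if ("HOX" %in% config$clusters) {
    plan <- .plan_cluster(config, co$LEP_HOX, shx_expand = TRUE)
    genes <- plan$genes
    abdb_end <- max(genes$end)
    lab_start <- as.integer(abdb_end + config$lab_offset)
    genes <- rbind(genes, data.frame(family = "lab", start = lab_start,
                                     end = lab_start + 180L,
                                     strand = sample(c("+", "-"), 1),
                                     stringsAsFactors = FALSE))
    L_need <- max(genes$end) + config$margin
    L <- if (is.null(config$contig_length)) L_need else
      as.integer(config$contig_length)
    if (L < L_need) {
      stop("planted content (", L_need, " bp) exceeds contig length ", L)
    }
    p <- plant("chr_hox", genes, L)
    genome["chr_hox"] <- p$seq
    truth_genes[[length(truth_genes) + 1L]] <- p$genes
    shx <- genes[genes$family %in% names(config$shx_copies), , drop = FALSE]
    shx_region <- if (nrow(shx)) c(min(shx$start), max(shx$end)) else NULL
    reps <- .sample_repeats(config, "chr_hox", L, shx_region)
    if (nrow(plan$lines)) {
      reps <- rbind(reps, data.frame(contig = "chr_hox",
                                     start = plan$lines$start,
                                     end = plan$lines$end,
                                     te_class = "LINE", name = "LINE/CR1",
                                     strand = plan$lines$strand,
                                     stringsAsFactors = FALSE))
    }
    truth_repeats[[length(truth_repeats) + 1L]] <- reps
  }
  if ("NK" %in% config$clusters) {
    plan <- .plan_cluster(config, co$NK)
    L <- max(plan$genes$end) + config$margin
    p <- plant("chr_nk", plan$genes, L)
    genome["chr_nk"] <- p$seq
    truth_genes[[length(truth_genes) + 1L]] <- p$genes
  }
  if ("PRD_TRIO" %in% config$clusters) {
    plan <- .plan_cluster(config, co$PRD_TRIO)
    L <- max(plan$genes$end) + config$margin
    p <- plant("chr_prd", plan$genes, L)
    genome["chr_prd"] <- p$seq
    truth_genes[[length(truth_genes) + 1L]] <- p$genes
  }

  tg <- do.call(rbind, truth_genes)
  tg <- tg[, c("family", "contig", "start", "end", "strand", "divergence")]
  rownames(tg) <- NULL
  tr <- if (length(truth_repeats)) do.call(rbind, truth_repeats) else
    data.frame(contig = character(), start = integer(), end = integer(),
               te_class = character(), name = character(),
               strand = character(), stringsAsFactors = FALSE)
  rownames(tr) <- NULL
  out <- list(genome = genome, truth_genes = tg, truth_repeats = tr,
              refset = refset, config = config)
  class(out) <- "synthetic_genome"
  out
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome (seed ", x$config$seed, "): ",
      length(x$genome), " contig(s), ",
      sum(nchar(x$genome)), " bp, ", nrow(x$truth_genes),
      " planted genes, ", nrow(x$truth_repeats), " planted repeats\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic genome and its ground truth to disk
#'
#' Writes `genome.fa`, the reference FASTA, a ground-truth GFF3
#' (1-based, closed coordinates) of planted genes, a ground-truth repeat
#' BED, and a JSON echo of the configuration.
#'
#' @param sim a `synthetic_genome` from [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             reference = file.path(dir, "reference.fa"),
             truth_genes = file.path(dir, "truth_genes.gff3"),
             truth_repeats = file.path(dir, "truth_repeats.bed"),
             config = file.path(dir, "config.json"))
  dna <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(dna, paths["genome"])
  write_reference(sim$refset, paths["reference"])
  tg <- sim$truth_genes
  gr <- GenomicRanges::GRanges(
    seqnames = tg$contig,
    ranges = IRanges::IRanges(start = tg$start + 1L, end = tg$end),
    strand = tg$strand)
  gr$type <- "gene"
  gr$ID <- sprintf("%s_%d", tg$family, seq_len(nrow(tg)))
  gr$family <- tg$family
  gr$divergence <- tg$divergence
  rtracklayer::export(gr, paths["truth_genes"], format = "gff3")
  tr <- sim$truth_repeats
  if (nrow(tr)) {
    bed <- GenomicRanges::GRanges(
      seqnames = tr$contig,
      ranges = IRanges::IRanges(start = tr$start + 1L, end = tr$end),
      strand = tr$strand)
    bed$name <- tr$name
    rtracklayer::export(bed, paths["truth_repeats"], format = "bed")
  } else {
    file.create(paths["truth_repeats"])
  }
  cfg <- sim$config
  cfg$refset <- NULL
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(paths)
}
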