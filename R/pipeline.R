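# File-coupled pipeline stages.  Every table is TSV with a leading comment
# header declaring the coordinate convention; GFF3 output is 1-based
# closed.  Stages communicate only through files so each is independently
# testable and resumable.

.tsv_header <- "# coordinates: 0-based half-open"

.write_tsv <- function(df, path, header = .tsv_header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

.write_manifest <- function(outdir, stage, inputs, thresholds, seed = NULL) {
  manifest <- list(stage = stage, inputs = inputs, thresholds = thresholds,
                   seed = seed,
                   package_version =
                     as.character(packageVersion("homeoscan")))
  path <- file.path(outdir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

.loci_gff3 <- function(loci, path) {
  if (nrow(loci) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = loci$contig,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand)
  gr$type <- "homeobox_candidate"
  gr$ID <- loci$locus_id
  gr$family <- loci$family
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Run the simulate stage
#'
#' Writes a seeded synthetic genome, reference, ground truth and config to
#' `outdir` (see [simulate_genome()]).
#'
#' @param outdir output directory.
#' @param seed integer seed (ignored when `config` is supplied).
#' @param config optional [sim_config()].
#' @return The `synthetic_genome`, invisibly.
#' @export
run_simulate <- function(outdir, seed = 1, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  write_synthetic_genome(sim, outdir)
  .write_manifest(outdir, "simulate", inputs = list(),
                  thresholds = list(), seed = config$seed)
  invisible(sim)
}

#' Run the scan stage
#'
#' Two-round locus discovery ([find_homeobox_loci()]); writes `hits.tsv`,
#' `loci.tsv` and `loci.gff3` plus a JSON run manifest.
#'
#' @param genome genome FASTA path.
#' @param reference reference FASTA path.
#' @param outdir output directory.
#' @param evalue primary E-value threshold.
#' @param flank flank rescan size in bp.
#' @return The loci, invisibly.
#' @export
run_scan <- function(genome, reference, outdir, evalue = 1e-5,
                     flank = 1000) {
  if (!file.exists(genome)) stop("genome FASTA not found: ", genome)
  refset <- load_reference(reference)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- find_homeobox_loci(genome, refset, evalue_max = evalue,
                            flank = flank)
  .write_tsv(res$hits, file.path(outdir, "hits.tsv"))
  .write_tsv(res$loci, file.path(outdir, "loci.tsv"))
  .loci_gff3(res$loci, file.path(outdir, "loci.gff3"))
  .write_manifest(outdir, "scan",
                  inputs = list(genome = genome, reference = reference),
                  thresholds = list(evalue = evalue, flank = flank))
  invisible(res$loci)
}

#' Run the classify stage
#'
#' Reads `loci.tsv` from `outdir`, classifies every locus reciprocally and
#' writes `classification.tsv`, `divergent.fa` and `census.tsv`.
#'
#' @param outdir directory holding `loci.tsv` (outputs go there too).
#' @param reference reference FASTA path.
#' @param identity identity threshold in percent (strictly greater).
#' @return The `classified_loci`, invisibly.
#' @export
run_classify <- function(outdir, reference, identity = 70) {
  loci_path <- file.path(outdir, "loci.tsv")
  if (!file.exists(loci_path)) {
    stop("missing loci file: ", loci_path, " (run the scan stage first)")
  }
  refset <- load_reference(reference)
  loci <- .read_tsv(loci_path)
  class(loci) <- c("homeobox_loci", "data.frame")
  classified <- classify_loci(loci, refset, identity_min = identity)
  .write_tsv(classified, file.path(outdir, "classification.tsv"))
  export_divergent(classified, file.path(outdir, "divergent.fa"))
  cen <- census(classified)
  .write_tsv(cen$by_family, file.path(outdir, "census.tsv"),
             header = c("# assigned locus counts per family",
                        sprintf("# total=%d assigned=%d divergent=%d shx_total=%d zen_shx_total=%d",
                                cen$total, cen$n_assigned, cen$n_divergent,
                                cen$shx_total, cen$zen_shx_total)))
  .write_manifest(outdir, "classify",
                  inputs = list(loci = loci_path, reference = reference),
                  thresholds = list(identity = identity))
  invisible(classified)
}

#' Run the cluster stage
#'
#' Reads `classification.tsv`, builds Hox (and, when members are present,
#' NK and hbn-Rx-otp) architectures and writes per-cluster architecture
#' TSVs, a rearrangement report and the Shx copy table.
#'
#' @param outdir directory holding `classification.tsv`.
#' @return Named list of `cluster_architecture`s, invisibly.
#' @export
run_cluster <- function(outdir) {
  cls_path <- file.path(outdir, "classification.tsv")
  if (!file.exists(cls_path)) {
    stop("missing classification file: ", cls_path,
         " (run the classify stage first)")
  }
  classified <- .read_tsv(cls_path)
  class(classified) <- c("classified_loci", "data.frame")
  archs <- list()
  rear_rows <- list()
  for (cl in c("HOX", "NK", "PRD_TRIO")) {
    fams <- .cluster_families(cl)
    if (!any(classified$family[classified$status == "ASSIGNED"] %in%
             fams)) next
    arch <- if (cl == "PRD_TRIO") prd_trio(classified) else
      suppressWarnings(build_cluster(classified, cl))
    archs[[cl]] <- arch
    tab <- rbind(
      cbind(role = rep("member", nrow(arch$members)), arch$members),
      cbind(role = rep("external", nrow(arch$external_members)),
            arch$external_members))
    .write_tsv(tab, file.path(outdir,
                              sprintf("architecture_%s.tsv", cl)),
               header = c(.tsv_header,
                          sprintf("# cluster=%s contig=%s span_bp=%s", cl,
                                  arch$contig, arch$span_bp)))
    rep_ <- detect_rearrangements(arch)
    if (nrow(rep_$broken_adjacencies)) {
      rear_rows[[cl]] <- cbind(cluster = cl, rep_$broken_adjacencies)
    }
  }
  rear <- if (length(rear_rows)) do.call(rbind, rear_rows) else
    data.frame(cluster = character(), family1 = character(),
               family2 = character())
  .write_tsv(rear, file.path(outdir, "rearrangements.tsv"),
             header = "# broken canonical adjacencies")
  if (!is.null(archs$HOX)) {
    sct <- shx_copy_table(archs$HOX)
    .write_tsv(data.frame(family = names(sct$counts),
                          n = as.integer(sct$counts)),
               file.path(outdir, "shx_copies.tsv"),
               header = if (is.null(sct$shx_region)) {
                 "# shx_region=undefined"
               } else {
                 sprintf("# shx_region=%d-%d", sct$shx_region[1],
                         sct$shx_region[2])
               })
  }
  .write_manifest(outdir, "cluster", inputs = list(classification =
                                                     cls_path),
                  thresholds = list())
  invisible(archs)
}

# Rebuild a cluster_architecture object from an architecture TSV.
.read_architecture <- function(path, cluster_name) {
  tab <- .read_tsv(path)
  members <- tab[tab$role == "member",
                 c("family", "locus_id", "contig", "start", "end",
                   "strand"), drop = FALSE]
  external <- tab[tab$role == "external",
                  c("family", "locus_id", "contig", "start", "end",
                    "strand"), drop = FALSE]
  members <- members[order(members$start), , drop = FALSE]
  rownames(members) <- rownames(external) <- NULL
  core <- members[members$family != "lab", , drop = FALSE]
  arch <- list(cluster_name = cluster_name,
               contig = if (nrow(members)) members$contig[1] else
                 NA_character_,
               members = members,
               span_bp = if (nrow(core)) as.integer(max(core$end) -
                                                      min(core$start)) else
                 NA_integer_,
               intergenic_bp = if (nrow(core) > 1L) {
                 as.integer(pmax(0L, core$start[-1] -
                                   core$end[-nrow(core)]))
               } else integer(0),
               external_members = external)
  class(arch) <- "cluster_architecture"
  arch
}

#' Run the enrichment stage
#'
#' Reads the Hox architecture written by [run_cluster()] and a repeat
#' annotation, computes windowed TE densities and writes `enrichment.tsv`
#' plus a per-window density BED (`window_density.bed`).
#'
#' @param outdir directory holding `architecture_HOX.tsv`.
#' @param repeats repeat annotation path (BED or RepeatMasker `.out`).
#' @param window window size in bp.
#' @param alpha significance level.
#' @param m Bonferroni multiplicity.
#' @return The `enrichment_result`, invisibly.
#' @export
run_enrich <- function(outdir, repeats, window = 5000, alpha = 0.05,
                       m = 4) {
  arch_path <- file.path(outdir, "architecture_HOX.tsv")
  if (!file.exists(arch_path)) {
    stop("missing architecture file: ", arch_path,
         " (run the cluster stage first)")
  }
  arch <- .read_architecture(arch_path, "HOX")
  rep_ann <- load_repeats(repeats)
  enr <- shx_enrichment(rep_ann, arch, window = window, alpha = alpha,
                        m = m)
  .write_tsv(as.data.frame(enr), file.path(outdir, "enrichment.tsv"),
             header = "# Shx region vs remaining Hox cluster")
  w <- attr(enr, "windows")
  dens <- attr(enr, "densities")
  bed <- data.frame(contig = arch$contig, start = w$start, end = w$end,
                    name = ifelse(w$in_shx, "shx", "rest"),
                    score = round(dens$LINE, 5), strand = ".")
  .write_tsv(bed, file.path(outdir, "window_density.bed"),
             header = c("# coordinates: 0-based half-open (BED)",
                        "# score column: LINE density"))
  .write_manifest(outdir, "enrich",
                  inputs = list(architecture = arch_path,
                                repeats = repeats),
                  thresholds = list(window = window, alpha = alpha,
                                    bonferroni_m = m))
  invisible(enr)
}

#' Run the identity-contrast stage
#'
#' Reads per-family aligned homeodomain FASTA (headers `family|species`)
#' and a two-column species-group TSV (`species`, `group`, group `focal`
#' marking the focal clade) and writes `contrasts.tsv`.
#'
#' @param alignment aligned protein FASTA path.
#' @param groups species-group TSV path.
#' @param outdir output directory.
#' @return Data.frame of contrasts, invisibly.
#' @export
run_rates <- function(alignment, groups, outdir) {
  if (!file.exists(alignment)) stop("alignment FASTA not found: ",
                                    alignment)
  if (!file.exists(groups)) stop("species-group TSV not found: ", groups)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::readAAStringSet(alignment)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 2L)) {
    stop("alignment headers must be 'family|species'")
  }
  fam <- vapply(parts, `[`, "", 1L)
  sp <- vapply(parts, `[`, "", 2L)
  grp <- .read_tsv(groups)
  focal <- grp$species[grp$group == "focal"]
  rows <- lapply(unique(fam), function(f) {
    seqs <- setNames(as.character(aa[fam == f]), sp[fam == f])
    ct <- clade_contrast(align_fixed_length(seqs), focal, family = f)
    data.frame(family = f, n_focal_pairs = length(ct$focal_pairs),
               n_background_pairs = length(ct$background_pairs),
               median_focal = median(ct$focal_pairs),
               median_background = median(ct$background_pairs),
               U = ct$U, p_raw = ct$p_raw, significant = ct$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  .write_tsv(out, file.path(outdir, "contrasts.tsv"),
             header = "# pairwise-identity clade contrasts")
  .write_manifest(outdir, "rates",
                  inputs = list(alignment = alignment, groups = groups),
                  thresholds = list(alpha = 0.05))
  invisible(out)
}

#' Run scan, classify, cluster and (optionally) enrichment end to end
#'
#' @param outdir output directory.
#' @param genome genome FASTA path.
#' @param reference reference FASTA path.
#' @param repeats optional repeat annotation path; when given the
#'   enrichment stage runs too.
#' @param evalue,identity,flank,window,alpha,m stage thresholds.
#' @return Invisibly, a list with the classified loci and architectures.
#' @export
run_all <- function(outdir, genome, reference, repeats = NULL,
                    evalue = 1e-5, identity = 70, flank = 1000,
                    window = 5000, alpha = 0.05, m = 4) {
  run_scan(genome, reference, outdir, evalue = evalue, flank = flank)
  classified <- run_classify(outdir, reference, identity = identity)
  archs <- run_cluster(outdir)
  enr <- NULL
  if (!is.null(repeats)) {
    enr <- run_enrich(outdir, repeats, window = window, alpha = alpha,
                      m = m)
  }
  .write_manifest(outdir, "all",
                  inputs = list(genome = genome, reference = reference,
                                repeats = repeats),
                  thresholds = list(evalue = evalue, identity = identity,
                                    flank = flank, window = window,
                                    alpha = alpha, bonferroni_m = m))
  invisible(list(classified = classified, architectures = archs,
                 enrichment = enr))
}

#' Summarize a completed run as Markdown
#'
#' @param outdir directory holding stage outputs.
#' @return Path of `report.md`, invisibly.
#' @export
run_report <- function(outdir) {
  path <- file.path(outdir, "report.md")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# homeoscan run report", con)
  cen_path <- file.path(outdir, "census.tsv")
  if (file.exists(cen_path)) {
    cen <- .read_tsv(cen_path)
    cen <- cen[cen$n > 0, , drop = FALSE]
    writeLines(c("", "## Census (assigned loci per family)", "",
                 "| family | class | n |", "|---|---|---|",
                 sprintf("| %s | %s | %d |", cen$family, cen$hclass,
                         cen$n)), con)
  }
  for (cl in c("HOX", "NK", "PRD_TRIO")) {
    ap <- file.path(outdir, sprintf("architecture_%s.tsv", cl))
    if (!file.exists(ap)) next
    arch <- .read_architecture(ap, cl)
    writeLines(c("", sprintf("## %s cluster", cl), "",
                 sprintf("Contig `%s`, span %s bp, order: %s", arch$contig,
                         arch$span_bp,
                         paste(arch$members$family, collapse = " - "))),
               con)
  }
  enr_path <- file.path(outdir, "enrichment.tsv")
  if (file.exists(enr_path)) {
    enr <- .read_tsv(enr_path)
    writeLines(c("", "## Shx-region TE enrichment", "",
                 "| class | median Shx | median rest | p (Bonferroni) | enriched |",
                 "|---|---|---|---|---|",
                 sprintf("| %s | %.4f | %.4f | %.3g | %s |", enr$te_class,
                         enr$median_shx, enr$median_rest,
                         enr$p_bonferroni, enr$enriched)), con)
  }
  invisible(path)
}

.cli_usage <- function() {
  paste(
    "usage: homeoscan <subcommand> [--flag value ...]",
    "subcommands:",
    "  simulate --outdir DIR [--seed N]",
    "  scan     --genome FA --reference FA --outdir DIR [--evalue X] [--flank N]",
    "  classify --outdir DIR --reference FA [--identity X]",
    "  cluster  --outdir DIR",
    "  enrich   --outdir DIR --repeats PATH [--window N] [--alpha X] [--bonferroni-m N]",
    "  rates    --alignment FA --groups TSV --outdir DIR",
    "  all      --genome FA --reference FA --outdir DIR [--repeats PATH] [...]",
    "  report   --outdir DIR",
    sep = "\n")
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    if (i + 1L > length(args)) stop("missing value for ", args[i])
    key <- gsub("-", "_", substring(args[i], 3))
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.cli_need <- function(opts, keys) {
  for (k in keys) {
    if (is.null(opts[[k]])) {
      stop("missing required option --", gsub("_", "-", k))
    }
  }
}

#' Command-line entry point
#'
#' In-process dispatcher for the `homeoscan` subcommand interface (see the
#' thin Rscript wrapper in `inst/cli/`).  Validation errors print a message
#' and return exit code 2; success returns 0.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
homeoscan_cli <- function(args) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
    message(.cli_usage())
    return(invisible(if (length(args) == 0L) 2L else 0L))
  }
  sub <- args[1]
  known <- c("simulate", "scan", "classify", "cluster", "enrich", "rates",
             "all", "report")
  status <- tryCatch({
    if (!sub %in% known) stop("unknown subcommand: ", sub)
    opts <- .cli_opts(args[-1])
    num <- function(k, default) {
      if (is.null(opts[[k]])) default else as.numeric(opts[[k]])
    }
    switch(sub,
      simulate = {
        .cli_need(opts, "outdir")
        run_simulate(opts$outdir, seed = as.integer(num("seed", 1)))
      },
      scan = {
        .cli_need(opts, c("genome", "reference", "outdir"))
        run_scan(opts$genome, opts$reference, opts$outdir,
                 evalue = num("evalue", 1e-5), flank = num("flank", 1000))
      },
      classify = {
        .cli_need(opts, c("outdir", "reference"))
        run_classify(opts$outdir, opts$reference,
                     identity = num("identity", 70))
      },
      cluster = {
        .cli_need(opts, "outdir")
        run_cluster(opts$outdir)
      },
      enrich = {
        .cli_need(opts, c("outdir", "repeats"))
        run_enrich(opts$outdir, opts$repeats,
                   window = num("window", 5000),
                   alpha = num("alpha", 0.05),
                   m = num("bonferroni_m", 4))
      },
      rates = {
        .cli_need(opts, c("alignment", "groups", "outdir"))
        run_rates(opts$alignment, opts$groups, opts$outdir)
      },
      all = {
        .cli_need(opts, c("genome", "reference", "outdir"))
        run_all(opts$outdir, opts$genome, opts$reference,
                repeats = opts$repeats, evalue = num("evalue", 1e-5),
                identity = num("identity", 70),
                flank = num("flank", 1000), window = num("window", 5000),
                alpha = num("alpha", 0.05), m = num("bonferroni_m", 4))
      },
      report = {
        .cli_need(opts, "outdir")
        run_report(opts$outdir)
      })
    0L
  }, error = function(e) {
    message("homeoscan ", sub, ": ", conditionMessage(e))
    2L
  })
  invisible(status)
}
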