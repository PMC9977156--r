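.te_class_of <- function(name) {
  cls <- sub("/.*$", "", name)
  ifelse(cls %in% c("LINE", "SINE", "LTR", "DNA"), cls, "other")
}

#' Load a repeat annotation from BED or RepeatMasker ".out"
#'
#' Format is auto-detected: a RepeatMasker `.out` table (whitespace-aligned,
#' with its standard two-line header) or a BED file with the repeat
#' class/family in the name column.  The TE class is the prefix of the
#' class/family field before `"/"` (`LINE/CR1` is a LINE); anything outside
#' LINE/SINE/LTR/DNA becomes `other`.  Elements shorter than `min_len`
#' (default 50 bp) are dropped at load; the drop count is reported and kept
#' as attribute `n_dropped`.
#'
#' @param path annotation file path.
#' @param min_len minimum element length in bp.
#' @return A `repeat_annotation` data.frame: `contig`, `start`, `end`
#'   (0-based half-open), `te_class`, `name`, `strand`.
#' @export
load_repeats <- function(path, min_len = 50) {
  if (!file.exists(path)) stop("repeat annotation not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty repeat annotation: ", path)
  is_rm <- grepl("^\\s*SW\\s+perc", lines[1]) || grepl("\\.out$", path)
  if (is_rm) {
    body <- lines[!grepl("^\\s*SW\\s+perc|^\\s*score\\s+div", lines)]
    f <- strsplit(trimws(body), "\\s+")
    ok <- vapply(f, length, 1L) >= 11L
    f <- f[ok]
    if (length(f) == 0L) stop("no parsable rows in RepeatMasker file: ",
                              path)
    df <- data.frame(
      contig = vapply(f, `[`, "", 5L),
      start = as.integer(vapply(f, `[`, "", 6L)) - 1L,
      end = as.integer(vapply(f, `[`, "", 7L)),
      name = vapply(f, `[`, "", 10L),
      class_src = vapply(f, `[`, "", 11L),
      strand = ifelse(vapply(f, `[`, "", 9L) == "C", "-", "+"),
      stringsAsFactors = FALSE)
  } else {
    f1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(f1) < 4L || anyNA(suppressWarnings(as.integer(f1[2:3])))) {
      stop("unrecognized repeat annotation format: ", path)
    }
    tab <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#")
    df <- data.frame(
      contig = as.character(tab[[1]]), start = as.integer(tab[[2]]),
      end = as.integer(tab[[3]]), name = as.character(tab[[4]]),
      strand = if (ncol(tab) >= 6) as.character(tab[[6]]) else "+",
      stringsAsFactors = FALSE)
  }
  if (any(df$end <= df$start)) stop("repeat interval with end <= start")
  if (is.null(df$class_src)) df$class_src <- df$name
  df$te_class <- .te_class_of(df$class_src)
  short <- (df$end - df$start) < min_len
  if (any(short)) {
    message("dropped ", sum(short), " repeat element(s) below ", min_len,
            " bp")
  }
  df <- df[!short, c("contig", "start", "end", "te_class", "name",
                     "strand"), drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_dropped") <- sum(short)
  class(df) <- c("repeat_annotation", "data.frame")
  df
}

.tile_region <- function(region_start, region_end, window, from_right) {
  len <- region_end - region_start
  if (len < window / 2) {
    stop("region shorter than ", window / 2, " bp")
  }
  if (from_right) {
    ends <- seq(region_end, region_start + 1, by = -window)
    starts <- pmax(region_start, ends - window)
    w <- data.frame(start = rev(starts), end = rev(ends))
  } else {
    starts <- seq(region_start, region_end - 1, by = window)
    ends <- pmin(region_end, starts + window)
    w <- data.frame(start = starts, end = ends)
  }
  # terminal partial window kept only when at least half a window wide
  w[w$end - w$start >= window / 2, , drop = FALSE]
}

.window_coverage <- function(repeats, contig, windows, te_class) {
  rr <- repeats[repeats$contig == contig & repeats$te_class == te_class, ,
                drop = FALSE]
  cov <- numeric(nrow(windows))
  if (nrow(rr)) {
    ir <- IRanges::reduce(IRanges::IRanges(rr$start + 1L, rr$end))
    win <- IRanges::IRanges(windows$start + 1L, windows$end)
    ov <- IRanges::findOverlaps(win, ir)
    if (length(ov)) {
      inter <- IRanges::pintersect(win[S4Vectors::queryHits(ov)],
                                   ir[S4Vectors::subjectHits(ov)])
      widths <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      cov[as.integer(names(widths))] <- as.numeric(widths)
    }
  }
  cov
}

#' Per-window repeat density of one TE class
#'
#' Tiles the region with non-overlapping windows anchored at the region
#' start and computes, per window, the merged coverage of the given TE
#' class divided by the actual window width.  The terminal partial window
#' is kept only when at least half a window wide.
#'
#' @param repeats a `repeat_annotation`.
#' @param region `c(start, end)`, 0-based half-open.
#' @param te_class one of `"LINE"`, `"SINE"`, `"LTR"`, `"DNA"`, `"other"`.
#' @param window window size in bp (default 5000).
#' @param contig contig name; may be omitted when the annotation covers a
#'   single contig.
#' @return Numeric density vector in `[0, 1]`, with the window coordinates
#'   as attribute `windows`.
#' @export
window_density <- function(repeats, region, te_class, window = 5000,
                           contig = NULL) {
  if (is.null(contig)) {
    ctgs <- unique(repeats$contig)
    if (length(ctgs) > 1L) stop("multiple contigs present; supply `contig`")
    contig <- if (length(ctgs)) ctgs else NA_character_
  }
  w <- .tile_region(region[1], region[2], window, from_right = FALSE)
  cov <- .window_coverage(repeats, contig, w, te_class)
  dens <- cov / (w$end - w$start)
  attr(dens, "windows") <- w
  dens
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with the U statistic from midranks.  The
#' p-value is exact (full null distribution) when the pooled sample size is
#' at most 20 and there are no ties, otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return List with `U` and `p`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p  # exact two-sided 0.1
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  exact <- (length(x) + length(y) <= 20L) && !anyDuplicated(c(x, y))
  wt <- wilcox.test(x, y, alternative = alternative, exact = exact,
                    correct = TRUE)
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # degenerate case: all observations tied
  list(U = unname(wt$statistic), p = p)
}

.enrich_row <- function(te_class, dx, dy, m, alpha) {
  w <- wilcoxon_rank_sum(dx, dy)
  p_bonf <- min(1, w$p * m)
  data.frame(te_class = te_class, n_shx = length(dx), n_rest = length(dy),
             median_shx = median(dx), median_rest = median(dy), U = w$U,
             p_raw = w$p, p_bonferroni = p_bonf,
             enriched = p_bonf < alpha && median(dx) > median(dy),
             stringsAsFactors = FALSE)
}

#' TE-density enrichment in the Shx region of the Hox cluster
#'
#' For each of the four TE classes, compares per-window densities inside
#' the Shx region against the remaining Hox cluster (which already excludes
#' `lab`, reported externally) with a two-sided Wilcoxon rank-sum test and
#' Bonferroni correction over the TE classes.  A class is called enriched
#' when the corrected p-value is below `alpha` and the Shx median density
#' exceeds the rest median (direction gate).
#'
#' @param repeats a `repeat_annotation`.
#' @param arch a HOX `cluster_architecture` with at least one Shx locus.
#' @param window window size in bp (default 5000).
#' @param alpha significance level (default 0.05).
#' @param m Bonferroni multiplicity (default 4, the TE classes).
#' @param anchor `"ro"` (default) tiles windows from the cluster's ro-side
#'   edge; `"left"` from the leftmost coordinate.
#' @param te_classes TE classes to test.
#' @return An `enrichment_result` data.frame (one row per TE class) with
#'   the window densities attached as attribute `densities` and the window
#'   tiling as attribute `windows`.
#' @export
shx_enrichment <- function(repeats, arch, window = 5000, alpha = 0.05,
                           m = 4, anchor = c("ro", "left"),
                           te_classes = c("LINE", "SINE", "LTR", "DNA")) {
  stopifnot(inherits(arch, "cluster_architecture"))
  anchor <- match.arg(anchor)
  sct <- shx_copy_table(arch)
  if (is.null(sct$shx_region)) {
    stop("Shx region undefined: no Shx loci in the architecture")
  }
  core <- arch$members[arch$members$family != "lab", , drop = FALSE]
  region <- c(min(core$start), max(core$end))
  from_right <- FALSE
  if (anchor == "ro" && "ro" %in% core$family) {
    ro_mid <- mean(unlist(core[core$family == "ro", c("start", "end")]))
    from_right <- abs(ro_mid - region[2]) < abs(ro_mid - region[1])
  }
  w <- .tile_region(region[1], region[2], window, from_right)
  mid <- (w$start + w$end) / 2
  in_shx <- mid >= sct$shx_region[1] & mid < sct$shx_region[2]
  if (!any(in_shx) || all(in_shx)) {
    stop("window tiling does not separate Shx region from remaining cluster")
  }
  dens <- lapply(te_classes, function(cl) {
    cov <- .window_coverage(repeats, arch$contig, w, cl)
    cov / (w$end - w$start)
  })
  names(dens) <- te_classes
  rows <- lapply(te_classes, function(cl) {
    .enrich_row(cl, dens[[cl]][in_shx], dens[[cl]][!in_shx], m, alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "densities") <- dens
  attr(out, "windows") <- cbind(w, in_shx = in_shx)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Shx-region TE enrichment (", x$n_shx[1], "Shx vs", x$n_rest[1],
      "rest windows )\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
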