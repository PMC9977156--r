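#' Percent identity of two aligned sequences
#'
#' Identity is computed over columns where both residues are non-gap:
#' 100 x identical columns / comparable columns.
#'
#' @param seq_a,seq_b aligned amino-acid strings of equal length (`-` for
#'   gaps).
#' @return Percent identity in `[0, 100]`; `NA` (with a warning) when no
#'   column is comparable.
#' @export
#' @examples
#' pairwise_identity("HE-LO", "HEALO")  # 100: gap column excluded
pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length")
  }
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  comparable <- a != "-" & b != "-"
  if (!any(comparable)) {
    warning("no comparable (both non-gap) columns")
    return(NA_real_)
  }
  100 * mean(a[comparable] == b[comparable])
}

#' Clade contrast of pairwise homeodomain identities
#'
#' Tests whether a focal clade's homeodomains diverge faster than the
#' background for one gene family: every focal-vs-background pair identity
#' is compared against every background-vs-background pair identity with a
#' Wilcoxon rank-sum test (two-sided by default).
#'
#' @param alignment named character vector of aligned homeodomain
#'   sequences, one per species (equal lengths; `NA` entries are dropped
#'   with a warning).
#' @param focal_species species names forming the focal clade.
#' @param family optional family label carried into the result.
#' @param alternative passed to [wilcoxon_rank_sum()].
#' @param alpha significance level (default 0.05).
#' @return An `identity_contrast`: list with `family`, `focal_pairs`,
#'   `background_pairs` (identity vectors), `U`, `p_raw`, `significant`.
#' @export
clade_contrast <- function(alignment, focal_species, family = NA_character_,
                           alternative = "two.sided", alpha = 0.05) {
  if (is.null(names(alignment))) stop("alignment must be named by species")
  missing_seq <- is.na(alignment)
  if (any(missing_seq)) {
    warning("dropping species without a sequence: ",
            paste(names(alignment)[missing_seq], collapse = ", "))
    alignment <- alignment[!missing_seq]
  }
  focal <- names(alignment) %in% focal_species
  if (sum(focal) < 2L || sum(!focal) < 2L) {
    stop("need at least 2 focal and 2 background species ",
         "(insufficient pairs)")
  }
  foc <- alignment[focal]
  bg <- alignment[!focal]
  focal_pairs <- as.vector(outer(seq_along(foc), seq_along(bg),
                                 Vectorize(function(i, j) {
                                   pairwise_identity(foc[[i]], bg[[j]])
                                 })))
  bg_idx <- combn(length(bg), 2)
  background_pairs <- apply(bg_idx, 2, function(ij) {
    pairwise_identity(bg[[ij[1]]], bg[[ij[2]]])
  })
  w <- wilcoxon_rank_sum(focal_pairs, background_pairs,
                         alternative = alternative)
  out <- list(family = family, focal_pairs = focal_pairs,
              background_pairs = background_pairs, U = w$U, p_raw = w$p,
              significant = w$p < alpha)
  class(out) <- "identity_contrast"
  out
}

#' @export
print.identity_contrast <- function(x, ...) {
  cat("Identity contrast", if (!is.na(x$family)) paste0("(", x$family, ")"),
      ": focal median", round(median(x$focal_pairs), 1),
      "vs background median", round(median(x$background_pairs), 1),
      " p =", signif(x$p_raw, 3),
      if (x$significant) "(significant)" else "", "\n")
  invisible(x)
}

#' Gapless alignment of equal-length homeodomains
#'
#' Trivial fixed-length "aligner" for homeodomain sets that are already the
#' same length (the nominal 60-residue domain): verifies equal lengths and
#' returns the input unchanged.  Internal MSA construction is out of scope;
#' pre-aligned input is expected for anything else.
#'
#' @param seqs named character vector of equal-length sequences.
#' @return The input, validated.
#' @export
align_fixed_length <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences differ in length; supply a pre-aligned set")
  }
  seqs
}
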