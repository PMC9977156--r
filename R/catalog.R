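#' @useDynLib homeoscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate median rlnorm rpois runif setNames wilcox.test
#' @importFrom utils read.table write.table packageVersion combn
NULL

# Flat family taxonomy: every homeobox gene family tracked by the census,
# with its homeodomain class and Hox-cluster / Shx flags.  The 14 Hox and
# Hox-derived families are lab..Abd-B incl. zen and ShxA-D; ro is ANTP-class
# but not Hox-derived.
.family_table <- function() {
  antp_hox <- c("lab", "pb", "zen", "ShxA", "ShxB", "ShxC", "ShxD", "Dfd",
                "Scr", "Antp", "ftz", "Ubx", "abd-A", "Abd-B")
  antp_other <- c("ro", "ind", "cad", "exex", "eve", "unpg", "btn", "Tlx",
                  "Msx", "NK4", "NK3", "Lbx", "NK1", "Hmx", "Emx", "Hhex",
                  "NK7", "NK6", "Nedx", "Dlx", "En", "NK2.1", "Msxlx", "Hlx",
                  "NK2.2", "Barhl", "Bari", "Bsx", "Dbx", "Abox", "Noto")
  prd <- c("Uncx", "Gsc", "Pitx", "otp", "Rx", "hbn", "Repo", "Prrx", "Shox",
           "Arx", "Pax4/6", "Phox", "Prop", "Vsx", "CG11294", "Pax3/7",
           "Drgx", "Otx")
  lim <- c("Lhx6/8", "Lmx", "Lhx2/9", "Lhx3/4", "Lhx1/5", "Isl")
  pou <- c("Pou2", "Pou3", "Pou4", "Pou6")
  six <- c("Six3/6", "Six1/2", "Six4/5")
  tale <- c("Meis", "Irx", "Mkx", "Pbx", "Tgif")
  cut <- c("Onecut", "Cux", "Cmp")
  fam <- c(antp_hox, antp_other, prd, lim, pou, six, tale, cut,
           "Prox", "Zfhx", "Cers")
  hclass <- c(rep("ANTP", length(antp_hox) + length(antp_other)),
              rep("PRD", length(prd)), rep("LIM", length(lim)),
              rep("POU", length(pou)), rep("SINE", length(six)),
              rep("TALE", length(tale)), rep("CUT", length(cut)),
              "PROS", "ZF", "CERS")
  data.frame(
    family = fam,
    hclass = hclass,
    is_hox_cluster_member = fam %in% antp_hox,
    is_shx = fam %in% c("ShxA", "ShxB", "ShxC", "ShxD"),
    stringsAsFactors = FALSE
  )
}

#' Homeobox gene-family catalog
#'
#' Static table of homeobox gene families used for classification and
#' cluster analysis: family name, homeodomain class (ANTP, PRD, LIM, POU,
#' SINE, TALE, CUT, PROS, ZF, CERS), whether the family is one of the 14
#' Hox/Hox-derived cluster members (`lab` through `Abd-B`, including `zen`
#' and the four Shx families), and whether it is a Shx family.  `ro` is
#' ANTP-class but not a Hox-derived family.
#'
#' @return A data.frame with columns `family`, `hclass`,
#'   `is_hox_cluster_member`, `is_shx`.
#' @export
#' @examples
#' head(homeobox_families())
homeobox_families <- function() .family_table()

#' Write the family catalog as TSV
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_family_catalog <- function(path) {
  write.table(homeobox_families(), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Canonical gene-cluster orders
#'
#' Ordered family lists used as the baseline for rearrangement detection:
#' * `LEP_HOX`: the lepidopteran Hox cluster from `ro` (adjacent to `pb`,
#'   where `lab` sits in other insects) through `Abd-B`, with the four Shx
#'   families between `pb` and `zen`.  `lab` is external to this order,
#'   having been relocated far beyond `Abd-B`.
#' * `NK`: the NK cluster (`Tlx`, two `Msx`, `NK4`/tin, `NK3`/bap, `Lbx`,
#'   `NK1`/slou, `Hmx`, `Emx`).
#' * `PRD_TRIO`: the conserved `hbn`-`Rx`-`otp` neuronal PRD-class trio.
#'
#' @return Named list of character vectors.
#' @export
#' @examples
#' canonical_orders()$LEP_HOX[1:2]  # ro is adjacent to pb
canonical_orders <- function() {
  list(
    LEP_HOX = c("ro", "pb", "ShxA", "ShxB", "ShxC", "ShxD", "zen", "Dfd",
                "Scr", "Antp", "ftz", "Ubx", "abd-A", "Abd-B"),
    NK = c("Tlx", "Msx", "Msx", "NK4", "NK3", "Lbx", "NK1", "Hmx", "Emx"),
    PRD_TRIO = c("hbn", "Rx", "otp")
  )
}

.aa_alphabet <- function() c("A","R","N","D","C","Q","E","G","H","I","L","K",
                             "M","F","P","S","T","W","Y","V")

.validate_refset <- function(entries) {
  cat_fam <- homeobox_families()$family
  if (nrow(entries) == 0L) stop("reference set is empty")
  bad_fam <- !(entries$family %in% cat_fam)
  if (any(bad_fam)) {
    stop("unknown family name(s) in record(s): ",
         paste(entries$id[bad_fam], collapse = ", "))
  }
  dup <- duplicated(entries$id)
  if (any(dup)) {
    stop("duplicate record id(s): ",
         paste(unique(entries$id[dup]), collapse = ", "))
  }
  ok_alpha <- grepl("^[ARNDCQEGHILKMFPSTWYVX]+$", entries$sequence)
  if (!all(ok_alpha)) {
    stop("invalid amino-acid alphabet in record(s): ",
         paste(entries$id[!ok_alpha], collapse = ", "))
  }
  if (any(nchar(entries$sequence) < 30L)) {
    stop("reference homeodomains must be at least 30 aa; offending record(s): ",
         paste(entries$id[nchar(entries$sequence) < 30L], collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a homeodomain reference set
#'
#' @param id,family,species_tag,sequence parallel character vectors, one
#'   element per reference homeodomain.  Sequences are amino acids (20
#'   standard residues plus `X`), nominal length 60, minimum 30.
#' @return A `reference_set` object (data.frame with columns `id`, `family`,
#'   `species_tag`, `sequence`).
#' @export
reference_set <- function(id, family, species_tag, sequence) {
  entries <- data.frame(id = as.character(id), family = as.character(family),
                        species_tag = as.character(species_tag),
                        sequence = toupper(as.character(sequence)),
                        stringsAsFactors = FALSE)
  .validate_refset(entries)
  class(entries) <- c("reference_set", "data.frame")
  entries
}

#' Load a homeodomain reference set from FASTA
#'
#' Headers must be pipe-delimited `family|species|id`.  Unknown family
#' names, duplicate ids, and malformed headers are errors.
#'
#' @param path protein FASTA path.
#' @return A [reference_set()] object.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("reference FASTA is empty: ", path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed header (expected 'family|species|id') in record(s): ",
         paste(names(aa)[bad], collapse = ", "))
  }
  reference_set(
    id = vapply(parts, `[`, "", 3L),
    family = vapply(parts, `[`, "", 1L),
    species_tag = vapply(parts, `[`, "", 2L),
    sequence = as.character(aa)
  )
}

#' Write a reference set to FASTA
#'
#' Inverse of [load_reference()]: headers are `family|species|id`.
#'
#' @param refset a [reference_set()] object.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(refset, path) {
  stopifnot(inherits(refset, "reference_set"))
  aa <- Biostrings::AAStringSet(refset$sequence)
  names(aa) <- paste(refset$family, refset$species_tag, refset$id, sep = "|")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Homeodomain reference set:", nrow(x), "entries,",
      length(unique(x$family)), "families\n")
  invisible(x)
}
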