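# Guide libraries and the degenerate UMI template.

GUIDE_CLASSES <- c("targeting", "non_targeting", "non_gene_targeting")

# Per-symbol degeneracies of the IUPAC subset used in UMI templates.
IUPAC_DEGENERACY <- c(A = 1L, C = 1L, G = 1L, T = 1L, S = 2L, N = 4L)

#' The default degenerate UMI template
#'
#' A 27-symbol IUPAC pattern (`N` = A/C/G/T, `S` = C/G) carried on the vector
#' next to the sgRNA cassette.  Its 10 `N` and 2 `S` positions admit
#' \eqn{4^{10} \times 2^2 = 4{,}194{,}304} concrete barcodes, so each founder
#' cell in a transduction receives an essentially unique label.
#'
#' @param orientation `"forward"` (as synthesized) or `"reverse_complement"`
#'   (as seen on the reverse sequencing read).
#' @return a `UmiTemplate` object.
#' @examples
#' template_cardinality(default_umi_template())
#' @export
default_umi_template <- function(orientation = "forward") {
  umi_template("NNATCNNGATSSAAANNGGTNNAACNN", orientation = orientation)
}

#' Construct a UMI template
#'
#' @param pattern IUPAC-degenerate DNA string over the alphabet
#'   `A,C,G,T,N,S`.
#' @param orientation `"forward"` or `"reverse_complement"`.
#' @return a `UmiTemplate`: a list with elements `pattern` and `orientation`.
#' @export
umi_template <- function(pattern,
                         orientation = c("forward", "reverse_complement")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(pattern), length(pattern) == 1L)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_DEGENERACY))
  if (length(bad)) {
    stop("unknown template symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(pattern = pattern, orientation = orientation),
            class = "UmiTemplate")
}

#' @export
print.UmiTemplate <- function(x, ...) {
  cat("UmiTemplate <", x$pattern, "> (", x$orientation, "), ",
      format(template_cardinality(x), big.mark = ","),
      " concrete barcodes\n", sep = "")
  invisible(x)
}

# Pattern of a template in the requested read orientation.
oriented_pattern <- function(template, orientation = "forward") {
  if (template$orientation == orientation) {
    template$pattern
  } else {
    reverse_complement(template$pattern)
  }
}

#' Number of concrete barcodes matching a degenerate template
#'
#' The product of per-position degeneracies (`N` contributes 4, `S` 2, fixed
#' bases 1).
#'
#' @param template a `UmiTemplate` or a bare IUPAC pattern string.
#' @return integer-valued count (as double, exact for any realistic template).
#' @examples
#' template_cardinality("NS")  # 8
#' @export
template_cardinality <- function(template) {
  pattern <- if (inherits(template, "UmiTemplate")) template$pattern else template
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_DEGENERACY))
  if (length(bad)) {
    stop("unknown template symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  prod(as.numeric(IUPAC_DEGENERACY[chars]))
}

#' Construct a guide library design
#'
#' @param name library name.
#' @param guides data frame with columns `guide_id`, `sequence` (20-nt
#'   A/C/G/T), `gene` (`NA` for controls) and `guide_class` (one of
#'   `"targeting"`, `"non_targeting"`, `"non_gene_targeting"`).
#' @param umi_template a `UmiTemplate`; defaults to the packaged 27-nt design.
#' @return a `LibraryDesign` object.
#' @export
library_design <- function(name, guides, umi_template = default_umi_template()) {
  stopifnot(is.data.frame(guides), inherits(umi_template, "UmiTemplate"))
  required <- c("guide_id", "sequence", "gene", "guide_class")
  missing_cols <- setdiff(required, names(guides))
  if (length(missing_cols)) {
    stop("guide table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  guides <- guides[required]
  guides$guide_id <- as.character(guides$guide_id)
  guides$sequence <- toupper(as.character(guides$sequence))
  guides$gene <- as.character(guides$gene)
  guides$guide_class <- as.character(guides$guide_class)
  if (nrow(guides) < 1L) stop("a library needs at least one guide", call. = FALSE)

  bad_row <- function(what, rows) {
    stop(what, " at row(s): ", paste(utils::head(rows, 10), collapse = ", "),
         call. = FALSE)
  }
  wrong_len <- which(nchar(guides$sequence) != 20L)
  if (length(wrong_len)) bad_row("guide sequence is not 20 nt", wrong_len)
  bad_alpha <- which(grepl("[^ACGT]", guides$sequence))
  if (length(bad_alpha)) bad_row("guide sequence has non-ACGT characters", bad_alpha)
  dup_id <- which(duplicated(guides$guide_id))
  if (length(dup_id)) bad_row("duplicate guide_id", dup_id)
  dup_seq <- which(duplicated(guides$sequence))
  if (length(dup_seq)) bad_row("duplicate guide sequence", dup_seq)
  bad_class <- which(!guides$guide_class %in% GUIDE_CLASSES)
  if (length(bad_class)) bad_row("unknown guide_class", bad_class)

  structure(list(name = name, guides = guides, umi_template = umi_template),
            class = "LibraryDesign")
}

#' @export
print.LibraryDesign <- function(x, ...) {
  cls <- table(factor(x$guides$guide_class, levels = GUIDE_CLASSES))
  cat("LibraryDesign '", x$name, "': ", nrow(x$guides), " guides (",
      paste(paste(cls, names(cls)), collapse = ", "), "), ",
      length(unique(stats::na.omit(x$guides$gene))), " genes\n", sep = "")
  invisible(x)
}

# Convenience accessors.
is_targeting <- function(design) design$guides$guide_class == "targeting"

#' Read / write a library design table
#'
#' Libraries are stored as plain TSV with header
#' `guide_id`, `sequence`, `gene`, `guide_class`.  The pair of functions
#' round-trips exactly.
#'
#' @param path file path.
#' @param name library name (defaults to the file stem).
#' @param umi_template template attached to the loaded design.
#' @return `load_library` returns a `LibraryDesign`; `write_library` its
#'   `path`, invisibly.
#' @export
load_library <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                         umi_template = default_umi_template()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = "NA")
  library_design(name, tab, umi_template = umi_template)
}

#' @param design a `LibraryDesign`.
#' @rdname load_library
#' @export
write_library <- function(design, path) {
  stopifnot(inherits(design, "LibraryDesign"))
  utils::write.table(design$guides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Deterministic synthetic guide sequences
#'
#' Draws random 20-mers under a fixed seed, rejecting any candidate closer
#' than `min_dist` (Hamming) to an already accepted sequence, so that
#' 1-mismatch guide assignment is unambiguous by construction.
#'
#' @param n number of sequences.
#' @param seed integer seed (fixed by callers so fixtures are bit-stable).
#' @param min_dist minimum pairwise Hamming distance.
#' @return character vector of `n` distinct 20-nt sequences.
#' @export
synthetic_guides <- function(n, seed, min_dist = 3L) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    out <- character(0)
    mat <- matrix(character(0), nrow = 0, ncol = 20)
    while (length(out) < n) {
      cand <- sample(bases, 20, replace = TRUE)
      if (nrow(mat) == 0L || min(hamming_to_set(cand, mat)) >= min_dist) {
        out <- c(out, paste(cand, collapse = ""))
        mat <- rbind(mat, cand)
      }
    }
    out
  })
}

#' Packaged fixture library designs
#'
#' Two synthetic designs mirroring the screens the package targets: a
#' `"signaling"` library of 56 genes in triplicate (168 targeting guides) plus
#' 24 non-targeting controls (192 guides total), and a `"notch"` library of
#' 128 guides across 26 genes.  Gene names are placeholders and sequences are
#' synthetic (fixed seed, pairwise Hamming distance >= 3); only the structure
#' of the designs matters.
#'
#' @param name `"signaling"` or `"notch"`.
#' @return a `LibraryDesign`.
#' @examples
#' make_fixture("signaling")
#' @export
make_fixture <- function(name = c("signaling", "notch")) {
  name <- match.arg(name)
  if (name == "signaling") {
    genes <- sprintf("gene%02d", 1:56)
    ids <- c(paste0(rep(genes, each = 3), "_", 1:3),
             sprintf("ntc_%02d", 1:24))
    gene <- c(rep(genes, each = 3), rep(NA_character_, 24))
    class <- c(rep("targeting", 168), rep("non_targeting", 24))
    seqs <- synthetic_guides(192, seed = 104729L)
  } else {
    genes <- sprintf("notch%02d", 1:26)
    per_gene <- c(rep(5L, 24), 4L, 4L)  # 24*5 + 2*4 = 128
    ids <- unlist(lapply(seq_along(genes),
                         function(i) paste0(genes[i], "_", seq_len(per_gene[i]))))
    gene <- rep(genes, per_gene)
    class <- rep("targeting", 128)
    seqs <- synthetic_guides(128, seed = 224737L)
  }
  library_design(name,
                 data.frame(guide_id = ids, sequence = seqs, gene = gene,
                            guide_class = class, stringsAsFactors = FALSE))
}
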