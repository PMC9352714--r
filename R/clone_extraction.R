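# Paired FASTQ -> merged clone table.
#
# Forward reads carry the sgRNA 24-43 nt downstream of an invariant vector
# anchor; reverse reads carry the UMI (reverse-complemented) within a 50-nt
# window downstream of a second anchor.  After quality filtering, assignment
# and depth standardization, reads sharing a (guide, UMI) pair form a clone
# and 1-mismatch UMI clones are merged with the directional rule.

FORWARD_ANCHOR <- "TCTTGTGGAAAGGACGAAACACCG"
REVERSE_ANCHOR <- "AGCCTCACTGGCCGTCGTTTTACA"
GUIDE_WINDOW <- c(24L, 43L)  # 1-based inclusive offsets after the anchor
UMI_SEARCH_LEN <- 50L

#' Construct a clone table
#'
#' The unit of all downstream statistics: one row per (guide, UMI) clone with
#' its read count.
#'
#' @param records data frame with columns `guide_id`, `umi`, `reads`.
#' @param sample_id sample label stored as an attribute.
#' @return a `CloneTable` (a data frame with attributes `sample_id`; total
#'   reads available via [total_reads()]).
#' @export
clone_table <- function(records, sample_id = "sample") {
  if (nrow(records) == 0L) {
    records <- data.frame(guide_id = character(), umi = character(),
                          reads = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("guide_id", "umi", "reads") %in% names(records)))
  records <- records[c("guide_id", "umi", "reads")]
  records$guide_id <- as.character(records$guide_id)
  records$umi <- as.character(records$umi)
  records$reads <- as.integer(records$reads)
  if (any(records$reads < 1L)) stop("clone read counts must be >= 1", call. = FALSE)
  if (anyDuplicated(paste(records$guide_id, records$umi))) {
    stop("(guide_id, umi) pairs must be unique in a clone table", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(records, sample_id = sample_id,
            class = c("CloneTable", "data.frame"))
}

#' @rdname clone_table
#' @param x a `CloneTable`.
#' @export
total_reads <- function(x) sum(x$reads)

#' Read / write clone tables as TSV
#'
#' Plain TSV with header `sample_id`, `guide_id`, `umi`, `reads`.
#'
#' @param path file path.
#' @return a `CloneTable` / the path, invisibly.
#' @export
read_clone_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "guide_id", "umi", "reads")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("clone table ", path, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(tab$reads) | tab$reads < 1)
  if (length(bad)) {
    stop("clone table ", path, ": invalid read count at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  sample_id <- unique(tab$sample_id)
  if (length(sample_id) != 1L) sample_id <- sample_id[1]
  clone_table(tab[c("guide_id", "umi", "reads")], sample_id = sample_id)
}

#' @rdname read_clone_table
#' @param table a `CloneTable`.
#' @export
write_clone_table <- function(table, path) {
  out <- data.frame(sample_id = attr(table, "sample_id"),
                    as.data.frame(table), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read paired FASTQ into a read-pair table
#'
#' Uses Biostrings for FASTQ parsing (gzip transparent).  Mates are paired in
#' file order.
#'
#' @param fastq_fwd,fastq_rev paths to the forward / reverse FASTQ files.
#' @return data frame with columns `forward_seq`, `forward_quals`,
#'   `reverse_seq`, `reverse_quals` (qualities as phred+33 strings).
#' @export
read_fastq_pairs <- function(fastq_fwd, fastq_rev) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  fw <- tryCatch(rd(fastq_fwd), error = function(e) {
    stop("unreadable FASTQ '", fastq_fwd, "': ", conditionMessage(e), call. = FALSE)
  })
  rv <- tryCatch(rd(fastq_rev), error = function(e) {
    stop("unreadable FASTQ '", fastq_rev, "': ", conditionMessage(e), call. = FALSE)
  })
  if (length(fw$seq) != length(rv$seq)) {
    stop("forward and reverse FASTQ have different read counts (",
         length(fw$seq), " vs ", length(rv$seq), ")", call. = FALSE)
  }
  data.frame(forward_seq = unname(fw$seq), forward_quals = unname(fw$qual),
             reverse_seq = unname(rv$seq), reverse_quals = unname(rv$qual),
             stringsAsFactors = FALSE)
}

mean_phred <- function(qual_strings) {
  vapply(qual_strings,
         function(q) if (nchar(q) == 0L) NaN else mean(utf8ToInt(q)) - 33,
         0, USE.NAMES = FALSE)
}

#' Quality-filter read pairs
#'
#' Retains pairs for which both mates have mean phred quality at or above the
#' threshold.  Records whose sequence and quality lengths disagree are
#' rejected (and counted in the `n_malformed` attribute).
#'
#' @param pairs read-pair data frame as from [read_fastq_pairs()].
#' @param min_mean_q minimum mean phred score per mate (default 30).
#' @return the retained subset of `pairs`.
#' @export
quality_filter <- function(pairs, min_mean_q = 30) {
  if (nrow(pairs) == 0L) return(pairs)
  ok_len <- nchar(pairs$forward_seq) == nchar(pairs$forward_quals) &
    nchar(pairs$reverse_seq) == nchar(pairs$reverse_quals)
  n_malformed <- sum(!ok_len)
  pairs <- pairs[ok_len, , drop = FALSE]
  keep <- mean_phred(pairs$forward_quals) >= min_mean_q &
    mean_phred(pairs$reverse_quals) >= min_mean_q
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- n_malformed
  out
}

# Assign one 20-nt window to a library guide: unique exact match, else the
# unique nearest guide within max_mismatch (ties discarded).
match_window_to_guides <- function(windows, lib_seqs, lib_mat, max_mismatch) {
  hit <- match(windows, lib_seqs)
  todo <- which(is.na(hit) & !is.na(windows) & nchar(windows) == 20L &
                  !grepl("[^ACGT]", windows))
  for (i in todo) {
    d <- hamming_to_set(strsplit(windows[i], "", fixed = TRUE)[[1]], lib_mat)
    dmin <- min(d)
    if (dmin <= max_mismatch && sum(d == dmin) == 1L) hit[i] <- which.min(d)
  }
  hit
}

#' Extract guide identities from forward reads
#'
#' Locates the first occurrence of the invariant forward anchor
#' `TCTTGTGGAAAGGACGAAACACCG`, takes the 20-nt window 24-43 nt (1-based,
#' inclusive) downstream of the anchor's last base, and assigns it to the
#' unique library guide matching exactly, or failing that the unique guide
#' within `max_mismatch` Hamming distance.  `NA` marks unassignable reads
#' (no anchor, truncated window, no match, or an ambiguous tie).
#'
#' @param forward_seq character vector of forward read sequences.
#' @param library a `LibraryDesign`.
#' @param max_mismatch allowed guide mismatches, 1..3 (default 1).
#' @return character vector of guide ids (`NA` where unassignable).
#' @export
extract_guide <- function(forward_seq, library, max_mismatch = 1L) {
  stopifnot(inherits(library, "LibraryDesign"),
            max_mismatch >= 1L, max_mismatch <= 3L)
  pos <- regexpr(FORWARD_ANCHOR, forward_seq, fixed = TRUE)
  start <- ifelse(pos > 0, pos + nchar(FORWARD_ANCHOR) + GUIDE_WINDOW[1] - 1L, NA)
  end <- start + (GUIDE_WINDOW[2] - GUIDE_WINDOW[1])
  window <- ifelse(!is.na(start) & end <= nchar(forward_seq),
                   substr(forward_seq, start, end), NA)
  # match unique windows once, then map back
  uw <- unique(window[!is.na(window)])
  if (length(uw) == 0L) return(rep(NA_character_, length(forward_seq)))
  lib_seqs <- library$guides$sequence
  lib_mat <- str_to_mat(lib_seqs)
  uhit <- match_window_to_guides(uw, lib_seqs, lib_mat, max_mismatch)
  idx <- uhit[match(window, uw)]
  library$guides$guide_id[idx]
}

# Mismatch count of a candidate window against the fixed positions of a
# degenerate pattern (N free; S requires C/G; letters require equality).
template_mismatches <- function(window_chars, pat_chars) {
  fixed <- pat_chars != "N"
  s_pos <- pat_chars == "S"
  lit <- fixed & !s_pos
  sum(window_chars[lit] != pat_chars[lit]) +
    sum(!window_chars[s_pos] %in% c("C", "G"))
}

#' Extract UMIs from reverse reads
#'
#' Takes the 50-nt substring downstream of the invariant reverse anchor
#' `AGCCTCACTGGCCGTCGTTTTACA` and scans it for the leftmost 27-nt window
#' whose fixed positions match the reverse-complement UMI template with zero
#' mismatches, or failing that with at most `max_mismatch`.  The matched
#' window is reverse-complemented so that returned UMIs are in forward
#' (as-synthesized) orientation.
#'
#' @param reverse_seq character vector of reverse read sequences (as
#'   sequenced).
#' @param template a `UmiTemplate` (forward orientation).
#' @param max_mismatch allowed fixed-position mismatches, 1..3 (default 1).
#' @return character vector of 27-nt forward-orientation UMIs (`NA` where
#'   unassignable).
#' @export
extract_umi <- function(reverse_seq, template = default_umi_template(),
                        max_mismatch = 1L) {
  stopifnot(inherits(template, "UmiTemplate"),
            max_mismatch >= 1L, max_mismatch <= 3L)
  rev_pattern <- oriented_pattern(template, "reverse_complement")
  pat_chars <- strsplit(rev_pattern, "", fixed = TRUE)[[1]]
  L <- length(pat_chars)
  pos <- regexpr(REVERSE_ANCHOR, reverse_seq, fixed = TRUE)
  start <- ifelse(pos > 0, pos + nchar(REVERSE_ANCHOR), NA)
  sub <- ifelse(!is.na(start),
                substr(reverse_seq, start, start + UMI_SEARCH_LEN - 1L), NA)
  usub <- unique(sub[!is.na(sub) & nchar(sub) >= L])
  find_in <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    offs <- seq_len(length(chars) - L + 1L)
    mm <- vapply(offs, function(o) template_mismatches(chars[o:(o + L - 1L)],
                                                       pat_chars), 0)
    hit <- which(mm == 0L)
    if (!length(hit)) hit <- which(mm <= max_mismatch)
    if (!length(hit)) return(NA_character_)
    o <- hit[1]  # leftmost
    substr(s, o, o + L - 1L)
  }
  if (length(usub) == 0L) return(rep(NA_character_, length(reverse_seq)))
  found <- vapply(usub, find_in, "", USE.NAMES = FALSE)
  rev_window <- found[match(sub, usub)]
  out <- rep(NA_character_, length(reverse_seq))
  ok <- !is.na(rev_window)
  if (any(ok)) out[ok] <- reverse_complement(rev_window[ok])
  out
}

#' Standardize sequencing depth by downsampling assigned reads
#'
#' A uniform without-replacement sample of exactly `cap` records when the
#' input exceeds the cap (default 2e6 sgRNA-UMI reads), the identity
#' otherwise.  Reproducible under `seed`; retained records keep their input
#' order.
#'
#' @param records data frame of assigned reads (one row per read, e.g.
#'   columns `guide_id`, `umi`).
#' @param cap maximum number of records retained.
#' @param seed integer seed (required when downsampling occurs).
#' @return the (possibly downsampled) data frame.
#' @export
standardize_depth <- function(records, cap = 2e6, seed = NULL) {
  stopifnot(cap >= 1)
  n <- nrow(records)
  if (n <= cap) return(records)
  keep <- with_seed(seed, sort(sample.int(n, cap)))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Directional merging of 1-mismatch UMI clones
#'
#' Corrects replication/PCR/sequencing errors in UMIs.  Per guide, UMI clones
#' form a graph with an edge between clones whose UMIs differ at exactly one
#' position and whose pre-merge counts satisfy `n_a > 2 * n_b - 1` (larger
#' vs smaller).  Each connected component collapses to a single clone whose
#' count is the component total and whose UMI is that of the largest member
#' (ties broken by lexicographically smallest UMI).  Total reads are
#' conserved.
#'
#' @param table a `CloneTable`.
#' @return the merged `CloneTable`.
#' @export
directional_merge <- function(table) {
  stopifnot(inherits(table, "CloneTable"))
  if (nrow(table) == 0L) return(table)
  pieces <- split(seq_len(nrow(table)), table$guide_id)
  out <- vector("list", length(pieces))
  for (p in seq_along(pieces)) {
    idx <- pieces[[p]]
    umis <- table$umi[idx]
    counts <- table$reads[idx]
    m <- length(idx)
    if (m == 1L) {
      out[[p]] <- data.frame(guide_id = table$guide_id[idx], umi = umis,
                             reads = counts, stringsAsFactors = FALSE)
      next
    }
    d <- hamming_matrix(umis)
    big <- outer(counts, counts, pmax)
    small <- outer(counts, counts, pmin)
    adj <- d == 1L & big > 2L * small - 1L
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    merged <- lapply(split(seq_len(m), comp), function(members) {
      total <- sum(counts[members])
      largest <- members[counts[members] == max(counts[members])]
      umi <- min(umis[largest])  # lexicographic tie-break
      data.frame(umi = umi, reads = total, stringsAsFactors = FALSE)
    })
    merged <- do.call(rbind, merged)
    out[[p]] <- data.frame(guide_id = table$guide_id[idx[1]], umi = merged$umi,
                           reads = merged$reads, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$guide_id, res$umi), , drop = FALSE]
  clone_table(res, sample_id = attr(table, "sample_id"))
}

#' Extract a merged clone table from paired FASTQ
#'
#' Composition of the whole read-processing chain: quality filter, guide and
#' UMI assignment (reads failing either are dropped), depth standardization
#' to at most `cap` assigned reads, tallying of (guide, UMI) read counts,
#' and directional merging.  Per-stage read/clone counts are attached as the
#' `stage_counts` attribute.
#'
#' @param fastq_fwd,fastq_rev paths to paired FASTQ files (mates in pairing
#'   order).
#' @param library a `LibraryDesign`.
#' @param sample_id label for the resulting table.
#' @param min_mean_q mean-phred threshold for the pair filter.
#' @param max_mismatch guide/UMI mismatch tolerance (1..3).
#' @param cap depth-standardization cap (default 2e6 reads).
#' @param seed integer seed for the downsampling stage.
#' @return a merged `CloneTable` with attribute `stage_counts`.
#' @export
extract_clones <- function(fastq_fwd, fastq_rev, library, sample_id = "sample",
                           min_mean_q = 30, max_mismatch = 1L, cap = 2e6,
                           seed = 1L) {
  pairs <- read_fastq_pairs(fastq_fwd, fastq_rev)
  stages <- list(reads_in = nrow(pairs))
  pairs <- quality_filter(pairs, min_mean_q = min_mean_q)
  stages$pass_quality <- nrow(pairs)
  guide <- extract_guide(pairs$forward_seq, library, max_mismatch = max_mismatch)
  umi <- extract_umi(pairs$reverse_seq, library$umi_template,
                     max_mismatch = max_mismatch)
  ok <- !is.na(guide) & !is.na(umi)
  stages$guide_assigned <- sum(!is.na(guide))
  stages$umi_assigned <- sum(!is.na(umi))
  stages$both_assigned <- sum(ok)
  assigned <- data.frame(guide_id = guide[ok], umi = umi[ok],
                         stringsAsFactors = FALSE)
  assigned <- standardize_depth(assigned, cap = cap, seed = seed)
  stages$after_downsample <- nrow(assigned)
  if (nrow(assigned) == 0L) {
    tab <- clone_table(data.frame(guide_id = character(), umi = character(),
                                  reads = integer()), sample_id = sample_id)
    stages$clones_premerge <- 0L
    stages$clones_postmerge <- 0L
    attr(tab, "stage_counts") <- stages
    return(tab)
  }
  agg <- stats::aggregate(list(reads = rep(1L, nrow(assigned))),
                          by = assigned[c("guide_id", "umi")], FUN = sum)
  tab <- clone_table(agg, sample_id = sample_id)
  stages$clones_premerge <- nrow(tab)
  tab <- directional_merge(tab)
  stages$clones_postmerge <- nrow(tab)
  stages$total_reads <- total_reads(tab)
  attr(tab, "stage_counts") <- stages
  tab
}
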