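# FASTQ -> clone table: filtering, anchor-window matching, depth
# standardization and directional merging.

FWD <- clonefit:::FORWARD_ANCHOR
REV <- clonefit:::REVERSE_ANCHOR

make_pair <- function(fseq, rseq, fq = 37, rq = 37) {
  data.frame(forward_seq = fseq,
             forward_quals = phred_string(rep(fq, nchar(fseq))),
             reverse_seq = rseq,
             reverse_quals = phred_string(rep(rq, nchar(rseq))),
             stringsAsFactors = FALSE)
}

test_that("quality filter keeps pairs with both mean phreds at the threshold", {
  pairs <- rbind(
    make_pair(strrep("A", 10), strrep("C", 10), fq = 35, rq = 31),
    make_pair(strrep("A", 10), strrep("C", 10), fq = 35, rq = 29),
    make_pair(strrep("A", 10), strrep("C", 10), fq = 29, rq = 40))
  # fractional mean: half 29, half 30 -> 29.5, removed
  pairs <- rbind(pairs, data.frame(
    forward_seq = strrep("A", 10),
    forward_quals = phred_string(rep(35, 10)),
    reverse_seq = strrep("C", 10),
    reverse_quals = phred_string(c(rep(29, 5), rep(30, 5))),
    stringsAsFactors = FALSE))
  kept <- quality_filter(pairs, min_mean_q = 30)
  expect_equal(nrow(kept), 1L)
  expect_equal(nrow(quality_filter(pairs[0, ])), 0L)
  # malformed record (seq/qual length mismatch) is rejected and counted
  bad <- make_pair(strrep("A", 10), strrep("C", 10))
  bad$forward_quals <- substr(bad$forward_quals, 1, 5)
  out <- quality_filter(rbind(pairs[1, ], bad))
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_malformed"), 1L)
})

test_that("guide extraction follows the 24-43 window and mismatch rules", {
  lib <- tiny_library(8, seed = 401L)
  g7 <- lib$guides$sequence[7]
  pad <- strrep("G", 11)
  spacer <- strrep("T", 23)
  read <- paste0(pad, FWD, spacer, g7, "ACGTAC")
  expect_equal(extract_guide(read, lib), lib$guides$guide_id[7])
  # one substitution in the guide is still assigned (nearest-unique rule)
  mut <- g7
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(g7, 5, 5))[1]
  expect_equal(extract_guide(paste0(pad, FWD, spacer, mut, "AC"), lib),
               lib$guides$guide_id[7])
  # no anchor, or a window running off the read end, is unassignable
  expect_true(is.na(extract_guide(paste0(pad, spacer, g7), lib)))
  expect_true(is.na(extract_guide(paste0(pad, FWD, spacer, substr(g7, 1, 15)), lib)))
})

test_that("ambiguous windows equidistant from two guides are discarded", {
  lib <- library_design("amb", data.frame(
    guide_id = c("a", "b"),
    sequence = c(paste0("AAAAA", strrep("C", 15)),
                 paste0("AAAAT", strrep("C", 15))),
    gene = "g1", guide_class = "targeting",
    stringsAsFactors = FALSE))
  # window differs from both guides at exactly one position
  window <- paste0("AAAAG", strrep("C", 15))
  d <- clonefit:::hamming_to_set(strsplit(window, "")[[1]],
                                 clonefit:::str_to_mat(lib$guides$sequence))
  expect_equal(as.vector(d), c(1, 1))  # oracle: a genuine tie
  read <- paste0(FWD, strrep("T", 23), window)
  expect_true(is.na(extract_guide(read, lib)))
})

test_that("guide assignment never exceeds the mismatch budget", {
  lib <- tiny_library(20, seed = 402L)
  lib_mat <- clonefit:::str_to_mat(lib$guides$sequence)
  set.seed(31)
  for (i in 1:40) {
    window <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                    collapse = "")
    hit <- extract_guide(paste0(FWD, strrep("T", 23), window), lib,
                         max_mismatch = 2)
    d <- clonefit:::hamming_to_set(strsplit(window, "")[[1]], lib_mat)
    if (!is.na(hit)) {
      expect_lte(d[match(hit, lib$guides$guide_id)], 2)
      expect_equal(sum(d == min(d)), 1L)
    } else {
      expect_true(min(d) > 2 || sum(d == min(d)) > 1L)
    }
  }
})

test_that("UMI extraction scans the 50-nt window for the reverse template", {
  tmpl <- default_umi_template()
  umi <- clonefit:::realize_umis(tmpl, 1)
  rc <- clonefit:::reverse_complement(umi)
  read <- paste0("ACGT", REV, strrep("A", 7), rc, strrep("G", 16))
  expect_equal(extract_umi(read), umi)
  # one substitution at a fixed template position is tolerated
  rc_mut <- rc
  substr(rc_mut, 3, 3) <- "C"  # fixed position 3 is G in the reverse pattern
  got <- extract_umi(paste0("ACGT", REV, strrep("A", 7), rc_mut, strrep("G", 16)))
  expect_equal(got, clonefit:::reverse_complement(rc_mut))
  # no anchor -> unassignable
  expect_true(is.na(extract_umi(paste0("ACGT", strrep("A", 7), rc))))
})

test_that("reads with no template window within tolerance are unassignable", {
  # oracle: scan all candidate offsets of a poly-A substring against the
  # reverse pattern and confirm every offset has >= 2 fixed-position misses
  pat <- strsplit("NNGTTNNACCNNTTTSSATCNNGATNN", "")[[1]]
  sub <- strrep("A", 50)
  chars <- strsplit(sub, "")[[1]]
  mm <- vapply(1:24, function(o)
    clonefit:::template_mismatches(chars[o:(o + 26)], pat), 0)
  expect_true(min(mm) >= 2)
  expect_true(is.na(extract_umi(paste0(REV, sub))))
})

test_that("the leftmost matching UMI window wins", {
  tmpl <- default_umi_template()
  umis <- clonefit:::realize_umis(tmpl, 2)
  rc <- clonefit:::reverse_complement(umis)
  read <- paste0(REV, rc[1], rc[2])  # two exact windows back to back
  expect_equal(extract_umi(read), umis[1])
})

test_that("depth standardization caps record streams reproducibly", {
  recs <- data.frame(guide_id = rep("g", 5000), umi = as.character(1:5000),
                     stringsAsFactors = FALSE)
  out <- standardize_depth(recs, cap = 1500, seed = 9)
  expect_equal(nrow(out), 1500L)
  expect_identical(out, standardize_depth(recs, cap = 1500, seed = 9))
  expect_false(identical(out, standardize_depth(recs, cap = 1500, seed = 10)))
  expect_identical(standardize_depth(recs, cap = 6000, seed = 9), recs)
  # retained records keep their stream order
  expect_true(all(diff(as.integer(out$umi)) > 0))
})

test_that("directional merge applies the count inequality on 1-mismatch pairs", {
  u <- c("AAAAA", "AAAAT", "GGGGG")
  tab <- clone_table(data.frame(guide_id = "g1", umi = u, reads = c(10L, 4L, 2L)))
  merged <- directional_merge(tab)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$reads[merged$umi == "AAAAA"], 14L)  # 10 > 2*4 - 1
  tab2 <- clone_table(data.frame(guide_id = "g1", umi = u[1:2], reads = c(7L, 4L)))
  expect_equal(nrow(directional_merge(tab2)), 2L)  # 7 > 7 is false
  single <- clone_table(data.frame(guide_id = "g1", umi = "AAAAA", reads = 3L))
  expect_equal(as.data.frame(directional_merge(single)), as.data.frame(single))
})

test_that("directional merge collapses whole connected components", {
  tab <- clone_table(data.frame(
    guide_id = "g1",
    umi = c("AAAAA", "AAAAT", "AAATT"),
    reads = c(100L, 40L, 15L)))
  merged <- directional_merge(tab)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$umi, "AAAAA")
  expect_equal(merged$reads, 155L)
})

# independent oracle: all-pairs Hamming + inequality + union-find components
brute_merge <- function(umis, counts) {
  n <- length(umis)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- clonefit:::hamming_matrix(umis)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && d[i, j] == 1 &&
        max(counts[i], counts[j]) > 2 * min(counts[i], counts[j]) - 1) {
      parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  out <- lapply(split(seq_len(n), comp), function(m) {
    big <- m[counts[m] == max(counts[m])]
    data.frame(umi = min(umis[big]), reads = sum(counts[m]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$umi), ]
}

test_that("directional merge matches the brute-force oracle on random tables", {
  set.seed(77)
  n_idempotent <- 0L
  for (rep in 1:12) {
    m <- sample(2:50, 1)
    umis <- unique(replicate(m, paste(sample(c("A", "C"), 6, replace = TRUE),
                                      collapse = "")))
    counts <- sample(1:200, length(umis), replace = TRUE)
    tab <- clone_table(data.frame(guide_id = "g1", umi = umis, reads = counts))
    merged <- as.data.frame(directional_merge(tab))
    oracle <- brute_merge(umis, counts)
    expect_equal(merged$umi, oracle$umi)
    expect_equal(merged$reads, oracle$reads)
    expect_equal(sum(merged$reads), sum(counts))  # reads conserved
    # idempotent whenever the merged table has no qualifying edges left
    # (summed counts can create new qualifying pairs, which a second pass
    # then legitimately merges)
    d2 <- clonefit:::hamming_matrix(merged$umi)
    q2 <- d2 == 1 & outer(merged$reads, merged$reads, pmax) >
      2 * outer(merged$reads, merged$reads, pmin) - 1
    if (!any(q2)) {
      again <- as.data.frame(directional_merge(directional_merge(tab)))
      expect_equal(again$umi, merged$umi)
      expect_equal(again$reads, merged$reads)
      n_idempotent <- n_idempotent + 1L
    }
  }
  expect_gte(n_idempotent, 2L)  # the idempotence branch is exercised
})

test_that("error-free simulated FASTQ round-trips to the exact clone table", {
  lib <- tiny_library(12, seed = 403L)
  sim <- simulate_screen(simulation_config(lib, seed = 51L,
                                           clones_per_guide = 6,
                                           size_params = mix_params),
                         fastq_prefix = file.path(tempdir(), "rt"))
  tab <- extract_clones(sim$fastq[1], sim$fastq[2], lib, seed = 1L)
  a <- as.data.frame(sim$clone_table)
  a <- a[order(a$guide_id, a$umi), ]; rownames(a) <- NULL
  b <- as.data.frame(tab)
  b <- b[order(b$guide_id, b$umi), ]; rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
  stages <- attr(tab, "stage_counts")
  expect_equal(stages$reads_in, total_reads(sim$clone_table))
  expect_equal(stages$both_assigned, stages$reads_in)
})

test_that("directional merging absorbs low-rate UMI sequencing errors", {
  lib <- tiny_library(10, seed = 404L)
  sim <- simulate_screen(simulation_config(lib, seed = 52L,
                                           clones_per_guide = 5,
                                           size_params = list(mean1 = 12, size1 = 2,
                                                              mean2 = 60, size2 = 2,
                                                              w = 0.5),
                                           umi_error_rate = 3e-4),
                         fastq_prefix = file.path(tempdir(), "err"))
  tab <- extract_clones(sim$fastq[1], sim$fastq[2], lib, seed = 1L)
  stages <- attr(tab, "stage_counts")
  expect_gte(stages$clones_premerge, nrow(sim$clone_table))
  expect_equal(nrow(tab), nrow(sim$clone_table))  # merge recovers truth
  expect_equal(total_reads(tab), total_reads(sim$clone_table))
})

test_that("FASTQ without anchors yields an empty clone table", {
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", strrep("A", 80), "+", strrep("F", 80)), f1)
  writeLines(c("@r1", strrep("C", 80), "+", strrep("F", 80)), f2)
  tab <- extract_clones(f1, f2, tiny_library(4, seed = 405L), seed = 1L)
  expect_equal(nrow(tab), 0L)
  expect_equal(total_reads(tab), 0L)
  expect_error(extract_clones("/nonexistent.fastq", f2,
                              tiny_library(4, seed = 405L), seed = 1L),
               "unreadable FASTQ")
})
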