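Package: clonefit
Title: Clone-Resolved Fitness Inference for Pooled CRISPR Screens with
    UMI Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of pooled CRISPR screens in
    which each transduced founder cell carries a single guide RNA
    (sgRNA) together with a degenerate unique molecular identifier
    (UMI), so that the progeny of every founder cell is countable as a
    clone.  The package extracts sgRNA-UMI clones from paired amplicon
    FASTQ (quality filtering, anchor-window matching with mismatch
    tolerance, depth standardization, directional error-merging of
    UMIs), summarizes clonal diversity (clones per million reads,
    Shannon diversity index, Lorenz-curve area), and infers per-guide
    fitness with a hierarchical Bayesian model over clone numbers and
    heavy-tailed clone sizes, using a menu of zero-truncated count
    likelihoods and reporting the posterior winsorized mean of cellular
    output per guide.  Post-inference utilities provide dataset
    normalization, neutrality calls with false-discovery-rate control,
    pairwise screen comparisons with outlier criteria, Hasse-diagram
    resolution of the fitness partial order, a frequentist delta-method
    comparator, and a fully seeded synthetic-screen simulator.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
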