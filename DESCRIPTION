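Package: codonpanel
Title: Codon Usage, Codon Context and Compositional Analysis of Coding-Sequence Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for codon-pattern analysis of panels of protein-coding
    sequences, built around an 18-gene human depression-associated panel as
    the worked example. Computes nucleotide composition by codon position,
    six nucleotide skews, dinucleotide odds ratios, relative synonymous codon
    usage (RSCU), the effective number of codons (ENc), scaled chi-square,
    the codon adaptation index (CAI), the translational-selection index P2,
    codon-pair context with adjusted-residual significance calls, and
    physicochemical indices of the translated proteins. Cross-gene analyses
    include neutrality (GC12 on GC3) regression, PR2 parity, bootstrap
    t-tests of RSCU between gene panels, correlation matrices with
    Bonferroni correction, and ordination of RSCU tables (covariance or
    correlation PCA, or correspondence analysis). A seeded synthetic-CDS
    generator with controllable codon usage, GC3 and dinucleotide structure
    makes every stage testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'tables.R'
    'seq_io.R'
    'synthetic_data.R'
    'composition.R'
    'codon_usage.R'
    'codon_context.R'
    'protein_props.R'
    'stat_suite.R'
    'pipeline.R'
    'codonpanel-package.R'
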