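Package: tbone
Title: Transcript Boundary Annotation from Trans-Splicing and Poly(A) Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines genome-guided transcriptome assemblies for organisms with
    spliced-leader trans-splicing. Assembled transcriptional units, which are
    often polycistronic precursors, are cut into mature mRNA gene models using
    experimentally derived evidence: spliced-leader-trimmed read 5' ends mark
    trans-splice acceptor sites and 3'-end (T-fill) read ends mark
    polyadenylation sites. Includes strand-specific signal pileup and peak
    calling, antisense and low-expression transcript filters, longest-ORF
    calling with ORF/poly(A)-aware merging of transcripts split across
    repetitive gaps, greedy nucleotide-identity clustering of redundant
    transcripts, codon-usage weight matrices and codon optimization for
    transgene design, detection of duplicated non-repetitive genomic blocks,
    and a synthetic-data generator with machine-readable ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    ShortRead,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
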