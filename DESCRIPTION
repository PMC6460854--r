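Package: stableRef
Title: Transcriptome-Wide Reference Gene Screening and RT-qPCR Stability
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate reference (housekeeping) genes from
    RNA-Seq expression matrices using a four-criterion TPM screen with
    coefficient-of-variation ranking, builds multi-dataset core sets,
    and tests term over-representation of candidates. Validates
    candidates from RT-qPCR quantification-cycle (Ct) data with three
    stability statistics (geNorm M value and pairwise variation,
    a NormFinder-style model-based measure, and the comparative
    delta-Ct method) combined by geometric-mean comprehensive ranking,
    estimates primer amplification efficiencies from dilution-series
    standard curves, and calibrates the linear relation between Ct and
    log2(TPM). Includes FASTQ read-quality filtering, TPM conversion
    from counts, and seeded synthetic-data generators for every input
    so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
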