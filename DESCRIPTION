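Package: cleftmir
Title: miRNA Over-Representation Analysis for the Mouse Cleft Lip Gene Catalog
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for curating a catalog of mouse cleft lip (CL) associated
    genes from mutant-line tables, auditing the systematic-review bookkeeping
    behind the catalog (PRISMA stage counts, inter-screener Cohen's kappa,
    Venn partition arithmetic), testing per-miRNA over-representation of the
    catalog against merged miRNA-target interaction maps with exact Fisher
    p-values and Benjamini-Hochberg false discovery rates, ranking catalog
    genes by the number of significant miRNAs that target them, and
    generating synthetic interaction databases with known null or planted
    enrichment structure for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
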