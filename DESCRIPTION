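Package: eglporin
Title: Annotation and Functional Analysis of Insect Glycerol-Transporting Aquaporins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to annotate aquaporin peptide sequences (NPA motifs and the
    aromatic/arginine selectivity-filter quartet), classify them into arthropod
    aquaporin subfamilies by nearest-reference alignment, and predict glycerol
    permeability from the diagnostic residue on transmembrane domain 5 (TMD5):
    water-selective channels carry a conserved histidine at this position while
    entomoglyceroporins carry an uncharged residue. Includes in-silico point
    mutagenesis, pore-radius profiling of channel coordinates, quantification of
    Xenopus oocyte functional assays (osmotic water permeability from swelling
    time-courses, radiotracer solute uptake with zero-time background
    subtraction, cRNA dose-response plateau detection, one-way ANOVA with
    versus-control comparisons), and seeded synthetic-data generators for every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    multcomp,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
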