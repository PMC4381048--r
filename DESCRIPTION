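Package: siaPCA
Title: Scaffold-Independent Analysis of RNA-Binding Specificity by PCA of 2D NMR Spectra
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Determines the nucleobase preference of an RNA-binding protein
    domain from ensembles of 2D 1H-15N correlation NMR spectra. One free-protein
    spectrum plus four spectra of complexes with quasi-degenerate RNA pools
    (A/C/G/U fixed at one position) are stacked and decomposed by NIPALS
    principal component analysis; the separation of each bound spectrum from the
    reference on the second principal component ranks the four pools by average
    affinity. Includes readers and writers for NMRPipe 2D and a plain matrix
    dialect, a fast-exchange binding simulator with known ground truth, the
    manual chemical-shift-perturbation scoring procedure for cross-validation,
    and a config-driven batch pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'pca.R'
    'scoring.R'
    'sia-manual.R'
    'pipeline.R'
    'siaPCA-package.R'
    'spectra-io.R'
    'simulate.R'
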