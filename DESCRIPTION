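Package: pegsound
Title: Unsupervised Detection, Phenotyping and Temporal Modeling of Bowel
    Sounds from Phonoenterograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing phonoenterogram (PEG) recordings of abdominal
    bowel sounds. Detects prominent bowel-sound events with a short-time-energy
    detector and dynamic threshold, encodes each event as a 279-dimensional
    acoustic feature vector (MFCCs, delta-MFCCs and six spectral descriptors),
    embeds events with PCA and UMAP, clusters them into acoustic phenotypes
    with k-means, Ward agglomerative and spectral clustering scored by
    silhouette, Calinski-Harabasz and Davies-Bouldin indices, and models the
    resulting event sequences as a first-order Markov chain with dwell-time
    and inter-event-gap statistics. Includes a synthetic phonoenterogram
    generator with ground-truth annotations so the whole pipeline can be
    exercised and validated without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    uwot,
    FNN,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
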