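Package: cuetopo
Title: Spatial Topography of Drug-Cue Reactivity Hotspots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the spatial topography of per-subject
    fMRI drug-cue reactivity "hotspots" and their proximity to scalp
    neuromodulation targets. Implements block-paradigm first- and second-level
    general linear models, Monte-Carlo cluster-extent thresholding of
    statistical maps, per-subject hotspot extraction from corrected clusters,
    k-means++ clustering of hotspot coordinates with silhouette-based model
    selection, chi-square tests of group composition across clusters, and
    coverage statistics of hotspots around EEG 10-10 scalp coordinates at
    transcranial magnetic stimulation-relevant distances. A synthetic cohort
    generator produces coordinate-level and image-level data with the same
    statistical structure, so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
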