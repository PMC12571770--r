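Package: lnmapr
Title: Lesion Network Mapping with Normative Connectomes and Multimodal
    Spatial Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for symptom network mapping from focal brain lesions and
    stimulation sites. Seeds drawn on a standard template are propagated
    through a normative resting-state connectome to per-subject Fisher-z
    functional connectivity maps, summarised by voxelwise group statistics
    (one-sample t maps, overlap/sensitivity maps, two-sample specificity
    maps with family-wise error control, conjunction hubs, subcortical
    peaks), and the derived network is compared with parcel-level
    annotation maps (cortical expansion, receptor densities, band-limited
    MEG maps) by spatial correlation with false-discovery-rate control.
    Includes band-limited oscillation analysis (zero-phase band-pass,
    Hilbert envelopes, amplitude envelope correlation, cross-band
    principal component) and a synthetic-data generator that plants a
    known spatial network so that every pipeline stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    signal,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
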