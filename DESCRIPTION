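Package: bbbquant
Title: Quantification of Activity-Dependent Blood-Brain Barrier Modulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipelines linking neuronal stimulation to
    blood-brain barrier (BBB) modulation: an intravital fluorescence
    angiography permeability index (registration, vessel segmentation,
    arterial-input-function normalization), a DCE-MRI voxelwise leakage
    mapper with variable-flip-angle T1 fitting, sinus normalization and
    control-cohort percentile thresholding, somatosensory evoked potential
    (SEP) plasticity measures, transcriptome divergence statistics
    (Jensen-Shannon divergence, DEG category contingency), and the
    supporting nonparametric and FDR machinery (exact Wilcoxon signed-rank,
    two-stage Benjamini-Krieger-Yekutieli step-up). Ships synthetic-data
    generators for every modality with stored ground truth so the full
    pipeline is testable without animal or human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tiff,
    RNifti,
    pracma,
    withr,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
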