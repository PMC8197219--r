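Package: voxbind
Title: Voxel-Based Prediction of DNA-Binding Sites on Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A structure-based pipeline for predicting DNA-binding sites on
    protein surfaces. Protein-DNA complex structures in PDB format are parsed,
    surface atoms are identified by a Shrake-Rupley solvent-accessible
    surface-area calculation on the protein in isolation, and each surface
    atom is assigned one of sixteen atom types encoding element, hybridisation
    context and polarity/charge. Complexes are voxelized into 4D one-hot grids
    at 1 Angstrom resolution, binding voxels are labelled by a triple 6
    Angstrom proximity rule, and grids are augmented with the 24 proper cubic
    rotations. A fully convolutional 3D UNET with DenseNet-style blocks and
    MISH activations is trained with binary cross-entropy to emit a per-voxel
    binding heat map, which is binarized by two rounds of k-means clustering.
    Per-voxel confusion statistics (accuracy, sensitivity, specificity,
    precision, MCC) and rank-based ROC AUC complete the pipeline.
    Deterministic synthetic protein-DNA fixtures and planted-pattern voxel
    tasks make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
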