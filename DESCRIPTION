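Package: nmhybrid
Title: Hybrid Radiomics and Deep-Feature Classification of Early Parkinson's
    Disease from Neuromelanin-Sensitive MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for classifying early Parkinson's disease
    from short-echo-time magnitude (setMag) volumes reconstructed from
    multi-echo QSM acquisitions. Includes a synthetic midbrain phantom
    generator, setMag reconstruction and preprocessing, a trainable
    brainstem localizer emitting 40x40x4 patch stacks, IBSI-style
    radiomics extraction (1781 features: six families over the original
    and 18 filtered images), ICC/LASSO feature selection, a modified
    LeNet feature extractor with a 1x200 feature layer, mean-decrease-
    in-impurity feature ranking and 10+20 hybrid fusion, six classical
    classifiers with patient-level 3-of-4 voting, and evaluation via
    ACC/SEN/SPE/PPV/NPV/F1, bootstrap AUC, NRI/IDI, and Dice agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    e1071,
    class,
    nnet,
    rpart,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
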