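Package: pancvas
Title: Tumor-Vessel Involvement Features and Risk Scores for Pancreatic
    Cancer CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the spatial relationship between a pancreatic tumor
    and the five major peripancreatic vessels (CA, CHA, SMA, PV, SMV) from
    co-registered 3D segmentation masks. Skeletonizes vessel masks, profiles
    vessel radius and tumor distance along each branch, and computes the 14
    anatomically designed tumor-vessel features (encasement angle, radius and
    radius-distance statistics, contact area and length) together with tumor
    shape features (sphericity, compactness, flatness, principal axes).
    Evaluates published logistic risk scores for vascular deformation and
    tumor morphology, fits per-vessel involvement and R0-resection models
    with Wald statistics, and provides ROC, DeLong, McNemar, kappa,
    Hosmer-Lemeshow, decision-curve and nomogram utilities. A phantom module
    generates synthetic vessel/tumor scenes with known geometric ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
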