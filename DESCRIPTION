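Package: meshgat
Title: Tumor Mesh Morphometry and Graph Attention Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies breast-tumor surface meshes as benign or malignant from
    ten clinically motivated three-dimensional shape features. Provides triangle
    mesh input/output for common formats (PLY, OBJ, OFF, STL), boundary-edge
    hole quality control, signed-distance geometry, covariance-eigenvalue and
    distance-based feature extraction, ANOVA and minimum-redundancy
    maximum-relevance feature assessment, construction of a sample-similarity
    graph from row-wise Spearman correlations, and a multi-head graph attention
    network for transductive node classification, together with a synthetic
    tumor-shape generator that emulates smooth benign-like and spiculated
    malignant-like lesions with controllable class separation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
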