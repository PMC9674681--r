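Package: gladet
Title: Graph-Level Anomaly Detection with a Contrastive Graph Convolutional Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects anomalous graphs in a graph set (for example molecular graph
    collections) by training a dual graph-convolutional autoencoder on normal
    graphs only. A Gaussian weight-perturbed twin encoder provides a second
    contrastive view without data augmentation; graphs are scored by the error
    between node-level and graph-level representations of the input graph and of
    its decoded reconstruction re-encoded through the shared encoder. Includes a
    reader and writer for the multi-file TUDataset plain-text layout, degree-based
    node features for plain graphs, synthetic benchmark generators with planted
    local and global structural anomalies, cross-validated evaluation by ROC AUC,
    and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
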