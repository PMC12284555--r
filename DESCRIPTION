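Package: paomninet
Title: Context-Conditioned Artifact Removal for Sparse-Sampled Photoacoustic Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing streak artifacts from sparse-sampled photoacoustic
    tomography reconstructions with a context-conditioned convolutional network
    (the PA OmniNet architecture): a shared embedding, seven Pairwise-Conv-Avg
    blocks in a U-net-like encoder/decoder, and an output convolution, consuming
    a target image together with a small set of labeled input-output example
    pairs (the context set) in a single forward pass, so one trained model
    adapts to new transducer configurations without retraining. Includes a
    delay-and-sum simulator for ring, semicircle and multi-segment transducer
    arrays that generates paired sparse/dense datasets with grouped splits, a
    plain U-net baseline, MSE/SSIM/Alpha training losses, SSIM/RMSE/PSNR and
    edge-sensitivity evaluation statistics, a seeded training loop with
    sliding-window context assembly and early stopping, and reporting utilities
    for improvement tables and paired t-tests. All model code runs on a small
    built-in reverse-mode differentiation engine with compiled convolution
    kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
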