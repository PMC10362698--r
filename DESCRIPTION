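Package: tvae
Title: Temporal Convolutional Variational Autoencoders for Protein Family
    Sequence Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns low-dimensional latent representations of aligned
    homologous protein families with a variational autoencoder whose encoder
    is a stack of dilated causal convolutional (temporal convolutional
    network) residual blocks, regresses protein fitness (e.g. T50
    thermostability) on the latent space with a radial-basis-function
    Gaussian process, and generates candidate variants by sampling the
    latent neighbourhood of high-fitness sequences, decoding, scoring
    sequence identity, and screening by predicted fitness. Includes
    alignment cleaning and position-based sequence weighting, a phylogenetic
    sequence simulator for fully synthetic benchmarking, and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    cluster,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
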