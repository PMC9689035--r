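Package: rgcsnn
Title: Retinal-Ganglion-Cell Spiking Neural Networks for Burn Wound Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a lightweight U-type spiking neural network built from
    retinal-ganglion-cell (RGC) neurons for binary semantic segmentation of burn
    wounds in RGB photographs. Provides the RGC and leaky integrate-and-fire
    neuron dynamics with threshold firing and soft reset, a trainable
    convolutional spike encoder, skip-concatenation modules, a pyramid pooling
    bottleneck, surrogate-gradient backpropagation-through-time with Adam,
    the accompanying augmentation policy (transposition, colour jitter,
    salt-and-pepper noise), segmentation metrics (pixel accuracy, mean IoU,
    Dice), a synthetic wound-image generator for self-contained experiments,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    EBImage,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
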