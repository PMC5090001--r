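Package: spikebench
Title: Spike-Based Vision Benchmarking: Encoders, LIF/STDP Simulation and
    Evaluation Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for benchmarking spiking neural network (SNN) vision
    systems on rate- and rank-order-coded image stimuli. Converts grayscale
    images to spike trains by rate-normalized Poisson encoding or by
    four-scale difference-of-Gaussians rank-order coding with greedy filter
    overlap correction; reads, writes and interconverts jAER AEDAT event
    streams and per-neuron spike-time arrays (NumPy .npy interchange);
    simulates clock-driven leaky integrate-and-fire networks with static or
    spike-timing-dependent-plasticity synapses; provides a two-layer
    template-matching benchmark classifier with k-means subclassing and a
    fixed-point weight-quantization harness for feed-forward networks; and
    computes the standard SNN evaluation metrics (classification accuracy,
    response latency, synaptic events per biological second, and the
    reciprocal energy measures J/SE and Sops/W).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
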