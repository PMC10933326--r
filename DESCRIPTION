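Package: frmm
Title: Forecasting All Components of High-Dimensional Dynamical Systems by
    Feature-and-Reconstructed Manifold Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free multistep forecasting of every variable in a
    high-dimensional nonlinear dynamical system. A low-dimensional feature
    manifold of the observed multivariate series is learned by manifold
    learning (diffusion maps, locally linear embedding, ISOMAP, Laplacian
    eigenmaps, or local tangent space alignment) and mapped, by Gaussian
    process regression, to the final coordinate of each variable's
    delay-coordinate reconstruction, yielding forecasts up to (E-1)*tau steps
    ahead. Includes delay-embedding parameter selection (mutual information,
    false nearest neighbours), coupled Lorenz and Roessler benchmark
    simulators, cross-validated evaluation, and robustness sweep harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
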