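Package: flara
Title: Fiducial-Less Joint Alignment and Reconstruction for Electron Tomography
Version: 0.1.0
Authors@R:
    person("FLARA", "Developers", email = "flara@example.org", role = c("aut", "cre"))
Description: Joint marker-free tilt-series alignment and limited-angle
    tomographic reconstruction. Per-projection 2D shifts are re-computed in
    closed form from a linearized warping model while the volume is
    reconstructed with a masked, total-variation regularized, diagonally
    preconditioned primal-dual scheme, interleaving exactly one primal-dual
    iteration per shift update. Includes a parallel-beam projector with a
    pluggable backend interface, a geometric 3D phantom simulator for
    validation, evaluation metrics (PSNR, per-component shift error
    statistics with gauge handling), MRC/TIFF tilt-series I/O and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
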