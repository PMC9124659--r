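# flara

Fiducial-less joint alignment and reconstruction for electron tomography.

Electron tomography acquires a tilt series — projection images of a
specimen rotated about a single axis, typically over ±60° — and
reconstructs a 3D volume from it. Two things make this hard in practice:

* **per-image jitter**: stage instabilities translate every projection by
  an unknown 2D shift, which must be corrected before the images are
  consistent with any volume. The gold standard is to deposit gold
  fiducial markers on the specimen and track them, which costs time,
  material, and can occlude structures of interest;
* **the missing wedge**: angles beyond ±60° are not measured, so the
  inverse problem is severely ill-posed and needs regularization.

`flara` addresses both jointly and without markers. It solves

```
min_{u, f}  1/2 || M ( A u − W(b, f) ) ||²  +  λ || ∇u ||_{2,1}
```

where `u` is the volume, `A` the discretized parallel-beam projector,
`b` the observed tilt series, `W(b, f)` the stack translated by one 2D
shift `f` per projection, `M` a tilt-dependent mask excluding detector
regions that leave the reconstructed field of view, and the second term
is 3D total variation. The scheme alternates, per outer iteration:

1. **one** preconditioned primal–dual (Chambolle–Pock) iteration on the
   TV-regularized reconstruction sub-problem, with dual variables warm
   across iterations;
2. a **closed-form** recomputation of all shifts from the current
   reconstruction: the warp is linearized to first order around the
   current shifts (a Lucas–Kanade step), which decouples into one 2×2
   normal-equation solve per tilt angle.

Initial shifts come from cosine-stretched cross-correlation of
successive projections. A built-in phantom simulator (random cubes,
cuboids, spheres, ellipsoids; limited-angle projections; standard-normal
per-image shifts) reproduces the validation protocol, and a metrics
module computes PSNR and per-component shift error statistics with
explicit handling of the alignment gauge ambiguity (the absolute object
position is unrecoverable).

## Worked example

```r
library(flara)

# simulate: 48^3 phantom, 41 projections over +-60 deg, N(0,1) shifts
spec <- phantom_spec(size = 48, n_shapes = 12, seed = 1)
geom <- tilt_geometry(seq(-60, 60, by = 3), c(48, 48, 48))
ds   <- make_dataset(spec, geom, shift_sigma = 1, seed = 1001)

# joint alignment + reconstruction
cfg <- flara_config(n_iter = 500, record_every = 100)
res <- flara(ds$b, cfg, geom = geom, u_gt = ds$u_gt)
print(res)

# how well were the injected shifts recovered?
shift_error_stats(res$shifts, ds$f_true, gauge = "linear_tan",
                  angles_deg = geom$angles_deg)
```

Output from this exact script:

```
flara_result: volume 48x48x48, 41 projections, 500 iterations
  final energy 2692.16, final max shift delta 0.0003925 px
  final PSNR vs ground truth 24.62 dB
  component          mse       std_sq         mae     std_abs     max_ae
1        f0 5.363419e-05 9.130098e-05 0.005660757 0.004704228 0.02133699
2        f1 2.021309e-04 2.186445e-04 0.012453911 0.006943112 0.03338170
```

Reading: after 500 joint iterations the shift updates have stabilized to
less than 0.001 px per iteration; the injected per-projection shifts are
recovered to ~0.006 px mean absolute error (horizontal) and ~0.012 px
(vertical) after removing the unidentifiable gauge, and the volume PSNR
against the known phantom is 24.6 dB — within ~0.4 dB of what a
reconstruction frozen at the *true* shifts achieves on the same data.
Freezing the shifts at their pre-alignment values instead costs several
dB (see the acceptance suite).

## Command line

```sh
Rscript -e 'flara::flara_cli()' simulate    --size 64 --shift-sigma 1 --seed 1 --out-dir sim
Rscript -e 'flara::flara_cli()' reconstruct --tilt-series sim/tilt_series.mrc \
        --angles sim/tilt_series.tlt --lambda 0.5 --iters 2000 --out-dir rec
Rscript -e 'flara::flara_cli()' evaluate    --recon rec/reconstruction.mrc \
        --truth-volume sim/phantom.mrc --est-shifts rec/estimated_shifts.tsv \
        --true-shifts sim/true_shifts.tsv --angles sim/tilt_series.tlt \
        --gauge translation --out metrics.json
```

Tilt series are read/written as MRC stacks or multi-page float TIFF, with
plain-text `.tlt` angle files; volumes as MRC mode 2.

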