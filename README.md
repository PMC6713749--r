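# myostrain

3D myocardial tracking and Lagrange strain estimation from time-resolved
tagged MR volumes, for researchers working on cardiac motion analysis and
deformable registration.

The left ventricle shortens, thickens and twists simultaneously during a
heartbeat; tagged 3D MRI makes that motion visible by imprinting a
deforming intensity grid on the muscle. `myostrain` recovers the motion
and the strain it implies:

1. **Hierarchical template matching.** The moving frame is decomposed
   into nested cubic blocks — templates (16³ voxels), segments (8³),
   chunks (4³) and windows (2³) — each matched into the end-diastolic
   reference frame by exhaustive 3D normalized cross-correlation
   (λ ∈ [−1, 1], invariant to affine intensity changes), children
   refining their parents. Candidate matches are screened by a pyramid of
   overlapping blocks; disagreeing subtrees become non-displaced points.
   Each matched window contributes one sparse correspondence (mᵢ, rᵢ).
2. **Local Weighted Mean (LWM) transformation.** Around every control
   point a second-order, ten-coefficient polynomial is least-squares
   fitted over the point and its n − 1 nearest neighbours (n = 100); a
   point p is mapped by the weighted mean of all local polynomials
   reaching it, blended with W(R) = 1 − 3R² + 2R³ (W' = 0 at R = 0, 1,
   so the map is C¹). No large linear system is solved, and local
   geometric differences are adapted naturally.
3. **Strain.** Mesh nodes are tracked forward per frame; at each node
   U = ∇u (w.r.t. deformed coordinates), F = (I − U)⁻¹ and
   E = ½(FᵀF − I). E is projected on the anatomical frame —
   longitudinal L (apex → mitral centre), radial R = M − (M·L)L from the
   outward normal M, circumferential C = L × R — and summarised as
   per-frame median curves plus median eigenvalue (principal strain)
   curves.

A synthetic tagged-LV phantom (analytic, invertible motion with exact
displacement and strain oracles) ships with the package so every stage is
testable without external data.

## Worked example

```r
library(myostrain)

spec  <- phantom_spec(seed = 1)            # 64^3, 10 frames, ES at frame 6
truth <- make_deformation(spec)
vols  <- render_frames(spec, truth)

tracking <- track_sequence(vols, hierarchy_params(t = 16, search_radius = 6),
                           n = 100)
result   <- strain_pipeline(tracking, phantom_mesh(spec))

lm  <- track_landmarks(tracking, phantom_landmarks(spec))
landmark_error(lm, export_truth(truth)$trajectories,
               end_systolic_index = spec$end_systolic_index)
#> <error_summary>
#> # A tibble: 3 × 3
#>   category     median_mm max_mm
#>   <chr>            <dbl>  <dbl>
#> 1 all_frames       0.242  0.552
#> 2 end_systolic     0.280  0.503
#> 3 final            0.208  0.238

round(as.data.frame(result$curves)[5:7, 1:5], 4)
#>   frame     E_L     E_C     E_R    eig1
#> 5     5 -0.0992 -0.0771 -0.0406 -0.1325
#> 6     6 -0.0884 -0.0881 -0.0516 -0.1373
#> 7     7 -0.1049 -0.0748 -0.0475 -0.1362
```

Tracked landmarks stay within ~0.25 mm (about a quarter voxel) of the
analytic trajectories. Longitudinal and circumferential strain are
negative through systole with peak magnitudes near −0.09 to −0.10 at
end-systole, radial strain is small — the physiological pattern for a
contracting ventricle — and the two lower principal-strain curves reach
their most negative values at the end-systolic frame.

`autoplot(result$curves)` draws the directional strain curves;
`plot_eigenvalue_curves(result$curves)` the principal-strain curves.

## Command line

A thin CLI over the same functions lives at
`system.file("cli", "myostrain.R", package = "myostrain")`:

```sh
Rscript myostrain.R phantom  --out phantom/ --seed 1
Rscript myostrain.R track    --frames phantom/frames.nii.gz --es 6 \
                             --out run/ --landmarks phantom/landmarks_truth.csv
Rscript myostrain.R strain   --frames phantom/frames.nii.gz \
                             --mesh phantom/mesh.obj --es 6 --out run/
Rscript myostrain.R validate --predicted run/landmarks_tracked.csv \
                             --truth phantom/landmarks_truth.csv \
                             --es 6 --out summary.json
```

All CSV/JSON outputs declare their units (mm vs voxel) and index base;
identical configuration and seed reproduce byte-identical outputs.

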