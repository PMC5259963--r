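# trabecula

Quantitative analysis of the conventional aqueous humor outflow pathway —
trabecular meshwork (TM), Schlemm's canal (SC) and aqueous vein — from
depth-resolved optical-section image stacks, with a linear-elastic
finite-element model of TM deformation under the pressure drop between
intraocular pressure (IOP) and episcleral venous pressure (EVP).

The package is aimed at researchers studying aqueous outflow resistance and
ocular hypertension who need reproducible, scriptable versions of
measurements that are usually done interactively on two-photon / SHG stacks
of the limbus:

* **TM porosity versus depth.** Per optical section: crop the valid TM
  region, linear 1–99 percentile contrast stretch, segmentation threshold
  from the gray histogram (Otsu's between-class-variance maximizer
  `argmax_t  w0(t) w1(t) (mu0(t) − mu1(t))^2` on 256 bins), pore mask =
  below-threshold pixels (signal voids), porosity = pore_pixels /
  valid_pixels.
* **Lumen diameters versus depth.** Largest dark 8-connected component in a
  region of interest, then the mean of `n = 5` chords through its centroid
  at orientations `0, pi/5, …` — a deterministic surrogate for "measured
  five times and averaged".
* **Reconstruction.** Threshold segmentation, seeded region growing and
  morphological editing with replayable provenance, then exact
  voxel-to-tetrahedron meshing (Kuhn subdivision: volume-conserving,
  face-conforming, positively oriented) with labeled pressure/fixed
  boundary faces, exported as legacy VTK or Gmsh MSH.
* **FEM.** Small-strain isotropic linear elasticity (default E = 162 Pa,
  nu = 0.48) on constant-strain tetrahedra; consistent pressure loads;
  per-dof Dirichlet elimination; sparse Cholesky with CG fallback; pressure
  sweep 10–160 Pa in 10 Pa steps reporting the maximum directional
  deformation (displacement component along the load direction).

Because no depth-resolved limbus stacks are publicly deposited, the package
includes a calibrated synthetic scene generator (`default_intact_config()`,
`default_broken_config()`) producing image stacks plus voxel ground-truth
labels; every measurement is validated by parameter recovery against those
labels, and the FEM against closed-form oracles. See the vignette
`vignettes/outflow-morphometry.Rmd` for the models, assumptions and
numerical choices.

## Worked example

```r
library(trabecula)

cfg <- default_intact_config()          # documented default seed 42
lab <- build_labels(cfg)                # ground-truth voxel labels
stk <- render_intensities(lab, cfg)     # synthetic two-photon stack
stk
#> image_stack: 512 x 512 px, 27 slices
#>   lateral pitch 2 um, axial step 5 um, depths 90..220 um
#>   intensity range [0, 1375]

porosity_profile(stk, default_tm_roi(cfg))
#> porosity_profile: 7 depths, porosity 0.628..0.737 over 185..215 um
#>   depth_um  porosity threshold pore_pixels valid_pixels
#> 1      185 0.6277344 0.4609375       14463        23040
#> 2      190 0.6456597 0.4570312       14876        23040
#> 3      195 0.6647569 0.4570312       15316        23040
#> 4      200 0.6820312 0.4531250       15714        23040
#> 5      205 0.7023438 0.4531250       16182        23040
#> 6      215 0.7366753 0.4453125       16973        23040
```

TM porosity rises monotonically with depth from 0.63 to 0.74: as imaging
proceeds toward the inner meshwork, the fluid-filled gaps occupy a growing
area fraction of the tissue. The per-slice `threshold` column shows the
Otsu cut adapting to depth attenuation. (Row 6 of 7 omitted above for
brevity.)

```r
diameter_profile(stk, default_sc_roi(cfg))[c("depth_um", "mean_diameter_um")]
#>   depth_um mean_diameter_um
#> 1      190         48.14934
#> 2      195         52.87080
#> 3      200         57.61646
#> 4      205         64.09473
#> 5      210         60.47861
#> 6      215         52.70592
```

The SC caliber grows from about 48 um at 190 um depth to a maximum of about
64 um near 205–207 um, then narrows again — the canal is widest near its
mid-depth. The broken-eye preset (`default_broken_config()`) reproduces the
collapsed meshwork: porosity 0.44–0.59, strictly below the intact profile
at every depth.

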