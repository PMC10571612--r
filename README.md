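# nucleopch

Coarse-grained simulation of pericentromeric-heterochromatin (PCH) /
nucleolus co-assembly, and the quantitative 3D image metrics used to score
condensate organization in microscopy volumes.

## The scientific problem

In many nuclei the nucleolus is surrounded by a shell of PCH, and this
layered arrangement is disrupted when the ribosomal DNA (and hence the
nucleolus) is removed: PCH first hyper-compacts, then reorganizes into a
hollow shell whose core fills with nucleolar proteins that form new bodies
("neocondensates"). A minimal physical explanation is a *hierarchy of
affinities* between four components — PCH (H), the rDNA block (rD),
a self-associating nucleolar protein (Fibrillarin, F), and an amphiphilic
protein (X) with affinity for both sides:

```
rD-F = F-F > X-X > F-X > X-H > H-H      (attraction strengths, kBT)
```

`nucleopch` implements this model as a bead-spring / free-particle system
under underdamped Langevin dynamics (BAOAB) inside a spherical nuclear
confinement: harmonic bonds `V = ks (r - sigma)^2` with `ks = 100
kBT/sigma^2`, a bending term giving a 2-bead (60 nm) persistence length,
12-6 Lennard-Jones pair interactions truncated at `2.5 sigma` (attractive
pairs) or `2^(1/6) sigma` (excluded-volume pairs, `epsilon = 1 kBT`), and a
confinement radius derived from the chromatin volume fraction
(`phi = 0.1` gives `Rc = 45 sigma` for the 72,000-bead diploid genome at
5 kbp per 30 nm bead). On top of the simulator sit the named experiments
(+rDNA / -rDNA scenarios, condensation phase diagram, chain-collapse,
rDNA-engulfment, wetting and amphiphile-depletion sweeps), the trajectory
observables (clustering, radius of gyration, inter-condensate distances,
wetting/engulfment/layering classification), and an imaging module with a
synthetic ground-truth nucleus-volume generator.

## A worked example

```r
library(nucleopch)

genome <- GenomeModel()              # 360 Mbp diploid, 5 kbp/bead, phi = 0.1
nGenomeBeads(genome)                 # 72000
confinementRadiusFromPhi(genome)     # 44.8 sigma  (the nominal 45 sigma)
countFromConcentration(0.013, 45)    # 4962 Fibrillarin beads at cF = 0.013

plusRdnaMatrix()
#> InteractionMatrix (kBT); '.' marks excluded-volume pairs
#>    H    rD F   X
#> H  0.35 .  .   1
#> rD .    .  2   .
#> F  .    2  2   1.5
#> X  1    .  1.5 1.75
```

Run a desk-scale -rDNA scenario and classify the outcome:

```r
res <- runScenario("minus-rdna", scale = 1/64, seed = 1,
                   prodSteps = 400000)
res$report   # verdict: neocondensate_in_H; rD interior fraction 0;
             # d_HF larger than the matched +rDNA run
```

Score a synthetic microscopy volume with known ground truth:

```r
g <- generateNucleusVolume("surrounded", dim = c(48, 48, 48),
                           noise = 0.05, seed = 7)
nuc <- segmentChannel(g$image, "fib",  method = "otsu", gaussianSigma = 1)
pch <- segmentChannel(g$image, "hp1a", method = "otsu", gaussianSigma = 1)
shellOccupancy(nuc, pch, dilationPx = 1)
#> [1] 1
nearestObjectDistance(nuc, pch)$distance
#> [1] 0.001        # micrometres; concentric objects share a centroid

ext <- generateNucleusVolume("extended", dim = c(64, 64, 48),
                             aspectRatio = 2, noise = 0.05, seed = 3)
segH <- segmentChannel(ext$image, "hp1a", method = "otsu", gaussianSigma = 1)
aspectRatio2D(apply(labelArray(segH) > 0, c(1, 2), any))$ratio
#> [1] 1.95        # recovers the generated 2:1 shape under noise
```

The shell occupancy of 1 means the PCH channel occupies the entire 1-pixel
shell around the segmented nucleolus — the canonical "surrounded"
organization; the aspect-ratio call recovers the generated elongation of
the "extended" organization to within a few percent.

A command-line wrapper is installed with the package
(`system.file("scripts", "nucleopch", package = "nucleopch")`) exposing
`sim scenario`, `sim sweep`, `img synth` and `img metrics`.

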