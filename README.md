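# scintiseg

Semi-supervised detection and delineation of bone-metastasis lesions in
planar bone-scan (skeletal scintigraphy) images, for nuclear-medicine
image analysts and methods researchers who need pixel-level lesion maps
from data where manual labels are scarce.

A bone scan is a count matrix: each pixel of the 256 x 1024 whole-body
(or 256 x 256 thoracic) image is a 16-bit integer count of detected
gamma photons. Metastases show as focal high-uptake regions, but so do
normal spine, sternum and ribs, and the count scale varies strongly
between patients — so neither thresholding nor purely supervised
learning (which needs labels nobody has at scale) is adequate.

## The method

A recurrent convolutional feature extractor — dilated residual blocks,
an inception bottleneck, and a decoder back to full resolution, unrolled
*t* times with the recurrence
*z*(*t*) = *W<sub>F</sub>* *u*(*t*) + *W<sub>R</sub>* *x*(*t*−1) + *b* —
feeds a per-pixel logistic classifier *m* = σ(logits) ∈ [0, 1]. Training
is semi-supervised through the loss

> ℓ = ℓ<sub>U</sub> + α · ℓ<sub>S</sub>,  α = 0.4

where every image (labeled or not) contributes the relaxed Chan–Vese
region energy

> ℓ<sub>U</sub> = v · Σ m + Σ m (g − c₁)² + Σ (1 − m)(g − c₂)²,  v = 0.004

(c₁, c₂ the mean intensities inside/outside the predicted region), and
labeled images add the label-guided smoothness term

> ℓ<sub>S</sub> = TV(m) + Σ (1 − 2μ) m

with μ the binary consensus mask from a triple-annotation protocol
(labels accepted when all pairwise area differences ΔA = 1 − IoU are
≤ 5%). Evaluation is pixel-wise Dice (DSC), class pixel accuracy
(precision) and recall, on patient-grouped 70/30 splits with ten
repeated test runs.

The clinical dataset behind the method is private, so the package ships
a dual-view phantom generator (torso + spine/ribs + Poisson counts +
elliptical lesions placed in the anterior view, the posterior view, or
both) that makes every stage — I/O, cropping, anterior/posterior
aggregation, annotation agreement, augmentation (geometric and DCGAN),
training, evaluation, boundary extraction — testable end to end. The
network, its backpropagation (including through-time for the
recurrence) and the losses are implemented in R with compiled kernels;
correctness is pinned by finite-difference gradient checks and
per-pixel loop oracles in the test suite.

## Worked example

Train on 200 synthetic phantoms (37% labeled), evaluate on 60 held-out
phantoms, and delineate lesions in one test image:

```r
library(scintiseg)

spec  <- phantom_spec(seed = 7)                 # 64x64 dual-view phantoms
ds    <- generate_dataset(spec, 260)
split <- make_split(ds$manifest, train_fraction = 200/260,
                    label_fraction = 0.37, seed = 7)

cfg   <- model_config(recurrence_t = 1L, stage_channels = c(3L, 6L),
                      input_size = 64L, seed = 7)
model <- build_model(cfg)
#> <seg_model> t = 1 (shared weights), stages [3, 6], dilated = TRUE,
#>             inception = TRUE, residual = TRUE, 2,635 parameters

tc  <- train_config(epochs = 20L, input_size = 64L, batch_size = 10L,
                    seed = 7)
fit <- train_semisupervised(model, ds$samples, split, tc)
ev  <- evaluate_repeated(fit$model, ds$samples, split$test_ids, runs = 10)
round(ev$mean, 3)
#>    DSC    CPA Recall
#>  0.597  0.493  0.922

seg        <- forward(fit$model, ds$samples[[split$test_ids[1]]]$image)
boundaries <- extract_lesion_boundaries(seg)
length(boundaries)
#> [1] 1
```

The mean test Dice of about 0.6 says that, averaged over held-out
phantoms, well over half of the predicted lesion area coincides with
the true lesion area; recall 0.922 means most true lesion pixels are
found, and the lower precision (0.493) reflects spill-over onto the
bright spine and rib bands — the same confounders that make clinical
scans hard. Training the identical model with no labels is what the
unsupervised region energy alone achieves (DSC ≈ 0.4 under these
conditions); the gap is the value of the 37% labeled subset. The single extracted
boundary polygon for a five-lesion phantom shows adjacent predicted
lesions merging into one component — multi-lesion images are the hard
case for this method class.

A thin command-line wrapper over these functions is installed at
`inst/cli/scintiseg.R` (subcommands `simulate`, `train`, `segment`,
`evaluate`).

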