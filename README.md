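# TaskSaliency

Predicting *where people look* changes character as soon as the viewer has a
task. Under free viewing, fixations are driven by bottom-up contrast and a
strong bias toward the image center; under a visual-search task ("count the
dogs in this picture"), fixations concentrate on the target objects and
agree strongly across observers. TaskSaliency is an R package for building
and evaluating **task-driven saliency models** from eye-tracking data: it is
aimed at vision researchers who have per-subject gaze recordings on images
with annotated target bounding boxes and want a transparent, linear,
feature-interpretable model of task-driven attention — plus the standard
dataset statistics (fixation-map entropy, center-bias fractions,
inter-observer consistency) that characterize such recordings.

## The model

Everything happens on a canonical 200 x 200 pixel frame. For each image the
package computes five per-pixel feature maps, each max-normalized to [0, 1]:

* **color, intensity, orientation** — bottom-up conspicuity in the classic
  center-surround tradition: Gaussian pyramids of the intensity, red–green /
  blue–yellow opponency, and oriented Gabor-energy channels; across-scale
  differences `|center − surround|` at center scales {2, 3} and scale deltas
  {2, 3}; a peak-promoting normalization `(M − m̄)²` of every intermediate
  map; summation at the canonical frame.
* **target** — for pixels inside an annotated target box, the Euclidean
  distance to the box center divided by the box half-diagonal (minimum over
  covering boxes); 0 outside all boxes. An inverted encoding
  (1 − distance inside boxes) is available as an option.
* **center** — the distance of each pixel to the frame center, normalized by
  the frame half-diagonal.

Ground truth for an image is the continuous fixation map
`G(p) = Σᵢ exp(−‖p − fᵢ‖² / 2σ²)` over its gaze points (σ = 10 px by
default), max-normalized. Per image, 20 pixels are sampled from the top 20%
of ground-truth values (positives) and 20 from the bottom 70% (negatives);
the resulting balanced feature matrix is standardized to zero mean and unit
variance and a **linear soft-margin SVM** (cost C = 1) is trained per search
category. Because the features are standardized, the learned weights are
directly comparable magnitudes: the weight table *is* the model's account of
what drives task-driven attention.

A predicted saliency map is the standardized weighted sum of the five maps,
min-max normalized. Evaluation is ROC/AUC with fixated pixels as positives
(the AUC equals the tie-corrected Mann–Whitney statistic), reported as
per-category mean ± SD under k-fold cross-validation. Inter-observer (IO)
consistency — the AUC of each subject's fixations predicted from everyone
else's pooled map — gives the empirical ceiling.

Because no public gaze recordings accompany this design, the package ships a
first-class synthetic generator: colored-rectangle scenes with distractors,
and per-subject gaze drawn from a target/center/uniform mixture whose
weights, spreads and sizes are all configurable. It exists so that every
stage — features, sampling, learning, evaluation — is testable end to end
with known ground truth.

## Worked example

```r
library(TaskSaliency)

cfg <- syntheticConfig(nImagesPerCategory = 6, categories = c("chair", "dog"),
                       nSubjects = 5, nGazePerSubjectPerImage = 40,
                       mix = c(0.7, 0.2, 0.1), seed = 42)
ds <- generateDataset(cfg)
ds
#> GazeDataset: 12 images, 2 categories, 2400 gaze points, 19 boxes

stacks <- buildFeatureStacks(ds)
cv <- crossValidate(ds, stacks = stacks, k = 3, seed = 42)
cv
#> CrossValResult: k = 3, mean AUC = 0.7926 (population SD 0.0211)

print(weightReport(cvModels(cv)), digits = 3)
#>    category     feature avg_weight std_weight abs_rank
#> 1     chair       color   -0.00831     0.2357        5
#> 2     chair   intensity    0.14542     0.1268        3
#> 3     chair orientation    0.09586     0.1792        4
#> 4     chair      target    0.98609     0.3816        2
#> 5     chair      center   -2.06154     0.3553        1
#> 6       dog       color    0.09905     0.1181        3
#> 7       dog   intensity   -0.07834     0.1001        4
#> 8       dog orientation   -0.05425     0.0920        5
#> 9       dog      target    1.29600     0.0573        2
#> 10      dog      center   -1.64345     0.1033        1

print(ioConsistency(ds), digits = 3)
#>   category target_present avg_auc std_auc n_images
#> 1    chair          FALSE   0.721 0.00811        2
#> 2    chair           TRUE   0.889 0.01580        4
#> 3      dog          FALSE   0.714 0.00401        2
#> 4      dog           TRUE   0.876 0.01658        4
```

Reading the output: the model predicts held-out fixations clearly above
chance (mean AUC 0.79). The weight table says attention in this simulated
study is pulled toward the frame center (large negative weight on the
center-*distance* feature) and toward target boxes (large positive target
weight), with the bottom-up channels contributing little — exactly the
structure the generator put in. IO consistency is higher on target-present
images (≈0.88) than target-absent ones (≈0.72): when a target exists,
subjects agree on where to look.

A command-line front end wraps the same workflow
(`inst/cli/saliency simulate|features|train|evaluate|analyze`); every stage
logs its resolved configuration and master seed, and reruns with the same
seed are byte-identical.

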