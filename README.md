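# panseg

Tooth segmentation on dental panoramic radiographs, implemented as a
self-contained R package: the classic **UNet** baseline, an adapter-tuned
hierarchical-transformer segmentation network (**S2AgScUNet** — frozen
pretrained-style trunk, bottleneck adapters, receptive-field blocks,
spatial/channel reconstruction units, attention-gated skip connections),
and a distilled 1/8-width student (**LightUNet**), together with the
training losses, pixel metrics, exact parameter/MAC cost accounting, a
heavy-tailed weight-spectrum overfit audit, and a synthetic
radiograph-fixture generator so the whole pipeline runs end-to-end on one
CPU with no external data or deep-learning framework.

Panoramic radiographs are noisy, low-contrast and scarce (the largest
public collection holds 1500 images in ten categories), so from-scratch
deep models overfit, and the accurate ones are too heavy for chairside
deployment. The package's model family addresses both ends: a frozen
large hierarchical encoder tuned through small adapters

    Adapter(X) = GeLU(W_up · GeLU(W_down · X)),

attention-gated skips

    Y = sigma(W_R ReLU(W_S X_S + W_D X_D)) ⊙ X_D,

a UNet-style decoder `ReLU(BN(Conv(ReLU(BN(Conv(X))))))`, and
temperature-scaled knowledge distillation of an eighth-width student

    L = alpha · L_CE(y, y_s) + (1 − alpha) · T² · KL(softmax(y_t/T) ‖ softmax(y_s/T)).

A spectral audit fits power-law tail exponents to each layer's weight
eigenvalue spectrum; exponents in (2, 6) mark well-trained layers, above 6
overfitting, below 2 underfitting.

All network primitives (convolution, transposed convolution, batch/group/
layer norm, windowed attention, Adam) are implemented in the package with
compiled kernels — no torch required.

## Worked example

```r
library(panseg)

# architecture accounting at the standard 3x512x512 input
count_costs(unet_spec())
#> unet @ input 3x512x512
#>   parameters : 31,037,698 learnable + 11,776 norm stats = 31.05 M state
#>   MACs       : 192.69 G
count_costs(lightunet_spec())
#> unet @ input 3x512x512
#>   parameters : 486,562 learnable + 1,472 norm stats = 0.49 M state
#>   MACs       : 3.06 G

# the published large trunk: 214 M parameters, 1152 deepest-stage channels
round(count_trunk_parameters(encoder_config("large")) / 1e6)
#> [1] 214
pyramid_shapes(encoder_config("large"), 512)
#>   stage channels height width
#> 1     1      144    128   128
#> 2     2      288     64    64
#> 3     3      576     32    32
#> 4     4     1152     16    16

# synthetic fixtures: train a small student and evaluate it
train_set <- scene_batch(20, size = 64, seed = 1000)
student <- build_unet(unet_spec(1/8, input_size = c(3, 64, 64)), seed = 2)
fit <- train(student, train_set,
             distill_config(epochs = 8, batch_size = 16, seed = 7))
tail(fit$log, 1)
#>   epoch     loss  ce_term kl_term
#> 8     8 0.446347 0.446347       0

test_set <- scene_batch(8, size = 64, seed = 1500)
pred <- predict(fit$model, test_set$images[, , , 1, drop = FALSE])
metrics_from_counts(confusion_counts(pred[, , 1], test_set$masks[, , 1]))
#>         iou      dice precision    recall        f1 degenerate
#> 1 0.6246575 0.7689713 0.8028169 0.7378641 0.7689713

# weight-spectrum overfit audit: exponents per layer with the 2/6 band
audit_model(fit$model)
#> spectral audit (well-trained band: 2 <= alpha <= 6)
#>  component mean_alpha n_layers         band
#>    Encoder   5.225663        8 well-trained
#>    Decoder   5.000361       10 well-trained
#> 18 layers fit, 5 flagged (too few eigenvalues)
```

The meaning of the headline numbers: `31.05` and `0.49` are the baseline
and student model sizes in millions of stored values (weights plus
normalization statistics), a ratio of `0.016`; `214` M is the published
size of the large encoder trunk whose four stages emit 144/288/576/1152
channels; the segmentation metrics lie in [0, 1] with
Dice = 2·IoU/(1+IoU) by identity.

A small command-line wrapper is installed with the package
(`system.file("cli", "panseg.R", package = "panseg")`) with `generate`,
`count`, `audit` and `eval` subcommands.

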