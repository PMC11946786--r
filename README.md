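# echoretnet

Left-ventricle segmentation in echocardiography video, in pure R.

Physicians outline the left ventricle (LV) at the end-diastolic (ED) and
end-systolic (ES) frames of an echo clip to compute the ejection
fraction. Speckle noise, low contrast and out-of-view truncation make
those contours ambiguous, and only the ED/ES frames carry labels — the
frames in between are unlabeled but informative. `echoretnet` implements
a video segmentation model that

* fuses an 8-frame clip's temporal context into its key frame with
  **temporal–channel self-attention** over multi-window groupings of the
  fused time–channel axis, plus a channel-aggregation stage
  `CA(Y) = Y + s ⊙ (Y − GELU(Conv1×1(Y)))`;
* encodes with a four-stage **retentive vision backbone** whose
  attention carries an explicit spatial prior,
  `MaSA(X) = (softmax(QKᵀ) ⊙ D) V` with
  `D[n,m] = γ^(|x_n−x_m| + |y_n−y_m|)` (Manhattan-distance decay;
  decomposed into two 1D attentions in stages 1–3, full 2D in stage 4);
* decodes with a feature-pyramid decoder and scores with Dice and
  HD95.

Because no deep-learning framework exists in a plain R stack, the
package ships its own reverse-mode autodiff (convolutions via im2col,
norms, attention, bilinear resampling) and an AdamW trainer, all
gradient-checked against finite differences. A speckle-phantom
generator produces echo-like clips with exact masks, so the entire
pipeline — dataset dialects included — is trainable and testable with no
downloads.

## Worked example

```r
library(echoretnet)

# a 64-clip synthetic corpus, written in the EchoNet-style dialect
pc   <- phantom_config(image_size = 64)
recs <- generate_corpus(64, pc, dir = "corpus", seed = 100)

train <- clean_dataset(Filter(function(r) r$split == "TRAIN", recs))
held  <- clean_dataset(Filter(function(r) r$split != "TRAIN", recs))

model <- assemble_model(reduced_config(), seed = 11)
fit   <- train_model(model, dataset_items(train),
                     train_config(lr = 3e-3, adam_eps = 1e-3,
                                  weight_decay = 0, epochs = 10,
                                  batch_size = 2, lr_drop_epochs = c()))
report <- evaluate_model(fit$model, held)
print(report)
```

Output from this exact run:

```
<seg_report>
  items: 40 (ED=20, ES=20)
  mean DSC:  0.9222
  mean HD95: 1.940 px
```

Mean DSC is the Dice overlap `2|A∩B|/(|A|+|B|)` between predicted and
true LV masks over the 40 held-out key frames (20 videos × ED/ES);
mean HD95 is the 95th-percentile Hausdorff boundary distance in pixels.
An untrained model scores DSC 0; a run of a few minutes on one CPU
reaches ~0.92 on the phantom's held-out clips.

Lower-level pieces are exported too:

```r
decay_2d(2, 2, 0.5)          # Manhattan decay over a 2x2 token grid
masa_full(q, k, v, 0.9)      # full 2D Manhattan self-attention
masa_decomposed(q, k, v, 0.9)
masa_flops(56, 56, 32) / masa_flops(56, 56, 32, decomposed = TRUE)
dice(A, B); hd95(A, B)
```

A thin CLI over these functions lives at `inst/cli/echoretnet.R`
(`generate`, `train`, `evaluate`, `predict`, `inspect-config`).

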