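# edgewalk

Edge-sensitive left-ventricle (LV) segmentation by deep reinforcement
learning, in pure R.

Most LV segmentation tools classify every pixel. `edgewalk` instead traces
the endocardial boundary the way a human annotator does: a convolutional
**first-point network** scans the image once, produces a 1/8-resolution
edge-probability map and picks the first boundary point; a **double
deep-Q-network agent** then walks from edge point to edge point through an
8-direction *skip neighborhood* (n pixels per move), guided by a local
5-layer state window, until the contour closes. The ordered point list is
the segmentation; its filled polygon is the mask.

## The model in brief

The tracing problem is a Markov decision process ⟨S, A, P, R, γ⟩:

- **S**: a `w × w × 5` window centred on the current edge point — grayscale,
  Sobel magnitude, upsampled edge-probability map, past-points map, plus the
  global probability map resized to `w × w` (a round-object shape prior).
- **A**: 8 skip-neighborhood moves (n = 5 px full size, reduced to 3 near
  closure; 4 → 2 in the desk profile).
- **R**: per step, `r = R_diffIoU + R_edgeDist + R_clus` where
  - `R_diffIoU = sign(IoU(M_curr, GT) − IoU(M_prev, GT)) ∈ {−1, 0, 1}`,
    `M_prev` omitting the last 5 traced points,
  - `R_edgeDist = 0.05 · (10 − d)` for distance-to-boundary `d < 10`, else 0,
  - `R_clus = −0.5` when the last 20 points' dispersion falls below 10 px,
  so `r ∈ [−1.5, 1.5]` with the default configuration.
- Learning: double DQN — `y = r + γ Q_targ(s′, argmax_a Q_eval(s′, a))`,
  γ = 0.9, ε-greedy behaviour with ε = 0.2 (train *and* test), FIFO replay
  buffer, target sync every 2,000 updates (200 at desk scale), Adam.

Everything runs on a compact neural-network engine written in R (im2col
convolutions, manual backprop, finite-difference-verified gradients) since
no deep-learning library is available in the target stack. A synthetic
LV-phantom generator (bright blood pool, darker myocardial ring, intensity
inhomogeneity, blur, noise, papillary-muscle-like boundary notches, with
exact ground-truth contour and mask) makes every stage trainable and
testable offline. See `vignettes/edgewalk-methods.Rmd` for the full account.

## Worked example

```r
library(edgewalk)

# 20 training phantoms + 1 held-out, with exact ground truth
train <- lapply(1:20, function(i) generate_phantom(phantom_spec(seed = i)))
held  <- generate_phantom(phantom_spec(seed = 101))

# 1) first-point network: BCE on 1/8-scale boundary-cell targets
fp <- train_first_p(train, first_p_config(profile = "desk"),
                    epochs = 6, seed = 11)

# 2) double-DQN agent: 5,000 env steps (2,000 warm-up + 3,000 updates)
ag <- train_agent(train, fp$net, total_steps = 5000, seed = 11)

# 3) trace the held-out phantom and score it
res <- segment_image(held$image, fp$net, ag$net_eval, epsilon = 0.2, seed = 1)
prf <- precision_recall_fmeasure(res$mask, held$mask)
apd <- average_perpendicular_distance(res$contour, held$contour)
round(c(prf, apd = apd), 3)
```

```
#> precision    recall         f       apd
#>     1.000     0.360     0.529    10.586
```

`precision`/`recall`/`f` score the filled mask against the ground-truth
mask (`f` is the Dice coefficient); `apd` is the mean distance, in pixels,
from traced contour points to the nearest ground-truth boundary point.
Here the agent traced a clean partial lap: every traced pixel lies inside
the true pool (precision 1.0) but the budgeted training left the lap
incomplete (recall 0.36). Desk-scale runs demonstrate the *mechanism* —
the reward trend and per-episode F rise during training, and degrading the
reward to its difference-IoU term alone measurably hurts held-out F — not
the published accuracy, which needs orders of magnitude more optimization
(see the methods vignette's limitations). Training logs (`ag$log`) carry
the per-step reward components, TD loss and per-episode F/APD — the
quantities whose upward trend the acceptance tests check.

## Command line

```sh
EW=$(Rscript -e 'cat(system.file("cli/edgewalk.R", package="edgewalk"))')
Rscript $EW simulate    --n 20 --out phantoms --seed 1
Rscript $EW train-first --manifest phantoms/manifest.tsv --out first.rds
Rscript $EW train-agent --manifest phantoms/manifest.tsv --first first.rds --out agent.rds
Rscript $EW segment     --image phantoms/phantom_001_image.pgm \
                        --first first.rds --agent agent.rds \
                        --gt phantoms/phantom_001_contour.txt --out seg
Rscript $EW evaluate    --pred pred_manifest.tsv --gt gt_manifest.tsv
```

Images and masks are ASCII PGM; contours use the Sunnybrook text dialect
("x y" per line, 0-based, x = column). Configs are JSON
(`--config cfg.json`), mirroring the `env` / `reward` / `dqn` / `first_p`
sections of `run_config()`.

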