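# Lightweight nano-scale variant: inverted-residual (mirb) low-level stages,
# universal inverted bottleneck (muib) mid/high stages, spatial pyramid
# pooling with the narrow 80/160 widths, pointwise projections realising the
# 40-80-128-480-512 channel schedule at the P4/P5 taps, and a pruned
# cross-stage-partial neck. Version 1.
name: yolov11n_plus
num_classes: 2
input_size: 640
layers:
  - {kind: conv_bn, out: 40, kernel: 3, stride: 2}                 # 0  P1/2
  - {kind: mirb, out: 80, kernel: 5, stride: 2, expansion: 2}      # 1  P2/4
  - {kind: mirb, out: 128, kernel: 3, stride: 2, expansion: 2}     # 2  P3/8 (tap)
  - {kind: muib, out: 160, kernel: 3, stride: 2, expansion: 4}     # 3  P4/16
  - {kind: conv_bn, out: 480, kernel: 1, stride: 1}                # 4  P4 tap
  - {kind: muib, out: 160, kernel: 3, stride: 2, expansion: 4, from: 3}  # 5  P5/32
  - {kind: muib, out: 160, kernel: 3, stride: 1, expansion: 4}     # 6
  - {kind: muib, out: 160, kernel: 3, stride: 1, expansion: 4}     # 7
  - {kind: sppf, out: 160, hidden: 80}                             # 8
  - {kind: conv_bn, out: 512, kernel: 1, stride: 1}                # 9  P5 tap
  - {kind: upsample, scale: 2}                                     # 10
  - {kind: concat, from: [10, 4]}                                  # 11
  - {kind: c3k2, out: 128, n: 1, pruned: true, hidden: 20}         # 12
  - {kind: upsample, scale: 2}                                     # 13
  - {kind: concat, from: [13, 2]}                                  # 14
  - {kind: c3k2, out: 64, n: 1, pruned: true, hidden: 16}          # 15 P3 head in
  - {kind: conv_bn, out: 64, kernel: 3, stride: 2}                 # 16
  - {kind: concat, from: [16, 12]}                                 # 17
  - {kind: c3k2, out: 128, n: 1, pruned: true, hidden: 44}         # 18 P4 head in
  - {kind: conv_bn, out: 128, kernel: 3, stride: 2}                # 19
  - {kind: concat, from: [19, 9]}                                  # 20
  - {kind: c3k2, out: 256, n: 1, pruned: true, hidden: 176}        # 21 P5 head in
  - {kind: detect, from: [15, 18, 21]}                             # 22
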