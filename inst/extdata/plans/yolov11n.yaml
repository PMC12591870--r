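# Baseline nano-scale detector layer plan (published topology, 2-class head).
name: yolov11n
num_classes: 2
input_size: 640
layers:
  - {kind: conv_bn, out: 16, kernel: 3, stride: 2}            # 0  P1/2
  - {kind: conv_bn, out: 32, kernel: 3, stride: 2}            # 1  P2/4
  - {kind: c3k2, out: 64, n: 1, e: 0.25}                      # 2
  - {kind: conv_bn, out: 64, kernel: 3, stride: 2}            # 3  P3/8
  - {kind: c3k2, out: 128, n: 1, e: 0.25}                     # 4  (P3 tap)
  - {kind: conv_bn, out: 128, kernel: 3, stride: 2}           # 5  P4/16
  - {kind: c3k2, out: 128, n: 1, c3k: true}                   # 6  (P4 tap)
  - {kind: conv_bn, out: 256, kernel: 3, stride: 2}           # 7  P5/32
  - {kind: c3k2, out: 256, n: 1, c3k: true}                   # 8
  - {kind: sppf, out: 256, hidden: 128}                       # 9
  - {kind: c2psa, n: 1}                                       # 10 (P5 tap)
  - {kind: upsample, scale: 2}                                # 11
  - {kind: concat, from: [11, 6]}                             # 12
  - {kind: c3k2, out: 128, n: 1}                              # 13
  - {kind: upsample, scale: 2}                                # 14
  - {kind: concat, from: [14, 4]}                             # 15
  - {kind: c3k2, out: 64, n: 1}                               # 16 P3 head in
  - {kind: conv_bn, out: 64, kernel: 3, stride: 2}            # 17
  - {kind: concat, from: [17, 13]}                            # 18
  - {kind: c3k2, out: 128, n: 1}                              # 19 P4 head in
  - {kind: conv_bn, out: 128, kernel: 3, stride: 2}           # 20
  - {kind: concat, from: [20, 10]}                            # 21
  - {kind: c3k2, out: 256, n: 1, c3k: true}                   # 22 P5 head in
  - {kind: detect, from: [16, 19, 22]}                        # 23
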