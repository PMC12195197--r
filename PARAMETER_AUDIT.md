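# Parameter audit

The detector is reported upstream with a total of **5216** trainable
parameters. Instantiating the architecture exactly as its hyperparameter
tables describe it, the enumeration below yields **2904** trainable scalars
(convolution weights and biases plus batch-norm scale and shift; BN running
statistics are buffers and excluded). `count_parameters()` on the shipped
default model returns 2904, and the acceptance script reports this computed
value.

## Enumeration of the implemented architecture

Leads-distillation module (13 filters, 1x11 kernels, leaky-ReLU units):

| block | weights | biases | BN | subtotal |
|---|---|---|---|---|
| 2D conv unit, 13 filters 1x11, 1 input channel | 143 | 13 | 26 | 182 |
| depth-wise conv, 13 kernels 1x11 | 143 | 13 | 26 | 182 |
| point-wise conv, 13 filters 1x1x13 | 169 | 13 | 26 | 208 |
| squeeze conv, 1 filter 1x11x13 + sigmoid | 143 | 1 | - | 144 |
| **LDM total** | | | | **716** |

QRS detection module (filter size 3, depth 3, levels 0-2 with kernels
11/17/13, parameter-free max-pool / nearest-neighbour upsampling, 1x1
sigmoid head; a conv unit with kernel k and c input channels costs
`3*k*c + 3 + 6`):

| block | subtotal |
|---|---|
| encoder level 0: units (k=11; c=1,3,3) | 42 + 108 + 108 = 258 |
| encoder level 1: 3 units (k=17, c=3) | 486 |
| bottom level 2: 3 units (k=13, c=3) | 378 |
| decoder level 1: units (k=17; c=6 after concat, then 3,3) | 315 + 162 + 162 = 639 |
| decoder level 0: units (k=11; c=6, 3, 3) | 207 + 108 + 108 = 423 |
| head: 1x1 conv, 3 -> 1 | 4 |
| **U-Net total** | **2188** |

**Grand total: 716 + 2188 = 2904.**

## Why 5216 is not reachable from the published description

An exhaustive search over structured variants of the description was run:
one to three copies of the LDM conv/DS units, bottom-level units on one or
both sides, decoder first-unit (or all-unit) input channels 3 or 6,
head kernel widths 1-31 with 3 or 6 input channels, transposed-convolution
up-sampling (kernel 2 or the level kernel), encoder depths 2-6, BN counted
as 2 or 4 scalars per channel, and channel-doubling across levels. No
combination sums to 5216.

There is also a parity obstruction for the natural family: every U-Net
conv unit with filter size 3 contributes a multiple of 3 parameters
(`3*k*c + 3 + 6`), the LDM contributes 716 = 2 (mod 3), and a biased
head contributes `3*k + 1` = 1 (mod 3), so any such total is divisible by
3 - while 5216 = 2 (mod 3). Matching 5216 exactly would therefore require
a structural departure from the published hyperparameter tables that the
description gives no basis for choosing.

The architecture is therefore implemented faithfully to the tables, the
discrepancy is recorded here rather than hidden by padding the network,
and the tests assert the enumerated count of the shipped architecture
alongside the (failing) reported total.
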