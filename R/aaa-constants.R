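# Shared constants (file name keeps them first in the collate order).

# one-letter codes of the 20 canonical amino acids
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# DNA bases in PWM row order
BASES <- c("A", "C", "G", "T")

# helix positions carried by every detected finger
HELIX_POSITIONS <- c("-2", "-1", "+1", "+2", "+3", "+6", "+9")

# the four specificity positions used in profiles and the recognition code
SPEC_POSITIONS <- c("+6", "+3", "-1", "+2")

# complement in A,C,G,T row order: A<->T, C<->G
COMPLEMENT_IDX <- c(4L, 3L, 2L, 1L)
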