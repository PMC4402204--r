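# Keep per-operation IEEE semantics (no FMA contraction) so the compiled
# day loop is bit-identical to the R reference implementation.
PKG_CXXFLAGS = -ffp-contract=off
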