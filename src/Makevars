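# disable FP contraction so the engine is bit-reproducible against the
# pure-R reference transport implementation
PKG_CXXFLAGS = -ffp-contract=off
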