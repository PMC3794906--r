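# Disable floating-point contraction so the compiled integrator is
# bit-identical to the pure-R reference integrator on FMA-capable targets.
PKG_CXXFLAGS = -ffp-contract=off
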