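Sample	unfiltered	filtered
Leaves	9856027	7951133
Flower buds	9857386	8321249
Seed-13	9148826	8938448
Seed-19	10596879	9135921
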