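dataset	region	constant	variable
Bdelloidea	non-hypervariable	940	90
Bdelloidea	hypervariable	488	185
Monogononta	non-hypervariable	944	167
Monogononta	hypervariable	411	295
Rotifera	non-hypervariable	784	354
Rotifera	hypervariable	359	472
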