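chrY	14500000	14800000	sc1
chrY	15000000	15300000	sc2
chrY	16000000	16300000	sc3
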