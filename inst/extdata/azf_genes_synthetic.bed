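chrY	19505000	19507000	HSFY
chrY	19550000	19552000	HSFY
chrY	23145000	23148000	BPY2
chrY	23178000	23182000	DAZ
chrY	23208000	23212000	DAZ
chrY	23340000	23342000	CDY1
chrY	23375000	23378000	BPY2
chrY	23408000	23412000	DAZ
chrY	23438000	23442000	DAZ
chrY	23470000	23472000	CDY1
chrY	23505000	23508000	BPY2
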