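chrY	14600000	14610000	rep_sc1
chrY	19510000	19512000	rep_P4a
chrY	23005000	23007000	rep_b1
chrY	23040000	23043000	rep_t1
chrY	23040500	23044000	simple_t1
chrY	23175000	23176000	rep_r1
chrY	23250000	23254000	rep_Gr1
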