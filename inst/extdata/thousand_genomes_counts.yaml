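# External comparison cohort: AZFb/c carrier counts among the 1,216 male
# 1000 Genomes samples. The source study reports only the percentages
# (16.0% any CNV, 7.8% duplication-only, 2.3%... deletion-only 6.9%); the
# counts below are the integer reconstruction closest to those percentages
# and are an editable input, not a measured quantity.
total: 1216
any_cnv: 195        # 195/1216 = 16.04%
duplication_only: 95   # 95/1216 = 7.81%
deletion_only: 84      # 84/1216 = 6.91%
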