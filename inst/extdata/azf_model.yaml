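# Default AZFb/c region model.
#
# Coordinates are a synthetic, compact stand-in for the GRCh37 amplicon
# annotation (the family copy counts, unit order, orientations and gene
# content follow the published AZFc architecture; interval sizes are reduced
# so that whole-cohort depth simulation stays cheap). The pipeline itself is
# coordinate-agnostic: point the *_bed entries at a full-scale annotation to
# analyse real data.
#
# BED conventions: 0-based half-open, name in column 4 (amplicon unit id or
# gene symbol). Everything is converted to 1-based closed GRanges on load.

chrom: chrY
amplicons_bed: azf_amplicons_synthetic.bed
masks_bed: azf_masks_synthetic.bed
single_copy_bed: azf_single_copy_synthetic.bed
genes_bed: azf_genes_synthetic.bed

# Genes whose intervals are excluded from depth calling on top of the mask
# track (partial CNVs of DAZ would otherwise distort the red-family depth).
exclude_genes_from_depth: [DAZ]

families:
  b:  {ref_cn: 4, color: blue}
  t:  {ref_cn: 2, color: teal}
  g:  {ref_cn: 3, color: green}
  r:  {ref_cn: 4, color: red}
  Gr: {ref_cn: 1, color: grey}
  "y":  {ref_cn: 2, color: yellow}
  P4: {ref_cn: 2, color: P4-arm}
  P5: {ref_cn: 2, color: P5-arm}
  P6: {ref_cn: 2, color: P6-arm}
  P7: {ref_cn: 2, color: P7-arm}
  P8: {ref_cn: 2, color: P8-arm}

genes:
  DAZ:  {ref_copies: 4}
  BPY2: {ref_copies: 3}
  CDY1: {ref_copies: 2}
  HSFY: {ref_copies: 2}

# Ordered reference structure, proximal -> distal. Orientations are chosen so
# that the NAHR geometry of the classical events holds: b1/b3, b2/b4, g1/g2,
# y1/y2 and r1/r2, r3/r4 are direct-orientation pairs (duplication/deletion
# competent); b2/b3 are inverted and become direct only after the r2/r3
# inversion; palindrome arms (P4..P8, t1/t2) are inverted pairs.
structure:
  - {unit: P8a, family: P8, orientation: "+"}
  - {unit: P8b, family: P8, orientation: "-"}
  - {unit: P7a, family: P7, orientation: "+"}
  - {unit: P7b, family: P7, orientation: "-"}
  - {unit: P6a, family: P6, orientation: "+"}
  - {unit: P6b, family: P6, orientation: "-"}
  - {unit: P5a, family: P5, orientation: "+"}
  - {unit: P5b, family: P5, orientation: "-"}
  - {unit: P4a, family: P4, orientation: "+", genes: {HSFY: 1}}
  - {unit: P4b, family: P4, orientation: "-", genes: {HSFY: 1}}
  - {unit: b1,  family: b,  orientation: "+"}
  - {unit: t1,  family: t,  orientation: "+"}
  - {unit: t2,  family: t,  orientation: "-"}
  - {unit: b2,  family: b,  orientation: "-"}
  - {unit: g1,  family: g,  orientation: "+", genes: {BPY2: 1}}
  - {unit: r1,  family: r,  orientation: "+", genes: {DAZ: 1}}
  - {unit: r2,  family: r,  orientation: "+", genes: {DAZ: 1}}
  - {unit: Gr1, family: Gr, orientation: "+"}
  - {unit: b3,  family: b,  orientation: "+"}
  - {unit: y1,  family: "y",  orientation: "+", genes: {CDY1: 1}}
  - {unit: g2,  family: g,  orientation: "+", genes: {BPY2: 1}}
  - {unit: r3,  family: r,  orientation: "-", genes: {DAZ: 1}}
  - {unit: r4,  family: r,  orientation: "-", genes: {DAZ: 1}}
  - {unit: y2,  family: "y",  orientation: "+", genes: {CDY1: 1}}
  - {unit: g3,  family: g,  orientation: "-", genes: {BPY2: 1}}
  - {unit: b4,  family: b,  orientation: "-"}

# Named NAHR event catalog. Anchors are unit ids resolved against the current
# structure (first occurrence). "aliases" are alternative conventional labels
# for the same operator.
events:
  "b2/b4 duplication":  {kind: duplication, a: b2, b: b4}
  "b2/b4 deletion":     {kind: deletion,    a: b2, b: b4}
  "gr/gr duplication":  {kind: duplication, a: g1, b: g2, aliases: ["g1/g2 duplication"]}
  "gr/gr deletion":     {kind: deletion,    a: g1, b: g2, aliases: ["g1/g2 deletion"]}
  "b1/b3 duplication":  {kind: duplication, a: b1, b: b3}
  "b1/b3 deletion":     {kind: deletion,    a: b1, b: b3}
  "r2/r3 inversion":    {kind: inversion,   a: r2, b: r3}
  "b2/b3 duplication":  {kind: duplication, a: b2, b: b3}
  "b2/b3 deletion":     {kind: deletion,    a: b2, b: b3}
  "b2/b3 rescue":       {kind: duplication, a: b3, b: b4}
  "P4 arm duplication": {kind: micro_duplication, a: P4a}
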