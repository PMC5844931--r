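# Dialect registry for merged circRNA call tables.
# start_basis one_based: the tool reports 1-based inclusive starts and is
# shifted by -1 on read; end coordinates are half-open already and untouched.
ACFS:
  start_basis: one_based
  has_strand: true
  score_columns: [is_annotated_splice]
CIRCexplorer:
  start_basis: zero_based
  has_strand: true
  score_columns: [is_ciRNA]
CIRCexplorer2:
  start_basis: zero_based
  has_strand: true
  score_columns: [is_ciRNA, is_annotated_splice]
circRNA_finder:
  start_basis: one_based
  has_strand: true
  score_columns: []
CIRI:
  start_basis: one_based
  has_strand: true
  score_columns: []
CIRI2:
  start_basis: one_based
  has_strand: true
  score_columns: []
DCC:
  start_basis: one_based
  has_strand: true
  score_columns: []
find_circ:
  start_basis: zero_based
  has_strand: true
  score_columns: [anchor_qual_a, anchor_qual_b]
KNIFE:
  start_basis: zero_based
  has_strand: true
  score_columns: [posterior_probability, is_annotated_splice]
MapSplice:
  start_basis: one_based
  has_strand: true
  score_columns: []
Uroborus:
  start_basis: zero_based
  has_strand: true
  score_columns: []
bed:
  start_basis: zero_based
  has_strand: true
  score_columns: [posterior_probability, anchor_qual_a, anchor_qual_b, is_ciRNA, is_annotated_splice]
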