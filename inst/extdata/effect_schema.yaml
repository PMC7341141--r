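# Default effect-term -> binary-feature schema (SnpEff-style vocabulary).
# 'deleterious: true/false' constrains the SIFT-style call; omitted = any.
is_nonsyn_deleterious:
  terms: [missense_variant]
  deleterious: true
is_nonsyn_tolerated:
  terms: [missense_variant]
  deleterious: false
is_synonymous:
  terms: [synonymous_variant]
is_frameshift:
  terms: [frameshift_variant]
is_stop_gained:
  terms: [stop_gained]
is_stop_lost:
  terms: [stop_lost]
is_splice:
  terms: [splice_region_variant, splice_donor_variant, splice_acceptor_variant]
is_utr:
  terms: [5_prime_UTR_variant, 3_prime_UTR_variant]
is_intron:
  terms: [intron_variant]
is_upstream:
  terms: [upstream_gene_variant]
is_downstream:
  terms: [downstream_gene_variant]
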